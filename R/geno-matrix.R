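#' Construct a genotype matrix
#'
#' The single substrate for every computation in the package: a set of
#' individuals genotyped at biallelic loci, coded as the number of copies of
#' the reference allele (0, 1, 2) with `NA` for missing genotypes.
#'
#' @param dose Integer matrix, individuals in rows and loci in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row names (if absent, taken from
#'   `individual_ids`) identify individuals; column names must match
#'   `loci$id`.
#' @param loci Data frame describing the marker panel with columns `id`,
#'   `chromosome`, `position` (non-negative integer, base pairs), `allele1`
#'   (reference) and `allele2` (alternate).
#' @param individual_ids Optional character vector of unique individual
#'   labels; defaults to `rownames(dose)`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dose`
#'   (integer matrix) and `loci` (data frame).
#' @export
#' @examples
#' gm <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                          dimnames = list(c("a", "b"), c("rs1", "rs2"))),
#'                   loci_table(c("rs1", "rs2")))
#' dim(gm)
geno_matrix <- function(dose, loci, individual_ids = rownames(dose)) {
  if (!is.matrix(dose)) stop("`dose` must be a matrix")
  if (nrow(dose) < 1L || ncol(dose) < 1L)
    stop("genotype matrix needs at least 1 individual and 1 locus")
  storage.mode(dose) <- "integer"
  bad <- !(dose %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dose values must be 0, 1, 2 or NA")
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(dose)))
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (length(individual_ids) != nrow(dose))
    stop("individual_ids length does not match dose rows")
  loci <- validate_loci(loci)
  if (nrow(loci) != ncol(dose))
    stop("loci table rows do not match dose columns")
  if (anyDuplicated(loci$id)) stop("locus ids must be unique")
  rownames(dose) <- individual_ids
  colnames(dose) <- loci$id
  structure(list(dose = dose, loci = loci), class = "geno_matrix")
}

validate_loci <- function(loci) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("id", "chromosome", "position", "allele1", "allele2")
  miss <- setdiff(need, names(loci))
  if (length(miss))
    stop("loci table missing columns: ", paste(miss, collapse = ", "))
  loci$id <- as.character(loci$id)
  loci$chromosome <- as.character(loci$chromosome)
  loci$position <- as.integer(loci$position)
  if (any(loci$position < 0L, na.rm = TRUE)) stop("positions must be >= 0")
  loci[, need]
}

#' Build a minimal locus table
#'
#' Convenience constructor for simulated panels: unlinked loci on one
#' nominal chromosome with consecutive positions and A/B allele labels.
#'
#' @param ids Character vector of locus ids.
#' @param chromosome Chromosome label(s), recycled.
#' @param position Base-pair positions; defaults to 1, 2, ...
#' @param allele1,allele2 Allele labels, recycled.
#' @return Data frame usable as the `loci` argument of [geno_matrix()].
#' @export
loci_table <- function(ids, chromosome = "1", position = seq_along(ids),
                       allele1 = "A", allele2 = "B") {
  n <- length(ids)
  data.frame(id = as.character(ids),
             chromosome = rep_len(as.character(chromosome), n),
             position = rep_len(as.integer(position), n),
             allele1 = rep_len(as.character(allele1), n),
             allele2 = rep_len(as.character(allele2), n),
             stringsAsFactors = FALSE)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dose)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$dose), ncol(x$dose),
              100 * mean(is.na(x$dose))))
  invisible(x)
}

#' Individual ids of a genotype matrix
#' @param gm A [geno_matrix()].
#' @return Character vector of individual labels.
#' @export
individual_ids <- function(gm) rownames(gm$dose)

#' Restrict a genotype matrix to a subset of individuals and/or loci
#'
#' @param gm A [geno_matrix()].
#' @param individuals Character vector of individual ids to keep (default all).
#' @param loci Character vector of locus ids to keep (default all).
#' @return A [geno_matrix()] restricted to the requested rows/columns.
#' @export
subset_geno <- function(gm, individuals = NULL, loci = NULL) {
  dose <- gm$dose
  ltab <- gm$loci
  if (!is.null(individuals)) {
    missing_ids <- setdiff(individuals, rownames(dose))
    if (length(missing_ids))
      stop("unknown individuals: ", paste(missing_ids, collapse = ", "))
    dose <- dose[individuals, , drop = FALSE]
  }
  if (!is.null(loci)) {
    missing_loci <- setdiff(loci, ltab$id)
    if (length(missing_loci))
      stop("unknown loci: ", paste(missing_loci, collapse = ", "))
    keep <- match(loci, ltab$id)
    dose <- dose[, keep, drop = FALSE]
    ltab <- ltab[keep, , drop = FALSE]
    rownames(ltab) <- NULL
  }
  geno_matrix(dose, ltab)
}

#' Construct a subpopulation map
#'
#' Assigns every individual to a named subpopulation and carries the
#' subpopulation-level metadata used throughout the analysis: which pool is
#' the outgroup (always retained, never a leave-one-out target by default),
#' and optional group / continent labels used for descriptive merging.
#'
#' @param assignment Named character vector mapping individual id to
#'   subpopulation label, or a data frame with columns `individual_id` and
#'   `subpop`.
#' @param outgroup Label of the outgroup pool, or `NULL` for none. At most
#'   one pool may be flagged.
#' @param group Optional named character vector: subpopulation label ->
#'   group label (e.g. "Creole", "Mediterranean").
#' @param continent Optional named character vector: subpopulation label ->
#'   continent label.
#' @return An object of class `subpop_map`.
#' @export
subpop_map <- function(assignment, outgroup = NULL, group = NULL,
                       continent = NULL) {
  if (is.data.frame(assignment)) {
    a <- stats::setNames(as.character(assignment$subpop),
                         as.character(assignment$individual_id))
  } else {
    a <- stats::setNames(as.character(assignment), names(assignment))
  }
  if (is.null(names(a)) || any(!nzchar(names(a))))
    stop("every individual in the assignment must be named")
  if (anyDuplicated(names(a))) stop("duplicated individual ids in assignment")
  if (!is.null(outgroup)) {
    outgroup <- as.character(outgroup)
    if (length(outgroup) != 1L)
      stop("at most one outgroup pool per analysis")
    if (!outgroup %in% a) stop("outgroup label not present in assignment")
  }
  structure(list(assignment = a, outgroup = outgroup,
                 group = group, continent = continent),
            class = "subpop_map")
}

#' @export
print.subpop_map <- function(x, ...) {
  n <- table(x$assignment)
  cat(sprintf("<subpop_map> %d individuals in %d subpopulations\n",
              length(x$assignment), length(n)))
  if (!is.null(x$outgroup)) cat("  outgroup:", x$outgroup, "\n")
  invisible(x)
}

#' Subpopulation labels of a map
#' @param subs A [subpop_map()].
#' @return Character vector of subpopulation labels, outgroup last.
#' @export
subpop_labels <- function(subs) {
  labs <- unique(unname(subs$assignment))
  if (!is.null(subs$outgroup))
    labs <- c(setdiff(labs, subs$outgroup), subs$outgroup)
  labs
}

#' Subpopulation sample sizes
#' @param subs A [subpop_map()].
#' @return Named integer vector of individuals per subpopulation.
#' @export
subpop_sizes <- function(subs) {
  tab <- table(subs$assignment)
  stats::setNames(as.integer(tab), names(tab))[subpop_labels(subs)]
}

check_assignment <- function(gm, subs) {
  ids <- individual_ids(gm)
  unassigned <- setdiff(ids, names(subs$assignment))
  if (length(unassigned))
    stop("individuals without subpopulation assignment: ",
         paste(utils::head(unassigned, 5), collapse = ", "))
  invisible(TRUE)
}

#' Restrict a subpopulation map to a set of individuals or subpopulations
#' @param subs A [subpop_map()].
#' @param individuals Individual ids to keep (default all).
#' @param subpops Subpopulation labels to keep (default all).
#' @return A [subpop_map()] restricted accordingly; the outgroup flag is
#'   dropped if its pool is removed.
#' @export
subset_subpops <- function(subs, individuals = NULL, subpops = NULL) {
  a <- subs$assignment
  if (!is.null(subpops)) a <- a[a %in% subpops]
  if (!is.null(individuals)) a <- a[names(a) %in% individuals]
  og <- subs$outgroup
  if (!is.null(og) && !og %in% a) og <- NULL
  subpop_map(a, outgroup = og, group = subs$group,
             continent = subs$continent)
}
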