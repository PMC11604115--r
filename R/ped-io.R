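#' Read genotypes from PLINK text PED/MAP files
#'
#' Parses the PLINK text dialect: PED columns are family (used here as the
#' subpopulation label), individual id, father (ignored), mother (ignored),
#' sex (ignored), phenotype (ignored), followed by two allele fields per
#' locus; MAP columns are chromosome, locus id, genetic distance (ignored)
#' and base-pair position. The missing allele code is `"0"`; a genotype pair
#' containing it is read as missing.
#'
#' By default the reference allele of each locus is the first non-missing
#' allele encountered in file order (row-major over the two allele columns),
#' which makes the dose coding deterministic for a given file. All diversity
#' statistics downstream are invariant to this choice; to recover an exact
#' dose-level round trip with [write_ped_map()] (whose files carry no allele
#' order), pass the writer's reference alleles via `ref_alleles`.
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file.
#' @param ref_alleles Optional character vector (one per locus) fixing the
#'   reference allele; overrides the first-observed convention.
#' @return A list with elements `geno` (a [geno_matrix()]) and `subs`
#'   (a [subpop_map()] built from the family column, with no outgroup flag).
#' @export
read_ped_map <- function(ped_path, map_path, ref_alleles = NULL) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) != 4L)
    stop("MAP file must have 4 columns, found ", ncol(map))
  n_loci <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PED file is empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  expected <- 6L + 2L * n_loci
  bad <- which(len != expected)
  if (length(bad))
    stop(sprintf("PED parse error at line %d: %d fields, expected %d",
                 bad[1], len[bad[1]], expected))
  ped <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  fam <- ped[, 1]
  ids <- ped[, 2]
  if (anyDuplicated(ids)) {
    ids <- paste(fam, ids, sep = "_")
    if (anyDuplicated(ids)) stop("duplicated individual ids in PED")
  }
  al <- ped[, -(1:6), drop = FALSE]
  n <- nrow(al)
  a1 <- al[, seq(1L, 2L * n_loci, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_loci, by = 2L), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    a1[half] <- "0"
    a2[half] <- "0"
  }
  dose <- matrix(NA_integer_, n, n_loci)
  ref <- alt <- character(n_loci)
  for (l in seq_len(n_loci)) {
    # interleave columns to recover strict file order within each row
    seen <- as.vector(rbind(a1[, l], a2[, l]))
    seen <- seen[seen != "0"]
    alleles <- unique(seen)
    if (length(alleles) > 2L)
      stop(sprintf("locus %s carries %d alleles; only biallelic loci supported",
                   map[l, 2], length(alleles)))
    if (!is.null(ref_alleles)) {
      if (length(ref_alleles) != n_loci)
        stop("ref_alleles must have one entry per locus")
      r <- ref_alleles[l]
      other <- setdiff(alleles, r)
      if (length(other) > 1L)
        stop(sprintf("locus %s: ref_alleles entry '%s' inconsistent with file",
                     map[l, 2], r))
      alleles <- c(r, if (length(other)) other else if (r == "A") "B" else "A")
    } else {
      if (length(alleles) == 0L) alleles <- c("A", "B")
      if (length(alleles) == 1L)
        alleles <- c(alleles, if (alleles == "A") "B" else "A")
    }
    ref[l] <- alleles[1]
    alt[l] <- alleles[2]
    d <- (a1[, l] == ref[l]) + (a2[, l] == ref[l])
    d[a1[, l] == "0"] <- NA_integer_
    dose[, l] <- d
  }
  loci <- data.frame(id = map[, 2], chromosome = map[, 1],
                     position = as.integer(map[, 4]),
                     allele1 = ref, allele2 = alt,
                     stringsAsFactors = FALSE)
  gm <- geno_matrix(dose, loci, individual_ids = ids)
  subs <- subpop_map(stats::setNames(fam, ids))
  list(geno = gm, subs = subs)
}

#' Write genotypes to PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: the subpopulation label is written as the
#' PED family field, father/mother/sex are written as 0 and the phenotype
#' as -9. Missing genotypes are written as `"0 0"`.
#'
#' @param gm A [geno_matrix()].
#' @param subs A [subpop_map()] covering every individual in `gm`.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(gm, subs, ped_path, map_path) {
  if (ncol(gm$dose) < 1L) stop("refusing to write a genotype file with no loci")
  check_assignment(gm, subs)
  loci <- gm$loci
  map <- data.frame(loci$chromosome, loci$id, 0L, loci$position)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(gm$dose)
  L <- ncol(gm$dose)
  geno_fields <- matrix("0", n, 2L * L)
  for (l in seq_len(L)) {
    d <- gm$dose[, l]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, loci$allele1[l], loci$allele2[l]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, loci$allele1[l], loci$allele2[l]))
    geno_fields[, 2L * l - 1L] <- a1
    geno_fields[, 2L * l] <- a2
  }
  ids <- individual_ids(gm)
  lead <- cbind(unname(subs$assignment[ids]), ids, "0", "0", "0", "-9")
  out <- apply(cbind(lead, geno_fields), 1L, paste, collapse = " ")
  writeLines(out, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}
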