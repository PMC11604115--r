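#' Principal component analysis of genotypes
#'
#' Standard genotype PCA: doses are centered by `2 p` and scaled by
#' `sqrt(2 p (1 - p))` per locus (plug-in frequency `p`); missing doses are
#' mean-imputed per locus for this operation only (the diversity modules
#' never use imputed values). Eigendecomposition of the individual-by-
#' individual covariance; the sign of each component is fixed by making its
#' largest-magnitude entry positive, so results are deterministic.
#'
#' @param gm A [geno_matrix()] with at least 2 individuals and 2
#'   polymorphic loci.
#' @param m Number of components to report (default 10, capped by rank).
#' @param subs Optional [subpop_map()]; if given, per-subpopulation mean
#'   eigenvectors are returned as well.
#' @return An object of class `pca_result`: list with `vectors`
#'   (individuals x m), `values` (eigenvalues), `prop_var` (proportion of
#'   variance per component) and, when `subs` is given, `subpop_means`.
#' @export
pca_genotypes <- function(gm, m = 10L, subs = NULL) {
  X <- gm$dose
  if (nrow(X) < 2L) stop("PCA needs at least 2 individuals")
  obs <- !is.na(X)
  p <- colSums(X * obs, na.rm = TRUE) / (2 * colSums(obs))
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("PCA needs at least 2 polymorphic loci")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  eig <- eigen(K, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  m <- min(m, sum(vals > 1e-12))
  if (m < 1L) stop("zero-variance data: no principal components")
  vec <- eig$vectors[, seq_len(m), drop = FALSE]
  for (c_i in seq_len(m)) {
    j <- which.max(abs(vec[, c_i]))
    if (vec[j, c_i] < 0) vec[, c_i] <- -vec[, c_i]
  }
  rownames(vec) <- rownames(X)
  colnames(vec) <- paste0("PC", seq_len(m))
  out <- list(vectors = vec, values = vals[seq_len(m)],
              prop_var = vals[seq_len(m)] / sum(vals))
  if (!is.null(subs)) {
    grp <- factor(subs$assignment[rownames(vec)])
    out$subpop_means <- rowsum(vec, grp) / as.vector(table(grp))
  }
  structure(out, class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d individuals, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$vectors), ncol(x$vectors), 100 * x$prop_var[1],
              if (length(x$prop_var) > 1) 100 * x$prop_var[2] else NA))
  invisible(x)
}

#' Classify subpopulations by contribution sign and sample size
#'
#' Cross-classifies each subpopulation by the signs of its total
#' contributions to gene diversity (`cHT`) and allelic richness (`cAT`)
#' (four classes: `++`, `+-`, `--`, `-+`) and by a sample-size scheme.
#'
#' @param contrib A [marginal_contributions()] table.
#' @param size_scheme `"lt10"` (< 10 vs >= 10), `"lt20"` (< 20 vs >= 20) or
#'   `"three"` (< 10, 10-19, >= 20).
#' @param tie `"positive"` or `"negative"`: which side an exactly-zero
#'   contribution falls on.
#' @return An object of class `sign_classification`: list with `table`
#'   (data frame: subpopulation, n, size_class, sign_class) and `xtab`
#'   (size class x sign class contingency table).
#' @export
classify_signs <- function(contrib,
                           size_scheme = c("lt10", "lt20", "three"),
                           tie = c("positive", "negative")) {
  size_scheme <- match.arg(size_scheme)
  tie <- match.arg(tie)
  sgn <- function(x) {
    pos <- if (tie == "positive") x >= 0 else x > 0
    ifelse(pos, "+", "-")
  }
  sign_class <- paste0(sgn(contrib$cHT), sgn(contrib$cAT))
  size_class <- switch(size_scheme,
    lt10 = ifelse(contrib$n < 10, "<10", ">=10"),
    lt20 = ifelse(contrib$n < 20, "<20", ">=20"),
    three = ifelse(contrib$n < 10, "<10",
                   ifelse(contrib$n < 20, "10-19", ">=20")))
  tab <- data.frame(subpopulation = contrib$subpopulation, n = contrib$n,
                    size_class = size_class, sign_class = sign_class,
                    stringsAsFactors = FALSE)
  lev <- c("++", "+-", "--", "-+")
  xtab <- table(factor(size_class), factor(sign_class, levels = lev))
  structure(list(table = tab, xtab = xtab, size_scheme = size_scheme),
            class = "sign_classification")
}

#' @export
print.sign_classification <- function(x, ...) {
  cat("<sign_classification>\n")
  print(x$xtab)
  invisible(x)
}

#' Generalized Cochran-Mantel-Haenszel test
#'
#' Stratified R x C test of general association; with a single stratum the
#' statistic equals `(N - 1) / N` times the Pearson chi-square. Strata with
#' an all-zero margin are dropped with a warning.
#'
#' @param tables An R x C matrix (single stratum), an R x C x K array, or a
#'   list of R x C matrices (one per stratum).
#' @return List with `statistic`, `df` and `p.value`.
#' @export
#' @examples
#' cmh_test(matrix(c(10, 20, 20, 10), 2, 2))
cmh_test <- function(tables) {
  if (is.matrix(tables)) tables <- list(tables)
  if (is.array(tables) && length(dim(tables)) == 3L)
    tables <- lapply(seq_len(dim(tables)[3]), function(k) tables[, , k])
  keep <- vapply(tables, function(t) {
    sum(t) >= 2 && !(any(rowSums(t) == 0) && any(colSums(t) == 0))
  }, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " stratum/strata with an all-zero margin dropped")
    tables <- tables[keep]
  }
  if (!length(tables)) stop("no usable stratum")
  ## collapse zero rows/columns consistently across strata
  tot <- Reduce(`+`, tables)
  tables <- lapply(tables, function(t)
    t[rowSums(tot) > 0, colSums(tot) > 0, drop = FALSE])
  R <- nrow(tables[[1]]); C <- ncol(tables[[1]])
  if (R < 2L || C < 2L) stop("need at least 2 rows and 2 columns")
  q <- (R - 1L) * (C - 1L)
  d <- rep(0, q)
  V <- matrix(0, q, q)
  for (t in tables) {
    n <- sum(t)
    r <- rowSums(t); cc <- colSums(t)
    u <- as.vector(t[-R, -C, drop = FALSE])
    m <- as.vector(outer(r[-R], cc[-C]) / n)
    ## multivariate hypergeometric covariance of the cell counts
    Rm <- diag(r[-R], R - 1L) * n - outer(r[-R], r[-R])
    Cm <- diag(cc[-C], C - 1L) * n - outer(cc[-C], cc[-C])
    d <- d + (u - m)
    V <- V + kronecker(Cm, Rm) / (n^2 * (n - 1))
  }
  stat <- if (all(abs(d) < 1e-12)) 0 else drop(crossprod(d, solve(V, d)))
  list(statistic = stat, df = q,
       p.value = stats::pchisq(stat, df = q, lower.tail = FALSE))
}

#' Pearson and Spearman correlations between paired estimates
#'
#' Pairs with a non-finite value in either vector (e.g. infinite Ne
#' estimates) are excluded, with the exclusion count reported. Spearman is
#' computed as Pearson on mid-ranks (average ranks for ties); p-values use
#' the t-distribution approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `pearson`, `spearman`, `p_pearson`, `p_spearman`,
#'   `n_used` and `n_excluded`.
#' @export
paired_correlations <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 complete finite pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_,
                p_pearson = NA_real_, p_spearman = NA_real_,
                n_used = n, n_excluded = sum(!ok)))
  t_p <- function(r) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  r_p <- stats::cor(x, y)
  r_s <- stats::cor(rank(x), rank(y))
  list(pearson = r_p, spearman = r_s,
       p_pearson = if (abs(r_p) < 1) t_p(r_p) else 0,
       p_spearman = if (abs(r_s) < 1) t_p(r_s) else 0,
       n_used = n, n_excluded = sum(!ok))
}
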