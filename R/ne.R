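## Contemporary effective population size per subpopulation.
##
## Two molecular methods: the linkage-disequilibrium method (composite
## dose-correlation r2 in excess of its sampling expectation, with the
## random-mating small-sample bias corrections of the LD-Ne literature and
## a minor-allele-frequency screen Pcrit), and the molecular-coancestry
## method (excess identity-in-state among pair members, with loci
## re-weighted towards small expected homozygosity / balanced allele
## frequencies).  95% confidence intervals by jackknife on the drift-signal
## scale: delete-one-individual for LD, delete-one-locus for coancestry.

## Random-mating bias-correction constants (sample-size expectation of the
## composite r2 and the matching quadratic inversion from drift signal to
## Ne), two sample-size regimes.  Waples (2006) Conserv Genet 7:167-184;
## Waples & Do (2008) Mol Ecol Resour 8:753-756 (NeEstimator's LD method).
ld_expected_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2
  else 0.0018 + 0.907 / S + 4.44 / S^2
}

ld_ne_from_drift <- function(r2_drift, S) {
  if (!is.finite(r2_drift) || r2_drift <= 0) return(Inf)
  if (S >= 30) {
    disc <- max(0, 1 / 9 - 2.76 * r2_drift)
    (1 / 3 + sqrt(disc)) / (2 * r2_drift)
  } else {
    disc <- max(0, 0.308^2 - 2.08 * r2_drift)
    (0.308 + sqrt(disc)) / (2 * r2_drift)
  }
}

#' Squared dose correlation between two loci
#'
#' Composite (Burrows-style) linkage disequilibrium for unphased genotypes:
#' the squared Pearson correlation of the two dose vectors over individuals
#' with both loci observed.
#'
#' @param gm A [geno_matrix()], typically restricted to one subpopulation.
#' @param a,b Locus ids or column indices.
#' @return `r^2` in `[0, 1]`, or `NA` if fewer than 2 complete cases or
#'   either locus is monomorphic over the complete cases.
#' @export
pairwise_r2 <- function(gm, a, b) {
  x <- gm$dose[, a]
  y <- gm$dose[, b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Window-based LD pruning
#'
#' Greedy within-window pruning per chromosome: within each window of
#' `window` consecutive loci, scan pairs in order and drop the later-indexed
#' locus of any retained pair with `r^2 >` `r2max`; slide the window by
#' `step` loci. Deterministic given the input locus order (loci must be
#' ordered by chromosome and position).
#'
#' @param gm A [geno_matrix()] (one subpopulation, or the pooled data).
#' @param window Loci per window (default 50).
#' @param step Window shift in loci (default 10).
#' @param r2max Pairwise `r^2` threshold (default 0.2).
#' @return An object of class `pruned_panel`: list with `retained` (locus
#'   ids), `removed` (locus ids) and the parameters.
#' @export
ld_prune <- function(gm, window = 50L, step = 10L, r2max = 0.2) {
  loci <- gm$loci
  ord <- order(loci$chromosome, loci$position)
  if (any(ord != seq_along(ord))) {
    gm <- subset_geno(gm, loci = loci$id[ord])
    loci <- gm$loci
  }
  keep <- rep(TRUE, nrow(loci))
  for (chr in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == chr)
    if (length(idx) < 2L) next
    starts <- seq(1L, length(idx), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      if (length(win) < 2L) next
      active <- win[keep[win]]
      if (length(active) < 2L) next
      r2 <- suppressWarnings(
        stats::cor(gm$dose[, active, drop = FALSE],
                   use = "pairwise.complete.obs")^2)
      for (ai in seq_len(length(active) - 1L)) {
        if (!keep[active[ai]]) next
        for (bi in (ai + 1L):length(active)) {
          if (!keep[active[bi]]) next
          if (isTRUE(r2[ai, bi] > r2max)) keep[active[bi]] <- FALSE
        }
      }
    }
  }
  structure(list(retained = loci$id[keep], removed = loci$id[!keep],
                 window = as.integer(window), step = as.integer(step),
                 r2max = r2max),
            class = "pruned_panel")
}

#' @export
print.pruned_panel <- function(x, ...) {
  cat(sprintf("<pruned_panel> %d retained / %d removed (window %d, step %d, r2 <= %g)\n",
              length(x$retained), length(x$removed), x$window, x$step,
              x$r2max))
  invisible(x)
}

## mean Burrows r2 over all locus pairs; general path tolerating missing
## doses (per-pair complete cases)
ld_mean_r2_general <- function(X) {
  L <- ncol(X)
  vals <- c()
  sizes <- c()
  for (a in seq_len(L - 1L)) {
    xa <- X[, a]
    for (b in (a + 1L):L) {
      xb <- X[, b]
      ok <- !is.na(xa) & !is.na(xb)
      S <- sum(ok)
      if (S < 3L) next
      x <- xa[ok]; y <- xb[ok]
      pa <- mean(x) / 2; pb <- mean(y) / 2
      dena <- pa * (1 - pa); denb <- pb * (1 - pb)
      if (dena <= 0 || denb <= 0) next
      D <- (S / (S - 1)) * (mean(x * y) / 2 - 2 * pa * pb)
      vals <- c(vals, D^2 / (dena * denb))
      sizes <- c(sizes, S)
    }
  }
  if (!length(vals)) return(list(mean_r2 = NA_real_, n_pairs = 0L,
                                 S_harm = NA_real_))
  list(mean_r2 = mean(vals), n_pairs = length(vals),
       S_harm = 1 / mean(1 / sizes))
}

#' Effective population size from linkage disequilibrium
#'
#' Loci with minor-allele frequency below `pcrit` (within this sample) are
#' excluded; the mean squared Burrows composite correlation (unphased
#' genotypes, no phasing assumed) over all retained locus pairs is reduced
#' by its random-mating sampling expectation for the harmonic-mean
#' complete-case sample size `S` — the expectation the published
#' small-sample corrections are calibrated for — and the resulting drift
#' signal is inverted to an estimate of `Ne`. A drift signal `<= 0` yields
#' `Ne = Inf` (no detectable drift). The 95% confidence interval is a
#' delete-one-individual jackknife built on the drift-signal scale and then
#' transformed, so an interval crossing zero has an infinite upper bound.
#'
#' @param gm A [geno_matrix()] restricted to one subpopulation.
#' @param panel Optional [ld_prune()] result (or character vector of locus
#'   ids) restricting the loci used.
#' @param pcrit Minor-allele-frequency screen (default 0.05).
#' @param jackknife Compute the jackknife confidence interval?
#' @return An object of class `ne_estimate` with fields `method`, `point`,
#'   `ci_low`, `ci_high`, `pcrit`, `n_loci_used`, `n_pairs_used`,
#'   `S_harmonic`, `r2_mean` and `r2_drift`.
#' @export
ne_ld <- function(gm, panel = NULL, pcrit = 0.05, jackknife = TRUE) {
  if (!is.null(panel)) {
    ids <- if (inherits(panel, "pruned_panel")) panel$retained else panel
    gm <- subset_geno(gm, loci = intersect(gm$loci$id, ids))
  }
  X <- gm$dose
  n <- nrow(X)
  if (n < 10L) warning("fewer than 10 individuals: LD Ne will be imprecise")
  obs <- !is.na(X)
  p <- colSums(X * obs, na.rm = TRUE) / (2 * colSums(obs))
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= pcrit & maf > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 polymorphic loci after the Pcrit screen")
  X <- X[, keep, drop = FALSE]
  complete <- !anyNA(X)
  if (complete) {
    st <- mean_r2_complete(X * 1.0, jackknife)
    S <- n
    jack <- if (jackknife) st$jack else NULL
    jack_S <- rep(n - 1L, length(jack))
  } else {
    st <- ld_mean_r2_general(X)
    S <- st$S_harm
    jack <- NULL
    if (jackknife) {
      jack <- numeric(n)
      jack_S <- numeric(n)
      for (k in seq_len(n)) {
        r <- ld_mean_r2_general(X[-k, , drop = FALSE])
        jack[k] <- r$mean_r2
        jack_S[k] <- r$S_harm
      }
    }
  }
  drift <- st$mean_r2 - ld_expected_r2(S)
  point <- ld_ne_from_drift(drift, S)
  ci <- c(NA_real_, NA_real_)
  if (jackknife && length(jack)) {
    ok <- is.finite(jack)
    if (sum(!ok) > 0.05 * length(jack))
      warning("more than 5% of jackknife replicates failed")
    theta <- jack[ok] - vapply(jack_S[ok], ld_expected_r2, numeric(1))
    m <- length(theta)
    se <- sqrt((m - 1) / m * sum((theta - mean(theta))^2))
    lo <- drift - 1.96 * se
    hi <- drift + 1.96 * se
    ci <- c(ld_ne_from_drift(hi, S), ld_ne_from_drift(lo, S))
  }
  structure(list(method = "LD", point = point, ci_low = ci[1],
                 ci_high = ci[2], pcrit = pcrit,
                 n_loci_used = ncol(X), n_pairs_used = st$n_pairs,
                 S_harmonic = S, r2_mean = st$mean_r2, r2_drift = drift),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate %s> point = %.3g  95%% CI [%.3g, %.3g]  (loci = %d)\n",
              x$method, x$point, x$ci_low, x$ci_high, x$n_loci_used))
  invisible(x)
}

#' Molecular similarity (identity in state) between two individuals
#'
#' The mean identity of the four allele comparisons between two diploid
#' genotypes at one locus: `s = (x_i x_j + (2 - x_i)(2 - x_j)) / 4` for
#' doses `x`.
#'
#' @param gm A [geno_matrix()].
#' @param i,j Individual ids or row indices.
#' @param locus Locus id or column index.
#' @return Similarity in `[0, 1]`, or `NA` if either dose is missing.
#' @export
molecular_similarity <- function(gm, i, j, locus) {
  xi <- gm$dose[i, locus]
  xj <- gm$dose[j, locus]
  (xi * xj + (2 - xi) * (2 - xj)) / 4
}

## per-pair weighted kinship sums; returns numerator and weight matrices
coancestry_sums <- function(X) {
  obs <- !is.na(X)
  p <- colSums(X * obs, na.rm = TRUE) / (2 * colSums(obs))
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("fewer than 2 polymorphic loci")
  X <- X[, poly, drop = FALSE]
  obs <- obs[, poly, drop = FALSE]
  p <- p[poly]
  h <- p^2 + (1 - p)^2
  X0 <- X; X0[!obs] <- 0
  Y0 <- 2 - X; Y0[!obs] <- 0
  s_sum <- (tcrossprod(X0) + tcrossprod(Y0)) / 4
  Hsum <- tcrossprod(obs * rep(h, each = nrow(obs)), obs + 0)
  W <- tcrossprod(obs + 0) - Hsum
  list(numer = s_sum - Hsum, W = W, X = X, obs = obs, h = h,
       n_loci = length(h))
}

#' Effective population size from molecular coancestry
#'
#' Per locus, the unrelated-pair expectation of identity in state is the
#' expected homozygosity `h_l = sum(p_a^2)`; the per-pair kinship at that
#' locus is `(s_l - h_l) / (1 - h_l)`. Loci are combined with weights
#' `w_l = 1 - h_l`, which up-weights loci with small expected homozygosity
#' and balanced allele frequencies.
#'
#' Because `h_l` is computed from the sample's own allele frequencies, the
#' raw mean pairwise kinship is relative to the sample itself and averages
#' about `-1/(2n - 1)` even for strongly related samples. The estimator
#' therefore rescales to an absolute base in which a non-inbred
#' individual's self-coancestry is 1/2: with `m_s` the mean self-kinship
#' and `m_p` the mean pair kinship on the relative scale, the base mean
#' coancestry is `gbar = (1/2 - m_s) / (1 - m_s)` and
#' `f1 = m_p (1 - gbar) + gbar`. The estimate is `Ne = 1 / (2 f1)` when
#' `f1 > 0`, else `Inf`. The 95% confidence interval is a delete-one-locus
#' jackknife on the `f1` scale; an interval crossing zero has an infinite
#' upper bound.
#'
#' @param gm A [geno_matrix()] restricted to one subpopulation
#'   (at least 3 individuals).
#' @param jackknife Compute the jackknife confidence interval?
#' @return An object of class `ne_estimate` with fields `method`, `point`,
#'   `ci_low`, `ci_high`, `n_loci_used`, `n_pairs_used` and `f1`.
#' @export
ne_coancestry <- function(gm, jackknife = TRUE) {
  X <- gm$dose
  n <- nrow(X)
  if (n < 3L) stop("coancestry Ne needs at least 3 individuals")
  cs <- coancestry_sums(X)
  f1_from_sums <- function(numer, W) {
    ut <- upper.tri(numer)
    ok <- ut & W > 0
    if (!any(ok)) return(NA_real_)
    m_p <- mean(numer[ok] / W[ok])
    ds <- diag(W) > 0
    if (!any(ds)) return(NA_real_)
    m_s <- mean(diag(numer)[ds] / diag(W)[ds])
    if (m_s >= 1) return(NA_real_)
    gbar <- (0.5 - m_s) / (1 - m_s)
    m_p * (1 - gbar) + gbar
  }
  if (!any(upper.tri(cs$numer) & cs$W > 0))
    stop("no individual pair shares a polymorphic locus")
  f1 <- f1_from_sums(cs$numer, cs$W)
  point <- if (is.finite(f1) && f1 > 0) 1 / (2 * f1) else Inf
  ci <- c(NA_real_, NA_real_)
  if (jackknife) {
    L <- cs$n_loci
    if (L < 5L) warning("fewer than 5 loci: jackknife CI unreliable")
    f1_jack <- numeric(L)
    for (l in seq_len(L)) {
      xl <- cs$X[, l]
      ol <- cs$obs[, l] + 0
      xl0 <- ifelse(ol == 1, xl, 0)
      yl0 <- ifelse(ol == 1, 2 - xl, 0)
      c_l <- (tcrossprod(xl0) + tcrossprod(yl0)) / 4 -
        cs$h[l] * tcrossprod(ol)
      w_l <- tcrossprod(ol) * (1 - cs$h[l])
      f1_jack[l] <- f1_from_sums(cs$numer - c_l, cs$W - w_l)
    }
    okj <- is.finite(f1_jack)
    if (sum(!okj) > 0.05 * L)
      warning("more than 5% of jackknife replicates failed")
    theta <- f1_jack[okj]
    m <- length(theta)
    se <- sqrt((m - 1) / m * sum((theta - mean(theta))^2))
    lo <- f1 - 1.96 * se
    hi <- f1 + 1.96 * se
    ci <- c(if (hi > 0) 1 / (2 * hi) else Inf,
            if (lo > 0) 1 / (2 * lo) else Inf)
  }
  n_pairs <- sum(upper.tri(cs$numer) & cs$W > 0)
  structure(list(method = "coancestry", point = point, ci_low = ci[1],
                 ci_high = ci[2], pcrit = NA_real_,
                 n_loci_used = cs$n_loci, n_pairs_used = n_pairs,
                 S_harmonic = NA_real_, f1 = f1),
            class = "ne_estimate")
}

#' Jackknife 95% confidence interval for an Ne estimate
#'
#' Convenience wrapper: re-runs [ne_ld()] (delete-one-individual jackknife)
#' or [ne_coancestry()] (delete-one-locus jackknife) and returns the
#' confidence bounds. Intervals are built on the drift-signal scale
#' (`r2_drift` or `f1`) and transformed to `Ne`, so an interval crossing
#' zero yields an infinite upper bound.
#'
#' @param gm A [geno_matrix()] restricted to one subpopulation.
#' @param method `"LD"` or `"coancestry"`.
#' @param ... Passed to the estimator.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
jackknife_ci <- function(gm, method = c("LD", "coancestry"), ...) {
  method <- match.arg(method)
  est <- if (method == "LD") ne_ld(gm, jackknife = TRUE, ...)
  else ne_coancestry(gm, jackknife = TRUE, ...)
  c(ci_low = est$ci_low, ci_high = est$ci_high)
}

#' Ne estimates for every subpopulation
#'
#' Runs both molecular methods per subpopulation and collects the results
#' in a table mirroring supplementary-style reporting.
#'
#' @param gm A [geno_matrix()].
#' @param subs A [subpop_map()].
#' @param panel Optional [ld_prune()] result used by the LD method.
#' @param pcrit Minor-allele-frequency screen for the LD method.
#' @param jackknife Compute confidence intervals?
#' @param min_n Skip subpopulations smaller than this (default 3).
#' @return Data frame with columns `subpopulation`, `method`, `point`,
#'   `ci_low`, `ci_high`, `pcrit`, `n_loci_used`, `S_harmonic`.
#' @export
ne_table <- function(gm, subs, panel = NULL, pcrit = 0.05,
                     jackknife = TRUE, min_n = 3L) {
  check_assignment(gm, subs)
  rows <- list()
  for (sp in subpop_labels(subs)) {
    ids <- names(subs$assignment)[subs$assignment == sp]
    if (length(ids) < min_n) next
    sub_gm <- subset_geno(gm, individuals = ids)
    for (method in c("LD", "coancestry")) {
      est <- tryCatch({
        if (method == "LD")
          ne_ld(sub_gm, panel = panel, pcrit = pcrit, jackknife = jackknife)
        else ne_coancestry(sub_gm, jackknife = jackknife)
      }, error = function(e) NULL)
      if (is.null(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subpopulation = sp, method = est$method, point = est$point,
        ci_low = est$ci_low, ci_high = est$ci_high, pcrit = est$pcrit,
        n_loci_used = est$n_loci_used, S_harmonic = est$S_harmonic,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
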