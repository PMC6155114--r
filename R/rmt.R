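# Random-matrix-theory threshold selection. The adjacency spectrum of a
# correlation matrix thresholded too low behaves like a correlated random
# matrix (GOE: Wigner-surmise spacing, level repulsion); once the threshold
# isolates the modular blocks the spectrum is a superposition of independent
# block spectra and the nearest-neighbour spacing distribution (NNSD) becomes
# Poisson. The chosen threshold is the first grid point from which the NNSD
# is stably Poisson.

#' Unfolded eigenvalue spacings
#'
#' Sorts the eigenvalues, removes degenerate levels (duplicates within
#' 1e-10 — e.g. the exact-zero eigenvalues that small graph fragments such
#' as paths and stars contribute, which would otherwise flood the spacing
#' histogram at zero), unfolds the spectrum by a cubic smoothing spline fit
#' of the empirical cumulative spectral density evaluated at the
#' eigenvalues, and returns successive differences normalised to mean 1.
#' Unfolding removes the system-specific mean level density so the spacing
#' statistics can be compared with the universal Poisson / GOE laws.
#'
#' @param m symmetric real matrix with at least `min_eigen` rows after
#'   degeneracy removal.
#' @param min_eigen minimum number of unique eigenvalues (100 is a sensible
#'   production floor; tests use 40).
#' @param spline_df equivalent degrees of freedom of the smoothing spline;
#'   default `ceiling(sqrt(n))`, flexible enough to track the mean density
#'   but far stiffer than the level fluctuations.
#' @return positive spacings with mean 1.
#' @export
unfolded_spacings <- function(m, min_eigen = 100L, spline_df = NULL) {
  check_symmetric(m, what = "input matrix")
  if (nrow(m) < min_eigen)
    stopf("matrix dimension %d below min_eigen = %d", nrow(m), min_eigen)
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  ev <- ev[c(TRUE, diff(ev) > 1e-10)]  # degenerate levels removed
  n <- length(ev)
  if (n < min_eigen)
    stopf("only %d unique eigenvalues, below min_eigen = %d", n, min_eigen)
  df <- spline_df %||% max(5, ceiling(sqrt(n)))
  fit <- smooth.spline(ev, seq_len(n), df = df)
  unf <- predict(fit, ev)$y
  s <- diff(unf)
  s[s < 0] <- 0
  mu <- mean(s)
  if (mu <= 0) stopf("degenerate spectrum: zero mean spacing")
  s / mu
}

#' Chi-squared goodness of fit of an NNSD to Poisson or GOE
#'
#' Histograms the spacings over \[0, 3\] in `n_bins` equal bins (overflow
#' pooled into the last bin) and compares observed counts with the named
#' law's density integrated per bin: Poisson `exp(-s)` or the Wigner surmise
#' `(pi s / 2) exp(-pi s^2 / 4)`. Bins with expected count < 1 are merged
#' into their neighbour.
#'
#' @param s unfolded spacings (>= 30 values).
#' @param law `"poisson"` or `"goe"`.
#' @param n_bins number of equal bins on `[0, s_max]`.
#' @param s_max upper edge of the histogram (overflow pooled).
#' @return list with `statistic`, `dof`, `p.value`.
#' @export
nnsd_chisq <- function(s, law = c("poisson", "goe"), n_bins = 30L, s_max = 3) {
  law <- match.arg(law)
  n <- length(s)
  if (n < 30) stopf("need at least 30 spacings (got %d)", n)
  width <- s_max / n_bins
  bin <- pmin(floor(s / width) + 1L, n_bins)
  obs <- tabulate(bin, nbins = n_bins)
  edges <- seq(0, s_max, length.out = n_bins + 1)
  cdf <- switch(law,
    poisson = function(x) 1 - exp(-x),
    goe     = function(x) 1 - exp(-pi * x^2 / 4))
  prob <- diff(cdf(edges))
  prob[n_bins] <- prob[n_bins] + (1 - cdf(s_max))  # overflow pooled
  expct <- n * prob
  # merge bins with expected < 1 into the preceding kept bin (the first bin
  # accumulates forward until it reaches 1)
  mo <- numeric(0); me <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_len(n_bins)) {
    co <- co + obs[i]; ce <- ce + expct[i]
    if (ce >= 1) {
      mo <- c(mo, co); me <- c(me, ce)
      co <- 0; ce <- 0
    }
  }
  if (ce > 0 && length(me)) {  # trailing remainder into the last kept bin
    mo[length(mo)] <- mo[length(mo)] + co
    me[length(me)] <- me[length(me)] + ce
  }
  stat <- sum((mo - me)^2 / me)
  dof <- length(me) - 1L
  list(statistic = stat, dof = dof,
       p.value = pchisq(stat, df = dof, lower.tail = FALSE))
}

#' Scan thresholds and select the Poisson-transition cutoff
#'
#' For each candidate threshold s, keeps `A_ij = |rho_ij|` where
#' `|rho_ij| >= s` (zero elsewhere and on the diagonal), drops all-zero
#' rows/columns, and — when the retained matrix is at least `min_eigen` —
#' tests the unfolded NNSD against Poisson and GOE. The chosen threshold is
#' the smallest grid point whose Poisson chi-squared statistic falls below
#' the critical value at `test_alpha` and stays below it over the next
#' `stability_window` computable grid points (so a single noisy verdict
#' cannot trigger selection, while the near-empty end of the grid cannot
#' veto it either).
#'
#' Thresholds whose retained matrix is smaller than `min_eigen` or sparser
#' than `min_degree` (a near-empty graph has a degenerate, untestable
#' spectrum) are recorded but excluded from the decision.
#'
#' @param rho symmetric (deconvolved) correlation matrix.
#' @param grid ascending candidate thresholds.
#' @param min_eigen minimum retained dimension for a spectral test.
#' @param min_degree minimum mean number of retained entries per row for a
#'   spectral test.
#' @param test_alpha significance level of the chi-squared criterion.
#' @param stability_window number of consecutive computable grid points
#'   above a candidate that must also satisfy the Poisson criterion.
#' @param spline_df passed to [unfolded_spacings()].
#' @return list with `table` (one row per threshold: retained size,
#'   chi-squared statistics, decision), `chosen_threshold`, `test_alpha`.
#' @export
rmt_scan <- function(rho, grid = seq(0.30, 0.99, by = 0.01),
                     min_eigen = 100L, min_degree = 2, test_alpha = 0.001,
                     stability_window = 5L, spline_df = NULL) {
  check_symmetric(rho, what = "correlation matrix")
  if (is.unsorted(grid, strictly = TRUE)) stopf("grid must be ascending")
  a0 <- abs(rho); diag(a0) <- 0
  res <- data.frame(threshold = grid, retained = NA_integer_,
                    chi2_poisson = NA_real_, dof_poisson = NA_integer_,
                    chi2_goe = NA_real_, poisson_ok = NA)
  any_edges <- FALSE
  for (i in seq_along(grid)) {
    a <- a0
    a[a < grid[i]] <- 0
    keep <- rowSums(a) > 0
    res$retained[i] <- sum(keep)
    if (sum(keep) > 0) any_edges <- TRUE
    if (sum(keep) < min_eigen) next
    if (sum(a > 0) / sum(keep) < min_degree) next
    s <- tryCatch(
      unfolded_spacings(a[keep, keep, drop = FALSE], min_eigen = min_eigen,
                        spline_df = spline_df),
      error = function(e) NULL)  # too few unique levels: untestable
    if (is.null(s) || length(s) < 30) next
    po <- nnsd_chisq(s, "poisson")
    go <- nnsd_chisq(s, "goe")
    res$chi2_poisson[i] <- po$statistic
    res$dof_poisson[i] <- po$dof
    res$chi2_goe[i] <- go$statistic
    res$poisson_ok[i] <- po$statistic < qchisq(1 - test_alpha, df = po$dof)
  }
  if (!any_edges) stopf("no edges at any threshold")
  ok <- res$poisson_ok
  chosen <- NA_real_
  for (i in seq_along(grid)) {
    if (!isTRUE(ok[i])) next
    later <- ok[-seq_len(i)]
    later <- later[!is.na(later)]
    if (length(later) > stability_window)
      later <- later[seq_len(stability_window)]
    if (all(later)) {
      chosen <- grid[i]
      break
    }
  }
  if (is.na(chosen))
    stopf("no threshold satisfies the Poisson spacing criterion")
  list(table = res, chosen_threshold = chosen, test_alpha = test_alpha,
       min_eigen = as.integer(min_eigen))
}
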