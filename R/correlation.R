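# Spearman correlation with FDR control, and network deconvolution of
# indirect correlations.

#' Spearman correlation matrix with p-values
#'
#' Computes the gene-by-gene Spearman matrix (Pearson correlation of
#' average-ranked values; ties get average ranks) on a genes x samples
#' table. Two-sided p-values come from the t statistic
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom,
#' adequate at survey-scale n; an exact permutation p-value (via
#' [stats::cor.test()]) is available for very small n. Constant genes get
#' rho = 0, p = 1 against every partner.
#'
#' @param m genes x samples numeric matrix (>= 4 samples).
#' @param p_method `"t"` (default) or `"exact"` (only for < 10 samples,
#'   tie-free data).
#' @return list with symmetric matrices `rho` (unit diagonal) and `p`
#'   (zero diagonal).
#' @export
spearman_matrix <- function(m, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  n <- ncol(m)
  if (n < 4) stopf("need at least 4 samples (got %d)", n)
  const <- apply(m, 1, function(x) max(x) == min(x))
  r <- t(apply(m, 1, rank))  # average ranks for ties
  rho <- suppressWarnings(cor(t(r)))
  rho[is.na(rho)] <- 0
  rho[const, ] <- 0; rho[, const] <- 0
  diag(rho) <- 1
  if (p_method == "exact") {
    if (n >= 10) stopf("exact p-values are only supported for n < 10 samples")
    g <- nrow(m)
    p <- matrix(0, g, g, dimnames = dimnames(rho))
    for (i in seq_len(g - 1)) for (j in (i + 1):g) {
      p[i, j] <- p[j, i] <- if (const[i] || const[j]) 1 else
        suppressWarnings(stats::cor.test(m[i, ], m[j, ],
                                         method = "spearman")$p.value)
    }
  } else {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    tt[abs(rho) >= 1] <- Inf * sign(rho[abs(rho) >= 1])
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  p[const, ] <- 1; p[, const] <- 1
  diag(p) <- 0
  dimnames(p) <- dimnames(rho) <- list(rownames(m), rownames(m))
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg adjustment over the upper triangle
#'
#' Each unordered gene pair is one hypothesis (m = g(g-1)/2, diagonal
#' excluded); adjusted values are mirrored back symmetrically.
#'
#' @param p symmetric matrix of p-values in \[0, 1\].
#' @return symmetric matrix of BH-adjusted q-values, zero diagonal.
#' @export
fdr_adjust <- function(p) {
  check_symmetric(p, what = "p-value matrix")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  ut <- upper.tri(p)
  q <- p
  q[ut] <- p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  q
}

#' Network deconvolution of indirect correlations
#'
#' Inverts the transitive closure G_obs = G_dir + G_dir^2 + ... by the
#' eigenvalue map lambda' = gamma * lambda / (1 + gamma * lambda), which
#' attenuates correlations reachable through indirect paths. `alpha` is the
#' fraction of off-diagonal entries (largest by magnitude) retained before
#' deconvolution; `beta` bounds the output spectral radius, with the scaling
#' factor gamma chosen in closed form,
#' gamma = min(1, beta / ((1 - beta) lambda_max+), beta / ((1 + beta) |lambda_min-|)),
#' so the bound is tight on the binding side.
#'
#' @param rho symmetric matrix of (signed) correlations.
#' @param alpha fraction of off-diagonal entries retained, in (0, 1].
#' @param beta output spectral-radius bound, in (0, 1).
#' @param gamma optional fixed scaling factor; overrides the closed form.
#' @param zero_diag zero the diagonal before and after the transform
#'   (default). Set `FALSE` to apply the raw eigenvalue map, the exact
#'   inverse of [nd_closure()].
#' @param rescale `"max"` (default) linearly rescales the output so its
#'   largest off-diagonal magnitude equals the input's, putting direct
#'   dependencies back on the correlation scale that downstream thresholds
#'   expect; `"none"` returns the raw eigenvalue-map output (whose spectral
#'   radius is bounded by `beta`). Rescaling is a positive scalar multiple:
#'   it preserves signs and the ranking of magnitudes.
#' @return symmetric deconvolved matrix; attributes `"gamma"` and
#'   `"rescale_factor"` record the scalings used.
#' @export
deconvolve <- function(rho, alpha = 1, beta = 0.99, gamma = NULL,
                       zero_diag = TRUE, rescale = c("max", "none")) {
  rescale <- match.arg(rescale)
  check_symmetric(rho, what = "correlation matrix")
  if (alpha <= 0 || alpha > 1) stopf("alpha must lie in (0, 1]")
  if (beta <= 0 || beta >= 1) stopf("beta must lie in (0, 1)")
  g <- rho
  if (zero_diag) diag(g) <- 0
  if (alpha < 1) {
    off <- abs(g[upper.tri(g)])
    cut <- quantile(off, probs = 1 - alpha, names = FALSE)
    mask <- abs(g) < cut
    diag(mask) <- FALSE
    g[mask] <- 0
  }
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  lam <- e$values
  if (is.null(gamma)) {
    lp <- max(c(lam[lam > 0], 0))
    ln <- min(c(lam[lam < 0], 0))
    g1 <- if (lp > 0) beta / ((1 - beta) * lp) else Inf
    g2 <- if (ln < 0) beta / ((1 + beta) * abs(ln)) else Inf
    gamma <- min(1, g1, g2)
  }
  lam2 <- gamma * lam / (1 + gamma * lam)
  out <- e$vectors %*% (lam2 * t(e$vectors))
  out <- (out + t(out)) / 2
  if (zero_diag) diag(out) <- 0
  sf <- 1
  if (rescale == "max") {
    in_max <- max(abs(rho[upper.tri(rho)]))
    out_max <- max(abs(out[upper.tri(out)]))
    if (out_max > 0 && in_max > 0) sf <- in_max / out_max
    out <- out * sf
  }
  dimnames(out) <- dimnames(rho)
  attr(out, "gamma") <- gamma
  attr(out, "rescale_factor") <- sf
  out
}

#' Transitive closure of a direct-dependency matrix
#'
#' Maps eigenvalues by lambda -> lambda / (1 - lambda); the exact inverse of
#' [deconvolve()] with `gamma = 1, zero_diag = FALSE`. Requires spectral
#' radius < 1.
#'
#' @param d symmetric matrix with all eigenvalues < 1.
#' @return symmetric matrix of observed (direct + indirect) dependencies.
#' @export
nd_closure <- function(d) {
  check_symmetric(d, what = "direct-dependency matrix")
  e <- eigen(d, symmetric = TRUE)
  if (max(e$values) >= 1) stopf("closure requires all eigenvalues < 1")
  out <- e$vectors %*% ((e$values / (1 - e$values)) * t(e$vectors))
  (out + t(out)) / 2
}
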