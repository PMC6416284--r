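#' Dual Spearman/Pearson correlation of all band pairs
#'
#' For every unordered pair of bands, computes the Pearson correlation with a
#' two-sided p-value from the t transform (n - 2 df) and the Spearman
#' correlation on midranks (ties averaged) with a two-sided p-value from the
#' same t approximation applied to rho. With few samples the t approximation
#' is poor, so a permutation mode replaces both analytic p-values: all n!
#' sample orderings are enumerated exactly when n <= 8, and Monte-Carlo
#' permutations with the add-one estimator are used for n of 9-10 (or on
#' request). Permutations are shared across the pair panel, which keeps every
#' pair's p-value marginally valid.
#'
#' A band that is constant within the sample subset has undefined
#' correlations; its pairs are returned with `valid = FALSE` (and NA
#' statistics) rather than raising an error, so that edge calling simply
#' skips them.
#'
#' @param matrix A [band_matrix()], already frequency-filtered; needs >= 4
#'   samples.
#' @param binarize Correlate presence/absence (0/1) instead of intensities.
#' @param p_method `"auto"` (permutation when n <= 10), `"analytic"`, or
#'   `"permutation"`.
#' @param n_perm Monte-Carlo permutation count when enumeration is not used.
#' @param seed Seed for Monte-Carlo permutations (not needed for exhaustive
#'   enumeration or analytic p-values).
#' @return Data frame of class `"correlation_pairs"`: `band_i`, `band_j`
#'   (column order, i before j), `rho_spearman`, `p_spearman`, `rho_pearson`,
#'   `p_pearson`, `n_samples`, `valid`.
#' @export
correlate_pairs <- function(matrix, binarize = FALSE,
                            p_method = c("auto", "analytic", "permutation"),
                            n_perm = 10000, seed = NULL) {
  stopifnot(inherits(matrix, "band_matrix"))
  p_method <- match.arg(p_method)
  x <- matrix$intensities
  if (binarize) x <- (x > 0) * 1
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) stop("need at least 4 samples to correlate pairs")
  if (m < 2) stop("need at least 2 bands")

  use_perm <- switch(p_method,
                     auto = n <= 10,
                     analytic = FALSE,
                     permutation = TRUE)

  sds <- apply(x, 2, sd)
  valid_band <- sds > 0
  rk <- apply(x, 2, rank)  # midranks; ties averaged

  r_p <- suppressWarnings(cor(x))
  r_s <- suppressWarnings(cor(rk))

  if (use_perm) {
    p_p <- perm_pvalue_matrix(x, n_perm = n_perm, seed = seed)
    p_s <- perm_pvalue_matrix(rk, n_perm = n_perm,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  } else {
    p_p <- t_approx_pvalue(r_p, n)
    p_s <- t_approx_pvalue(r_s, n)
  }

  idx <- combn(m, 2)
  i <- idx[1, ]; j <- idx[2, ]
  flat <- (j - 1) * m + i
  ok <- valid_band[i] & valid_band[j]
  out <- data.frame(
    band_i = colnames(x)[i],
    band_j = colnames(x)[j],
    rho_spearman = ifelse(ok, r_s[flat], NA_real_),
    p_spearman = ifelse(ok, p_s[flat], NA_real_),
    rho_pearson = ifelse(ok, r_p[flat], NA_real_),
    p_pearson = ifelse(ok, p_p[flat], NA_real_),
    n_samples = n,
    valid = ok,
    stringsAsFactors = FALSE
  )
  attr(out, "p_method") <- if (use_perm) "permutation" else "analytic"
  class(out) <- c("correlation_pairs", "data.frame")
  out
}

# two-sided p from t = r sqrt((n-2)/(1-r^2)); |r| = 1 -> p at the positivity
# floor so the (0, 1] invariant holds
t_approx_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, 1e-300))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  pmax(pmin(p, 1), .Machine$double.xmin)
}

# permutation p-values for all column pairs of x, via shared sample-order
# permutations; exact enumeration when n! is small, else Monte Carlo add-one
perm_pvalue_matrix <- function(x, n_perm = 10000, seed = NULL,
                               enumerate_limit = 40320) {
  n <- nrow(x)
  m <- ncol(x)
  xs <- scale(x)
  constant <- attr(xs, "scaled:scale") == 0
  xs[, constant] <- 0
  r_obs <- crossprod(xs) / (n - 1)
  exact <- factorial(n) <= enumerate_limit
  if (exact) {
    perms <- all_permutations(n)
  } else {
    if (is.null(seed))
      stop("a seed is required for Monte-Carlo permutation p-values")
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(n)))
  }
  b_tot <- nrow(perms)
  count <- matrix(0, m, m)
  thr <- abs(r_obs) - 1e-12
  for (b in seq_len(b_tot)) {
    rp <- crossprod(xs[perms[b, ], , drop = FALSE], xs) / (n - 1)
    count <- count + (abs(rp) >= thr)
  }
  count <- count + t(count)  # both orientations of each pair
  p <- if (exact) count / (2 * b_tot) else (1 + count) / (1 + 2 * b_tot)
  p <- pmin(p, 1)
  p[constant, ] <- NA
  p[, constant] <- NA
  p
}
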