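# Independent oracles and small generators shared across the suite.
# These deliberately avoid the package's own code paths (and igraph) so that
# agreement is evidence, not tautology.

# all set partitions of 1..n as membership vectors (restricted growth strings)
rgs_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxval) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxval + 1)) recurse(c(prefix, v), max(maxval, v))
  }
  recurse(integer(0), 0L)
  out
}

# Newman-Girvan modularity from an edge list (two-column matrix of vertex
# indices) and a membership vector; hand-rolled formula
modularity_oracle <- function(edges, membership, n_vertices) {
  m <- nrow(edges)
  if (m == 0) return(NA_real_)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_vertices)
  q <- 0
  for (cmty in unique(membership)) {
    vs <- which(membership == cmty)
    within <- sum(edges[, 1] %in% vs & edges[, 2] %in% vs)
    d_c <- sum(deg[vs])
    q <- q + within / m - (d_c / (2 * m))^2
  }
  q
}

# exhaustive maximum modularity over all partitions (tiny graphs only)
max_modularity_oracle <- function(edges, n_vertices) {
  best <- -Inf
  for (p in rgs_partitions(n_vertices)) {
    q <- modularity_oracle(edges, p, n_vertices)
    if (q > best) best <- q
  }
  best
}

# closed-form simple OLS
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- sxy^2 / (sxx * syy)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# random band matrix with iid lognormal intensities (no planted structure)
random_band_matrix <- function(n = 12, m = 20, seed = 1, zero_frac = 0.1,
                               n_bacteria = ceiling(m / 2)) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n * m)), n, m)
  x[matrix(runif(n * m) < zero_frac, n, m)] <- 0
  rownames(x) <- sprintf("s%02d", seq_len(n))
  colnames(x) <- sprintf("b%02d", seq_len(m))
  kingdom <- setNames(rep(c("bacteria", "fungi"), c(n_bacteria, m - n_bacteria)),
                      colnames(x))
  band_matrix(x, kingdom)
}

# the benchmark condition for planted-edge recovery: planted correlations
# only (treatment effects off, no zero mask), default strength 0.8, n = 32
recovery_config <- function() {
  synthetic_config(source_effect_sd = c(bacteria = 0, fungi = 0),
                   inoculum_effect_sd = c(bacteria = 0, fungi = 0),
                   zero_inflation = 0)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

recovery_rates <- function(network, planted) {
  found <- edge_key(network$edges$band_i, network$edges$band_j)
  truth <- edge_key(planted$band_i, planted$band_j)
  tp <- sum(found %in% truth)
  c(precision = tp / max(1, length(found)), recall = tp / length(truth))
}
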