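#' Configuration of the synthetic study generator
#'
#' Defines the simulated counterpart of the greenhouse study: 4 phosphate
#' sources x 2 inoculum levels x `n_replicates` pots, a 157-band panel
#' (90 bacterial + 67 fungal DGGE bands), planted pairwise dependencies
#' between bands, zero-inflated lognormal intensities, and phenotype curves
#' versus %P2O5.
#'
#' Band intensities are built from a latent Gaussian copula: each planted edge
#' `(i, j, sign, strength w)` contributes a shared standard-normal factor F so
#' that `log x_i = mu_i + noise_sd * (sqrt(w) F + sqrt(1-w) e_i)` and band j
#' loads on F with the edge's sign, giving correlation `sign * w` on the log
#' scale (monotone, hence visible to both Spearman and Pearson after
#' exponentiation). Treatment structure is added as per-band random offsets by
#' source (and, for bacterial bands, by inoculum), and a Bernoulli presence
#' mask creates zero inflation.
#'
#' The phenotype defaults mirror the printed study conditions: colonization
#' 43% at 0% P2O5 declining linearly (slope -1.5 reaches 16% at SS's 18%),
#' and a peaked dry-matter response `c + a x exp(b x)` whose maximum
#' (6.57 g/pot at 11.09% P2O5) matches the study's fitted regression curve,
#' with noise sized so the replicate-level fit explains roughly two thirds of
#' the variance.
#'
#' @param n_replicates Pots per source x inoculum cell (default 4; 32 pots).
#' @param n_bacteria_bands,n_fungi_bands Panel sizes (defaults 90 and 67).
#' @param planted_edges Data frame with columns `band_i`, `band_j`,
#'   `sign` (+1/-1), `strength` in (0, 1]; see [default_planted_edges()].
#' @param zero_inflation Probability a band is masked to absent in a sample.
#' @param noise_sd Standard deviation of log-intensities around the band mean.
#' @param band_mean_log,band_mean_sd Distribution of band mean log-intensities.
#' @param source_effect_sd Named vector (`bacteria`, `fungi`): SD of per-band,
#'   per-source log-intensity offsets (the planted treatment effect that
#'   PERMANOVA should detect). Set to 0 to remove the source effect.
#' @param source_effect_frac Fraction of bands carrying source offsets.
#' @param inoculum_effect_sd Named vector (`bacteria`, `fungi`): SD of the
#'   per-band inoculum offset. Default affects bacteria only, echoing the
#'   study's finding that inoculation restructured the bacterial but not the
#'   fungal community.
#' @param inoculum_effect_frac Fraction of bands carrying inoculum offsets.
#' @param dm_curve Dry-matter curve: list with `form` (see
#'   [fit_exponential()]) and parameters `a`, `b` and optionally `c`.
#' @param dm_noise_sd SD of additive dry-matter noise (g/pot).
#' @param colonization_curve Named vector `intercept` (%) and `slope`
#'   (% per unit %P2O5) of the colonization decline.
#' @param colonization_noise_sd SD of additive colonization noise (%).
#'
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_replicates = 4,
                             n_bacteria_bands = 90,
                             n_fungi_bands = 67,
                             planted_edges = default_planted_edges(
                               n_bacteria_bands, n_fungi_bands),
                             zero_inflation = 0.1,
                             noise_sd = 0.35,
                             band_mean_log = log(50),
                             band_mean_sd = 0.5,
                             source_effect_sd = c(bacteria = 0.55, fungi = 0.6),
                             source_effect_frac = 0.6,
                             inoculum_effect_sd = c(bacteria = 0.6, fungi = 0),
                             inoculum_effect_frac = 0.5,
                             dm_curve = list(form = "peaked_offset",
                                             a = 1.071, b = -1 / 11.09,
                                             c = 2.2),
                             dm_noise_sd = 1.4,
                             colonization_curve = c(intercept = 43,
                                                    slope = -1.5),
                             colonization_noise_sd = 2) {
  stopifnot(n_replicates >= 1, n_bacteria_bands >= 2, n_fungi_bands >= 2)
  stopifnot(zero_inflation >= 0, zero_inflation < 1)
  if (noise_sd < 0 || dm_noise_sd < 0 || colonization_noise_sd < 0)
    stop("noise standard deviations must be nonnegative")
  planted_edges <- as.data.frame(planted_edges)
  if (nrow(planted_edges)) {
    stopifnot(all(c("band_i", "band_j", "sign", "strength") %in%
                    names(planted_edges)))
    if (!all(planted_edges$sign %in% c(-1, 1)))
      stop("planted edge signs must be +1 or -1")
    if (any(planted_edges$strength <= 0 | planted_edges$strength > 1))
      stop("planted edge strengths must lie in (0, 1]")
  }
  structure(list(
    n_replicates = as.integer(n_replicates),
    n_bacteria_bands = as.integer(n_bacteria_bands),
    n_fungi_bands = as.integer(n_fungi_bands),
    planted_edges = planted_edges,
    zero_inflation = zero_inflation,
    noise_sd = noise_sd,
    band_mean_log = band_mean_log,
    band_mean_sd = band_mean_sd,
    source_effect_sd = source_effect_sd,
    source_effect_frac = source_effect_frac,
    inoculum_effect_sd = inoculum_effect_sd,
    inoculum_effect_frac = inoculum_effect_frac,
    dm_curve = dm_curve,
    dm_noise_sd = dm_noise_sd,
    colonization_curve = colonization_curve,
    colonization_noise_sd = colonization_noise_sd
  ), class = "synthetic_config")
}

#' Default planted dependency graph
#'
#' 45 vertex-disjoint planted edges at strength 0.8: 12 positive + 6 negative
#' bacteria-bacteria, 8 positive + 4 negative fungi-fungi, and 10 positive +
#' 5 negative bacteria-fungi pairs. Vertex-disjointness keeps the ground truth
#' clean: no correlation is induced between bands that do not share an edge.
#'
#' @param n_bacteria,n_fungi Panel sizes; must be large enough to host the
#'   default edges (>= 51 bacteria, >= 39 fungi).
#' @param strength Shared latent-factor loading of every planted edge.
#' @return Data frame with columns `band_i`, `band_j`, `sign`, `strength`.
#' @export
default_planted_edges <- function(n_bacteria = 90, n_fungi = 67,
                                  strength = 0.8) {
  if (n_bacteria < 51 || n_fungi < 39)
    stop("default planted edges need >= 51 bacterial and >= 39 fungal bands")
  b <- function(i) sprintf("B%03d", i)
  f <- function(i) sprintf("F%03d", i)
  bb_pos <- data.frame(band_i = b(seq(1, 23, 2)),  band_j = b(seq(2, 24, 2)),
                       sign = 1)
  bb_neg <- data.frame(band_i = b(seq(25, 35, 2)), band_j = b(seq(26, 36, 2)),
                       sign = -1)
  ff_pos <- data.frame(band_i = f(seq(1, 15, 2)),  band_j = f(seq(2, 16, 2)),
                       sign = 1)
  ff_neg <- data.frame(band_i = f(seq(17, 23, 2)), band_j = f(seq(18, 24, 2)),
                       sign = -1)
  bf_pos <- data.frame(band_i = b(37:46), band_j = f(25:34), sign = 1)
  bf_neg <- data.frame(band_i = b(47:51), band_j = f(35:39), sign = -1)
  out <- rbind(bb_pos, bb_neg, ff_pos, ff_neg, bf_pos, bf_neg)
  out$strength <- strength
  out
}

make_design <- function(n_replicates) {
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      inoculum = c(TRUE, FALSE),
                      source = names(SOURCE_P2O5),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("source", "inoculum", "replicate")]
  data.frame(
    sample_id = sprintf("S%02d", seq_len(nrow(grid))),
    source = grid$source,
    p2o5_percent = p2o5_for_source(grid$source),
    inoculum = grid$inoculum,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic study
#'
#' Produces a band matrix, sample table, phenotype table and the generative
#' ground truth for one simulated run of the 32-pot experiment. Identical
#' seeds give bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed (required).
#' @return A list with elements `band_matrix` ([band_matrix()]), `samples`,
#'   `phenotypes` (data frames), and `truth` (planted edges, latent factors
#'   and phenotype curve parameters).
#' @export
#' @examples
#' study <- generate_study(synthetic_config(), seed = 1)
#' dim(study$band_matrix$intensities)
generate_study <- function(config = synthetic_config(), seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)

  samples <- make_design(config$n_replicates)
  n <- nrow(samples)
  bands <- c(sprintf("B%03d", seq_len(config$n_bacteria_bands)),
             sprintf("F%03d", seq_len(config$n_fungi_bands)))
  kingdom <- setNames(rep(c("bacteria", "fungi"),
                          c(config$n_bacteria_bands, config$n_fungi_bands)),
                      bands)
  m <- length(bands)

  pe <- config$planted_edges
  if (nrow(pe)) {
    unknown <- setdiff(c(pe$band_i, pe$band_j), bands)
    if (length(unknown))
      stop("planted edge references unknown band(s): ",
           paste(unknown, collapse = ", "))
  }

  mu <- rnorm(m, config$band_mean_log, config$band_mean_sd)
  z <- matrix(rnorm(n * m), n, m, dimnames = list(samples$sample_id, bands))
  factors <- NULL
  if (nrow(pe)) {
    factors <- matrix(rnorm(n * nrow(pe)), n, nrow(pe))
    for (e in seq_len(nrow(pe))) {
      w <- pe$strength[e]
      i <- pe$band_i[e]; j <- pe$band_j[e]
      z[, i] <- sqrt(w) * factors[, e] + sqrt(1 - w) * z[, i]
      z[, j] <- pe$sign[e] * sqrt(w) * factors[, e] + sqrt(1 - w) * z[, j]
    }
  }

  logx <- sweep(config$noise_sd * z, 2, mu, "+")

  # per-band treatment offsets: source (both kingdoms), inoculum (by kingdom)
  src_levels <- names(SOURCE_P2O5)
  sd_src <- config$source_effect_sd[kingdom]
  hit_src <- runif(m) < config$source_effect_frac
  src_off <- matrix(rnorm(length(src_levels) * m), length(src_levels), m,
                    dimnames = list(src_levels, bands))
  src_off <- sweep(src_off, 2, ifelse(hit_src, sd_src, 0), "*")
  logx <- logx + src_off[samples$source, , drop = FALSE]

  sd_ino <- config$inoculum_effect_sd[kingdom]
  hit_ino <- runif(m) < config$inoculum_effect_frac
  ino_off <- rnorm(m) * ifelse(hit_ino, sd_ino, 0)
  logx <- logx + outer(ifelse(samples$inoculum, 0.5, -0.5), ino_off)

  present <- matrix(rbinom(n * m, 1, 1 - config$zero_inflation), n, m)
  x <- exp(logx) * present
  bm <- band_matrix(x, kingdom)

  phenotypes <- generate_phenotypes(samples, config, seed = seed + 1L)

  truth <- list(
    planted_edges = pe,
    latent_factors = factors,
    band_means_log = setNames(mu, bands),
    dm_curve = config$dm_curve,
    colonization_curve = config$colonization_curve
  )
  list(band_matrix = bm, samples = samples, phenotypes = phenotypes,
       truth = truth)
}

#' Generate phenotypes for a sample table
#'
#' Colonization is `max(0, intercept + slope * %P2O5 + noise)` for inoculated
#' samples and exactly 0 otherwise (colonization was never observed without
#' inoculum); dry matter follows the configured curve plus Gaussian noise,
#' floored at a small positive value.
#'
#' @param samples A validated sample table (see [read_tables()]).
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed (required).
#' @return Phenotype data frame with `sample_id`, `total_dry_matter`,
#'   `colonization_index`.
#' @export
generate_phenotypes <- function(samples, config = synthetic_config(), seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  samples <- validate_sample_table(samples)
  set.seed(seed)
  n <- nrow(samples)
  x <- samples$p2o5_percent

  cc <- config$colonization_curve
  col <- cc[["intercept"]] + cc[["slope"]] * x +
    rnorm(n, 0, config$colonization_noise_sd)
  col <- pmax(0, col)
  col[!samples$inoculum] <- 0

  dm <- eval_curve(config$dm_curve$form, config$dm_curve, x) +
    rnorm(n, 0, config$dm_noise_sd)
  dm <- pmax(dm, 0.05)

  data.frame(sample_id = samples$sample_id,
             total_dry_matter = dm,
             colonization_index = col,
             stringsAsFactors = FALSE)
}

#' Deterministic hand-built test fixture
#'
#' An 8-sample x 10-band dataset (6 bacterial, 4 fungal bands) with
#' hand-verifiable structure: `B2 = 2 * B1` (correlation exactly +1),
#' `F1 = 20 - 2 * B3` (exactly -1), a constant band `B6` (all its pairs have
#' undefined correlation), a zero-heavy band `F3` exercising tied midranks,
#' and a singleton band `F4` present in 1/8 samples, which the 25% frequency
#' filter removes. Built from literal values, no RNG involved.
#'
#' @return A list with `band_matrix`, `samples`, `phenotypes`, and `truth`
#'   (the two planted edges).
#' @export
tiny_fixture <- function() {
  vals <- rbind(
    B1 = c(5, 8, 2, 9, 4, 7, 3, 6),
    B2 = 2 * c(5, 8, 2, 9, 4, 7, 3, 6),
    B3 = c(3, 1, 4, 9, 2, 8, 5, 7),
    B4 = c(3, 5, 7, 2, 8, 6, 4, 1),
    B5 = c(8, 6, 3, 5, 7, 2, 1, 4),
    B6 = rep(4, 8),
    F1 = 20 - 2 * c(3, 1, 4, 9, 2, 8, 5, 7),
    F2 = c(7, 4, 5, 6, 3, 2, 1, 8),
    F3 = c(0, 6, 0, 5, 0, 8, 0, 9),
    F4 = c(0, 0, 0, 12, 0, 0, 0, 0)
  )
  m <- t(vals)
  rownames(m) <- sprintf("T%d", 1:8)
  kingdom <- setNames(rep(c("bacteria", "fungi"), c(6, 4)), rownames(vals))
  bm <- band_matrix(m, kingdom)
  samples <- data.frame(
    sample_id = rownames(m),
    source = rep(names(SOURCE_P2O5), each = 2),
    p2o5_percent = rep(unname(SOURCE_P2O5), each = 2),
    inoculum = rep(c(TRUE, FALSE), 4),
    replicate = 1L,
    stringsAsFactors = FALSE
  )
  phenotypes <- data.frame(
    sample_id = samples$sample_id,
    total_dry_matter = c(3.1, 2.8, 4.9, 4.6, 6.4, 6.6, 6.0, 6.2),
    colonization_index = c(42, 0, 39, 0, 22, 0, 15, 0),
    stringsAsFactors = FALSE
  )
  truth <- list(planted_edges = data.frame(
    band_i = c("B1", "B3"), band_j = c("B2", "F1"),
    sign = c(1, -1), strength = 1
  ))
  list(band_matrix = bm, samples = samples, phenotypes = phenotypes,
       truth = truth)
}
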