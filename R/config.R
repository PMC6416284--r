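#' Analysis configuration
#'
#' Bundles the fixed constants of the published analysis protocol (25%
#' band-frequency filter, p < 0.05 on both correlations, 9999 permutations)
#' together with the conventions the pipeline must choose where the published
#' topology table is ambiguous (degree and density are each printed under two
#' different formulas in different columns, so both are always computed and
#' the convention here only selects which one is labelled primary).
#'
#' @param min_band_frequency Minimum fraction of samples in which a band must
#'   be present (intensity > 0) to be retained. Default 0.25.
#' @param edge_alpha Significance level applied to both the Spearman and the
#'   Pearson p-value when calling network edges. Default 0.05.
#' @param n_permutations Number of label permutations for PERMANOVA.
#'   Default 9999.
#' @param rng_seed Integer seed used by stochastic stages (permutations,
#'   spinglass). `NULL` means the caller must supply a seed per call.
#' @param group_by Factor defining per-group networks: `"source"` (one network
#'   per phosphate source, pooling both inoculum levels) or `"inoculum"`
#'   (one network per inoculum level, pooling all sources).
#' @param density_convention Which graph-density formula is primary:
#'   `"total_nodes_directed_pairs"` = E / (N_total * (N_total - 1)), or
#'   `"interacting_nodes"` = E / (N_int * (N_int - 1)).
#' @param degree_convention Which average-degree formula is primary:
#'   `"two_e_over_n"` = 2E / N_int, or `"e_over_n"` = E / N_int.
#' @param curve_family Character vector of exponential form identifiers for
#'   response-surface model selection; see [fit_exponential()].
#' @param edge_rule `"both"` requires p < alpha for Spearman AND Pearson plus
#'   sign agreement (the published rule); `"either"` is a sensitivity mode
#'   requiring only one of the two tests (sign agreement still enforced).
#' @param p_adjust `"none"` (raw p-values, the published protocol) or `"BH"`
#'   (Benjamini-Hochberg across the pair panel, applied to each correlation's
#'   p-vector before thresholding).
#' @param binarize Use band presence/absence (0/1) instead of intensities when
#'   correlating pairs.
#' @param normalize Rescale each sample row to unit sum before Bray-Curtis.
#' @param p_method `"auto"` (exact/Monte-Carlo permutation p when n <= 10,
#'   analytic otherwise), `"analytic"`, or `"permutation"`.
#'
#' @return An object of class `"analysis_config"` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$min_band_frequency
analysis_config <- function(min_band_frequency = 0.25,
                            edge_alpha = 0.05,
                            n_permutations = 9999,
                            rng_seed = NULL,
                            group_by = c("source", "inoculum"),
                            density_convention = c("total_nodes_directed_pairs",
                                                   "interacting_nodes"),
                            degree_convention = c("two_e_over_n", "e_over_n"),
                            curve_family = c("exp", "exp_offset", "peaked",
                                             "peaked_offset"),
                            edge_rule = c("both", "either"),
                            p_adjust = c("none", "BH"),
                            binarize = FALSE,
                            normalize = TRUE,
                            p_method = c("auto", "analytic", "permutation")) {
  stopifnot(is.numeric(min_band_frequency), length(min_band_frequency) == 1,
            min_band_frequency > 0, min_band_frequency <= 1)
  stopifnot(is.numeric(edge_alpha), length(edge_alpha) == 1,
            edge_alpha > 0, edge_alpha < 1)
  stopifnot(is.numeric(n_permutations), length(n_permutations) == 1,
            n_permutations >= 1)
  if (!is.null(rng_seed)) {
    stopifnot(is.numeric(rng_seed), length(rng_seed) == 1)
    rng_seed <- as.integer(rng_seed)
  }
  curve_family <- match.arg(curve_family, several.ok = TRUE)
  structure(list(
    min_band_frequency = min_band_frequency,
    edge_alpha         = edge_alpha,
    n_permutations     = as.integer(n_permutations),
    rng_seed           = rng_seed,
    group_by           = match.arg(group_by),
    density_convention = match.arg(density_convention),
    degree_convention  = match.arg(degree_convention),
    curve_family       = curve_family,
    edge_rule          = match.arg(edge_rule),
    p_adjust           = match.arg(p_adjust),
    binarize           = isTRUE(binarize),
    normalize          = isTRUE(normalize),
    p_method           = match.arg(p_method)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
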