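#' Run the full analysis pipeline on one study
#'
#' Ties the stages together in the published order: 25% band-frequency
#' filtering; per-kingdom Bray-Curtis distances, PCoA, UPGMA and PERMANOVA
#' (`distance ~ source + inoculum`); per-group dual-correlation networks with
#' spinglass communities and the topology table; phenotype ANOVA/Tukey and
#' the colonization regression; exponential fits of replicate-level dry
#' matter and of per-source bacteria-fungi edge counts against %P2O5,
#' composed into the prediction surface and its optimum.
#'
#' @param band_matrix A [band_matrix()].
#' @param samples,phenotypes Validated tables (see [read_tables()]).
#' @param config An [analysis_config()].
#' @param seed Integer base seed for every stochastic stage (required).
#' @param surface_step Grid step of the composed surface, %P2O5.
#' @return A list with elements `filtered` (band matrix), `distances`,
#'   `ordination`, `dendrogram`, `permanova` (each a per-kingdom list),
#'   `networks`, `topology`, `inoculum_networks`, `inoculum_topology`,
#'   `phenotype_anova`, `tukey`, `colonization_fit`, `fits`
#'   (`dry_matter`, `bf_edges`), `surface`, `optimum`.
#' @export
#' @examples
#' \donttest{
#' study <- generate_study(synthetic_config(), seed = 1)
#' res <- run_study_pipeline(study$band_matrix, study$samples,
#'                           study$phenotypes,
#'                           config = analysis_config(n_permutations = 199),
#'                           seed = 1)
#' res$topology[, c("group", "total_edges", "pos_neg_ratio")]
#' }
run_study_pipeline <- function(band_matrix, samples, phenotypes,
                               config = analysis_config(), seed,
                               surface_step = 0.01) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  seed <- as.integer(seed)
  samples <- validate_sample_table(samples)
  phenotypes <- validate_phenotype_table(phenotypes, samples)
  samples <- samples[match(sample_ids(band_matrix), samples$sample_id), ,
                     drop = FALSE]
  ph <- phenotypes[match(samples$sample_id, phenotypes$sample_id), ,
                   drop = FALSE]

  filtered <- filter_low_frequency(band_matrix, config$min_band_frequency)

  # per-kingdom community structure
  distances <- list(); ordination <- list(); dendrogram <- list()
  permanova_res <- list()
  for (kg in c("bacteria", "fungi")) {
    sel <- filtered$kingdom == kg
    if (!any(sel)) next
    sub <- band_matrix(filtered$intensities[, sel, drop = FALSE],
                       filtered$kingdom[sel])
    d <- bray_curtis(sub, normalize = config$normalize)
    distances[[kg]] <- d
    ordination[[kg]] <- pcoa(d, k = 2)
    dendrogram[[kg]] <- upgma(d)
    permanova_res[[kg]] <- permanova(d, samples,
                                     terms = c("source", "inoculum"),
                                     n_perm = config$n_permutations,
                                     seed = seed + 101L)
  }

  # per-source and per-inoculum networks over the shared filtered panel
  networks <- group_networks(filtered, samples, group_by = "source",
                             config = config, seed = seed + 200L)
  topology <- topology_table(networks, config = config, seed = seed + 300L)
  inoculum_networks <- group_networks(filtered, samples,
                                      group_by = "inoculum",
                                      config = config, seed = seed + 400L)
  inoculum_topology <- topology_table(inoculum_networks, config = config,
                                      seed = seed + 500L)

  # phenotype statistics
  phenotype_anova <- list(
    total_dry_matter = anova_two_factor(ph$total_dry_matter,
                                        samples$source, samples$inoculum))
  cell <- paste(samples$source, ifelse(samples$inoculum, "+I", "-I"))
  tukey <- list(total_dry_matter = tukey_hsd(ph$total_dry_matter, cell,
                                             alpha = config$edge_alpha))
  colonization_fit <- NULL
  if (!is.null(ph$colonization_index) && any(samples$inoculum)) {
    inoc <- samples$inoculum
    colonization_fit <- linear_fit(samples$p2o5_percent[inoc],
                                   ph$colonization_index[inoc])
  }

  # response surface: replicate-level dry matter and per-source bf edges
  candidates_dm <- lapply(config$curve_family, function(fm)
    fit_exponential(samples$p2o5_percent, ph$total_dry_matter, fm))
  fit_dm <- select_by_rse(candidates_dm)

  src_p <- p2o5_for_source(topology$group)
  candidates_ed <- lapply(config$curve_family, function(fm)
    fit_exponential(src_p, topology$bf_edges, fm))
  fit_edges <- select_by_rse(candidates_ed)

  surface <- compose_surface(fit_dm, fit_edges,
                             from = 0, to = max(samples$p2o5_percent),
                             step = surface_step)
  optimum <- find_optimum(surface)

  list(filtered = filtered, distances = distances, ordination = ordination,
       dendrogram = dendrogram, permanova = permanova_res,
       networks = networks, topology = topology,
       inoculum_networks = inoculum_networks,
       inoculum_topology = inoculum_topology,
       phenotype_anova = phenotype_anova, tukey = tukey,
       colonization_fit = colonization_fit,
       fits = list(dry_matter = fit_dm, bf_edges = fit_edges),
       surface = surface, optimum = optimum,
       config = config, seed = seed)
}
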