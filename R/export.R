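# Writers for pipeline outputs. All writes are deterministic: the same
# objects always produce byte-identical files.

#' Write a network as GraphML and as a TSV edge list
#'
#' GraphML carries the vertex `kingdom` attribute and the per-edge
#' correlation provenance (`sign`, `rho_spearman`, `rho_pearson`,
#' `p_spearman`, `p_pearson`); the TSV edge list holds the same columns.
#'
#' @param network A [build_network()] result.
#' @param graphml_path,edges_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  stopifnot(inherits(network, "microbial_network"))
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    e <- network$edges[, c("band_i", "band_j", "sign", "rho_spearman",
                           "rho_pearson", "p_spearman", "p_pearson"),
                       drop = FALSE]
    write.table(e, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}

#' Write a dendrogram in Newick format
#'
#' @param hc An `hclust` object (e.g. from [upgma()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export all pipeline results to a directory
#'
#' Writes whatever stages are present in a [run_study_pipeline()] result:
#' per-group networks (GraphML + edge-list TSV), the topology table (one TSV
#' row per network), PERMANOVA tables, ordination coordinates, phenotype
#' statistics, response-surface fits, the surface grid, and the optimum as
#' JSON.
#'
#' @param results A [run_study_pipeline()] result (or any list using the
#'   same element names).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
export_results <- function(results, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)

  if (!is.null(results$networks)) {
    for (nm in names(results$networks)) {
      safe <- gsub("[^A-Za-z0-9_-]", "", nm)
      write_network(results$networks[[nm]],
                    graphml_path = file.path(out_dir,
                                             paste0("network_", safe,
                                                    ".graphml")),
                    edges_path = file.path(out_dir,
                                           paste0("edges_", safe, ".tsv")))
    }
  }
  if (!is.null(results$topology)) tsv(results$topology, "topology.tsv")
  if (!is.null(results$permanova)) {
    for (nm in names(results$permanova))
      tsv(as.data.frame(results$permanova[[nm]]),
          paste0("permanova_", nm, ".tsv"))
  }
  if (!is.null(results$ordination)) {
    for (nm in names(results$ordination)) {
      ord <- results$ordination[[nm]]
      tsv(data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates, check.names = FALSE),
          paste0("pcoa_", nm, ".tsv"))
    }
  }
  if (!is.null(results$fits)) {
    rows <- lapply(names(results$fits), function(nm) {
      f <- results$fits[[nm]]
      if (inherits(f, "linear_fit")) {
        data.frame(response = nm, form = "linear",
                   a = f$slope, b = f$intercept, c = NA_real_,
                   r_squared = f$r_squared, rse = f$rse,
                   p_value = f$p_value, n = f$n)
      } else if (isTRUE(f$ok)) {
        data.frame(response = nm, form = f$form,
                   a = f$parameters$a, b = f$parameters$b,
                   c = if (is.null(f$parameters$c)) NA_real_
                       else f$parameters$c,
                   r_squared = f$r_squared, rse = f$rse,
                   p_value = f$p_value, n = f$n)
      } else {
        data.frame(response = nm, form = f$form, a = NA_real_, b = NA_real_,
                   c = NA_real_, r_squared = NA_real_, rse = NA_real_,
                   p_value = NA_real_, n = NA_integer_)
      }
    })
    tsv(do.call(rbind, rows), "fits.tsv")
  }
  if (!is.null(results$surface)) {
    tsv(results$surface$grid, "surface_grid.tsv")
  }
  if (!is.null(results$optimum)) {
    jsonlite::write_json(unclass(results$optimum),
                         file.path(out_dir, "optimum.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$phenotype_anova)) {
    for (nm in names(results$phenotype_anova))
      tsv(as.data.frame(results$phenotype_anova[[nm]]),
          paste0("anova_", nm, ".tsv"))
  }
  if (!is.null(results$tukey)) {
    for (nm in names(results$tukey)) {
      tk <- results$tukey[[nm]]
      tsv(tk$pairs, paste0("tukey_", nm, ".tsv"))
      tsv(data.frame(group = names(tk$letters), letters = unname(tk$letters)),
          paste0("tukey_letters_", nm, ".tsv"))
    }
  }
  invisible(out_dir)
}
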