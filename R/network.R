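#' Build a signed co-occurrence network from correlation pairs
#'
#' Applies the published edge rule: a pair becomes an edge when both the
#' Spearman and the Pearson p-value fall below `alpha` and the two
#' coefficients agree in sign; the edge carries that shared sign. All bands
#' that survived the frequency filter remain nodes whether or not they gain
#' an edge, which is what makes the interacting-vs-total node distinction of
#' the topology report meaningful.
#'
#' @param pairs A [correlate_pairs()] result.
#' @param nodes Named character vector of kingdom labels
#'   (`"bacteria"`/`"fungi"`) over all retained band ids, or a `band_matrix`.
#' @param alpha Significance level applied to both p-values. Default 0.05.
#' @param edge_rule `"both"` (published rule) or `"either"` (sensitivity
#'   mode: one significant test suffices; sign agreement still required).
#' @param p_adjust `"none"` (raw p, the published protocol) or `"BH"`
#'   (Benjamini-Hochberg within each correlation's p-vector across the pair
#'   panel before thresholding; used when false-edge control matters, e.g.
#'   planted-edge recovery benchmarks).
#' @param group Optional label recording which sample subset built the
#'   network.
#' @return Object of class `"microbial_network"`: a list with `graph`
#'   (an undirected `igraph` with vertex attribute `kingdom` and edge
#'   attributes `sign`, `rho_spearman`, `rho_pearson`, `p_spearman`,
#'   `p_pearson`), `edges` (data frame), `nodes` (data frame), `group`,
#'   `alpha`, `n_samples`.
#' @export
build_network <- function(pairs, nodes, alpha = 0.05,
                          edge_rule = c("both", "either"),
                          p_adjust = c("none", "BH"),
                          group = NA_character_) {
  edge_rule <- match.arg(edge_rule)
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1)
  if (inherits(nodes, "band_matrix")) nodes <- nodes$kingdom
  if (is.null(names(nodes))) stop("nodes must be a named kingdom vector")
  if (!all(nodes %in% c("bacteria", "fungi")))
    stop("kingdom labels must be 'bacteria' or 'fungi'")

  pairs <- as.data.frame(pairs)
  n_samples <- if (nrow(pairs)) pairs$n_samples[1] else NA_integer_
  if (nrow(pairs)) {
    unknown <- setdiff(unique(c(pairs$band_i, pairs$band_j)), names(nodes))
    if (length(unknown))
      stop("pair references band(s) without kingdom label: ",
           paste(unknown, collapse = ", "))
    ok <- pairs$valid
    ps <- pairs$p_spearman
    pp <- pairs$p_pearson
    if (p_adjust == "BH") {
      ps[ok] <- p.adjust(ps[ok], method = "BH")
      pp[ok] <- p.adjust(pp[ok], method = "BH")
    }
    sig <- if (edge_rule == "both") ps < alpha & pp < alpha
           else ps < alpha | pp < alpha
    agree <- sign(pairs$rho_spearman) == sign(pairs$rho_pearson) &
      sign(pairs$rho_spearman) != 0
    keep <- ok & !is.na(sig) & sig & agree
    edges <- pairs[keep, c("band_i", "band_j", "rho_spearman", "p_spearman",
                           "rho_pearson", "p_pearson"), drop = FALSE]
    edges$sign <- as.integer(sign(edges$rho_spearman))
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(band_i = character(), band_j = character(),
                        rho_spearman = numeric(), p_spearman = numeric(),
                        rho_pearson = numeric(), p_pearson = numeric(),
                        sign = integer())
  }

  vertices <- data.frame(name = names(nodes), kingdom = unname(nodes),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("band_i", "band_j", "sign", "rho_spearman", "rho_pearson",
              "p_spearman", "p_pearson")],
    directed = FALSE, vertices = vertices)
  structure(list(graph = g, edges = edges, nodes = vertices,
                 group = group, alpha = alpha, n_samples = n_samples),
            class = "microbial_network")
}

#' @export
print.microbial_network <- function(x, ...) {
  cat(sprintf("<microbial_network%s> %d nodes (%d interacting), %d edges\n",
              if (is.na(x$group)) "" else paste0(" ", x$group),
              igraph::vcount(x$graph),
              sum(igraph::degree(x$graph) > 0),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Count edges by endpoint kingdoms and by sign
#'
#' @param network A [build_network()] result.
#' @return List of class `"edge_class_counts"`: `bb`, `ff`, `bf` (edge counts
#'   by endpoint kingdoms), `positives`, `negatives`, `total`. Conservation
#'   holds by construction: `bb + ff + bf = positives + negatives = total`.
#' @export
classify_edges <- function(network) {
  stopifnot(inherits(network, "microbial_network"))
  kd <- setNames(network$nodes$kingdom, network$nodes$name)
  if (anyNA(kd)) stop("unlabelled node in network")
  e <- network$edges
  ki <- kd[e$band_i]; kj <- kd[e$band_j]
  structure(list(
    bb = sum(ki == "bacteria" & kj == "bacteria"),
    ff = sum(ki == "fungi" & kj == "fungi"),
    bf = sum(ki != kj),
    positives = sum(e$sign > 0),
    negatives = sum(e$sign < 0),
    total = nrow(e)
  ), class = "edge_class_counts")
}

#' Spinglass community detection
#'
#' Runs the spinglass algorithm per connected component (the algorithm
#' requires a connected graph), on the subgraph of interacting nodes
#' (degree >= 1). Components with fewer than 3 nodes are kept as single
#' communities. Reports the Newman-Girvan modularity of the combined
#' partition.
#'
#' @param network A [build_network()] result.
#' @param seed Integer seed (required; spinglass is stochastic).
#' @param spins Maximum number of spins per component. Default 25.
#' @param gamma Spinglass resolution parameter. Default 1.
#' @return List of class `"community_partition"`: `membership` (named
#'   integer vector over interacting nodes), `n_communities`, `modularity`
#'   (`NA` for an empty network).
#' @export
detect_communities <- function(network, seed, spins = 25, gamma = 1) {
  stopifnot(inherits(network, "microbial_network"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  g <- network$graph
  inter <- igraph::V(g)[igraph::degree(g) > 0]
  if (length(inter) == 0) {
    return(structure(list(membership = setNames(integer(0), character(0)),
                          n_communities = 0L, modularity = NA_real_),
                     class = "community_partition"))
  }
  gi <- igraph::induced_subgraph(g, inter)
  comp <- igraph::components(gi)
  membership <- integer(igraph::vcount(gi))
  names(membership) <- igraph::V(gi)$name
  set.seed(seed)
  offset <- 0L
  for (k in seq_len(comp$no)) {
    vk <- which(comp$membership == k)
    if (length(vk) < 3) {
      membership[vk] <- offset + 1L
      offset <- offset + 1L
    } else {
      sub <- igraph::induced_subgraph(gi, vk)
      cl <- igraph::cluster_spinglass(sub,
                                      spins = min(spins, igraph::vcount(sub)),
                                      gamma = gamma)
      membership[vk] <- offset + igraph::membership(cl)
      offset <- offset + max(igraph::membership(cl))
    }
  }
  mod <- igraph::modularity(gi, membership)
  structure(list(membership = membership,
                 n_communities = length(unique(membership)),
                 modularity = mod),
            class = "community_partition")
}

#' Average degree under both published conventions
#'
#' The published topology table mixes two formulas across its columns, so
#' both are first-class: `"two_e_over_n"` = 2E/N (the graph-theoretic mean
#' degree) and `"e_over_n"` = E/N.
#'
#' @param n_edges Edge count E.
#' @param n_nodes Node count N (interacting nodes).
#' @param convention `"two_e_over_n"` or `"e_over_n"`.
#' @return Numeric.
#' @export
#' @examples
#' avg_degree(520, 86)            # 12.09...
#' avg_degree(1024, 110, "e_over_n")  # 9.309...
avg_degree <- function(n_edges, n_nodes,
                       convention = c("two_e_over_n", "e_over_n")) {
  convention <- match.arg(convention)
  if (n_nodes == 0) return(NA_real_)
  if (convention == "two_e_over_n") 2 * n_edges / n_nodes
  else n_edges / n_nodes
}

#' Graph density under both published conventions
#'
#' `"total_nodes_directed_pairs"` divides E by the number of ordered node
#' pairs over the full band panel, `N_total * (N_total - 1)`;
#' `"interacting_nodes"` divides by `N_int * (N_int - 1)` over interacting
#' nodes only. The published table uses each in different columns.
#'
#' @param n_edges Edge count E.
#' @param n_total Total nodes (full filtered band panel).
#' @param n_interacting Nodes with degree >= 1.
#' @param convention Which denominator to use.
#' @return Numeric density.
#' @export
#' @examples
#' graph_density(448, n_total = 157)                       # 0.018...
#' graph_density(1024, n_interacting = 110,
#'               convention = "interacting_nodes")         # 0.085...
graph_density <- function(n_edges, n_total = NULL, n_interacting = NULL,
                          convention = c("total_nodes_directed_pairs",
                                         "interacting_nodes")) {
  convention <- match.arg(convention)
  if (convention == "total_nodes_directed_pairs") {
    stopifnot(!is.null(n_total))
    if (n_total < 2) return(NA_real_)
    n_edges / (n_total * (n_total - 1))
  } else {
    stopifnot(!is.null(n_interacting))
    if (n_interacting < 2) return(NA_real_)
    n_edges / (n_interacting * (n_interacting - 1))
  }
}

#' Full topology report for one network
#'
#' The machine twin of one column of the published topology table: node and
#' edge counts, kingdom percentages among interacting nodes, sign counts and
#' their ratio, kingdom-partitioned edge classes, average degree and density
#' under both conventions, spinglass communities and modularity, and average
#' clustering coefficient, average path length and diameter computed on the
#' largest connected component.
#'
#' @param network A [build_network()] result.
#' @param partition Optional [detect_communities()] result; computed with
#'   `seed` if omitted.
#' @param config An [analysis_config()] (selects which degree/density
#'   convention is labelled primary; both are always present).
#' @param seed Seed used if `partition` must be computed.
#' @return One-row data frame of class `"topology_report"`.
#' @export
topology_report <- function(network, partition = NULL,
                            config = analysis_config(), seed = NULL) {
  stopifnot(inherits(network, "microbial_network"))
  g <- network$graph
  if (is.null(partition)) partition <- detect_communities(network, seed = seed)
  deg <- igraph::degree(g)
  n_total <- igraph::vcount(g)
  inter <- names(deg)[deg > 0]
  n_int <- length(inter)
  e <- igraph::ecount(g)
  counts <- classify_edges(network)
  kd <- setNames(network$nodes$kingdom, network$nodes$name)

  if (n_int > 0) {
    gi <- igraph::induced_subgraph(g, inter)
    comp <- igraph::components(gi)
    lcc <- igraph::induced_subgraph(
      gi, which(comp$membership == which.max(comp$csize)))
    clustering <- igraph::transitivity(lcc, type = "localaverage",
                                       isolates = "zero")
    path_len <- igraph::mean_distance(lcc)
    diam <- igraph::diameter(lcc)
  } else {
    clustering <- NA_real_; path_len <- NA_real_; diam <- NA_real_
  }

  out <- data.frame(
    group = network$group,
    total_nodes = n_total,
    interacting_nodes = n_int,
    pct_bacteria_nodes = if (n_int) 100 * mean(kd[inter] == "bacteria")
                         else NA_real_,
    pct_fungi_nodes = if (n_int) 100 * mean(kd[inter] == "fungi")
                      else NA_real_,
    total_edges = e,
    positives = counts$positives,
    negatives = counts$negatives,
    pos_neg_ratio = if (counts$negatives > 0)
      counts$positives / counts$negatives else NA_real_,
    bb_edges = counts$bb,
    ff_edges = counts$ff,
    bf_edges = counts$bf,
    avg_degree_2e_over_n = avg_degree(e, n_int, "two_e_over_n"),
    avg_degree_e_over_n = avg_degree(e, n_int, "e_over_n"),
    density_total_nodes = graph_density(e, n_total = n_total),
    density_interacting = graph_density(e, n_interacting = n_int,
                                        convention = "interacting_nodes"),
    n_communities = partition$n_communities,
    modularity = partition$modularity,
    avg_clustering_coefficient = clustering,
    avg_path_length = path_len,
    diameter = diam,
    stringsAsFactors = FALSE
  )
  out$avg_degree <- if (config$degree_convention == "two_e_over_n")
    out$avg_degree_2e_over_n else out$avg_degree_e_over_n
  out$graph_density <- if (config$density_convention ==
                           "total_nodes_directed_pairs")
    out$density_total_nodes else out$density_interacting
  class(out) <- c("topology_report", "data.frame")
  out
}

#' Per-group co-occurrence networks
#'
#' Splits the samples by treatment factor and infers one network per group
#' over the shared filtered band panel: grouping by `"source"` gives four
#' networks of 8 samples each (both inoculum levels pooled); grouping by
#' `"inoculum"` gives two networks of 16 samples (all sources pooled). This
#' mirrors the constant total-node panel across the published table's
#' columns.
#'
#' @param matrix A frequency-filtered [band_matrix()].
#' @param samples Sample table matching the matrix rows.
#' @param group_by `"source"` or `"inoculum"`.
#' @param config An [analysis_config()].
#' @param seed Base seed; group k uses `seed + k` for its permutation
#'   p-values.
#' @return Named list of `microbial_network` objects.
#' @export
group_networks <- function(matrix, samples, group_by = c("source", "inoculum"),
                           config = analysis_config(), seed = NULL) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(matrix, "band_matrix"))
  samples <- samples[match(sample_ids(matrix), samples$sample_id), ,
                     drop = FALSE]
  fac <- if (group_by == "inoculum")
    ifelse(samples$inoculum, "+Inoculum", "-Inoculum") else samples$source
  groups <- unique(fac)
  out <- list()
  for (k in seq_along(groups)) {
    gname <- groups[k]
    sub <- band_matrix(
      matrix$intensities[fac == gname, , drop = FALSE], matrix$kingdom)
    prs <- correlate_pairs(sub, binarize = config$binarize,
                           p_method = config$p_method,
                           seed = if (is.null(seed)) NULL else seed + k)
    out[[gname]] <- build_network(prs, matrix$kingdom,
                                  alpha = config$edge_alpha,
                                  edge_rule = config$edge_rule,
                                  p_adjust = config$p_adjust,
                                  group = gname)
  }
  out
}

#' Topology table across a list of networks
#'
#' One report row per network, mirroring the published table's column-per-
#' treatment layout (transposed: here networks are rows).
#'
#' @param networks Named list of `microbial_network` objects.
#' @param config An [analysis_config()].
#' @param seed Base seed for spinglass; network k uses `seed + k`.
#' @return Data frame with one row per network.
#' @export
topology_table <- function(networks, config = analysis_config(), seed = NULL) {
  rows <- lapply(seq_along(networks), function(k) {
    topology_report(networks[[k]], config = config,
                    seed = if (is.null(seed)) NULL else seed + k)
  })
  do.call(rbind, rows)
}
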