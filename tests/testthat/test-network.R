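make_pairs <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$n_samples <- 8L
  if (is.null(df$valid)) df$valid <- TRUE
  df
}

test_that("correlate_pairs reports exact dependence and invalid bands", {
  x <- matrix(c(1, 3, 2, 5, 4, 8, 7, 6), 8, 1)
  m <- cbind(b1 = x, b2 = 2 * x, b3 = rep(4, 8))
  colnames(m) <- c("b1", "b2", "b3")
  rownames(m) <- sprintf("s%d", 1:8)
  bm <- band_matrix(m, c(b1 = "bacteria", b2 = "bacteria", b3 = "fungi"))
  pr <- correlate_pairs(bm, p_method = "analytic")
  p12 <- pr[pr$band_i == "b1" & pr$band_j == "b2", ]
  expect_equal(p12$rho_spearman, 1)
  expect_equal(p12$rho_pearson, 1)
  # the constant band invalidates its pairs without raising
  expect_false(any(pr$valid[pr$band_i == "b3" | pr$band_j == "b3"]))
  expect_error(correlate_pairs(band_matrix(m[1:3, ], bm$kingdom)),
               "at least 4 samples")
})

test_that("analytic p approximates the exact permutation p at n = 8", {
  set.seed(17)
  x <- exp(rnorm(8)); y <- 0.6 * x + exp(rnorm(8))
  m <- cbind(u = x, v = y)
  rownames(m) <- sprintf("s%d", 1:8)
  bm <- band_matrix(m, c(u = "bacteria", v = "fungi"))
  exact <- correlate_pairs(bm, p_method = "permutation")
  approx <- correlate_pairs(bm, p_method = "analytic")
  expect_identical(attr(exact, "p_method"), "permutation")
  expect_lt(abs(exact$p_pearson - approx$p_pearson), 0.02)
  expect_lt(abs(exact$p_spearman - approx$p_spearman), 0.02)
  # exact p of a perfect monotone pair is the enumeration floor, 2/8!
  m2 <- cbind(u = sort(x), v = sort(y))
  rownames(m2) <- sprintf("s%d", 1:8)
  pr2 <- correlate_pairs(band_matrix(m2, bm$kingdom))
  expect_equal(pr2$p_spearman, 2 / factorial(8), tolerance = 1e-12)
})

test_that("edge calling applies the dual-significance sign-agreement rule", {
  nodes <- c(a = "bacteria", b = "bacteria", c = "fungi")
  pr <- make_pairs(
    list(band_i = "a", band_j = "b", rho_spearman = 0.9, p_spearman = 0.002,
         rho_pearson = 0.8, p_pearson = 0.007),       # edge, positive
    list(band_i = "a", band_j = "c", rho_spearman = 0.9, p_spearman = 0.002,
         rho_pearson = 0.6, p_pearson = 0.2),         # Pearson fails
    list(band_i = "b", band_j = "c", rho_spearman = 0.8, p_spearman = 0.01,
         rho_pearson = -0.7, p_pearson = 0.01))       # sign conflict
  nw <- build_network(pr, nodes, alpha = 0.05)
  expect_equal(nrow(nw$edges), 1)
  expect_equal(nw$edges$band_i, "a")
  expect_equal(nw$edges$band_j, "b")
  expect_equal(nw$edges$sign, 1L)
  # isolated node c is retained in the graph
  expect_equal(igraph::vcount(nw$graph), 3)
  # the either-rule admits the single-test pair but not the sign conflict
  nw2 <- build_network(pr, nodes, alpha = 0.05, edge_rule = "either")
  expect_equal(nrow(nw2$edges), 2)
  # empty pair list is an empty network, not an error
  nw0 <- build_network(pr[0, ], nodes, alpha = 0.05)
  expect_equal(igraph::ecount(nw0$graph), 0)
  expect_equal(igraph::vcount(nw0$graph), 3)
})

test_that("edge sets grow monotonically with alpha", {
  for (s in 1:5) {
    bm <- random_band_matrix(n = 16, m = 15, seed = 300 + s)
    pr <- correlate_pairs(bm, p_method = "analytic")
    alphas <- c(0.01, 0.05, 0.2, 0.5)
    prev <- character(0)
    for (a in alphas) {
      nw <- build_network(pr, bm, alpha = a)
      cur <- edge_key(nw$edges$band_i, nw$edges$band_j)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("edge classes are counted and conserved", {
  # a synthetic network with the published BA column's class mix:
  # 156 bacteria-bacteria + 84 fungi-fungi + 208 bacteria-fungi = 448
  set.seed(4)
  b <- sprintf("b%02d", 1:30); f <- sprintf("f%02d", 1:20)
  nodes <- setNames(rep(c("bacteria", "fungi"), c(30, 20)), c(b, f))
  pick <- function(pool_i, pool_j, k, same) {
    all_pairs <- expand.grid(i = pool_i, j = pool_j,
                             stringsAsFactors = FALSE)
    if (same) all_pairs <- all_pairs[all_pairs$i < all_pairs$j, ]
    all_pairs[sample(nrow(all_pairs), k), ]
  }
  eds <- rbind(pick(b, b, 156, TRUE), pick(f, f, 84, TRUE),
               pick(b, f, 208, FALSE))
  sgn <- rep(c(1, -1), length.out = nrow(eds))
  pr <- data.frame(band_i = eds$i, band_j = eds$j,
                   rho_spearman = 0.9 * sgn, p_spearman = 1e-4,
                   rho_pearson = 0.8 * sgn, p_pearson = 1e-4,
                   n_samples = 8L, valid = TRUE)
  nw <- build_network(pr, nodes, alpha = 0.05)
  cls <- classify_edges(nw)
  expect_equal(cls$bb, 156)
  expect_equal(cls$ff, 84)
  expect_equal(cls$bf, 208)
  expect_equal(cls$bb + cls$ff + cls$bf, 448)
  expect_equal(cls$positives + cls$negatives, cls$total)
  expect_equal(cls$total, 448)

  # all-bacteria network has no fungal or mixed edges
  nb <- setNames(rep("bacteria", 30), b)
  prb <- pr[pr$band_i %in% b & pr$band_j %in% b, ]
  clb <- classify_edges(build_network(prb, nb, alpha = 0.05))
  expect_equal(clb$ff, 0)
  expect_equal(clb$bf, 0)
})

test_that("class and sign conservation holds on random synthetic networks", {
  for (s in 1:10) {
    bm <- random_band_matrix(n = 16, m = 18, seed = 500 + s)
    pr <- correlate_pairs(bm, p_method = "analytic")
    nw <- build_network(pr, bm, alpha = 0.3)
    cls <- classify_edges(nw)
    expect_equal(cls$bb + cls$ff + cls$bf, cls$total)
    expect_equal(cls$positives + cls$negatives, cls$total)
    expect_equal(cls$total, igraph::ecount(nw$graph))
    # every edge's sign matches both coefficients' shared sign
    expect_true(all(sign(nw$edges$rho_spearman) == nw$edges$sign))
    expect_true(all(sign(nw$edges$rho_pearson) == nw$edges$sign))
  }
})

clique_bridge_network <- function() {
  # two 4-cliques joined by one bridge edge
  b <- sprintf("n%d", 1:8)
  nodes <- setNames(rep(c("bacteria", "fungi"), each = 4), b)
  e1 <- t(combn(b[1:4], 2)); e2 <- t(combn(b[5:8], 2))
  eds <- rbind(e1, e2, c(b[4], b[5]))
  pr <- data.frame(band_i = eds[, 1], band_j = eds[, 2],
                   rho_spearman = 0.9, p_spearman = 1e-4,
                   rho_pearson = 0.9, p_pearson = 1e-4,
                   n_samples = 8L, valid = TRUE)
  build_network(pr, nodes, alpha = 0.05)
}

test_that("spinglass finds the optimal two-community split of bridged cliques", {
  nw <- clique_bridge_network()
  part <- detect_communities(nw, seed = 5)
  expect_equal(part$n_communities, 2)
  ms <- part$membership[sprintf("n%d", 1:8)]
  expect_equal(length(unique(ms[1:4])), 1)
  expect_equal(length(unique(ms[5:8])), 1)
  # modularity equals the exhaustive maximum over all 4140 partitions
  eds <- cbind(match(nw$edges$band_i, names(ms)),
               match(nw$edges$band_j, names(ms)))
  expect_equal(part$modularity, max_modularity_oracle(eds, 8),
               tolerance = 1e-12)
  # determinism under a fixed seed
  part2 <- detect_communities(nw, seed = 5)
  expect_identical(part$membership, part2$membership)
})

test_that("a complete graph is a single community with nonpositive modularity", {
  b <- sprintf("k%d", 1:6)
  eds <- t(combn(b, 2))
  pr <- data.frame(band_i = eds[, 1], band_j = eds[, 2],
                   rho_spearman = 0.9, p_spearman = 1e-4,
                   rho_pearson = 0.9, p_pearson = 1e-4,
                   n_samples = 8L, valid = TRUE)
  nw <- build_network(pr, setNames(rep("bacteria", 6), b), alpha = 0.05)
  part <- detect_communities(nw, seed = 2)
  expect_equal(part$n_communities, 1)
  expect_lte(part$modularity, 1e-12)
})

test_that("reported modularity matches the hand-rolled evaluator", {
  for (s in 1:6) {
    bm <- random_band_matrix(n = 16, m = 8, seed = 700 + s, zero_frac = 0)
    pr <- correlate_pairs(bm, p_method = "analytic")
    nw <- build_network(pr, bm, alpha = 0.4)
    if (igraph::ecount(nw$graph) == 0) next
    part <- detect_communities(nw, seed = s)
    ids <- names(part$membership)
    eds <- cbind(match(nw$edges$band_i, ids), match(nw$edges$band_j, ids))
    eds <- eds[stats::complete.cases(eds), , drop = FALSE]
    expect_equal(part$modularity,
                 modularity_oracle(eds, part$membership, length(ids)),
                 tolerance = 1e-12)
  }
})

test_that("degree, density and ratio formulas reproduce published arithmetic", {
  expect_equal(round(avg_degree(520, 86), 2), 12.09)
  expect_equal(round(avg_degree(1024, 110, "e_over_n"), 3), 9.309)
  expect_equal(round(graph_density(448, n_total = 157), 3), 0.018)
  expect_equal(round(graph_density(1024, n_interacting = 110,
                                   convention = "interacting_nodes"), 3),
               0.085)
  expect_equal(round(256 / 192, 2), 1.33)
})

test_that("topology report computes path metrics on the largest component", {
  # path graph on 3 nodes plus one isolated node
  nodes <- setNames(c(rep("bacteria", 3), "fungi"),
                    c("p1", "p2", "p3", "iso"))
  pr <- data.frame(band_i = c("p1", "p2"), band_j = c("p2", "p3"),
                   rho_spearman = c(0.9, -0.9), p_spearman = 1e-4,
                   rho_pearson = c(0.9, -0.9), p_pearson = 1e-4,
                   n_samples = 8L, valid = TRUE)
  nw <- build_network(pr, nodes, alpha = 0.05)
  tr <- topology_report(nw, seed = 1)
  expect_equal(tr$total_nodes, 4)
  expect_equal(tr$interacting_nodes, 3)
  expect_equal(tr$avg_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(tr$diameter, 2)
  expect_equal(tr$pos_neg_ratio, 1)
  expect_equal(tr$pct_bacteria_nodes, 100)
  expect_equal(tr$avg_degree_2e_over_n, 2 * 2 / 3, tolerance = 1e-12)
  expect_equal(tr$density_total_nodes, 2 / (4 * 3), tolerance = 1e-12)

  # triangle: clustering coefficient 1
  prt <- data.frame(band_i = c("p1", "p1", "p2"),
                    band_j = c("p2", "p3", "p3"),
                    rho_spearman = 0.9, p_spearman = 1e-4,
                    rho_pearson = 0.9, p_pearson = 1e-4,
                    n_samples = 8L, valid = TRUE)
  nwt <- build_network(prt, nodes[1:3], alpha = 0.05)
  trt <- topology_report(nwt, seed = 1)
  expect_equal(trt$avg_clustering_coefficient, 1)
})

test_that("Benjamini-Hochberg mode only removes edges relative to raw p", {
  bm <- random_band_matrix(n = 20, m = 20, seed = 41)
  pr <- correlate_pairs(bm, p_method = "analytic")
  raw <- build_network(pr, bm, alpha = 0.05)
  bh <- build_network(pr, bm, alpha = 0.05, p_adjust = "BH")
  raw_keys <- edge_key(raw$edges$band_i, raw$edges$band_j)
  bh_keys <- edge_key(bh$edges$band_i, bh$edges$band_j)
  expect_true(all(bh_keys %in% raw_keys))
})
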