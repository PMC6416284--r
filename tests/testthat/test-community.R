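test_that("frequency filter applies the inclusive 25% rule", {
  x <- matrix(1, 8, 3, dimnames = list(sprintf("s%d", 1:8),
                                       c("common", "quarter", "single")))
  x[1:6, "quarter"] <- 0   # present in exactly 2/8 = 25%
  x[1:7, "single"] <- 0    # present in 1/8
  bm <- band_matrix(x, c(common = "bacteria", quarter = "bacteria",
                         single = "fungi"))
  f <- filter_low_frequency(bm, 0.25)
  expect_setequal(band_ids(f), c("common", "quarter"))
  # all bands everywhere: identity
  full <- band_matrix(matrix(1, 4, 2, dimnames = list(letters[1:4],
                                                      c("b1", "b2"))),
                      c(b1 = "bacteria", b2 = "fungi"))
  expect_identical(filter_low_frequency(full, 0.25)$intensities,
                   full$intensities)
  rare <- band_matrix(x[, c("quarter", "single")],
                      c(quarter = "bacteria", single = "fungi"))
  expect_error(filter_low_frequency(rare, 0.9), "removed every band")
})

test_that("Bray-Curtis matches its closed form and invariants", {
  m <- rbind(a = c(1, 2, 0), b = c(0, 2, 4), c = c(1, 2, 0))
  colnames(m) <- c("x", "y", "z")
  bm <- band_matrix(m, c(x = "bacteria", y = "bacteria", z = "fungi"))
  d <- as.matrix(bray_curtis(bm, normalize = FALSE))
  expect_equal(d["a", "b"], 1 - 2 * 2 / 9, tolerance = 1e-12)  # 0.5556
  expect_equal(d["a", "c"], 0)
  disj <- band_matrix(matrix(c(1, 0, 0, 3), 2,
                             dimnames = list(c("a", "b"), c("u", "v"))),
                      c(u = "bacteria", v = "fungi"))
  expect_equal(as.vector(bray_curtis(disj, normalize = FALSE)), 1)
  # column order invariance
  perm <- sample(ncol(m))
  bm2 <- band_matrix(m[, perm], bm$kingdom[perm])
  expect_equal(as.matrix(bray_curtis(bm2)), as.matrix(bray_curtis(bm)))
  # all-zero sample is undefined
  zero <- band_matrix(matrix(c(0, 1, 0, 2), 2,
                             dimnames = list(c("a", "b"), c("u", "v"))),
                      c(u = "bacteria", v = "fungi"))
  expect_error(bray_curtis(zero), "all-zero")
})

test_that("PCoA reproduces classical-scaling geometry", {
  # two samples at distance d embed at +/- d/2
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  ord <- pcoa(stats::as.dist(d2), k = 1)
  expect_equal(sort(ord$coordinates[, 1]), c(-0.3, 0.3),
               ignore_attr = TRUE)

  # collinear points: axis 1 recovers spacing, axis 2 carries nothing
  pts <- c(0, 1, 3)
  d3 <- dist(pts)
  expect_warning(ord3 <- pcoa(d3, k = 2), "positive eigenvalues")
  ax1 <- ord3$coordinates[, 1]
  expect_equal(abs(diff(ax1)), c(1, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(abs(ord3$eigenvalues[2]), 1e-9)

  # planar points: embedded pairwise distances reproduce the input
  set.seed(5)
  xy <- matrix(rnorm(12), 6, 2)
  dp <- dist(xy)
  op <- pcoa(dp, k = 2)
  expect_equal(as.matrix(dist(op$coordinates)), as.matrix(dp),
               tolerance = 1e-9)
  # eigenvalues nonincreasing, coordinates centered
  expect_true(all(diff(op$eigenvalues) <= 1e-9))
  expect_equal(colSums(op$coordinates), c(PCoA1 = 0, PCoA2 = 0),
               tolerance = 1e-9)
})

test_that("UPGMA merges nearest pair first and is exact on ultrametric input", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma(stats::as.dist(d))
  expect_equal(hc$height[1], 1)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("A", "B"))
  expect_true(all(diff(hc$height) >= 0))

  # ultrametric distances are reproduced exactly by the cophenetic oracle
  du <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 4,
                 8, 8, 4, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  hcu <- upgma(stats::as.dist(du))
  expect_equal(as.matrix(cophenetic(hcu))[letters[1:4], letters[1:4]], du,
               tolerance = 1e-12)
})

test_that("PERMANOVA partitions variance exactly like the vegan oracle", {
  st <- generate_study(synthetic_config(), seed = 21)
  f <- filter_low_frequency(st$band_matrix)
  d <- bray_curtis(f)
  mine <- permanova(d, st$samples, n_perm = 99, seed = 5)
  ora <- vegan::adonis2(d ~ source + inoculum, data = st$samples,
                        permutations = 99, by = "terms")
  expect_equal(mine$ss[1:2], ora$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(mine$pseudo_f[1:2], ora$F[1:2], tolerance = 1e-10)
  expect_equal(mine$r2[1:2], ora$R2[1:2], tolerance = 1e-10)
  # R2 conservation and p-value bounds
  expect_equal(sum(mine$r2[1:3]), 1, tolerance = 1e-12)
  expect_true(all(mine$p_value[1:2] >= 1 / 100 &
                    mine$p_value[1:2] <= 1))
})

test_that("PERMANOVA pseudo-F is invariant to joint sample reordering", {
  st <- generate_study(synthetic_config(), seed = 8)
  f <- filter_low_frequency(st$band_matrix)
  d <- as.matrix(bray_curtis(f))
  r1 <- permanova(stats::as.dist(d), st$samples, n_perm = 49, seed = 1)
  set.seed(42)
  p <- sample(nrow(d))
  r2 <- permanova(stats::as.dist(d[p, p]), st$samples[p, ],
                  n_perm = 49, seed = 1)
  expect_equal(r1$pseudo_f[1:2], r2$pseudo_f[1:2], tolerance = 1e-10)
  expect_equal(r1$ss, r2$ss, tolerance = 1e-10)
})

test_that("PERMANOVA enumerates small designs exhaustively", {
  # two groups of 3 with extreme separation: enumeration of all 720 sample
  # orders; only the 72 orders reproducing the split (in either orientation)
  # reach the observed F, so the exact p is 2/20
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- dist(pts)
  samples <- data.frame(sample_id = as.character(1:6),
                        grp = rep(c("lo", "hi"), each = 3))
  res <- permanova(d, samples, terms = "grp")
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_perm_used"), 720)
  expect_equal(res$p_value[1], 2 / 20, tolerance = 1e-12)
  expect_error(permanova(d, data.frame(sample_id = as.character(1:6),
                                       grp = "one"), terms = "grp"),
               "single level")
})

test_that("PERMANOVA permutation p is calibrated under the null", {
  # structureless data: empirical type-I error at alpha = 0.05 stays within
  # 0.05 +/- 0.02 across 500 simulated datasets at 999 permutations; two
  # groups of 6 give 924 distinct splits, fine enough that discreteness of
  # the permutation distribution does not floor the attainable p-values
  set.seed(99)
  rejections <- 0
  n_sets <- 500
  for (i in seq_len(n_sets)) {
    x <- matrix(exp(rnorm(12 * 12)), 12, 12)
    rownames(x) <- sprintf("s%02d", 1:12)
    d <- vegan::vegdist(x / rowSums(x), method = "bray")
    samples <- data.frame(sample_id = rownames(x),
                          grp = rep(c("a", "b"), each = 6))
    res <- permanova(d, samples, terms = "grp", n_perm = 999, seed = i,
                     exhaustive_limit = 1)
    rejections <- rejections + (res$p_value[1] < 0.05)
  }
  expect_lt(abs(rejections / n_sets - 0.05), 0.02)
})

test_that("a planted source effect dominates an absent inoculum effect", {
  # source R2 exceeds inoculum R2 in at least 95 of 100 seeded runs
  cfg <- synthetic_config(inoculum_effect_sd = c(bacteria = 0, fungi = 0))
  wins <- 0
  for (s in 1:100) {
    st <- generate_study(cfg, seed = 4000 + s)
    f <- filter_low_frequency(st$band_matrix)
    d <- bray_curtis(f)
    res <- permanova(d, st$samples, n_perm = 1, seed = 1)
    wins <- wins + (res$r2[1] > res$r2[2])
  }
  expect_gte(wins, 95)
})
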