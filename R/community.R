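#' Remove low-frequency bands
#'
#' Drops bands present (intensity > 0) in fewer than `min_freq` of the
#' samples; the published protocol used a minimal frequency of 25%, which
#' eliminates singleton bands. The boundary is inclusive: a band present in
#' exactly `min_freq` of the samples is retained. Sample set and band order
#' are preserved.
#'
#' @param matrix A [band_matrix()].
#' @param min_freq Minimum presence proportion in (0, 1]. Default 0.25.
#' @return A filtered `band_matrix`.
#' @export
filter_low_frequency <- function(matrix, min_freq = 0.25) {
  stopifnot(inherits(matrix, "band_matrix"))
  stopifnot(min_freq > 0, min_freq <= 1)
  freq <- colMeans(matrix$intensities > 0)
  keep <- freq >= min_freq - 1e-12
  if (!any(keep)) stop("frequency filter removed every band")
  band_matrix(matrix$intensities[, keep, drop = FALSE],
              matrix$kingdom[keep])
}

#' Bray-Curtis distance between sample profiles
#'
#' `d(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`. By default each
#' sample row is first rescaled to unit sum, because gel lanes vary in total
#' signal; pass `normalize = FALSE` for raw intensities.
#'
#' @param matrix A [band_matrix()] (or a plain numeric matrix, samples in
#'   rows).
#' @param normalize Rescale rows to unit sum first. Default `TRUE`.
#' @return A `dist` object over samples with values in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 2, 0, 4), 2, 3, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("x", "y", "z")))
#' bray_curtis(band_matrix(m, c(x = "bacteria", y = "bacteria",
#'                              z = "fungi")), normalize = FALSE)
bray_curtis <- function(matrix, normalize = TRUE) {
  x <- if (inherits(matrix, "band_matrix")) matrix$intensities else
    as.matrix(matrix)
  if (nrow(x) < 2) stop("Bray-Curtis needs at least 2 samples")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("sample(s) with all-zero intensities have undefined distance: ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  if (normalize) x <- x / rs
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical scaling: the matrix of `-d^2/2` is double-centered and
#' eigendecomposed; axes are ordered by decreasing eigenvalue and only axes
#' with positive eigenvalues carry coordinates. Negative eigenvalues (possible
#' for non-Euclidean distances such as Bray-Curtis) are reported but excluded.
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param k Number of axes requested (at most n - 1). If fewer positive
#'   eigenvalues exist, the result is reduced with a warning.
#' @return A list of class `"pcoa_ordination"`: `coordinates`
#'   (samples x axes, column-centered), `eigenvalues` (all n, nonincreasing),
#'   `proportion_explained` (per returned axis, relative to the positive
#'   eigenvalue total).
#' @export
pcoa <- function(dist, k = 2) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  if (k > n - 1) stop("k must be at most n - 1")
  # request every axis; negative/zero eigenvalues are handled below, so
  # cmdscale's own count warning is redundant here
  eig_all <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  ev <- eig_all$eig
  tol <- max(abs(ev)) * 1e-8
  n_pos <- sum(ev > tol)
  k_use <- k
  if (k > n_pos) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes",
                    n_pos, n_pos))
    k_use <- n_pos
  }
  coords <- eig_all$points[, seq_len(k_use), drop = FALSE]
  colnames(coords) <- paste0("PCoA", seq_len(k_use))
  structure(list(
    coordinates = coords,
    eigenvalues = ev,
    proportion_explained = ev[seq_len(k_use)] / sum(ev[ev > tol])
  ), class = "pcoa_ordination")
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @return An `hclust` object (merge heights are nondecreasing for average
#'   linkage on a proper dissimilarity).
#' @seealso [write_dendrogram_newick()]
#' @export
upgma <- function(dist) {
  d <- stats::as.dist(dist)
  if (attr(d, "Size") < 2) stop("need at least 2 samples")
  hclust(d, method = "average")
}

#' PERMANOVA: sequential partition of a distance matrix
#'
#' Permutational multivariate ANOVA of `dist ~ term1 + term2 + ...` with
#' sequential (Type I) sums of squares, in the published model's order
#' (phosphate source, then inoculum). The squared distances are Gower-centered
#' into `G`; the SS of each term is the increment in `tr(H G)` over nested
#' hat matrices, pseudo-F uses the residual mean square, and p-values come
#' from free permutation of the sample labels with the add-one estimator
#' `p = (1 + #[F* >= F]) / (1 + n_perm)`. When the number of sample orderings
#' `n!` is at most `exhaustive_limit`, all of them are enumerated and the
#' p-value is exact (`p = #[F* >= F] / n!`, identity included).
#'
#' @param dist A `dist` object or symmetric distance matrix over samples.
#' @param samples Sample table whose rows match the distance labels.
#' @param terms Character vector of factor column names, in model order.
#'   Default `c("source", "inoculum")`.
#' @param n_perm Number of random permutations (ignored in exhaustive mode).
#' @param seed Integer seed for the permutations (required unless exhaustive).
#' @param exhaustive_limit Enumerate all orderings when `n! <=` this.
#' @return Data frame of class `"permanova_result"`: one row per term plus
#'   `Residual` and `Total`, with columns `df`, `ss`, `pseudo_f`, `r2`,
#'   `p_value`, and attributes `n_perm_used` and `exhaustive`.
#' @export
permanova <- function(dist, samples, terms = c("source", "inoculum"),
                      n_perm = 9999, seed = NULL, exhaustive_limit = 10000) {
  d <- as.matrix(stats::as.dist(dist))
  n <- nrow(d)
  if (!is.null(rownames(d)) && all(rownames(d) %in% samples$sample_id))
    samples <- samples[match(rownames(d), samples$sample_id), , drop = FALSE]
  if (nrow(samples) != n) stop("sample table does not match distance matrix")
  miss <- setdiff(terms, names(samples))
  if (length(miss)) stop("term(s) not in sample table: ",
                         paste(miss, collapse = ", "))
  for (tm in terms) {
    if (length(unique(samples[[tm]])) < 2)
      stop("term '", tm, "' has a single level")
  }

  ctr <- diag(n) - 1 / n
  g <- -0.5 * ctr %*% (d^2) %*% ctr
  ss_total <- sum(diag(g))

  # nested hat matrices for the sequential decomposition
  hats <- vector("list", length(terms))
  dfs <- numeric(length(terms))
  df_prev <- 1
  for (k in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(k)],
                                              collapse = "+")))
    x <- model.matrix(fml, data = samples)
    q <- qr(x)
    qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(qq)
    dfs[k] <- q$rank - df_prev
    df_prev <- q$rank
  }
  df_res <- n - df_prev
  if (df_res <= 0) stop("no residual degrees of freedom")

  stat_fun <- function(gp) {
    tr <- vapply(hats, function(h) sum(h * gp), numeric(1))
    ss_terms <- diff(c(0, tr))
    ss_res <- sum(diag(gp)) - tr[length(tr)]
    f <- (ss_terms / dfs) / (ss_res / df_res)
    list(ss_terms = ss_terms, ss_res = ss_res, f = f)
  }
  obs <- stat_fun(g)

  n_total_perm <- factorial(n)
  exhaustive <- is.finite(n_total_perm) && n_total_perm <= exhaustive_limit
  if (exhaustive) {
    perms <- all_permutations(n)
    count <- numeric(length(terms))
    for (b in seq_len(nrow(perms))) {
      p <- perms[b, ]
      fp <- stat_fun(g[p, p])$f
      count <- count + (fp >= obs$f - 1e-12)
    }
    p_value <- count / nrow(perms)
    n_perm_used <- nrow(perms)
  } else {
    if (is.null(seed)) stop("an explicit seed is required for random permutations")
    set.seed(seed)
    count <- numeric(length(terms))
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      fp <- stat_fun(g[p, p])$f
      count <- count + (fp >= obs$f - 1e-12)
    }
    p_value <- (1 + count) / (1 + n_perm)
    n_perm_used <- n_perm
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    ss = c(obs$ss_terms, obs$ss_res, ss_total),
    pseudo_f = c(obs$f, NA, NA),
    r2 = c(obs$ss_terms, obs$ss_res, ss_total) / ss_total,
    p_value = c(p_value, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm_used") <- n_perm_used
  attr(out, "exhaustive") <- exhaustive
  class(out) <- c("permanova_result", "data.frame")
  out
}

# all n! permutations of 1..n as rows (n kept small by callers)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  })
  do.call(rbind, out)
}
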