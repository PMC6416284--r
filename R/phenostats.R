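#' Two-factor ANOVA with interaction
#'
#' Partitions a response (total dry matter, colonization, leaf nutrients)
#' over two crossed factors, their interaction, and residual. Balanced
#' layouts use the classical sequential decomposition; unbalanced layouts
#' fall back to Type II sums of squares.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factor labels (e.g. phosphate source and
#'   inoculum), each with at least 2 levels and no empty cell.
#' @return Data frame of class `"anova_table"` with rows for A, B, A:B and
#'   Residuals: columns `term`, `df`, `ss`, `ms`, `f`, `p_value`.
#' @export
anova_two_factor <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("both factors need at least 2 levels")
  cells <- table(a, b)
  if (any(cells == 0)) stop("empty factor cell in the two-way layout")
  balanced <- length(unique(c(cells))) == 1
  dat <- data.frame(y = values, a = a, b = b)
  fit <- lm(y ~ a * b, data = dat)
  if (balanced) {
    tab <- anova(fit)
  } else {
    tab <- car::Anova(fit, type = 2)
    # reorder to A, B, A:B, Residuals and add MS
    tab <- tab[c("a", "b", "a:b", "Residuals"), ]
    tab <- data.frame(`Sum Sq` = tab[["Sum Sq"]], Df = tab[["Df"]],
                      `F value` = tab[["F value"]], `Pr(>F)` = tab[["Pr(>F)"]],
                      check.names = FALSE)
    tab <- tab[, c("Df", "Sum Sq", "F value", "Pr(>F)")]
  }
  ss <- tab[["Sum Sq"]]; df <- tab[["Df"]]
  ms <- ss / df
  f <- tab[["F value"]]; p <- tab[["Pr(>F)"]]
  # degenerate data: all observations identical -> define F = 0, p = 1
  zero <- abs(ss) < 1e-12
  res <- length(ss)
  f[seq_len(res - 1)][zero[seq_len(res - 1)]] <- 0
  p[seq_len(res - 1)][zero[seq_len(res - 1)]] <- 1
  out <- data.frame(
    term = c("A", "B", "A:B", "Residuals"),
    df = df, ss = ss, ms = ms,
    f = c(f[seq_len(res - 1)], NA),
    p_value = c(p[seq_len(res - 1)], NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean comparisons via the studentized range distribution with
#' the one-way residual degrees of freedom (Tukey-Kramer standard error for
#' unequal group sizes), plus a compact letter display: groups sharing a
#' letter are not significantly different at `alpha`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels; at least 2 groups with >= 2 observations each.
#' @param alpha Family-wise significance level. Default 0.05. The published
#'   methods quote p < 0.05 while the dry-matter figure uses p < 0.001, so
#'   the level is a parameter rather than a constant.
#' @return List of class `"tukey_table"`: `pairs` (data frame with
#'   `group_i`, `group_j`, `diff` = mean_j - mean_i, `q`, `p_adj`,
#'   `significant`), `letters` (compact letter display, named by group),
#'   `alpha`, `df_residual`, `ms_error`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2))
    stop("every group needs >= 2 observations for a residual df")
  k <- nlevels(g)
  n <- length(values)
  means <- tapply(values, g, mean)
  df_res <- n - k
  mse <- sum((values - means[g])^2) / df_res

  cmb <- combn(levels(g), 2)
  di <- as.numeric(means[cmb[2, ]] - means[cmb[1, ]])
  ni <- as.numeric(sizes[cmb[1, ]]); nj <- as.numeric(sizes[cmb[2, ]])
  se <- sqrt(mse / 2 * (1 / ni + 1 / nj))
  q <- abs(di) / se
  q[se == 0] <- 0
  p_adj <- as.numeric(ptukey(q, nmeans = k, df = df_res,
                             lower.tail = FALSE))
  p_adj[is.nan(p_adj)] <- 1
  pairs <- data.frame(group_i = cmb[1, ], group_j = cmb[2, ],
                      diff = di, q = q, p_adj = p_adj,
                      significant = p_adj < alpha,
                      stringsAsFactors = FALSE)
  letters_out <- compact_letters(levels(g)[order(-means)], pairs)
  structure(list(pairs = pairs, letters = letters_out[levels(g)],
                 alpha = alpha, df_residual = df_res, ms_error = mse),
            class = "tukey_table")
}

# insert-and-absorb compact letter display; groups ordered for assignment
compact_letters <- function(ordered_groups, pairs) {
  sets <- list(ordered_groups)
  sig <- pairs[pairs$significant, , drop = FALSE]
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      i <- sig$group_i[r]; j <- sig$group_j[r]
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else new_sets <- c(new_sets, list(s))
      }
      # absorb sets fully contained in another
      keep <- rep(TRUE, length(new_sets))
      for (u in seq_along(new_sets)) for (v in seq_along(new_sets)) {
        if (u != v && keep[u] && keep[v] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            !(all(new_sets[[v]] %in% new_sets[[u]]) && u < v))
          keep[u] <- FALSE
      }
      sets <- new_sets[keep]
    }
  }
  out <- setNames(rep("", length(ordered_groups)), ordered_groups)
  for (s in seq_along(sets)) {
    lab <- letters[(s - 1) %% 26 + 1]
    for (gp in sets[[s]]) out[gp] <- paste0(out[gp], lab)
  }
  out
}

#' Ordinary least-squares line
#'
#' Simple linear regression used for the colonization-versus-%P2O5 decline:
#' slope p-value from the t distribution with n - 2 df, and residual standard
#' error `sqrt(SS_res / (n - 2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must not be constant.
#' @return List of class `"linear_fit"`: `slope`, `intercept`, `r_squared`,
#'   `p_value` (of the slope), `rse`, `n`.
#' @export
#' @examples
#' linear_fit(c(0, 2.93, 14, 18), c(43, 35, 23, 16))
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("x is constant; fit is degenerate")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    rse = sm$sigma,
    n = length(x)
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> y = %.4g + %.4g x  (R2 = %.4f, p = %.3g, RSE = %.4g, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$p_value, x$rse, x$n))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Reported alongside the phenotype ANOVA (the protocol tests normality but
#' does not transform); never enforced.
#'
#' @param values Numeric vector (3 to 5000 values).
#' @return List with `statistic` and `p_value`.
#' @export
normality_check <- function(values) {
  s <- stats::shapiro.test(values)
  list(statistic = unname(s$statistic), p_value = s$p.value)
}
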