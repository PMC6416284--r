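# Exponential dose-response fits and the composed prediction surface.
#
# Curve family identifiers:
#   "exp"           y = a * exp(b x)            (2 parameters)
#   "exp_offset"    y = a * exp(b x) + c        (3)
#   "peaked"        y = a * x * exp(b x)        (2; interior maximum at -1/b
#                                                when b < 0)
#   "peaked_offset" y = a * x * exp(b x) + c    (3)
# The pure monotone form cannot place a maximum inside the dose range, which
# is why the family includes the peaked forms; selection among forms is by
# residual standard error, the published criterion.

CURVE_FORMS <- c("exp", "exp_offset", "peaked", "peaked_offset")

eval_curve <- function(form, params, x) {
  a <- params$a; b <- params$b; c0 <- if (is.null(params$c)) 0 else params$c
  switch(form,
         exp = a * exp(b * x),
         exp_offset = a * exp(b * x) + c0,
         peaked = a * x * exp(b * x),
         peaked_offset = a * x * exp(b * x) + c0,
         stop("unknown curve form: ", form))
}

n_curve_params <- function(form) {
  switch(form, exp = 2L, peaked = 2L, exp_offset = 3L, peaked_offset = 3L,
         stop("unknown curve form: ", form))
}

# conditional-linearity initialization: for a fixed b the model is linear in
# a (and c), so profile the SS over a b grid, refine with a log-linear fit
# where the data allow it
init_params <- function(form, x, y) {
  basis <- function(b) {
    switch(form,
           exp = cbind(exp(b * x)),
           exp_offset = cbind(exp(b * x), 1),
           peaked = cbind(x * exp(b * x)),
           peaked_offset = cbind(x * exp(b * x), 1))
  }
  xr <- max(abs(x)); if (xr == 0) xr <- 1
  grid <- seq(-5 / xr, 5 / xr, length.out = 201)
  grid <- grid[grid != 0]
  best <- NULL; best_ss <- Inf
  for (b in grid) {
    bm <- basis(b)
    cf <- tryCatch(qr.coef(qr(bm), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    ss <- sum((y - bm %*% cf)^2)
    if (ss < best_ss) { best_ss <- ss; best <- c(b = b, cf) }
  }
  if (is.null(best)) stop("could not initialize curve fit")
  out <- list(a = unname(best[2]), b = unname(best[1]))
  if (form %in% c("exp_offset", "peaked_offset")) out$c <- unname(best[3])
  out
}

#' Fit an exponential dose-response curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) for one member of the curve
#' family, initialized by profiling the conditionally-linear parameters over
#' a grid of rate constants. Reports `r_squared = 1 - SS_res/SS_tot`,
#' `rse = sqrt(SS_res / (n - k))` (the published model-selection criterion),
#' and a fit p-value from the F test against the constant model.
#' Non-convergence yields a fit-failure object (`ok = FALSE`) carrying the
#' diagnostic message, not an exception.
#'
#' @param x,y Numeric vectors (>= 4 points).
#' @param form One of `"exp"`, `"exp_offset"`, `"peaked"`, `"peaked_offset"`.
#' @return List of class `"exponential_fit"`: `ok`, `form`, `parameters`
#'   (named list `a`, `b`, optionally `c`), `r_squared`, `rse`, `p_value`,
#'   `n`, `fitted`, `model` (the underlying `nls` object), or on failure
#'   `ok = FALSE` with `message`.
#' @export
#' @examples
#' x <- 0:18
#' f <- fit_exponential(x, 2 * exp(0.1 * x), "exp")
#' f$parameters
fit_exponential <- function(x, y, form = c("exp", "exp_offset", "peaked",
                                           "peaked_offset")) {
  form <- match.arg(form)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- n_curve_params(form)
  if (n < 4) stop("need at least 4 points")
  if (n <= k) stop("need more points than parameters")
  ss_tot <- sum((y - mean(y))^2)

  # constant response: the fit degenerates to the mean where the form can
  # represent it (b = 0 with the constant carried by a or c); R2 is 0
  if (ss_tot < 1e-12 * max(1, mean(y)^2) &&
      form %in% c("exp", "exp_offset", "peaked_offset")) {
    prm <- switch(form,
                  exp = list(a = mean(y), b = 0),
                  exp_offset = list(a = 0, b = 0, c = mean(y)),
                  peaked_offset = list(a = 0, b = 0, c = mean(y)))
    return(structure(list(ok = TRUE, form = form, parameters = prm,
                          r_squared = 0, rse = 0, p_value = 1, n = n,
                          fitted = rep(mean(y), n), model = NULL),
                     class = "exponential_fit"))
  }

  fml <- switch(form,
                exp = y ~ a * exp(b * x),
                exp_offset = y ~ a * exp(b * x) + c,
                peaked = y ~ a * x * exp(b * x),
                peaked_offset = y ~ a * x * exp(b * x) + c)
  start <- tryCatch(init_params(form, x, y), error = function(e) NULL)
  if (is.null(start))
    return(structure(list(ok = FALSE, form = form,
                          message = "initialization failed"),
                     class = "exponential_fit"))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(x = x, y = y), start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(ok = FALSE, form = form,
                          message = conditionMessage(fit)),
                     class = "exponential_fit"))
  prm <- as.list(coef(fit))
  ss_res <- sum(resid(fit)^2)
  r2 <- if (ss_tot < 1e-12) 0 else max(0, 1 - ss_res / ss_tot)
  rse <- sqrt(ss_res / (n - k))
  f_stat <- if (ss_res < 1e-300) Inf else
    ((ss_tot - ss_res) / (k - 1)) / (ss_res / (n - k))
  p <- if (ss_tot < 1e-12) 1 else
    pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  structure(list(ok = TRUE, form = form, parameters = prm,
                 r_squared = r2, rse = rse, p_value = p, n = n,
                 fitted = fitted(fit), model = fit),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat(sprintf("<exponential_fit:%s> FAILED: %s\n", x$form, x$message))
  } else {
    cat(sprintf("<exponential_fit:%s> %s  (R2 = %.4f, RSE = %.4g, p = %.3g)\n",
                x$form,
                paste(names(x$parameters),
                      signif(unlist(x$parameters), 5),
                      sep = "=", collapse = ", "),
                x$r_squared, x$rse, x$p_value))
  }
  invisible(x)
}

#' Predict from an exponential or linear fit
#'
#' @param object An `exponential_fit` or [linear_fit()] result.
#' @param x Dose values.
#' @param ... Unused.
#' @return Predicted response.
#' @export
predict_fit <- function(object, x, ...) {
  if (inherits(object, "linear_fit"))
    return(object$intercept + object$slope * x)
  stopifnot(inherits(object, "exponential_fit"), isTRUE(object$ok))
  eval_curve(object$form, object$parameters, x)
}

#' Select the best fit by residual standard error
#'
#' Returns the candidate with the smallest RSE (the published selection
#' criterion); ties go to the form with fewer parameters. Failed fits
#' (`ok = FALSE`) are skipped.
#'
#' @param fits List of `exponential_fit` and/or `linear_fit` objects.
#' @return The winning fit.
#' @export
select_by_rse <- function(fits) {
  if (inherits(fits, c("exponential_fit", "linear_fit"))) fits <- list(fits)
  usable <- Filter(function(f) inherits(f, "linear_fit") || isTRUE(f$ok), fits)
  if (!length(usable)) stop("no successful fit to select from")
  rse <- vapply(usable, function(f) f$rse, numeric(1))
  npar <- vapply(usable, function(f) {
    if (inherits(f, "linear_fit")) 2L else n_curve_params(f$form)
  }, integer(1))
  usable[[order(rse, npar)[1]]]
}

#' Compose the dry-matter / interaction-count prediction surface
#'
#' Evaluates the dry-matter fit and the bacteria-fungi edge-count fit over a
#' common %P2O5 grid; the (dose, edges, dry matter) triples form the
#' trendline of the 3D response surface. A bivariate exponential trend
#' `dm ~ exp(c0 + c1 * dose + c2 * edges)` is fit over the grid and its R2
#' and p reported (0 and 1 for a flat surface).
#'
#' @param fit_dm Dry-matter-vs-%P2O5 fit (`exponential_fit` or `linear_fit`).
#' @param fit_edges Bacteria-fungi-edges-vs-%P2O5 fit.
#' @param from,to Grid range of %P2O5 (must cover the observed doses).
#' @param step Grid step. Default 0.01.
#' @return List of class `"surface_grid"`: `grid` (data frame `p2o5_percent`,
#'   `bf_edges`, `dry_matter`), `step`, `trend_r_squared`, `trend_p_value`.
#' @export
compose_surface <- function(fit_dm, fit_edges, from = 0, to = 18,
                            step = 0.01) {
  p <- seq(from, to, by = step)
  if (length(p) < 10) stop("surface grid needs at least 10 points")
  dm <- predict_fit(fit_dm, p)
  ed <- predict_fit(fit_edges, p)
  if (any(!is.finite(dm)) || any(!is.finite(ed)))
    stop("non-finite predictions on the surface grid")
  grid <- data.frame(p2o5_percent = p, bf_edges = ed, dry_matter = dm)

  ss_tot <- sum((dm - mean(dm))^2)
  if (ss_tot < 1e-12) {
    trend_r2 <- 0; trend_p <- 1
  } else {
    tr <- tryCatch({
      dmin <- min(dm)
      off <- if (dmin <= 0) -dmin + 0.05 * diff(range(dm)) + 1e-9 else 0
      lf <- lm(log(dm + off) ~ p + ed)
      st <- coef(lf)
      st[is.na(st)] <- 0  # collinear dose/edge trendlines drop a coefficient
      pred0 <- exp(st[1] + st[2] * p + st[3] * ed) - off
      trfit <- tryCatch(minpack.lm::nlsLM(
        dm ~ exp(c0 + c1 * p + c2 * ed) - off,
        data = data.frame(dm = dm, p = p, ed = ed),
        start = list(c0 = st[1], c1 = st[2], c2 = st[3]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      # an exact log-linear fit leaves nls a singular gradient; keep it
      ssr <- if (is.null(trfit)) sum((dm - pred0)^2) else
        sum(resid(trfit)^2)
      f <- ((ss_tot - ssr) / 2) / (ssr / (length(dm) - 3))
      list(r2 = max(0, 1 - ssr / ss_tot),
           p = pf(f, 2, length(dm) - 3, lower.tail = FALSE))
    }, error = function(e) list(r2 = NA_real_, p = NA_real_))
    trend_r2 <- tr$r2; trend_p <- tr$p
  }
  structure(list(grid = grid, step = step,
                 trend_r_squared = trend_r2, trend_p_value = trend_p),
            class = "surface_grid")
}

#' Locate the surface optimum
#'
#' Grid argmax of predicted dry matter; ties resolve to the smallest %P2O5.
#'
#' @param surface A [compose_surface()] result.
#' @return List of class `"optimum_estimate"`: `p2o5_percent`, `bf_edges`,
#'   `dry_matter`.
#' @export
find_optimum <- function(surface) {
  stopifnot(inherits(surface, "surface_grid"))
  g <- surface$grid
  if (!nrow(g)) stop("empty surface")
  i <- which.max(g$dry_matter)  # first maximum = smallest dose on a tie
  structure(list(p2o5_percent = g$p2o5_percent[i],
                 bf_edges = g$bf_edges[i],
                 dry_matter = g$dry_matter[i]),
            class = "optimum_estimate")
}

#' @export
print.optimum_estimate <- function(x, ...) {
  cat(sprintf(
    "<optimum> %.4g g/pot dry matter at %.4g%% P2O5 (%.4g bacteria-fungi edges)\n",
    x$dry_matter, x$p2o5_percent, x$bf_edges))
  invisible(x)
}
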