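#' Fit a single-term exponential curve y = a * exp(b * x)
#'
#' Least squares on the original response scale: the residual sum of
#' squares `sum((y - a*exp(b*x))^2)` is minimized by Levenberg-Marquardt
#' iteration started from the ordinary least-squares line of `log(y)` on
#' `x`. Zero responses are tolerated (they arise when a distance is
#' reported as 0.000 at printed precision): they enter the nonlinear
#' objective but are left out of the logarithmic initialization. The
#' coefficient of determination is reported on the original scale,
#' `R^2 = 1 - RSS/TSS`, the convention of the nonlinear fitters used in
#' this literature.
#'
#' @param x predictor values.
#' @param y response values, all `>= 0` with at least two positive.
#' @param predictor,response metric labels carried into the fit object.
#' @param max_iter iteration cap for the optimizer.
#' @return An object of class `exp_fit`: list with `a` (scale, > 0), `b`
#'   (rate, any sign), `predictor`, `response`, `n`, `rss`, `r2`.
#' @examples
#' f <- fit_exponential(0:3, 2 * exp(0.5 * (0:3)))
#' c(f$a, f$b, f$r2)
#' @export
fit_exponential <- function(x, y, predictor = "x", response = "y",
                            max_iter = 200L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in x or y", call. = FALSE)
  if (any(y < 0))
    stop("domain error: negative response values", call. = FALSE)
  pos <- y > 0
  if (sum(pos) < 2L)
    stop("domain error: need at least two positive response values",
         call. = FALSE)

  # a constant response is fit exactly by the flat curve a = y, b = 0;
  # the optimizer's gradient is singular there, so return it directly
  if (length(unique(y)) == 1L) {
    return(structure(list(a = y[1L], b = 0,
                          predictor = predictor, response = response,
                          n = length(x), rss = 0, r2 = 1),
                     class = "exp_fit"))
  }

  # log-linear OLS start
  ols <- stats::lm.fit(cbind(1, x[pos]), log(y[pos]))
  a0 <- exp(ols$coefficients[[1L]])
  b0 <- ols$coefficients[[2L]]

  fit <- minpack.lm::nlsLM(
    y ~ a * exp(b * x),
    data = data.frame(x = x, y = y),
    start = list(a = a0, b = b0),
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-12, ptol = 1e-12)
  )
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  if (!fit$convInfo$isConv && fit$convInfo$stopCode %in% c(5L, 9L, 10L))
    stop(sprintf(
      "exponential fit did not converge (best point a=%.6g, b=%.6g, rss=%.6g)",
      co[["a"]], co[["b"]], rss), call. = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) {
    if (rss < 1e-12) 1 else NA_real_
  } else 1 - rss / tss
  structure(list(a = co[["a"]], b = co[["b"]],
                 predictor = predictor, response = response,
                 n = length(x), rss = rss, r2 = r2),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: %s = %.6g * exp(%.6g * %s)\n",
              x$response, x$a, x$b, x$predictor))
  cat(sprintf("  n = %d, RSS = %.6g, R^2 = %.5f\n", x$n, x$rss, x$r2))
  invisible(x)
}

#' Evaluate a fitted exponential curve
#'
#' @param fit an `exp_fit`.
#' @param x0 predictor value(s).
#' @return `a * exp(b * x0)`.
#' @export
predict_at <- function(fit, x0) {
  stopifnot(inherits(fit, "exp_fit"))
  fit$a * exp(fit$b * x0)
}

#' Invert a fitted exponential curve at a response value
#'
#' Solves `a * exp(b * x) = y0` for the unique predictor value at which the
#' fitted curve attains `y0`. This is how a threshold on one metric is
#' translated into the equivalent threshold on another, e.g. the ANIm value
#' corresponding to the classical 70% dDDH species boundary.
#'
#' @param fit an `exp_fit` with `b != 0`.
#' @param y0 response value(s), `> 0`.
#' @return Predictor value(s) `x0 = (log(y0) - log(a)) / b`.
#' @export
invert_at <- function(fit, y0) {
  stopifnot(inherits(fit, "exp_fit"))
  if (fit$b == 0)
    stop("inversion undefined: fitted rate b is 0 (flat curve)",
         call. = FALSE)
  if (any(y0 <= 0)) stop("y0 must be positive", call. = FALSE)
  (log(y0) - log(fit$a)) / fit$b
}

#' Fit the three cross-metric exponential regressions
#'
#' The calibration directions used for the threshold analysis: dDDH as
#' response against ANIm (whose inversion at dDDH = 70 gives the ANIm
#' equivalent of the classical boundary), and the MLSA distance as response
#' against dDDH and against ANIm (whose forward evaluation at dDDH = 70
#' gives the MLSA equivalent, about 0.008 substitutions/site on the
#' packaged table).
#'
#' @param table a `pair_metric_table`.
#' @return A named list of three `exp_fit` objects: `ddh_vs_anim`,
#'   `mlsa_vs_ddh`, `mlsa_vs_anim`.
#' @examples
#' fits <- fit_metric_pairs(streptomyces_pairs())
#' fits$ddh_vs_anim$r2
#' invert_at(fits$ddh_vs_anim, 70)
#' @export
fit_metric_pairs <- function(table) {
  if (nrow(table) == 0L) stop("empty metric table", call. = FALSE)
  list(
    ddh_vs_anim = fit_exponential(table$anim, table$ddh,
                                  predictor = "anim", response = "ddh"),
    mlsa_vs_ddh = fit_exponential(table$ddh, table$mlsa,
                                  predictor = "ddh", response = "mlsa"),
    mlsa_vs_anim = fit_exponential(table$anim, table$mlsa,
                                   predictor = "anim", response = "mlsa")
  )
}
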