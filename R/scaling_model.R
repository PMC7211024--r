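#' Four-parameter logistic compute-cost model
#'
#' The 4PL curve `y(x) = y_inf + (y_0 - y_inf) / (1 + (x/c)^b)` describes
#' how assembly compute cost (CPU core hours) scales with read depth:
#' `y_0` is the cost as depth approaches 0, `y_inf` the asymptotic cost at
#' large depth, `c` the midpoint scale (in depth units; `y(c)` is the
#' average of the two asymptotes) and `b` the steepness exponent.
#'
#' @param y_inf,y_0 asymptotic costs at large and small `x`.
#' @param c midpoint scale, > 0, in the units of `x`.
#' @param b exponent, > 0.
#' @return An object of class `FourPLModel`.
#' @export
fourpl_model <- function(y_inf, y_0, c, b) {
  assert_scalar_number(y_inf, "y_inf")
  assert_scalar_number(y_0, "y_0")
  assert_scalar_number(c, "c", min = .Machine$double.eps)
  assert_scalar_number(b, "b", min = .Machine$double.eps)
  structure(list(y_inf = y_inf, y_0 = y_0, c = c, b = b),
            class = "FourPLModel")
}

#' @export
print.FourPLModel <- function(x, ...) {
  cat(sprintf("FourPLModel: y(x) = %g + (%g - %g) / (1 + (x/%g)^%g)\n",
              x$y_inf, x$y_0, x$y_inf, x$c, x$b))
  invisible(x)
}

#' Evaluate a 4PL model
#'
#' @param model a [fourpl_model()].
#' @param x depth value(s), >= 0; `y(0) = y_0` and `y(c)` is the midpoint
#'   `(y_inf + y_0)/2`.
#' @return Predicted cost(s).
#' @export
fourpl_eval <- function(model, x) {
  stopifnot(inherits(model, "FourPLModel"))
  if (any(x < 0)) stop("x must be >= 0")
  model$y_inf + (model$y_0 - model$y_inf) / (1 + (x / model$c)^model$b)
}

#' @export
predict.FourPLModel <- function(object, newdata, ...) {
  fourpl_eval(object, if (is.list(newdata)) newdata$x else newdata)
}

#' Fit a 4PL curve by nonlinear least squares
#'
#' Levenberg-Marquardt least squares on the 4PL with default
#' initialization `y_0 = min(y)`, `y_inf = 10 * max(y)`, `c = median(x)`,
#' `b = 2`. Optionally fits in log-y space, which stabilizes regimes where
#' the upper asymptote lies far above the data (common for compute-cost
#' curves: predictions within the data range are then well identified
#' even when the asymptote itself is not).
#'
#' @param xs,ys at least 4 points; `xs` distinct and positive.
#' @param init optional named list/vector with `y_inf`, `y_0`, `c`, `b`.
#' @param log_y fit `log(y)` instead of `y` (requires `ys > 0`).
#' @param maxiter,tol Levenberg-Marquardt iteration cap and relative
#'   residual tolerance.
#' @return A list of class `FourPLFit`: `model` (a [fourpl_model()]),
#'   `residuals`, `converged`, `degenerate` (all-equal `ys`), `rss`.
#' @export
fit_fourpl <- function(xs, ys, init = NULL, log_y = FALSE,
                       maxiter = 1000, tol = 1e-10) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) < 4L) stop("fit_fourpl requires at least 4 points")
  if (length(xs) != length(ys)) stop("xs and ys differ in length")
  if (anyDuplicated(xs) || any(xs <= 0))
    stop("xs must be distinct and positive")
  if (stats::var(ys) == 0) {
    model <- fourpl_model(ys[1L], ys[1L], stats::median(xs), 1)
    return(structure(list(model = model, residuals = ys * 0,
                          converged = TRUE, degenerate = TRUE, rss = 0),
                     class = "FourPLFit"))
  }
  start <- as.list(init %||% list(y_inf = 10 * max(ys), y_0 = min(ys),
                                  c = stats::median(xs), b = 2))
  start <- start[c("y_inf", "y_0", "c", "b")]
  d <- data.frame(x = xs, y = ys)
  fml <- if (log_y) {
    if (any(ys <= 0)) stop("log_y requires positive ys")
    log(y) ~ log(y_inf + (y_0 - y_inf) / (1 + (x / c)^b))
  } else {
    y ~ y_inf + (y_0 - y_inf) / (1 + (x / c)^b)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = d, start = start,
                      # log_y additionally needs non-negative asymptotes so
                      # the curve (always between them) stays positive
                      lower = if (log_y) c(0, 0, 1e-12, 1e-12)
                              else c(-Inf, -Inf, 1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = min(maxiter, 1024), ftol = tol,
                        ptol = tol)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    model <- do.call(fourpl_model, start[c("y_inf", "y_0", "c", "b")])
    return(structure(list(model = model,
                          residuals = ys - fourpl_eval(model, xs),
                          converged = FALSE, degenerate = FALSE,
                          rss = sum((ys - fourpl_eval(model, xs))^2),
                          message = conditionMessage(fit)),
                     class = "FourPLFit"))
  }
  cf <- as.list(coef(fit))
  model <- fourpl_model(cf$y_inf, cf$y_0, cf$c, cf$b)
  res <- ys - fourpl_eval(model, xs)
  structure(list(model = model, residuals = res,
                 converged = fit$convInfo$isConv %||% TRUE,
                 degenerate = abs(cf$y_0 - cf$y_inf) <
                   1e-8 * max(abs(cf$y_0), abs(cf$y_inf), 1),
                 rss = sum(res^2)),
            class = "FourPLFit")
}

#' @export
print.FourPLFit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  converged: %s  degenerate: %s  RSS: %.4g\n",
              x$converged, x$degenerate, x$rss))
  invisible(x)
}

#' Published compute-cost scaling models for the NC358 21k datasets
#'
#' 4PL coefficients relating CPU core hours to depth for the maize NC358
#' 21-kb-N50 titration series: `falcon_cpu_model()` predicts Falcon
#' error-correction cost from subread depth, `canu_cpu_model()` predicts
#' Canu assembly cost from corrected-read depth.
#'
#' @return A [fourpl_model()].
#' @export
falcon_cpu_model <- function() {
  fourpl_model(y_inf = 20603100000, y_0 = 3136.685,
               c = 1932.377, b = 4.148144)
}

#' @rdname falcon_cpu_model
#' @export
canu_cpu_model <- function() {
  fourpl_model(y_inf = 6438752000, y_0 = 1284.689,
               c = 56334.74, b = 1.872455)
}
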