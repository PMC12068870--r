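#' Fit an exponential decay y = a * exp(b * t)
#'
#' Nonlinear least-squares fit of a single exponential to (t, y) points, as
#' used for sensitization-recovery curves and for the falling phase of
#' calcium transients. The fit reports the rate `b` (1/s, negative for a
#' decay), the time constant `tau = -1/b`, and a goodness-of-fit
#' `r_squared = 1 - SS_res / SS_tot`; fits with `r_squared > 0.9` are
#' flagged `reliable`.
#'
#' Initialization is deterministic: an ordinary least-squares line through
#' `(t, log y)` restricted to `y > 0` supplies `b0` (its slope) and `a0`
#' (its exponentiated intercept), with fallback `a0 = max(y)`,
#' `b0 = -1 / max(t)` when fewer than two positive points exist or the
#' log-linear fit is degenerate. Non-convergence returns a
#' fit with `reliable = FALSE` and a diagnostic rather than an error.
#'
#' @param t Numeric times (seconds), length >= 3.
#' @param y Numeric values; at least one must be positive. May also be a
#'   two-column data.frame/matrix of (t, y) with `y` missing.
#' @return An object of class `decay_fit` with fields `a`, `b`, `tau`,
#'   `r_squared`, `reliable`, `points_used`, `fitted`, `residuals`,
#'   `data`, `converged`, `diagnostic`.
#' @examples
#' t <- c(10, 60, 120, 300, 600)
#' fit <- fit_exponential_decay(t, 0.5 * exp(-t / 337))
#' fit$tau
#' @export
fit_exponential_decay <- function(t, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(t)
    t <- as.numeric(m[, 1]); y <- as.numeric(m[, 2])
  }
  stopifnot(length(t) == length(y))
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 3L) stop("need at least 3 points to fit a decay", call. = FALSE)
  if (!any(y > 0)) stop("all values are <= 0; cannot fit a positive exponential",
                        call. = FALSE)

  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    # constant series: b -> 0, tau -> Inf; degenerate, never reliable
    return(new_decay_fit(a = y[1], b = 0, t = t, y = y,
                         fitted = rep(y[1], length(y)), r_squared = NA_real_,
                         converged = FALSE,
                         diagnostic = "constant series; decay degenerate (tau = Inf)"))
  }

  # log-linear initialization: OLS on (t, log y) over the positive values
  # is exact for noiseless data, so the optimizer starts at (or near) the
  # optimum; fallback for < 2 positive points
  a0 <- max(y)
  pos <- y > 0
  b0 <- -1 / max(t)
  if (sum(pos) >= 2L && stats::var(t[pos]) > 0) {
    cf0 <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    if (all(is.finite(cf0)) && cf0[2] != 0) {
      b0 <- unname(cf0[2])
      a0 <- unname(exp(cf0[1]))
    }
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * t),
                      start = list(a = a0, b = b0),
                      data = data.frame(t = t, y = y),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    pred <- a0 * exp(b0 * t)
    return(new_decay_fit(a = a0, b = b0, t = t, y = y, fitted = pred,
                         r_squared = 1 - sum((y - pred)^2) / ss_tot,
                         converged = FALSE,
                         diagnostic = paste("fit did not converge:",
                                            conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  pred <- cf[["a"]] * exp(cf[["b"]] * t)
  new_decay_fit(a = cf[["a"]], b = cf[["b"]], t = t, y = y, fitted = pred,
                r_squared = 1 - sum((y - pred)^2) / ss_tot,
                converged = TRUE, diagnostic = NA_character_)
}

new_decay_fit <- function(a, b, t, y, fitted, r_squared, converged, diagnostic) {
  structure(list(
    a = a, b = b,
    tau = if (b != 0) -1 / b else Inf,
    r_squared = r_squared,
    reliable = isTRUE(r_squared > 0.9) && converged,
    points_used = length(t),
    data = data.frame(t = t, y = y),
    fitted = fitted,
    residuals = y - fitted,
    converged = converged,
    diagnostic = diagnostic), class = "decay_fit")
}

#' Fit the decay of a series from its peak to the end
#'
#' Identifies the maximum of the series (earliest sample on ties) and fits
#' [fit_exponential_decay()] to the sub-series from the peak to the end,
#' the convention used for calcium-transient decay constants.
#'
#' @param t,y Numeric vectors (times in seconds, values); `y` may be
#'   omitted when `t` is a two-column object.
#' @return A `decay_fit` (its `points_used` counts peak-to-end samples).
#' @export
decay_fit_from_trace <- function(t, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(t); t <- as.numeric(m[, 1]); y <- as.numeric(m[, 2])
  }
  peak <- which.max(y)  # earliest maximum on ties
  if (peak == length(y))
    stop("peak is at the final sample; nothing to fit", call. = FALSE)
  fit_exponential_decay(t[peak:length(y)], y[peak:length(y)])
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit: y = a * exp(b * t)\n")
  cat(sprintf("  a = %s, b = %s /s, tau = %s s\n",
              fmt_num(x$a), fmt_num(x$b), fmt_num(x$tau)))
  cat(sprintf("  R^2 = %s on %d points; %s\n",
              if (is.na(x$r_squared)) "NA" else fmt_num(x$r_squared),
              x$points_used,
              if (x$reliable) "reliable (R^2 > 0.9)" else "NOT reliable"))
  if (!is.na(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual SS = %s, converged = %s\n",
              fmt_num(sum(object$residuals^2)), object$converged))
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) c(a = object$a, b = object$b)

#' Predict from a decay fit
#' @param object A `decay_fit`.
#' @param newdata Optional data.frame with a `t` column (or numeric vector
#'   of times); defaults to the fitted times.
#' @param ... Unused.
#' @return Numeric vector `a * exp(b * t)`.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.numeric(newdata)) newdata
       else newdata$t
  object$a * exp(object$b * t)
}

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
fitted.decay_fit <- function(object, ...) object$fitted

#' Plot a decay fit
#' @param x A `decay_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, xlab = "time (s)", ylab = "y", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Fit the sensitization recovery curve of a two-stimulus experiment
#'
#' Convenience wrapper: computes the enhancement [recovery_curve()] and
#' fits its decay over recovery interval, returning the time constant of
#' sensitization decay.
#'
#' @inheritParams recovery_curve
#' @return A `decay_fit` over (interval, enhancement) points.
#' @export
fit_recovery <- function(trials, pooled_p1 = FALSE) {
  curve <- recovery_curve(trials, pooled_p1 = pooled_p1)
  if (nrow(curve) < 3L)
    stop("need >= 3 distinct recovery intervals to fit the decay", call. = FALSE)
  fit_exponential_decay(curve$interval, curve$enhancement)
}
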