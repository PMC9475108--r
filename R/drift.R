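#' Fit a latency-drift model to a latency series
#'
#' Characterizes the systematic change of trial latency over recording time.
#' Two models are available:
#' \describe{
#'   \item{`linear`}{\eqn{\Delta t(t) = c + s\,t}; appropriate for short
#'     (15 min) sessions, where residual relative clock drift appears as an
#'     approximately linear trend.}
#'   \item{`linear_plus_saturating`}{\eqn{\Delta t(t) = c + s\,t +
#'     a\,(1 - e^{-t/\tau})}; captures latency curves that rise and then
#'     flatten over multi-hour sessions.}
#' }
#' The linear model is an ordinary least-squares fit; the saturating model
#' is fitted by Levenberg-Marquardt nonlinear least squares.  A
#' non-converging nonlinear fit is reported as an explicit failure
#' (`converged = FALSE`, parameters `NA`) -- never silently replaced by the
#' linear fit.
#'
#' @param series A [latency_series()] (or numeric latencies with a
#'   `trial_times` attribute is not supported -- construct a series).  At
#'   least 10 trials are required for the linear model and 50 for the
#'   saturating model.
#' @param model `"linear"` or `"linear_plus_saturating"`.
#' @return An object of class `drift_fit`: list with `model`, `converged`,
#'   `parameters` (named: `intercept` s, `slope` s/s, and for the saturating
#'   model `amplitude` s, `timescale` s) and `residual_sd` (seconds).
#' @export
drift_fit <- function(series, model = c("linear", "linear_plus_saturating")) {
  stopifnot(inherits(series, "latency_series"))
  model <- match.arg(model)
  t <- series$trial_times - series$trial_times[1L]
  y <- series$latencies
  n <- length(y)
  if (model == "linear") {
    if (n < 10L) stop("linear drift fit requires at least 10 trials", call. = FALSE)
    fit <- stats::lm.fit(cbind(1, t), y)
    pars <- c(intercept = unname(fit$coefficients[1L]),
              slope = unname(fit$coefficients[2L]))
    res_sd <- stats::sd(fit$residuals)
    return(structure(list(model = model, converged = TRUE, parameters = pars,
                          residual_sd = res_sd), class = "drift_fit"))
  }
  if (n < 50L) {
    stop("saturating drift fit requires at least 50 trials", call. = FALSE)
  }
  span <- max(t)
  # starting values: split the series; late half slope estimates the linear
  # term, the early excess the saturating amplitude
  late <- t > span / 2
  s0 <- if (sum(late) >= 2L) {
    stats::cov(t[late], y[late]) / stats::var(t[late])
  } else 0
  a0 <- max(stats::median(y[late]) - y[1L] - s0 * span / 2, 1e-4)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c0 + s * t + a * (1 - exp(-t / tau)),
      start = list(c0 = y[1L], s = s0, a = a0, tau = span / 5),
      lower = c(-Inf, -Inf, -Inf, span * 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$convInfo$isConv) {
    return(structure(list(model = model, converged = FALSE,
                          parameters = c(intercept = NA_real_, slope = NA_real_,
                                         amplitude = NA_real_, timescale = NA_real_),
                          residual_sd = NA_real_),
                     class = "drift_fit"))
  }
  cf <- stats::coef(fit)
  structure(
    list(model = model, converged = TRUE,
         parameters = c(intercept = unname(cf["c0"]), slope = unname(cf["s"]),
                        amplitude = unname(cf["a"]), timescale = unname(cf["tau"])),
         residual_sd = stats::sd(stats::residuals(fit))),
    class = "drift_fit"
  )
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("<drift_fit> model %s (%s)\n", x$model,
              if (x$converged) "converged" else "FAILED"))
  if (x$converged) {
    print(signif(x$parameters, 6))
    cat(sprintf("  residual sd: %.4g ms\n", 1e3 * x$residual_sd))
  }
  invisible(x)
}
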