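#' Parametric survival distributions
#'
#' A `parametric_survival` object holds one parametric time-to-event
#' distribution for one endpoint (overall survival or progression-free
#' survival) of one treatment arm: the family, its parameters on the natural
#' scale, and optionally their standard errors.  Time is measured in
#' **months** throughout; conversion to years happens only when person-time
#' is accrued.
#'
#' Supported families and their parameter order:
#' \describe{
#'   \item{exponential}{`rate` (> 0)}
#'   \item{weibull}{`shape`, `scale` (both > 0)}
#'   \item{gompertz}{`shape` (any sign), `rate` (> 0)}
#'   \item{loglogistic}{`shape`, `scale` (both > 0)}
#'   \item{lognormal}{`meanlog`, `sdlog` (> 0)}
#'   \item{gengamma}{`mu`, `sigma` (> 0), `Q` -- the (mu, sigma, Q)
#'     parameterization used in survival extrapolation practice}
#' }
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`, `"gengamma"`.
#' @param params Numeric vector of parameters in the order listed above.
#'   Names are optional; positional order is authoritative.
#' @param se Optional numeric vector of standard errors, same order.
#' @return An object of class `parametric_survival`.
#' @examples
#' ps <- parametric_survival("lognormal", c(meanlog = 2.2773, sdlog = 1.13))
#' survival_probability(ps, exp(2.2773))  # median -> 0.5
#' @export
parametric_survival <- function(family, params, se = NULL) {
  family <- match.arg(family, psm_families())
  info <- family_info(family)
  params <- as.numeric(params)
  if (length(params) != info$k)
    stop(sprintf("family '%s' needs %d parameters, got %d",
                 family, info$k, length(params)), call. = FALSE)
  bad <- info$positive & params <= 0
  if (any(bad))
    stop(sprintf("family '%s': parameter '%s' must be strictly positive",
                 family, info$names[which(bad)[1]]), call. = FALSE)
  if (!is.null(se)) {
    se <- as.numeric(se)
    if (length(se) != info$k)
      stop("standard-error vector length must match parameter count", call. = FALSE)
  }
  structure(list(family = family, params = stats::setNames(params, info$names),
                 se = if (is.null(se)) NULL else stats::setNames(se, info$names)),
            class = "parametric_survival")
}

psm_families <- function() {
  c("exponential", "weibull", "gompertz", "loglogistic", "lognormal", "gengamma")
}

# parameter count, names, positivity constraints, flexsurv dist string
family_info <- function(family) {
  switch(family,
    exponential = list(k = 1L, names = "rate", positive = TRUE, flexsurv = "exp"),
    weibull     = list(k = 2L, names = c("shape", "scale"),
                       positive = c(TRUE, TRUE), flexsurv = "weibull"),
    gompertz    = list(k = 2L, names = c("shape", "rate"),
                       positive = c(FALSE, TRUE), flexsurv = "gompertz"),
    loglogistic = list(k = 2L, names = c("shape", "scale"),
                       positive = c(TRUE, TRUE), flexsurv = "llogis"),
    lognormal   = list(k = 2L, names = c("meanlog", "sdlog"),
                       positive = c(FALSE, TRUE), flexsurv = "lnorm"),
    gengamma    = list(k = 3L, names = c("mu", "sigma", "Q"),
                       positive = c(FALSE, TRUE, FALSE), flexsurv = "gengamma"),
    stop("unknown family: ", family, call. = FALSE))
}

#' Survival probability of a parametric distribution
#'
#' Evaluates S(t) for a [parametric_survival()] distribution at times `t`
#' (months).  For the log-normal family this is
#' \eqn{1 - \Phi((\log t - \mu)/\sigma)}.
#'
#' @param dist A `parametric_survival` object.
#' @param t Non-negative times in months (vectorized).
#' @return Survival probabilities in `[0, 1]`; `S(0) = 1`.
#' @export
survival_probability <- function(dist, t) {
  stopifnot(inherits(dist, "parametric_survival"))
  if (any(t < 0)) stop("survival times must be non-negative", call. = FALSE)
  p <- dist$params
  s <- switch(dist$family,
    exponential = stats::pexp(t, rate = p[1], lower.tail = FALSE),
    weibull     = stats::pweibull(t, shape = p[1], scale = p[2], lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p[1], rate = p[2], lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[1], scale = p[2], lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = p[1], sdlog = p[2], lower.tail = FALSE),
    gengamma    = flexsurv::pgengamma(t, mu = p[1], sigma = p[2], Q = p[3],
                                      lower.tail = FALSE))
  s[t == 0] <- 1
  unname(s)
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival: %s>\n", x$family))
  m <- rbind(estimate = x$params)
  if (!is.null(x$se)) m <- rbind(m, se = x$se)
  print(m)
  invisible(x)
}

#' Survival curve objects
#'
#' A `survival_curve` wraps an evaluator \eqn{t \mapsto S(t)} (time in
#' months) with its provenance: `"parametric"` (closed-form extrapolation),
#' `"kaplan-meier"` (step function from data), or `"hybrid"` (KM within the
#' trial window, rescaled parametric tail beyond).  Evaluation past
#' `support_end` of a KM curve carries the last value forward.
#'
#' @param fn Vectorized function of time in months returning S(t).
#' @param provenance One of `"parametric"`, `"kaplan-meier"`, `"hybrid"`.
#' @param support_end Last time (months) the curve is data-supported;
#'   `Inf` for parametric curves.
#' @return An object of class `survival_curve`, callable via
#'   [eval_curve()].
#' @export
survival_curve <- function(fn, provenance = c("parametric", "kaplan-meier", "hybrid"),
                           support_end = Inf) {
  provenance <- match.arg(provenance)
  stopifnot(is.function(fn), support_end > 0)
  structure(list(fn = fn, provenance = provenance, support_end = support_end),
            class = "survival_curve")
}

#' Evaluate a survival curve
#' @param curve A [survival_curve()].
#' @param t Times in months.
#' @return S(t), clamped to `[0, 1]`.
#' @export
eval_curve <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(t < 0)) stop("survival times must be non-negative", call. = FALSE)
  pmin(1, pmax(0, curve$fn(t)))
}

#' Convert a parametric distribution to a survival curve
#' @param dist A [parametric_survival()].
#' @return A `survival_curve` with provenance `"parametric"`.
#' @export
as_survival_curve <- function(dist) {
  stopifnot(inherits(dist, "parametric_survival"))
  survival_curve(function(t) survival_probability(dist, t),
                 provenance = "parametric", support_end = Inf)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve: %s, support to %s months>\n",
              x$provenance, format(x$support_end)))
  invisible(x)
}

#' Hybrid Kaplan-Meier plus extrapolation curve
#'
#' Within the trial follow-up (`t <= cutoff`) the curve equals the KM
#' estimate; beyond the cutoff the parametric tail is rescaled to attach
#' continuously: \eqn{S(t) = KM(c) \cdot S_p(t) / S_p(c)} for \eqn{t > c}.
#'
#' @param km A `survival_curve` (typically from [km_estimate()]) defined at
#'   least on `[0, cutoff]`.
#' @param dist A [parametric_survival()] supplying the extrapolated tail.
#' @param cutoff Junction time in months (end of the trial window).
#' @return A `survival_curve` with provenance `"hybrid"`.
#' @export
build_hybrid_curve <- function(km, dist, cutoff) {
  stopifnot(inherits(km, "survival_curve"), inherits(dist, "parametric_survival"),
            cutoff > 0)
  if (cutoff > km$support_end)
    stop("cutoff lies beyond the KM curve's supported range", call. = FALSE)
  s_cut <- survival_probability(dist, cutoff)
  if (s_cut <= 0)
    stop("parametric tail has zero survival at the cutoff; cannot rescale",
         call. = FALSE)
  km_cut <- eval_curve(km, cutoff)
  survival_curve(function(t) {
    ifelse(t <= cutoff,
           eval_curve(km, pmin(t, cutoff)),
           km_cut * survival_probability(dist, pmax(t, cutoff)) / s_cut)
  }, provenance = "hybrid", support_end = Inf)
}

#' Discounted restricted person-time under a survival curve
#'
#' Computes \eqn{\int_0^T S(t) (1+r)^{-t}\,dt} (t in years) by the trapezoid
#' rule on the model's cycle grid.  With a 3% annual rate this is the
#' discounted person-time credited to a state whose membership is `curve`.
#' Discounting is continuous-in-time, \eqn{(1+r)^{-t}}, which coincides with
#' a half-cycle-corrected discrete sum as the grid refines.
#'
#' @param curve A [survival_curve()] (time in months).
#' @param horizon Time horizon in years.
#' @param rate Annual discount rate (e.g. 0.03); 0 disables discounting.
#' @param cycle Cycle length in years (default 1/12, i.e. one month).
#' @return Discounted person-years (a scalar).
#' @export
discounted_state_time <- function(curve, horizon, rate = 0, cycle = 1 / 12) {
  stopifnot(horizon > 0, rate >= 0, cycle > 0)
  t_yr <- seq(0, horizon, by = cycle)
  if (t_yr[length(t_yr)] < horizon) t_yr <- c(t_yr, horizon)
  y <- eval_curve(curve, t_yr * 12) * (1 + rate)^(-t_yr)
  trapezoid(t_yr, y)
}

# trapezoid rule on an ordered grid
trapezoid <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
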