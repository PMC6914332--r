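#' Gaze-weighted average absolute decision signals
#'
#' Computes the trial-average absolute decision signal for each item,
#' `A_i = g_i * r_i + (1 - g_i) * gamma * r_i`, where `g_i` is the fraction
#' of total trial time spent fixating item `i` and `r_i` is its value.
#' While an item is not fixated its value signal is discounted by the gaze
#' bias parameter `gamma`; `gamma = 1` removes the discount entirely, and
#' negative `gamma` turns non-fixation into active evidence loss.
#'
#' @param values Numeric vector of item values `r_i` (length >= 2).
#' @param gazes Numeric vector of gaze fractions `g_i` in `[0, 1]`, same
#'   length as `values`.
#' @param gamma Gaze bias weight (scalar, `<= 1`; may be negative).
#' @return Numeric vector of average absolute decision signals.
#' @examples
#' gaze_weighted_signal(c(5, 1, 3), c(0.16, 0.62, 0.22), gamma = 0)
#' @export
gaze_weighted_signal <- function(values, gazes, gamma) {
  if (length(values) != length(gazes))
    stop("`values` and `gazes` must have the same length", call. = FALSE)
  if (length(values) < 2)
    stop("at least two items are required", call. = FALSE)
  if (gamma == 1) return(values)  # exactly gaze-independent
  gazes * values + (1 - gazes) * gamma * values
}

#' Scaled relative decision signals
#'
#' Transforms average absolute decision signals into the relative signals
#' that drive the race: `R*_i = A_i - max_{j != i} A_j` (difference to the
#' best competitor), passed through a logistic `s(x) = 1 / (1 + exp(-tau x))`
#' with sensitivity `tau`. The logistic makes the representation maximally
#' sensitive to differences near zero; `tau = 0` yields `R_i = 0.5` for all
#' items (no sensitivity to value differences).
#'
#' @param a_bar Numeric vector of average absolute decision signals.
#' @param tau Logistic sensitivity (scalar, `>= 0`).
#' @return Numeric vector of relative signals `R_i` in `(0, 1)`.
#' @export
relative_signals <- function(a_bar, tau) {
  if (length(a_bar) < 2)
    stop("at least two items are required", call. = FALSE)
  if (tau < 0)
    stop("`tau` must be non-negative", call. = FALSE)
  rstar <- vapply(seq_along(a_bar),
                  function(i) a_bar[i] - max(a_bar[-i]), numeric(1))
  stats::plogis(tau * rstar)
}

#' First-passage time density of a linear stochastic accumulator
#'
#' Density of the time at which a linear accumulator with drift `drift`,
#' Gaussian increment noise `sigma` and absorbing boundary `b` first reaches
#' the boundary: the inverse-Gaussian (Wald) distribution with mean
#' `mu = b / drift` and shape `lambda = b^2 / sigma^2`. Evaluated in log
#' space internally; `t <= 0` yields density 0.
#'
#' @param t Time (seconds); vectorized.
#' @param drift Accumulation rate (`> 0`).
#' @param sigma Accumulation noise standard deviation (`> 0`).
#' @param b Decision boundary (fixed to 1 in the GLAM).
#' @param log Return the log density?
#' @return Density (or log density) at `t`.
#' @export
ig_fpt_pdf <- function(t, drift, sigma, b = 1, log = FALSE) {
  mu <- b / pmax(drift, 1e-10)
  lambda <- b^2 / sigma^2
  lp <- ifelse(t > 0,
               0.5 * (base::log(lambda) - base::log(2 * pi) - 3 * base::log(pmax(t, 1e-300)))
               - lambda * (t - mu)^2 / (2 * mu^2 * pmax(t, 1e-300)),
               -Inf)
  if (log) lp else exp(lp)
}

#' First-passage time distribution function
#'
#' Cumulative distribution of the inverse-Gaussian first-passage time,
#' `F(t) = Phi(sqrt(lambda/t) (t/mu - 1)) +
#'         exp(2 lambda / mu) Phi(-sqrt(lambda/t) (t/mu + 1))`,
#' with the second term evaluated as `exp(2 lambda/mu + log Phi(.))` so it
#' cannot overflow.
#'
#' @inheritParams ig_fpt_pdf
#' @return Probability that the accumulator has crossed the boundary by `t`.
#' @export
ig_fpt_cdf <- function(t, drift, sigma, b = 1) {
  mu <- b / pmax(drift, 1e-10)
  lambda <- b^2 / sigma^2
  tt <- pmax(t, 1e-300)
  s <- sqrt(lambda / tt)
  term1 <- stats::pnorm(s * (tt / mu - 1))
  lterm2 <- 2 * lambda / mu + stats::pnorm(-s * (tt / mu + 1), log.p = TRUE)
  out <- term1 + ifelse(lterm2 > -745, exp(lterm2), 0)
  out[t <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Joint win density of the linear stochastic race
#'
#' Probability density that accumulator `item` crosses the boundary at time
#' `t` *and* no competitor has crossed earlier:
#' `p_i(t) = f_i(t) * prod_{j != i} (1 - F_j(t))`, with all racers sharing
#' the noise `sigma` and boundary `b` but holding their own drifts.
#'
#' @param t Time (seconds); vectorized.
#' @param item Winning item index, 0-based as in the `choice` column of a
#'   trial table.
#' @param drifts Numeric vector of per-item drift rates `v * R_i`.
#' @param sigma Accumulation noise standard deviation.
#' @param b Decision boundary.
#' @param log Return the log density?
#' @return Joint density `p_item(t)`.
#' @export
race_density <- function(t, item, drifts, sigma, b = 1, log = FALSE) {
  if (length(drifts) < 2)
    stop("a race needs at least two accumulators", call. = FALSE)
  if (item < 0 || item >= length(drifts))
    stop("`item` must be a 0-based index into `drifts`", call. = FALSE)
  lp <- ig_fpt_pdf(t, drifts[item + 1], sigma, b, log = TRUE)
  for (j in seq_along(drifts)[-(item + 1)]) {
    surv <- pmax(1 - ig_fpt_cdf(t, drifts[j], sigma, b), 1e-300)
    lp <- lp + base::log(surv)
  }
  if (log) lp else exp(lp)
}

#' Per-item drift rates for one trial
#'
#' Composes the decision-signal pipeline for a single trial: gaze-weighted
#' absolute signals, relative signals through the logistic transform, and
#' linear scaling by the velocity `v`.
#'
#' @param values,gazes Per-item values and gaze fractions.
#' @param pars Named list or vector with elements `v`, `gamma`, `s`, `tau`.
#' @return Numeric vector of drift rates `v * R_i`.
#' @export
glam_drifts <- function(values, gazes, pars) {
  pars <- as.list(pars)
  a_bar <- gaze_weighted_signal(values, gazes, pars$gamma)
  pars$v * relative_signals(a_bar, pars$tau)
}

#' GLAM likelihood of one observed trial
#'
#' Likelihood of observing `(choice, rt)` for a trial with the given item
#' values and gaze fractions, under the gaze-weighted race with parameters
#' `pars` and a fixed-rate contaminant mixture:
#' `l_i(t) = (1 - epsilon) p_i(t) + epsilon u_s(t)`, where `u_s` is uniform
#' over items and the subject's observed response-time interval
#' (`u_s(t) = 1 / (N (rt_max - rt_min))`).
#'
#' @param values,gazes Per-item values and gaze fractions.
#' @param choice Chosen item (0-based).
#' @param rt Response time in seconds.
#' @param pars Named list or vector with `v`, `gamma`, `s`, `tau`.
#' @param error_weight Contaminant rate `epsilon` in `[0, 1)`; default 0.05.
#' @param rt_range Length-2 vector: the subject's empirical RT range used by
#'   the contaminant density.
#' @param b Decision boundary.
#' @param log Return the log likelihood?
#' @return Likelihood (or log likelihood) of the trial.
#' @export
trial_likelihood <- function(values, gazes, choice, rt, pars,
                             error_weight = 0.05, rt_range, b = 1,
                             log = FALSE) {
  if (error_weight > 0) {
    if (missing(rt_range) || diff(rt_range) <= 0)
      stop("`rt_range` with rt_max > rt_min is required when error_weight > 0",
           call. = FALSE)
    # u_s is a density on the observed RT interval only
    log_u <- if (rt >= rt_range[1] && rt <= rt_range[2])
      -base::log(length(values) * diff(rt_range)) else -Inf
  } else {
    log_u <- -Inf
  }
  pars <- as.list(pars)
  drifts <- glam_drifts(values, gazes, pars)
  lp_race <- race_density(rt, choice, drifts, pars$s, b, log = TRUE)
  lp <- if (error_weight <= 0) {
    lp_race
  } else if (error_weight >= 1) {
    log_u
  } else {
    a <- log1p(-error_weight) + lp_race
    c_ <- base::log(error_weight) + log_u
    hi <- pmax(a, c_)
    ifelse(is.finite(hi), hi + log1p(exp(pmin(a, c_) - hi)), -Inf)
  }
  if (any(is.nan(lp) | is.na(lp) | lp == Inf))
    stop(sprintf("non-finite likelihood at rt=%.4g with v=%.3g gamma=%.3g s=%.3g tau=%.3g",
                 rt, pars$v, pars$gamma, pars$s, pars$tau), call. = FALSE)
  if (log) lp else exp(lp)
}

# Fast pointwise log-likelihood over a prepared trial block (C++ backend).
# Parameter arguments may be scalars or per-trial vectors.
glam_loglik_pointwise <- function(block, v, gamma, s, tau, eps, b = 1) {
  cpp_glam_loglik(block$value, block$gaze, block$choice, block$rt,
                  as.numeric(v), as.numeric(gamma), as.numeric(s),
                  as.numeric(tau), eps, block$log_u, b)
}
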