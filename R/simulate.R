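#' Inverse-Gaussian (Wald) random variates
#'
#' Exact sampling by the transformation-with-rejection method of Michael,
#' Schucany and Haas: a chi-square variate is transformed to a root of the
#' inverse-Gaussian density and the smaller/larger root is selected with the
#' appropriate probability.
#'
#' @param n Number of draws.
#' @param mu Mean `b / drift` (vectorized).
#' @param lambda Shape `b^2 / sigma^2` (vectorized).
#' @return Numeric vector of first-passage times.
#' @export
rinvgauss <- function(n, mu, lambda) {
  mu <- rep_len(mu, n)
  lambda <- rep_len(lambda, n)
  y <- stats::rnorm(n)^2
  # smaller root of the quadratic, written in its cancellation-free form
  s <- mu * y / (2 * lambda)
  x <- mu / (1 + s + sqrt(s * (s + 2)))
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Simulate choices and response times for one trial
#'
#' Exact forward sampling of the gaze-weighted race: one inverse-Gaussian
#' first-passage time is drawn per accumulator (mean `b / (v R_i)`, shape
#' `b^2 / s^2`) and the winning item and its time are returned. With
#' probability `error_weight` the trial is instead a contaminant response:
#' a uniformly random item at a uniformly random time in `rt_range`.
#'
#' @param values,gazes Per-item values and gaze fractions for the trial.
#' @param pars Named list or vector with `v`, `gamma`, `s`, `tau`.
#' @param error_weight Contaminant rate (default 0: pure race).
#' @param rt_range RT interval of the contaminant density; required when
#'   `error_weight > 0`.
#' @param n Number of independent repetitions of the trial.
#' @param b Decision boundary.
#' @return Data frame with columns `choice` (0-based) and `rt` (seconds).
#' @export
simulate_trial <- function(values, gazes, pars, error_weight = 0,
                           rt_range = NULL, n = 1, b = 1) {
  pars <- as.list(pars)
  drifts <- glam_drifts(values, gazes, pars)
  lambda <- b^2 / pars$s^2
  m <- length(drifts)
  fpt <- matrix(rinvgauss(n * m, rep(b / pmax(drifts, 1e-10), each = n), lambda),
                nrow = n)
  choice <- max.col(-fpt, ties.method = "first") - 1L
  rt <- fpt[cbind(seq_len(n), choice + 1L)]
  if (error_weight > 0) {
    if (is.null(rt_range))
      stop("`rt_range` is required when error_weight > 0", call. = FALSE)
    is_err <- stats::runif(n) < error_weight
    n_err <- sum(is_err)
    if (n_err > 0) {
      choice[is_err] <- sample.int(m, n_err, replace = TRUE) - 1L
      rt[is_err] <- stats::runif(n_err, rt_range[1], rt_range[2])
    }
  }
  data.frame(choice = choice, rt = rt)
}

#' Response-time quantiles of the race component
#'
#' The marginal RT distribution of the race (ignoring which item wins) has
#' closed-form CDF `1 - prod_i (1 - F_i(t))`; averaged over a set of trials
#' this gives the model-implied RT distribution, whose quantiles are found
#' by root-finding. Used to give de-novo simulations a self-consistent
#' contaminant RT interval when no empirical response times exist.
#'
#' @param value,gaze Matrices (trials x items) of values and gaze fractions.
#' @param pars Named list with `v`, `gamma`, `s`, `tau` (scalars).
#' @param probs Quantile probabilities.
#' @param b Decision boundary.
#' @return Numeric vector of RT quantiles (seconds).
#' @export
race_rt_quantiles <- function(value, gaze, pars, probs = c(0.01, 0.99), b = 1) {
  pars <- as.list(pars)
  n <- nrow(value)
  drifts <- t(vapply(seq_len(n), function(i)
    glam_drifts(value[i, ], gaze[i, ], pars), numeric(ncol(value))))
  race_cdf <- function(t) {
    surv <- rep(1, n)
    for (j in seq_len(ncol(drifts)))
      surv <- surv * (1 - ig_fpt_cdf(t, drifts[, j], pars$s, b))
    mean(1 - surv)
  }
  upper <- 1
  while (race_cdf(upper) < max(probs) && upper < 1e6) upper <- upper * 2
  vapply(probs, function(p) {
    stats::uniroot(function(t) race_cdf(t) - p, c(1e-8, upper),
                   tol = 1e-6)$root
  }, numeric(1))
}

default_generating_parameters <- function(n, priors = glam_priors()) {
  h <- priors$hyper
  draw <- function(p) {
    m <- h$m[h$param == p & h$level == "mu"]
    s <- h$m[h$param == p & h$level == "sd"]
    b <- priors$bounds[[p]]
    rtnorm(n, m, s, b[1], b[2])
  }
  data.frame(v = draw("v"), gamma = draw("gamma"), s = draw("s"),
             tau = draw("tau"))
}

#' Simulate a cohort of subjects
#'
#' Generates a full trial table for `n_individuals` subjects performing
#' `n_trials` choices among `n_items` items. Item values are drawn i.i.d.
#' uniform on the integers `value_range[1]..value_range[2]` (mimicking a
#' 1-10 liking-rating scale) and gaze vectors from a symmetric
#' Dirichlet(`gaze_alpha`), independent of the values. With
#' `kind = "individual"`, `parameters` is a list of per-subject vectors
#' (elements `v`, `gamma`, `s`, `tau`, each length 1 or `n_individuals`);
#' missing entries are drawn from truncated-normal population defaults
#' centred on published group-level estimates. With `kind = "hierarchical"`,
#' `parameters` gives per-parameter `c(mean, sd)` pairs and each subject's
#' parameters are drawn from the corresponding truncated-normal group
#' distribution. The contaminant RT interval is the race component's
#' 1st-99th percentile range, computed per subject from the closed-form
#' race RT distribution.
#'
#' @param kind `"individual"` or `"hierarchical"`.
#' @param n_individuals,n_trials,n_items Cohort dimensions (`n_items >= 2`).
#' @param parameters Generating parameters (see Details above).
#' @param error_weight Contaminant rate (default 0.05).
#' @param value_range Integer range of item values.
#' @param gaze_alpha Dirichlet concentration of the gaze generator.
#' @param label Named list of constant factor columns to attach (e.g.
#'   `list(group = "group1")`).
#' @param subject_offset Added to the subject ids (for binding several
#'   simulated groups into one table).
#' @param seed Optional RNG seed.
#' @return A validated trial table; the per-subject generating parameters
#'   are attached as attribute `"generating_parameters"`.
#' @export
simulate_group <- function(kind = c("individual", "hierarchical"),
                           n_individuals = 10, n_trials = 100, n_items = 3,
                           parameters = NULL, error_weight = 0.05,
                           value_range = c(1, 10), gaze_alpha = 1,
                           label = NULL, subject_offset = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (n_items < 2) stop("`n_items` must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  defaults <- default_generating_parameters(n_individuals)
  gen <- defaults
  if (kind == "individual") {
    for (p in .glam_params) {
      if (!is.null(parameters[[p]])) {
        val <- parameters[[p]]
        if (!(length(val) %in% c(1, n_individuals)))
          stop("parameters$", p, " must have length 1 or n_individuals",
               call. = FALSE)
        gen[[p]] <- rep_len(val, n_individuals)
      }
    }
  } else {
    priors <- glam_priors()
    for (p in .glam_params) {
      spec <- parameters[[p]]
      if (!is.null(spec)) {
        if (length(spec) != 2)
          stop("hierarchical parameters$", p, " must be c(mean, sd)",
               call. = FALSE)
        b <- priors$bounds[[p]]
        gen[[p]] <- rtnorm(n_individuals, spec[1], spec[2], b[1], b[2])
      }
    }
  }

  out <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    pars <- as.list(gen[i, ])
    value <- matrix(sample(value_range[1]:value_range[2],
                           n_trials * n_items, replace = TRUE),
                    nrow = n_trials)
    g <- matrix(stats::rgamma(n_trials * n_items, shape = gaze_alpha),
                nrow = n_trials)
    gaze <- g / rowSums(g)
    rt_range <- if (error_weight > 0)
      race_rt_quantiles(value, gaze, pars) else NULL
    sim <- do.call(rbind, lapply(seq_len(n_trials), function(tr)
      simulate_trial(value[tr, ], gaze[tr, ], pars,
                     error_weight = error_weight, rt_range = rt_range)))
    d <- data.frame(subject = i - 1 + subject_offset, trial = 0:(n_trials - 1),
                    choice = sim$choice, rt = sim$rt)
    d <- cbind(d, as.data.frame(value), as.data.frame(gaze))
    names(d) <- c("subject", "trial", "choice", "rt",
                  paste0("item_value_", 0:(n_items - 1)),
                  paste0("gaze_", 0:(n_items - 1)))
    out[[i]] <- d
  }
  data <- do.call(rbind, out)
  if (!is.null(label))
    for (nm in names(label)) data[[nm]] <- label[[nm]]
  gen$subject <- seq_len(n_individuals) - 1 + subject_offset
  gen <- gen[c("subject", .glam_params)]
  if (subject_offset == 0) data <- validate_trial_table(data, n_items)
  attr(data, "generating_parameters") <- gen
  attr(data, "n_items") <- as.integer(n_items)
  data
}

#' Bind simulated groups into one trial table
#'
#' Convenience wrapper that concatenates trial tables produced by
#' [simulate_group()] with different `subject_offset`s, merging their
#' generating-parameter attributes.
#'
#' @param ... Trial tables from [simulate_group()].
#' @return A single validated trial table with combined
#'   `"generating_parameters"`.
#' @export
bind_groups <- function(...) {
  tables <- list(...)
  gen <- do.call(rbind, lapply(tables, attr, "generating_parameters"))
  data <- do.call(rbind, lapply(tables, as.data.frame))
  data <- validate_trial_table(data)
  attr(data, "generating_parameters") <- gen
  data
}
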