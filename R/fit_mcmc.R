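# Adaptive random-walk Metropolis over a box-bounded parameter vector.
# Coordinates are updated one at a time; proposal scales adapt toward a
# 0.44 acceptance rate during the tuning phase (in windows of 50
# iterations, damped over successive windows) and are frozen afterwards,
# so the retained chain satisfies detailed balance.
mh_chain <- function(logpost, init, lower, upper, draws, tune,
                     scale = NULL, target = 0.44) {
  k <- length(init)
  theta <- init
  lp <- logpost(theta)
  if (!is.finite(lp))
    stop("non-finite log density at the initial point (",
         paste(sprintf("%.3g", init), collapse = ", "), ")", call. = FALSE)
  if (is.null(scale)) scale <- pmin((upper - lower) / 10, 1)
  out <- matrix(NA_real_, draws, k)
  acc <- integer(k)
  window <- 0L
  for (i in seq_len(tune + draws)) {
    for (j in seq_len(k)) {
      prop <- theta
      prop[j] <- theta[j] + stats::rnorm(1, 0, scale[j])
      if (prop[j] < lower[j] || prop[j] > upper[j]) next
      lp2 <- logpost(prop)
      if (is.finite(lp2) && base::log(stats::runif(1)) < lp2 - lp) {
        theta <- prop
        lp <- lp2
        acc[j] <- acc[j] + 1L
      }
    }
    if (i <= tune && i %% 50 == 0) {
      window <- window + 1L
      rate <- acc / 50
      scale <- scale * exp((rate - target) / sqrt(window))
      acc[] <- 0L
    }
    if (i > tune) out[i - tune, ] <- theta
  }
  out
}

# Draws x chains x params array with parameter dimnames.
run_chains <- function(logpost, init_fn, lower, upper, draws, tune, chains,
                       names) {
  k <- length(lower)
  samples <- array(NA_real_, c(draws, chains, k),
                   dimnames = list(NULL, NULL, names))
  for (ch in seq_len(chains)) {
    init <- init_fn(ch)
    samples[, ch, ] <- mh_chain(logpost, init, lower, upper, draws, tune)
  }
  samples
}

jitter_into <- function(x, lower, upper, amount = 0.05) {
  pmin(pmax(x + stats::rnorm(length(x), 0, amount * (upper - lower)),
            lower + 1e-6 * (upper - lower)),
       upper - 1e-6 * (upper - lower))
}

# -- individual / pooled kinds -------------------------------------------

fit_flat_unit <- function(model, blocks, subject, draws, tune, chains,
                          prior_only = FALSE) {
  fpt <- free_param_table(model, subject)
  eps <- model$error_weight
  all_rows <- unlist(lapply(blocks, `[[`, "rows"))
  logpost <- function(theta) {
    if (prior_only) return(0)
    names(theta) <- fpt$name
    total <- 0
    for (b in blocks) {
      pv <- trial_param_vectors(model, theta, b$rows, b$subject)
      ll <- glam_loglik_pointwise(b, pv$v, pv$gamma, pv$s, pv$tau, eps)
      total <- total + sum(ll)
    }
    total
  }
  init_fn <- function(ch) {
    stats::runif(nrow(fpt), fpt$lo + 0.2 * (fpt$hi - fpt$lo),
                 fpt$hi - 0.2 * (fpt$hi - fpt$lo))
  }
  run_chains(logpost, init_fn, fpt$lo, fpt$hi, draws, tune, chains, fpt$name)
}

# -- hierarchical kind ---------------------------------------------------

# Group-level parameter table: one row per (param, mu/sd, level). For a
# between-subject factor each level gets its own group distribution; each
# subject is assigned the level it exhibits.
hier_group_table <- function(model) {
  h <- model$priors$hyper
  f <- model$priors$f
  rows <- list()
  for (p in .glam_params) {
    l <- model$layout[[p]]
    if (l$status == "fixed") next
    levels <- if (is.null(l$levels)) NA_character_ else l$levels
    for (lev in levels) {
      for (side in c("mu", "sd")) {
        hh <- h[h$param == p & h$level == side, ]
        nm <- if (is.na(lev)) paste0(p, "_", side)
              else paste0(p, "_", side, "[", lev, "]")
        rows[[length(rows) + 1]] <- data.frame(
          name = nm, param = p, side = side, level = lev,
          m = hh$m, scale = f * hh$sd, lo = hh$lo, hi = hh$hi,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Subject-level unit table: one row per (subject, param, level present for
# that subject), with the subject-parameter truncation bounds.
hier_subject_table <- function(model) {
  rows <- list()
  for (s in model$subjects) {
    for (p in .glam_params) {
      l <- model$layout[[p]]
      if (l$status == "fixed") next
      b <- model$priors$bounds[[p]]
      levs <- if (is.null(l$levels)) NA_character_ else
        l$levels[sort(unique(l$trial_level[model$data$subject == s]))]
      for (lev in levs) {
        nm <- if (is.na(lev)) sprintf("%s[%d]", p, s)
              else sprintf("%s[%d,%s]", p, s, lev)
        rows[[length(rows) + 1]] <- data.frame(
          name = nm, subject = s, param = p, level = lev,
          lo = b[1], hi = b[2], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# One Metropolis-within-Gibbs sweep cannot be vectorized across subjects, so
# the hierarchical sampler keeps explicit state: subject-level values theta
# (named), group-level values phi (named). Subject likelihoods are cached.
fit_hierarchical <- function(model, draws, tune, chains, prior_only = FALSE) {
  gt <- hier_group_table(model)
  st <- hier_subject_table(model)
  eps <- model$error_weight
  blocks <- model$blocks
  names(blocks) <- vapply(blocks, function(b) as.character(b$subject), "")

  # map subject units -> their group-level mu/sd rows
  st$mu_name <- ifelse(is.na(st$level), paste0(st$param, "_mu"),
                       paste0(st$param, "_mu[", st$level, "]"))
  st$sd_name <- ifelse(is.na(st$level), paste0(st$param, "_sd"),
                       paste0(st$param, "_sd[", st$level, "]"))

  subj_loglik <- function(s, theta) {
    if (prior_only) return(0)
    b <- blocks[[as.character(s)]]
    pv <- trial_param_vectors(model, theta_for_subject(theta, s), b$rows, s)
    sum(glam_loglik_pointwise(b, pv$v, pv$gamma, pv$s, pv$tau, eps))
  }
  # rename subject's units to plain parameter names for trial_param_vectors
  theta_for_subject <- function(theta, s) {
    idx <- st$subject == s
    nm <- ifelse(is.na(st$level[idx]), st$param[idx],
                 paste0(st$param[idx], "[", st$level[idx], "]"))
    stats::setNames(theta[st$name[idx]], nm)
  }

  k_total <- nrow(st) + nrow(gt)
  samples <- array(NA_real_, c(draws, chains, k_total),
                   dimnames = list(NULL, NULL, c(st$name, gt$name)))

  for (ch in seq_len(chains)) {
    phi <- stats::setNames(jitter_into(gt$m, gt$lo, gt$hi), gt$name)
    theta <- stats::setNames(
      jitter_into(phi[st$mu_name], st$lo, st$hi), st$name)
    ll <- stats::setNames(vapply(model$subjects, function(s)
      subj_loglik(s, theta), numeric(1)), as.character(model$subjects))
    s_theta <- stats::setNames(pmin((st$hi - st$lo) / 20, 0.25), st$name)
    s_phi <- stats::setNames(pmin((gt$hi - gt$lo) / 10, 0.25), gt$name)
    acc_t <- integer(nrow(st)); acc_p <- integer(nrow(gt))
    window <- 0L

    for (i in seq_len(tune + draws)) {
      # subject-level updates
      for (u in seq_len(nrow(st))) {
        s <- st$subject[u]
        cur <- theta[[u]]
        prop <- cur + stats::rnorm(1, 0, s_theta[[u]])
        if (prop < st$lo[u] || prop > st$hi[u]) next
        mu <- phi[[st$mu_name[u]]]; sd_ <- phi[[st$sd_name[u]]]
        lp_cur <- dtnorm_log(cur, mu, sd_, st$lo[u], st$hi[u])
        lp_prop <- dtnorm_log(prop, mu, sd_, st$lo[u], st$hi[u])
        theta2 <- theta; theta2[[u]] <- prop
        ll_prop <- subj_loglik(s, theta2)
        if (is.finite(ll_prop) &&
            base::log(stats::runif(1)) <
              (ll_prop + lp_prop) - (ll[[as.character(s)]] + lp_cur)) {
          theta <- theta2
          ll[[as.character(s)]] <- ll_prop
          acc_t[u] <- acc_t[u] + 1L
        }
      }
      # group-level updates: prior x truncated-normal likelihood of the
      # subject units assigned to this group distribution
      for (u in seq_len(nrow(gt))) {
        cur <- phi[[u]]
        prop <- cur + stats::rnorm(1, 0, s_phi[[u]])
        if (prop < gt$lo[u] || prop > gt$hi[u]) next
        if (gt$side[u] == "sd" && prop <= 1e-4) next
        members <- if (gt$side[u] == "mu") st$mu_name == gt$name[u]
                   else st$sd_name == gt$name[u]
        th <- theta[st$name[members]]
        lo <- st$lo[members][1]; hi <- st$hi[members][1]
        mu_cur <- if (gt$side[u] == "mu") cur else phi[[st$mu_name[members][1]]]
        mu_prop <- if (gt$side[u] == "mu") prop else mu_cur
        sd_cur <- if (gt$side[u] == "sd") cur else phi[[st$sd_name[members][1]]]
        sd_prop <- if (gt$side[u] == "sd") prop else sd_cur
        lp_cur <- sum(dtnorm_log(th, mu_cur, sd_cur, lo, hi)) +
          dtnorm_log(cur, gt$m[u], gt$scale[u], gt$lo[u], gt$hi[u])
        lp_prop <- sum(dtnorm_log(th, mu_prop, sd_prop, lo, hi)) +
          dtnorm_log(prop, gt$m[u], gt$scale[u], gt$lo[u], gt$hi[u])
        if (is.finite(lp_prop) &&
            base::log(stats::runif(1)) < lp_prop - lp_cur) {
          phi[[u]] <- prop
          acc_p[u] <- acc_p[u] + 1L
        }
      }
      if (i <= tune && i %% 50 == 0) {
        window <- window + 1L
        s_theta <- s_theta * exp((acc_t / 50 - 0.44) / sqrt(window))
        s_phi <- s_phi * exp((acc_p / 50 - 0.44) / sqrt(window))
        acc_t[] <- 0L; acc_p[] <- 0L
      }
      if (i > tune) samples[i - tune, ch, ] <- c(theta, phi)
    }
  }
  samples
}

#' Fit a GLAM model
#'
#' Estimates the free parameters of a [glam_model()] by MCMC (default:
#' adaptive Metropolis-Hastings, one chain sweep updating each scalar
#' parameter in turn) or by a mean-field variational approximation
#' (`method = "VI"`, see [fit_vi()]). Individual models are fitted
#' subject by subject; hierarchical models sample subject-level parameters
#' and group-level means/standard deviations jointly by
#' Metropolis-within-Gibbs.
#'
#' @param model A `"glam_model"` object.
#' @param method `"MCMC"` or `"VI"`.
#' @param draws Retained posterior draws per chain (after tuning).
#' @param tune Tuning (burn-in) iterations per chain, discarded.
#' @param chains Number of chains (at least 2 for convergence diagnostics).
#' @param seed Optional RNG seed.
#' @param prior_only Sample from the prior alone (likelihood disabled);
#'   used for prior predictive checks.
#' @param ... Passed to [fit_vi()] when `method = "VI"`.
#' @return An object of class `"glam_fit"`: posterior samples (per subject
#'   for individual models), the model, and convergence diagnostics
#'   (split R-hat and effective sample size per parameter).
#' @export
fit_glam <- function(model, method = c("MCMC", "VI"), draws = 2000,
                     tune = 2000, chains = 4, seed = NULL,
                     prior_only = FALSE, ...) {
  method <- match.arg(method)
  stopifnot(inherits(model, "glam_model"))
  if (!is.null(seed)) set.seed(seed)
  if (method == "VI") return(fit_vi(model, draws = draws, seed = NULL, ...))
  if (draws <= 0 || tune < 0) stop("draws must be positive", call. = FALSE)

  samples <- switch(model$kind,
    individual = {
      res <- lapply(model$blocks, function(b)
        fit_flat_unit(model, list(b), b$subject, draws, tune, chains,
                      prior_only))
      names(res) <- as.character(vapply(model$blocks, `[[`, 0, "subject"))
      res
    },
    pooled = fit_flat_unit(model, model$blocks, NULL, draws, tune, chains,
                           prior_only),
    hierarchical = fit_hierarchical(model, draws, tune, chains, prior_only)
  )
  new_glam_fit(model, samples, method = "MCMC",
               settings = list(draws = draws, tune = tune, chains = chains,
                               seed = seed, prior_only = prior_only))
}

new_glam_fit <- function(model, samples, method, settings) {
  fit <- structure(list(
    model = model,
    kind = model$kind,
    method = method,
    samples = samples,
    settings = settings,
    name = model$name
  ), class = "glam_fit")
  fit$diagnostics <- convergence_diagnostics(fit)
  fit
}

#' @export
print.glam_fit <- function(x, ...) {
  cat("GLAM fit '", x$name, "' (kind: ", x$kind, ", method: ", x$method,
      ")\n", sep = "")
  s <- x$settings
  cat("  ", s$chains %||% 1, " chain(s) x ", s$draws, " draws\n", sep = "")
  d <- x$diagnostics
  if (!is.null(d) && nrow(d) > 0) {
    cat("  worst split R-hat: ", sprintf("%.3f", max(d$rhat, na.rm = TRUE)),
        ", smallest ESS: ", sprintf("%.0f", min(d$ess, na.rm = TRUE)), "\n",
        sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
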