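# Mean-field Gaussian variational approximation on the unconstrained scale.
# Each box-bounded parameter is mapped to the real line by a scaled logit;
# the ELBO is maximized by stochastic gradient ascent (Adam) with the
# reparameterization trick, gradients of the log posterior taken by central
# finite differences (the parameter spaces here are small). Approximate
# posterior draws are then transformed back to the constrained scale.

logit_fwd <- function(x, lo, hi) stats::qlogis((x - lo) / (hi - lo))
logit_inv <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)
# log |d theta / d z| for the scaled-logit transform
logit_ljac <- function(z, lo, hi)
  base::log(hi - lo) + stats::plogis(z, log.p = TRUE) +
    stats::plogis(-z, log.p = TRUE)

advi <- function(logpost, lower, upper, names, iterations = 2000,
                 samples = 1000, lr = 0.05, grad_eps = 1e-4) {
  k <- length(lower)
  m <- rep(0, k)
  log_s <- rep(base::log(0.2), k)
  ma <- va <- rep(0, k)   # Adam moments for m
  ms <- vs <- rep(0, k)   # Adam moments for log_s
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  target <- function(z) {
    th <- logit_inv(z, lower, upper)
    lp <- logpost(th) + sum(logit_ljac(z, lower, upper))
    if (!is.finite(lp)) -1e10 else lp
  }
  grad_z <- function(z) {
    g <- numeric(k)
    for (j in seq_len(k)) {
      zp <- z; zm <- z
      zp[j] <- z[j] + grad_eps
      zm[j] <- z[j] - grad_eps
      g[j] <- (target(zp) - target(zm)) / (2 * grad_eps)
    }
    g
  }
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    eta <- stats::rnorm(k)
    z <- m + exp(log_s) * eta
    g <- grad_z(z)
    if (any(!is.finite(g)))
      stop("variational optimizer diverged at iteration ", it, call. = FALSE)
    gm <- g
    gs <- g * exp(log_s) * eta + 1  # d ELBO / d log_s (entropy term is +1)
    ma <- b1 * ma + (1 - b1) * gm; va <- b2 * va + (1 - b2) * gm^2
    ms <- b1 * ms + (1 - b1) * gs; vs <- b2 * vs + (1 - b2) * gs^2
    step <- lr * sqrt(1 - b2^it) / (1 - b1^it)
    m <- m + step * ma / (sqrt(va) + eps_adam)
    log_s <- log_s + step * ms / (sqrt(vs) + eps_adam)
    trace[it] <- target(z)
  }
  z_draws <- matrix(stats::rnorm(samples * k), samples, k)
  z_draws <- sweep(sweep(z_draws, 2, exp(log_s), `*`), 2, m, `+`)
  draws <- sapply(seq_len(k), function(j)
    logit_inv(z_draws[, j], lower[j], upper[j]))
  dimnames(draws) <- list(NULL, names)
  list(draws = draws, m = m, s = exp(log_s), elbo_trace = trace)
}

#' Variational approximation of a GLAM posterior
#'
#' Fits a mean-field Gaussian approximation on the unconstrained
#' (logit-transformed) parameter scale by stochastic-gradient ELBO
#' maximization and returns approximate posterior draws. Variational
#' estimates are fast but can be inaccurate (they ignore posterior
#' correlations); MCMC is recommended for final analyses. The returned fit
#' is flagged `method = "VI"`.
#'
#' @param model A `"glam_model"` object (individual or pooled kind).
#' @param draws Number of approximate posterior draws to return.
#' @param iterations Optimizer iterations.
#' @param seed Optional RNG seed.
#' @return A `"glam_fit"` with a single pseudo-chain of approximate draws.
#' @export
fit_vi <- function(model, draws = 2000, iterations = 2000, seed = NULL) {
  stopifnot(inherits(model, "glam_model"))
  if (!is.null(seed)) set.seed(seed)
  if (model$kind == "hierarchical")
    stop("variational fitting is implemented for individual and pooled kinds; ",
         "use MCMC for hierarchical models", call. = FALSE)
  eps <- model$error_weight
  fit_unit <- function(blocks, subject) {
    fpt <- free_param_table(model, subject)
    logpost <- function(theta) {
      names(theta) <- fpt$name
      total <- 0
      for (b in blocks) {
        pv <- trial_param_vectors(model, theta, b$rows, b$subject)
        total <- total + sum(glam_loglik_pointwise(b, pv$v, pv$gamma,
                                                   pv$s, pv$tau, eps))
      }
      total
    }
    res <- advi(logpost, fpt$lo, fpt$hi, fpt$name,
                iterations = iterations, samples = draws)
    array(res$draws, c(draws, 1, nrow(fpt)),
          dimnames = list(NULL, NULL, fpt$name))
  }
  samples <- if (model$kind == "individual") {
    res <- lapply(model$blocks, function(b) fit_unit(list(b), b$subject))
    names(res) <- as.character(vapply(model$blocks, `[[`, 0, "subject"))
    res
  } else {
    fit_unit(model$blocks, NULL)
  }
  new_glam_fit(model, samples, method = "VI",
               settings = list(draws = draws, tune = 0, chains = 1,
                               iterations = iterations, seed = seed,
                               approximate = TRUE))
}
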