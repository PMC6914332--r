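log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + base::log(sum(exp(x - m)))
}

# Pointwise log-likelihood matrix (posterior draws x trials) for one subject
# of an individual fit, or for the whole data of a pooled/hierarchical fit.
pointwise_loglik <- function(fit, subject = NULL, n_draws_max = 2000) {
  model <- fit$model
  eps <- model$error_weight
  if (fit$kind == "individual") {
    stopifnot(!is.null(subject))
    arr <- fit$samples[[as.character(subject)]]
    blocks <- Filter(function(b) b$subject == subject, model$blocks)
  } else {
    arr <- fit$samples
    blocks <- model$blocks
  }
  k <- dim(arr)[3]
  flat <- matrix(arr, ncol = k)
  colnames(flat) <- dimnames(arr)[[3]]
  if (nrow(flat) > n_draws_max) {
    keep <- round(seq(1, nrow(flat), length.out = n_draws_max))
    flat <- flat[keep, , drop = FALSE]
  }
  n_trials <- sum(vapply(blocks, `[[`, 0, "n"))
  L <- matrix(NA_real_, nrow(flat), n_trials)
  for (d in seq_len(nrow(flat))) {
    theta <- flat[d, ]
    off <- 0
    for (b in blocks) {
      th <- theta
      if (fit$kind == "hierarchical") {
        idx <- grep(sprintf("\\[%d(,|\\])", b$subject), names(theta))
        nm <- sub(sprintf("\\[%d\\]", b$subject), "", names(theta)[idx])
        nm <- sub(sprintf("\\[%d,", b$subject), "[", nm)
        th <- stats::setNames(theta[idx], nm)
      }
      pv <- trial_param_vectors(model, th, b$rows, b$subject)
      L[d, off + seq_len(b$n)] <-
        glam_loglik_pointwise(b, pv$v, pv$gamma, pv$s, pv$tau, eps)
      off <- off + b$n
    }
  }
  L
}

# WAIC on the deviance scale (lower is better) from a draws x trials
# pointwise log-likelihood matrix.
waic_from_loglik <- function(L) {
  S <- nrow(L)
  lppd_i <- apply(L, 2, log_sum_exp) - base::log(S)
  p_i <- apply(L, 2, stats::var)
  elpd_i <- lppd_i - p_i
  pointwise <- -2 * elpd_i
  list(ic = sum(pointwise), p = sum(p_i),
       se = sqrt(ncol(L) * stats::var(pointwise)),
       pointwise = pointwise, warn = any(p_i > 0.4))
}

# Generalized Pareto fit to sample tails (profile-likelihood estimator of
# Zhang & Stephens 2009), used by PSIS.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3 * x[max(1, floor(n / 4 + 0.5))]
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / prior_bs
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (base::log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  list(k = k, sigma = k / theta_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smoothed importance weights for one vector of log ratios.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exc <= 0)) return(list(lw = lw, k = NA_real_))
  fitted <- gpd_fit(exc[exc > 0])
  if (!is.finite(fitted$k)) return(list(lw = lw, k = NA_real_))
  q <- qgpd((seq_len(M) - 0.5) / M, fitted$k, fitted$sigma)
  smoothed <- base::log(exp(cutoff) + q)
  lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
  list(lw = lw, k = fitted$k)
}

# PSIS-LOO on the deviance scale from a pointwise log-likelihood matrix.
loo_from_loglik <- function(L) {
  S <- nrow(L)
  n <- ncol(L)
  elpd_i <- numeric(n)
  khat <- numeric(n)
  lppd_i <- apply(L, 2, log_sum_exp) - base::log(S)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-L[, i])
    elpd_i[i] <- log_sum_exp(sm$lw + L[, i]) - log_sum_exp(sm$lw)
    khat[i] <- sm$k
  }
  pointwise <- -2 * elpd_i
  list(ic = sum(pointwise), p = sum(lppd_i - elpd_i),
       se = sqrt(n * stats::var(pointwise)),
       pointwise = pointwise,
       warn = any(is.finite(khat) & khat > 0.7))
}

#' Compare fitted GLAM variants by information criterion
#'
#' Computes WAIC (widely applicable information criterion) or PSIS-LOO
#' (Pareto-smoothed importance-sampling leave-one-out cross-validation)
#' for each fitted model from its pointwise trial log-likelihoods, on the
#' deviance scale where the lowest value marks the best-fitting model.
#' Individual fits are compared per subject; pooled and hierarchical fits
#' as a whole. Alongside the criterion the table reports the effective
#' number of parameters (`pWAIC`/`pLOO`), the difference to the best model
#' (`dWAIC`/`dLOO`) with its standard error, Akaike-style model weights
#' (per subject, summing to 1), and a variance warning flag.
#'
#' @param fits List of `"glam_fit"` objects sharing the same data.
#' @param ic `"WAIC"` (default) or `"LOO"`.
#' @param n_draws_max Cap on posterior draws used per model (thinned
#'   evenly).
#' @return Data frame with one row per model (x subject for individual
#'   fits).
#' @export
compare_models <- function(fits, ic = c("WAIC", "LOO"), n_draws_max = 2000) {
  ic <- match.arg(ic)
  stopifnot(length(fits) >= 2)
  names(fits) <- vapply(fits, function(f) f$name, character(1))
  kinds <- unique(vapply(fits, function(f) f$kind, character(1)))
  n_trials <- unique(vapply(fits, function(f) nrow(f$model$data), numeric(1)))
  if (length(n_trials) > 1)
    stop("fits must share the same data", call. = FALSE)
  calc <- if (ic == "WAIC") waic_from_loglik else loo_from_loglik

  one_comparison <- function(results, subject = NA) {
    vals <- vapply(results, `[[`, 0, "ic")
    best <- which.min(vals)
    d <- vals - vals[best]
    dse <- vapply(seq_along(results), function(m) {
      if (m == best) return(0)
      pw <- results[[m]]$pointwise - results[[best]]$pointwise
      sqrt(length(pw) * stats::var(pw))
    }, numeric(1))
    w <- exp(-0.5 * d)
    w <- w / sum(w)
    out <- data.frame(
      subject = subject,
      model = names(results),
      ic = vals,
      p_ic = vapply(results, `[[`, 0, "p"),
      d_ic = d,
      weight = w,
      SE = vapply(results, `[[`, 0, "se"),
      dSE = dse,
      var_warn = as.integer(vapply(results, `[[`, TRUE, "warn")),
      stringsAsFactors = FALSE
    )
    names(out)[names(out) == "ic"] <- ic
    names(out)[names(out) == "p_ic"] <- paste0("p", ic)
    names(out)[names(out) == "d_ic"] <- paste0("d", ic)
    out[order(out[[ic]]), ]
  }

  if (all(kinds == "individual")) {
    subjects <- fits[[1]]$model$subjects
    for (f in fits)
      if (!identical(f$model$subjects, subjects))
        stop("fits must share the same data", call. = FALSE)
    out <- lapply(subjects, function(s) {
      results <- lapply(fits, function(f)
        calc(pointwise_loglik(f, s, n_draws_max)))
      one_comparison(results, s)
    })
    out <- do.call(rbind, out)
  } else {
    results <- lapply(fits, function(f)
      calc(pointwise_loglik(f, n_draws_max = n_draws_max)))
    out <- one_comparison(results)
  }
  rownames(out) <- NULL
  out
}

#' Posterior contrasts of parameters between groups or conditions
#'
#' For each requested parameter and each pair of levels, computes the
#' posterior distribution of the difference (level A minus level B): its
#' mean, the fraction of posterior samples above zero, and the 95% HPD
#' interval of the difference. Hierarchical fits contrast the group-level
#' mean parameters; individual fits return one contrast per subject over
#' that subject's condition-specific parameters.
#'
#' @param fit A `"glam_fit"` whose model used `depends_on`.
#' @param parameters Character vector among `c("v", "gamma", "s", "tau")`.
#' @param comparisons List of length-2 character vectors of level names,
#'   e.g. `list(c("group1", "group2"))`.
#' @param prob HPD mass (default 0.95).
#' @return Data frame with columns `parameter`, `level_a`, `level_b`,
#'   `subject`, `mean_diff`, `p_gt_0`, `hpd_lo`, `hpd_hi`.
#' @export
compare_parameters <- function(fit, parameters, comparisons, prob = 0.95) {
  stopifnot(inherits(fit, "glam_fit"))
  bad <- setdiff(parameters, .glam_params)
  if (length(bad) > 0)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.list(comparisons)) comparisons <- list(comparisons)

  get_draws <- function(arr, name, context) {
    pars <- dimnames(arr)[[3]]
    if (!(name %in% pars))
      stop("no sampled parameter '", name, "'", context,
           "; available: ", paste(pars, collapse = ", "), call. = FALSE)
    as.vector(arr[, , name])
  }
  contrast <- function(xa, xb, p, a, b, subject = NA) {
    d <- xa - xb
    h <- hpd_interval(d, prob)
    data.frame(parameter = p, level_a = a, level_b = b, subject = subject,
               mean_diff = mean(d),
               p_gt_0 = mean(d > 0) + 0.5 * mean(d == 0),
               hpd_lo = h[1], hpd_hi = h[2], stringsAsFactors = FALSE)
  }

  rows <- list()
  for (p in parameters) {
    for (cmp in comparisons) {
      a <- cmp[1]; b <- cmp[2]
      if (fit$kind == "hierarchical") {
        arr <- fit$samples
        rows[[length(rows) + 1]] <- contrast(
          get_draws(arr, sprintf("%s_mu[%s]", p, a), " (group level)"),
          get_draws(arr, sprintf("%s_mu[%s]", p, b), " (group level)"),
          p, a, b)
      } else if (fit$kind == "individual") {
        for (s in names(fit$samples)) {
          arr <- fit$samples[[s]]
          rows[[length(rows) + 1]] <- contrast(
            get_draws(arr, sprintf("%s[%s]", p, a),
                      paste0(" for subject ", s)),
            get_draws(arr, sprintf("%s[%s]", p, b),
                      paste0(" for subject ", s)),
            p, a, b, as.integer(s))
        }
      } else {
        arr <- fit$samples
        rows[[length(rows) + 1]] <- contrast(
          get_draws(arr, sprintf("%s[%s]", p, a), ""),
          get_draws(arr, sprintf("%s[%s]", p, b), ""),
          p, a, b)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split a trial table into even- and odd-numbered trials
#'
#' Partitions each subject's trials by the parity of the `trial` index,
#' the standard split for out-of-sample evaluation: fit on even trials,
#' predict the odd ones.
#'
#' @param data A trial table.
#' @return List with elements `even` and `odd`.
#' @export
out_of_sample_split <- function(data) {
  data <- validate_trial_table(data)
  even <- data[data$trial %% 2 == 0, , drop = FALSE]
  odd <- data[data$trial %% 2 == 1, , drop = FALSE]
  for (s in unique(data$subject)) {
    if (sum(even$subject == s) == 0 || sum(odd$subject == s) == 0)
      warning("subject ", s, " has trials on only one side of the split")
  }
  n_items <- attr(data, "n_items")
  attr(even, "n_items") <- n_items
  attr(odd, "n_items") <- n_items
  list(even = even, odd = odd)
}

#' Model recovery: is a simulated gaze bias detected by model comparison?
#'
#' Fits the full GLAM and the no-gaze-bias variant (`gamma` fixed to 1) to
#' each subject of a simulated dataset, compares them by information
#' criterion, and checks the preferred variant against the variant that
#' generated each subject (subjects simulated with `gamma = 1` should be
#' assigned to the no-bias variant, all others to the full model).
#'
#' @param data A trial table carrying a `"generating_parameters"`
#'   attribute (as produced by [simulate_group()]), or `generating_gamma`
#'   given explicitly.
#' @param generating_gamma Optional per-subject generating gamma values.
#' @param ic Information criterion for the comparison.
#' @param draws,tune,chains MCMC settings for both fits.
#' @param error_weight Contaminant rate for both fits.
#' @param seed Optional RNG seed.
#' @return Data frame with one row per subject (`subject`, `gen_gamma`,
#'   `true_variant`, `preferred`, `correct`); overall accuracy in
#'   attribute `"accuracy"`.
#' @export
model_recovery <- function(data, generating_gamma = NULL, ic = "WAIC",
                           draws = 2000, tune = 2000, chains = 2,
                           error_weight = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(generating_gamma)) {
    gen <- attr(data, "generating_parameters")
    if (is.null(gen))
      stop("`data` has no generating_parameters attribute; ",
           "supply `generating_gamma`", call. = FALSE)
    generating_gamma <- gen$gamma[order(gen$subject)]
  }
  full <- fit_glam(glam_model(data, kind = "individual", name = "glam_bias",
                              error_weight = error_weight),
                   draws = draws, tune = tune, chains = chains)
  nobias <- fit_glam(glam_model(data, kind = "individual",
                                fixed = list(gamma = 1),
                                name = "glam_nobias",
                                error_weight = error_weight),
                     draws = draws, tune = tune, chains = chains)
  cmp <- compare_models(list(full, nobias), ic = ic)
  ic_col <- ic
  pref <- vapply(sort(unique(cmp$subject)), function(s) {
    sub <- cmp[cmp$subject == s, ]
    sub$model[which.min(sub[[ic_col]])]
  }, character(1))
  truth <- ifelse(abs(generating_gamma - 1) < 1e-12, "glam_nobias",
                  "glam_bias")
  out <- data.frame(
    subject = sort(unique(cmp$subject)),
    gen_gamma = generating_gamma,
    true_variant = truth,
    preferred = pref,
    correct = pref == truth,
    stringsAsFactors = FALSE
  )
  attr(out, "accuracy") <- mean(out$correct)
  attr(out, "fits") <- list(full = full, nobias = nobias)
  out
}
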