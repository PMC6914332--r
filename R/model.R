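#' Prior configuration for GLAM parameter estimation
#'
#' Individual (and pooled) model variants place uniform priors between broad
#' empirically-motivated limits on the four parameters:
#' `v ~ U(0, 4)`, `gamma ~ U(-2, 1)`, `s ~ U(0, 4)`, `tau ~ U(0, 10)`.
#' Hierarchical variants draw each subject's parameters from truncated
#' normal group distributions whose mean and standard deviation carry
#' weakly informative truncated-normal hyperpriors `N(M, f * SD)` bounded
#' between sensible limits; the vagueness factor `f` (default 10) widens
#' the hyperpriors relative to the spread of published group-level
#' estimates.
#'
#' @param f Hyperprior vagueness factor (default 10).
#' @return A list with elements `bounds` (per-parameter uniform limits,
#'   also the truncation bounds of the subject-level group distributions),
#'   `hyper` (a data frame of hyperprior locations `m`, base scales `sd`,
#'   truncation bounds, one row per group-level parameter), and `f`.
#' @export
glam_priors <- function(f = 10) {
  hyper <- data.frame(
    param = rep(c("v", "gamma", "s", "tau"), each = 2),
    level = rep(c("mu", "sd"), 4),
    m  = c(0.63, 0.26, 0.12, 0.35, 0.27, 0.05, 1.03, 0.62),
    sd = c(0.26, 0.11, 0.11, 0.10, 0.08, 0.01, 0.58, 0.26),
    lo = c(0, 0, -2, 0, 0, 0, 0, 0),
    hi = c(2, 1, 1, 1, 1, 0.2, 5, 3),
    stringsAsFactors = FALSE
  )
  list(
    bounds = list(v = c(0, 4), gamma = c(-2, 1), s = c(0, 4), tau = c(0, 10)),
    hyper = hyper,
    f = f
  )
}

# Truncated-normal log density (location/scale are the pre-truncation
# mean/sd); -Inf outside [lo, hi].
dtnorm_log <- function(x, mean, sd, lo, hi) {
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  out <- stats::dnorm(x, mean, sd, log = TRUE) - base::log(pmax(z, 1e-300))
  out[x < lo | x > hi] <- -Inf
  out
}

rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

# Prepare the per-subject data blocks consumed by the C++ likelihood:
# value/gaze matrices, choice/rt vectors, and the log contaminant density
# log u_s = -log(N * (max rt_s - min rt_s)) per trial.
make_blocks <- function(data, n_items) {
  vcols <- paste0("item_value_", 0:(n_items - 1))
  gcols <- paste0("gaze_", 0:(n_items - 1))
  lapply(sort(unique(data$subject)), function(s) {
    d <- data[data$subject == s, , drop = FALSE]
    rng <- range(d$rt)
    width <- max(diff(rng), 1e-6)
    list(
      subject = s,
      value = as.matrix(d[vcols]),
      gaze = as.matrix(d[gcols]),
      choice = as.integer(d$choice),
      rt = d$rt,
      n = nrow(d),
      log_u = rep(-base::log(n_items * width), nrow(d)),
      rows = which(data$subject == s)
    )
  })
}

#' Specify a GLAM model variant
#'
#' Builds the model object later passed to [fit_glam()]. The `kind`
#' controls the parameter structure: `"individual"` estimates an
#' independent parameter set per subject, `"pooled"` a single set for all
#' subjects, and `"hierarchical"` draws each subject's parameters from
#' truncated-normal group distributions with hyperpriors from
#' [glam_priors()]. Parameters (`v`, `gamma`, `s`, `tau`) can be made
#' condition-dependent through `depends_on` (one parameter per factor
#' level; within- and between-subject factors are detected automatically)
#' or fixed to constants through `fixed` (a scalar, or for individual
#' models a per-subject vector).
#'
#' @param data A trial table (validated on entry).
#' @param kind One of `"individual"`, `"pooled"`, `"hierarchical"`.
#' @param depends_on Named list mapping parameter names to factor column
#'   names, e.g. `list(v = "speed")`.
#' @param fixed Named list mapping parameter names to fixed values, e.g.
#'   `list(gamma = 1)`.
#' @param error_weight Contaminant rate `epsilon` (default 0.05; never
#'   estimated).
#' @param f Hyperprior vagueness factor for hierarchical models.
#' @param priors Prior configuration, defaults to `glam_priors(f)`.
#' @param name Model name used in comparison tables.
#' @return An object of class `"glam_model"`.
#' @export
glam_model <- function(data, kind = c("individual", "pooled", "hierarchical"),
                       depends_on = list(), fixed = list(),
                       error_weight = 0.05, f = 10, priors = glam_priors(f),
                       name = "GLAM") {
  kind <- match.arg(kind)
  data <- validate_trial_table(data)
  n_items <- attr(data, "n_items")
  params <- .glam_params

  bad <- setdiff(names(depends_on), params)
  if (length(bad) > 0)
    stop("depends_on names unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unlist(depends_on), names(data))
  if (length(bad) > 0)
    stop("depends_on references missing column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(names(fixed), params)
  if (length(bad) > 0)
    stop("fixed values for unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  both <- intersect(names(depends_on), names(fixed))
  if (length(both) > 0)
    stop("parameter(s) cannot be both fixed and condition-dependent: ",
         paste(both, collapse = ", "), call. = FALSE)

  subjects <- sort(unique(data$subject))
  for (p in names(fixed)) {
    len <- length(fixed[[p]])
    if (!(len == 1 || (kind == "individual" && len == length(subjects))))
      stop("fixed value for ", p, " must be a scalar",
           if (kind == "individual") " or one value per subject", call. = FALSE)
  }

  # per-parameter condition structure
  layout <- lapply(params, function(p) {
    if (!is.null(depends_on[[p]])) {
      col <- depends_on[[p]]
      levels <- sort(unique(as.character(data[[col]])))
      # between-subject iff every subject exhibits exactly one level
      per_subj <- tapply(as.character(data[[col]]), data$subject,
                         function(x) length(unique(x)))
      list(status = "free", column = col, levels = levels,
           between = all(per_subj == 1),
           trial_level = match(as.character(data[[col]]), levels))
    } else if (!is.null(fixed[[p]])) {
      list(status = "fixed", value = fixed[[p]])
    } else {
      list(status = "free", column = NULL, levels = NULL, between = NA,
           trial_level = rep(1L, nrow(data)))
    }
  })
  names(layout) <- params

  structure(list(
    data = data,
    n_items = n_items,
    kind = kind,
    depends_on = depends_on,
    fixed = fixed,
    error_weight = error_weight,
    priors = priors,
    layout = layout,
    subjects = subjects,
    blocks = make_blocks(data, n_items),
    name = name
  ), class = "glam_model")
}

#' @export
print.glam_model <- function(x, ...) {
  cat("GLAM model '", x$name, "' (kind: ", x$kind, ")\n", sep = "")
  cat("  ", length(x$subjects), " subject(s), ", nrow(x$data), " trials, ",
      x$n_items, " items\n", sep = "")
  free <- names(Filter(function(l) l$status == "free", x$layout))
  fixed <- names(Filter(function(l) l$status == "fixed", x$layout))
  cat("  free parameters: ", paste(free, collapse = ", "), "\n", sep = "")
  if (length(fixed) > 0)
    cat("  fixed: ", paste(sprintf("%s = %s", fixed,
        vapply(x$fixed[fixed], function(v) paste(signif(v, 3), collapse = "/"),
               character(1))), collapse = ", "), "\n", sep = "")
  if (length(x$depends_on) > 0)
    cat("  depends on: ", paste(sprintf("%s ~ %s", names(x$depends_on),
        unlist(x$depends_on)), collapse = ", "), "\n", sep = "")
  cat("  error weight: ", x$error_weight, "\n", sep = "")
  invisible(x)
}

# Free-parameter table for one subject of an individual model (or the whole
# data of a pooled model): one row per sampled scalar, with the parameter it
# belongs to, its condition level (NA when unconditioned) and prior bounds.
free_param_table <- function(model, subject = NULL) {
  rows <- list()
  for (p in .glam_params) {
    l <- model$layout[[p]]
    if (l$status != "free") next
    if (is.null(l$levels)) {
      b <- model$priors$bounds[[p]]
      rows[[length(rows) + 1]] <- data.frame(
        name = p, param = p, level = NA_character_,
        lo = b[1], hi = b[2], stringsAsFactors = FALSE)
    } else {
      levs <- l$levels
      if (!is.null(subject)) {
        present <- unique(l$trial_level[model$data$subject == subject])
        levs <- l$levels[sort(present)]
      }
      for (lev in levs) {
        b <- model$priors$bounds[[p]]
        rows[[length(rows) + 1]] <- data.frame(
          name = paste0(p, "[", lev, "]"), param = p, level = lev,
          lo = b[1], hi = b[2], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Fixed value of parameter p for a given subject (handles per-subject lists).
fixed_value <- function(model, p, subject) {
  val <- model$fixed[[p]]
  if (length(val) == 1) return(val)
  val[match(subject, model$subjects)]
}

# Per-trial parameter vectors for a block of trials, given a named theta
# vector over the free-parameter table and the model layout.
trial_param_vectors <- function(model, theta, rows, subject) {
  out <- list()
  for (p in .glam_params) {
    l <- model$layout[[p]]
    if (l$status == "fixed") {
      out[[p]] <- fixed_value(model, p, subject)
    } else if (is.null(l$levels)) {
      out[[p]] <- theta[[p]]
    } else {
      vals <- theta[paste0(p, "[", l$levels, "]")]
      out[[p]] <- as.numeric(vals[l$trial_level[rows]])
    }
  }
  out
}
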