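#' Sample-based MAP estimate
#'
#' Mode of the marginal posterior, located as the peak of a Gaussian
#' kernel density estimate over a 512-point grid spanning the sample range.
#' Degenerate samples (all equal) return that value directly.
#'
#' @param x Numeric vector of posterior samples.
#' @return The estimated posterior mode.
#' @export
map_estimate <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  if (stats::sd(x) == 0) return(x[1])
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval containing a fraction `prob` of the
#' samples (assumes a unimodal marginal).
#'
#' @param x Numeric vector of posterior samples.
#' @param prob Probability mass of the interval (default 0.95).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  m <- max(1, floor(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

flatten_draws <- function(arr, p) {
  as.vector(arr[, , p])
}

#' Extract parameter estimates from a fitted GLAM
#'
#' Summarizes the posterior of each free parameter as a MAP estimate (mode
#' of a kernel density estimate of the marginal) with a 95% highest
#' posterior density interval. For individual fits the table has one row
#' per subject (x condition where a parameter is condition-dependent);
#' hierarchical fits additionally expose the group-level means and
#' standard deviations via `level = "group"`.
#'
#' @param fit A `"glam_fit"` object.
#' @param level `"subject"` (default) or `"group"` (hierarchical fits).
#' @param prob HPD mass (default 0.95).
#' @return Data frame with columns `subject`, `condition`, `parameter`,
#'   `map`, `hpd_lo`, `hpd_hi`.
#' @export
extract_estimates <- function(fit, level = c("subject", "group"),
                              prob = 0.95) {
  level <- match.arg(level)
  min_draws <- 100
  summarize <- function(x, subject, condition, parameter) {
    if (length(x) < min_draws)
      stop("fewer than ", min_draws,
           " posterior samples; MAP estimation is unreliable", call. = FALSE)
    h <- hpd_interval(x, prob)
    data.frame(subject = subject, condition = condition,
               parameter = parameter, map = map_estimate(x),
               hpd_lo = h[1], hpd_hi = h[2], stringsAsFactors = FALSE)
  }
  split_name <- function(nm) {
    # "v", "v[fast]", "v[3]", "v[3,fast]", "v_mu[g1]" -> param/index/level
    m <- regmatches(nm, regexec("^([a-z_]+)(\\[([^\\]]*)\\])?$", nm))[[1]]
    list(param = m[2], inner = m[4])
  }
  rows <- list()
  if (fit$kind == "individual") {
    for (s in names(fit$samples)) {
      arr <- fit$samples[[s]]
      for (p in dimnames(arr)[[3]]) {
        sp <- split_name(p)
        rows[[length(rows) + 1]] <- summarize(
          flatten_draws(arr, p), as.integer(s),
          if (is.na(sp$inner) || sp$inner == "") NA_character_ else sp$inner,
          sp$param)
      }
    }
  } else if (fit$kind == "pooled") {
    arr <- fit$samples
    for (p in dimnames(arr)[[3]]) {
      sp <- split_name(p)
      rows[[length(rows) + 1]] <- summarize(
        flatten_draws(arr, p), NA_integer_,
        if (is.na(sp$inner) || sp$inner == "") NA_character_ else sp$inner,
        sp$param)
    }
  } else {
    arr <- fit$samples
    pars <- dimnames(arr)[[3]]
    is_group <- grepl("_(mu|sd)(\\[|$)", pars)
    keep <- if (level == "group") pars[is_group] else pars[!is_group]
    for (p in keep) {
      sp <- split_name(p)
      inner <- if (is.na(sp$inner)) "" else sp$inner
      parts <- strsplit(inner, ",")[[1]]
      if (level == "group") {
        rows[[length(rows) + 1]] <- summarize(
          flatten_draws(arr, p), NA_integer_,
          if (length(parts) >= 1 && nzchar(parts[1])) parts[1] else NA_character_,
          sp$param)
      } else {
        subject <- as.integer(parts[1])
        cond <- if (length(parts) > 1) parts[2] else NA_character_
        rows[[length(rows) + 1]] <- summarize(
          flatten_draws(arr, p), subject, cond, sp$param)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wide per-subject MAP table
#'
#' Convenience reshaping of [extract_estimates()] into one row per subject
#' (x condition) with one column per parameter, as used by
#' [predict.glam_fit()].
#'
#' @param fit A `"glam_fit"` object.
#' @return Data frame with columns `subject`, `condition`, and MAP columns
#'   `v`, `gamma`, `s`, `tau` (fixed parameters filled in from the model).
#' @export
map_table <- function(fit) {
  est <- extract_estimates(fit, level = "subject")
  est$condition[is.na(est$condition)] <- ""
  subjects <- if (fit$kind == "individual") {
    as.integer(names(fit$samples))
  } else {
    fit$model$subjects
  }
  conditions <- sort(unique(est$condition[nzchar(est$condition)]))
  if (length(conditions) == 0) conditions <- ""
  grid <- expand.grid(subject = subjects, condition = conditions,
                      stringsAsFactors = FALSE)
  for (p in .glam_params) grid[[p]] <- NA_real_
  for (i in seq_len(nrow(grid))) {
    s <- grid$subject[i]; cond <- grid$condition[i]
    for (p in .glam_params) {
      l <- fit$model$layout[[p]]
      if (l$status == "fixed") {
        grid[[p]][i] <- fixed_value(fit$model, p, s)
        next
      }
      sel <- est$parameter == p &
        (est$condition == cond | est$condition == "") &
        (if (fit$kind == "pooled") TRUE else est$subject == s)
      if (any(sel)) grid[[p]][i] <- est$map[which(sel)[1]]
    }
  }
  # drop duplicate rows for parameters without conditions
  unique(grid)
}
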