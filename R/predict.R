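#' Predict choices and response times from a fitted GLAM
#'
#' Posterior prediction: every observed trial is replayed `n_repeats`
#' times through the exact race sampler using the subject's (and, where
#' condition-dependent, the trial's condition's) MAP parameter estimates
#' and the trial's observed item values and gaze fractions. Repeating
#' each trial several times stabilizes the predicted behavioural pattern.
#' Contaminant responses are generated at the model's error rate, uniform
#' over items and over the subject's observed RT range.
#'
#' @param object A `"glam_fit"`.
#' @param newdata Trial table to predict for; defaults to the data the
#'   model was fitted to. Every subject present must also be present in
#'   the fit.
#' @param n_repeats Number of repetitions of each trial (default 1 gives a
#'   predicted dataset the same size as the observed one).
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A trial table of predicted trials; observed provenance columns
#'   are preserved and a `repetition` column (0-based) is added.
#' @export
predict.glam_fit <- function(object, newdata = NULL, n_repeats = 1,
                             seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  data <- if (is.null(newdata)) object$model$data else
    validate_trial_table(newdata, object$model$n_items)
  n_items <- object$model$n_items
  maps <- map_table(object)
  missing_subj <- setdiff(unique(data$subject), maps$subject)
  if (length(missing_subj) > 0)
    stop("no parameter estimates for subject(s): ",
         paste(missing_subj, collapse = ", "), call. = FALSE)

  vcols <- paste0("item_value_", 0:(n_items - 1))
  gcols <- paste0("gaze_", 0:(n_items - 1))
  eps <- object$model$error_weight
  cond_cols <- unique(unlist(object$model$depends_on))

  rt_ranges <- tapply(data$rt, data$subject, range)
  pick_pars <- function(row) {
    cand <- maps[maps$subject == row$subject, , drop = FALSE]
    if (nrow(cand) > 1 && length(cond_cols) > 0) {
      lev <- as.character(row[[cond_cols[1]]])
      hit <- cand[cand$condition %in% c(lev, ""), , drop = FALSE]
      if (nrow(hit) > 0) cand <- hit
    }
    as.list(cand[1, .glam_params])
  }

  reps <- data[rep(seq_len(nrow(data)), each = n_repeats), , drop = FALSE]
  reps$repetition <- rep(0:(n_repeats - 1), nrow(data))
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    pars <- pick_pars(row)
    sim <- simulate_trial(as.numeric(row[vcols]), as.numeric(row[gcols]),
                          pars, error_weight = eps,
                          rt_range = rt_ranges[[as.character(row$subject)]],
                          n = n_repeats)
    idx <- (i - 1) * n_repeats + seq_len(n_repeats)
    reps$choice[idx] <- sim$choice
    reps$rt[idx] <- sim$rt
  }
  rownames(reps) <- NULL
  reps
}
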