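#' Detect the number of items in a trial table
#'
#' @param data A trial-table data frame.
#' @return Number of items `N` inferred from the `item_value_*` / `gaze_*`
#'   column pairs.
#' @keywords internal
infer_n_items <- function(data) {
  vals <- grep("^item_value_[0-9]+$", names(data), value = TRUE)
  gzs <- grep("^gaze_[0-9]+$", names(data), value = TRUE)
  iv <- sort(as.integer(sub("^item_value_", "", vals)))
  ig <- sort(as.integer(sub("^gaze_", "", gzs)))
  n <- length(iv)
  if (n < 2 || !identical(iv, 0:(n - 1)) || !identical(ig, 0:(n - 1)))
    stop("could not infer n_items: need matching item_value_0..N-1 and gaze_0..N-1 columns (N >= 2)",
         call. = FALSE)
  n
}

#' Validate a trial table
#'
#' Checks a trial-level data frame against the expected schema: one row per
#' trial with columns `subject`, `trial`, `choice`, `rt`, `item_value_0..N-1`
#' and `gaze_0..N-1`, plus optional factor columns. Enforces the data
#' invariants: gaze fractions in `[0, 1]` summing to at most 1 per trial
#' (off-item gaze is allowed), positive response times, choices coded
#' `0..N-1`, and contiguous 0-based subject ids.
#'
#' @param data Data frame to validate.
#' @param n_items Number of items, or `NULL` to infer it from the columns.
#' @return The validated data frame, with attribute `n_items` set.
#' @export
validate_trial_table <- function(data, n_items = NULL) {
  data <- as.data.frame(data)
  required <- c("subject", "trial", "choice", "rt")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(n_items)) n_items <- infer_n_items(data)
  vcols <- paste0("item_value_", 0:(n_items - 1))
  gcols <- paste0("gaze_", 0:(n_items - 1))
  missing_cols <- setdiff(c(vcols, gcols), names(data))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  gaze <- as.matrix(data[gcols])
  bad <- which(apply(gaze < -1e-12 | gaze > 1 + 1e-12, 1, any))
  if (length(bad) > 0)
    stop("gaze fractions outside [0, 1] in row(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  oversum <- which(rowSums(gaze) > 1 + 1e-6)
  if (length(oversum) > 0)
    stop("per-trial gaze fractions sum to more than 1 in row(s): ",
         paste(head(oversum, 10), collapse = ", "), call. = FALSE)
  bad_rt <- which(!is.finite(data$rt) | data$rt <= 0)
  if (length(bad_rt) > 0)
    stop("non-positive rt in row(s): ",
         paste(head(bad_rt, 10), collapse = ", "), call. = FALSE)
  bad_choice <- which(!(data$choice %in% 0:(n_items - 1)))
  if (length(bad_choice) > 0)
    stop("choice outside 0..", n_items - 1, " in row(s): ",
         paste(head(bad_choice, 10), collapse = ", "), call. = FALSE)
  subjects <- sort(unique(data$subject))
  if (!identical(as.integer(subjects), seq_along(subjects) - 1L))
    stop("subject ids must form a contiguous 0-based range (first subject 0); found: ",
         paste(head(subjects, 10), collapse = ", "), call. = FALSE)
  attr(data, "n_items") <- as.integer(n_items)
  data
}

#' Load a trial table from a delimited text file
#'
#' Reads a CSV in the standard one-row-per-trial dialect (columns `subject`,
#' `trial`, `choice`, `rt`, `item_value_0..N-1`, `gaze_0..N-1`, optional
#' factor columns) and validates it. Lines starting with `#` (metadata
#' headers written by this package) are skipped.
#'
#' @param path Path to the CSV file.
#' @param n_items Number of items, or `NULL` to infer it.
#' @return A validated trial table with attribute `n_items`.
#' @export
load_trial_table <- function(path, n_items = NULL) {
  data <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_trial_table(data, n_items = n_items)
}

#' Write a trial table (or any result table) with a metadata header
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param meta Named character vector written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_glam_csv <- function(x, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# glamr %s", as.character(utils::packageVersion("glamr"))), con)
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

# Long item-trial expansion: one row per (trial, item) with the item's value,
# gaze, relative value/gaze (difference to the best competitor) and a chosen
# indicator. `row` indexes the originating trial row.
item_trial_long <- function(data, n_items) {
  vcols <- paste0("item_value_", 0:(n_items - 1))
  gcols <- paste0("gaze_", 0:(n_items - 1))
  value <- as.matrix(data[vcols])
  gaze <- as.matrix(data[gcols])
  max_other <- function(m) {
    vapply(seq_len(ncol(m)), function(j)
      do.call(pmax, as.data.frame(m[, -j, drop = FALSE])), numeric(nrow(m)))
  }
  rel_value <- value - max_other(value)
  rel_gaze <- gaze - max_other(gaze)
  n <- nrow(data)
  data.frame(
    row = rep(seq_len(n), n_items),
    subject = rep(data$subject, n_items),
    trial = rep(data$trial, n_items),
    item = rep(0:(n_items - 1), each = n),
    value = as.vector(value),
    gaze = as.vector(gaze),
    rel_value = as.vector(rel_value),
    rel_gaze = as.vector(rel_gaze),
    chosen = as.integer(rep(data$choice, n_items) == rep(0:(n_items - 1), each = n))
  )
}

# Behavioural gaze-influence score for one subject's item-trial rows: fit a
# logistic model of item choice on relative item value, then average the
# residual choice probability (observed - value-predicted) over item-trials
# in which the item received more gaze than any competitor.
gaze_influence_score <- function(long) {
  fit <- suppressWarnings(
    stats::glm(chosen ~ rel_value, family = stats::binomial(), data = long))
  pred <- stats::predict(fit, type = "response")
  resid <- long$chosen - pred
  keep <- long$rel_gaze > 0
  if (!any(keep)) return(NA_real_)
  mean(resid[keep])
}

#' Subject-level behavioural summary
#'
#' Summarizes each subject's response behaviour on the three standard
#' metrics: mean response time, probability of choosing the highest-valued
#' item (ties between top values all count as best), and the behavioural
#' gaze-influence measure — the mean increase in choice probability for
#' items fixated longer than their competitors, after correcting for item
#' value via a per-subject logistic choice model.
#'
#' @param data A validated trial table (see [validate_trial_table()]).
#' @param n_items Number of items per trial.
#' @return Data frame with one row per subject: `subject`, `n_trials`,
#'   `mean_rt`, `p_choose_best`, `gaze_influence`.
#' @export
aggregate_subject_level_data <- function(data, n_items) {
  data <- validate_trial_table(data, n_items)
  vcols <- paste0("item_value_", 0:(n_items - 1))
  value <- as.matrix(data[vcols])
  best <- value[cbind(seq_len(nrow(data)), data$choice + 1)] >=
    apply(value, 1, max) - 1e-12
  long_all <- item_trial_long(data, n_items)
  out <- lapply(sort(unique(data$subject)), function(s) {
    idx <- data$subject == s
    if (!any(idx)) {
      warning("subject ", s, " has no trials and is excluded")
      return(NULL)
    }
    data.frame(
      subject = s,
      n_trials = sum(idx),
      mean_rt = mean(data$rt[idx]),
      p_choose_best = mean(best[idx]),
      gaze_influence = gaze_influence_score(long_all[long_all$subject == s, ])
    )
  })
  do.call(rbind, out)
}

bin_table <- function(x, y, n_bins) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  n <- tabulate(bin, n_bins)
  means <- rep(NA_real_, n_bins)
  ses <- rep(NA_real_, n_bins)
  for (b in which(n > 0)) {
    yb <- y[bin == b & !is.na(bin)]
    means[b] <- mean(yb)
    if (length(yb) > 1) ses[b] <- stats::sd(yb) / sqrt(length(yb))
  }
  data.frame(bin = seq_len(n_bins), mid = mids, n = n, mean = means, se = ses)
}

#' Binned behavioural curves
#'
#' Computes the four standard binned summaries of a choice dataset:
#' \describe{
#'   \item{rt_by_difficulty}{mean RT against trial difficulty (highest item
#'     value minus the maximum of the other values).}
#'   \item{p_choose_by_value}{probability that an item is chosen against its
#'     relative value, over item-trials.}
#'   \item{p_choose_by_gaze}{probability that an item is chosen against its
#'     relative gaze.}
#'   \item{corrected_p_choose_by_gaze}{choice probability corrected for item
#'     value (observed minus the per-subject value-model prediction) against
#'     relative gaze.}
#' }
#' Bins are equal-width over the observed range; empty bins are reported
#' with `n = 0` and an undefined mean.
#'
#' @param data A validated trial table.
#' @param n_items Number of items; inferred when `NULL`.
#' @param n_bins Number of bins (default 8).
#' @return Named list of four binned data frames.
#' @export
behavioural_curves <- function(data, n_items = NULL, n_bins = 8) {
  data <- validate_trial_table(data, n_items)
  n_items <- attr(data, "n_items")
  value <- as.matrix(data[paste0("item_value_", 0:(n_items - 1))])
  sorted <- t(apply(value, 1, sort, decreasing = TRUE))
  difficulty <- sorted[, 1] - sorted[, 2]
  long <- item_trial_long(data, n_items)
  corrected <- unlist(lapply(sort(unique(data$subject)), function(s) {
    sub <- long[long$subject == s, ]
    fit <- suppressWarnings(
      stats::glm(chosen ~ rel_value, family = stats::binomial(), data = sub))
    sub$chosen - stats::predict(fit, type = "response")
  }))
  long_order <- order(long$subject)
  corr_by_row <- numeric(nrow(long))
  corr_by_row[long_order] <- corrected
  list(
    rt_by_difficulty = bin_table(difficulty, data$rt, n_bins),
    p_choose_by_value = bin_table(long$rel_value, long$chosen, n_bins),
    p_choose_by_gaze = bin_table(long$rel_gaze, long$chosen, n_bins),
    corrected_p_choose_by_gaze = bin_table(long$rel_gaze, corr_by_row, n_bins)
  )
}
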