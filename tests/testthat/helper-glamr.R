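# Shared fixtures, all generated in code.

# The canonical two-row example table (three items, one factor column).
example_table <- function() {
  data.frame(
    subject = c(0L, 0L), trial = c(0L, 1L), choice = c(0L, 2L),
    rt = c(2.056, 3.685),
    item_value_0 = c(5, 3), item_value_1 = c(1, 6), item_value_2 = c(3, 9),
    gaze_0 = c(0.16, 0.44), gaze_1 = c(0.62, 0.22), gaze_2 = c(0.22, 0.34),
    speed = c("fast", "slow"),
    stringsAsFactors = FALSE
  )
}

example_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "example_trials.csv")
  utils::write.csv(example_table(), path, row.names = FALSE, quote = FALSE)
  path
}

# Moderate, well-identified generating parameters used across fitting tests.
moderate_pars <- function() list(v = 0.7, gamma = 0.3, s = 0.25, tau = 1.0)

# Small simulated dataset cached per session to keep the suite fast.
local({
  env <- new.env()
  assign("cache", list(), envir = env)
  cached_sim <<- function(key, expr) {
    cache <- get("cache", envir = env)
    if (is.null(cache[[key]])) {
      cache[[key]] <- force(expr)
      assign("cache", cache, envir = env)
    }
    cache[[key]]
  }
})
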