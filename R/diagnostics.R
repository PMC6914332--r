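# Split R-hat (potential scale reduction): each chain is split in half and
# the classic between/within variance ratio is computed over the 2*chains
# half-chains.
split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(mat)), function(ch)
    cbind(mat[seq_len(half), ch], mat[(n - half + 1):n, ch])))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective sample size from the chain-averaged autocorrelation function,
# truncated by Geyer's initial positive sequence rule.
ess_basic <- function(mat) {
  n <- nrow(mat)
  chains <- ncol(mat)
  if (n < 4) return(NA_real_)
  acf_mean <- rowMeans(sapply(seq_len(chains), function(ch) {
    x <- mat[, ch] - mean(mat[, ch])
    v <- sum(x^2) / n
    if (v == 0) return(rep(0, n))
    stats::acf(mat[, ch], lag.max = n - 1, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }))
  rho_sum <- 0
  lag <- 1
  while (lag + 1 < n) {
    pair <- acf_mean[lag + 1] + if (lag + 2 <= n) acf_mean[lag + 2] else 0
    if (!is.finite(pair) || pair < 0) break
    rho_sum <- rho_sum + pair
    lag <- lag + 2
  }
  max(1, (n * chains) / (1 + 2 * rho_sum))
}

#' Convergence diagnostics of a GLAM fit
#'
#' Split R-hat (Gelman-Rubin potential scale reduction over split chains)
#' and autocorrelation-based effective sample size per free parameter.
#' Values of R-hat below about 1.05 indicate convergence of the chains.
#'
#' @param fit A `"glam_fit"` object.
#' @return Data frame with columns `subject` (NA for pooled/hierarchical
#'   fits), `parameter`, `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(fit) {
  to_mat <- function(arr, p) {
    m <- arr[, , p, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    m
  }
  diag_one <- function(arr, subject = NA) {
    pars <- dimnames(arr)[[3]]
    data.frame(
      subject = subject,
      parameter = pars,
      rhat = vapply(pars, function(p) split_rhat(to_mat(arr, p)), numeric(1)),
      ess = vapply(pars, function(p) ess_basic(to_mat(arr, p)), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  if (is.list(fit$samples)) {
    do.call(rbind, lapply(names(fit$samples), function(s)
      diag_one(fit$samples[[s]], as.integer(s))))
  } else {
    diag_one(fit$samples)
  }
}
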