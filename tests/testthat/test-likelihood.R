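test_that("gaze weighting mixes biased and unbiased value signals", {
  # hand evaluation on the canonical first trial, gamma = 0
  expect_equal(gaze_weighted_signal(c(5, 1, 3), c(0.16, 0.62, 0.22), 0),
               c(0.80, 0.62, 0.66))
  # gamma = 1 removes the gaze dependence entirely
  expect_equal(gaze_weighted_signal(c(5, 1, 3), c(0.9, 0.05, 0.05), 1),
               c(5, 1, 3))
  # full gaze on an item makes its signal gaze-independent
  expect_equal(gaze_weighted_signal(c(7, 2), c(1, 0), gamma = -1)[1], 7)
  expect_error(gaze_weighted_signal(c(1, 2), c(0.5), 0), "length")
})

test_that("relative signals pass through the logistic with sensitivity tau", {
  a <- c(0.80, 0.62, 0.66)
  # hand arithmetic: R* = (0.14, -0.18, -0.14)
  expect_equal(round(relative_signals(a, 1), 5), c(0.53494, 0.45512, 0.46506),
               tolerance = 1e-5)
  # tau = 0: no sensitivity to signal differences
  expect_equal(relative_signals(a, 0), rep(0.5, 3))
  # exact tie of the top two gives R = 0.5
  expect_equal(relative_signals(c(2, 2, 1), 3)[1:2], c(0.5, 0.5))
})

test_that("first-passage density is a proper inverse-Gaussian", {
  f <- function(t) ig_fpt_pdf(t, drift = 0.5, sigma = 0.3, b = 1)
  expect_equal(integrate(f, 0, Inf)$value, 1, tolerance = 1e-6)
  # mean identity: E[T] = b / drift
  expect_equal(integrate(function(t) t * f(t), 0, Inf)$value, 2,
               tolerance = 1e-6)
  # closed-form mode of the inverse-Gaussian as an independent oracle
  mu <- 1 / 0.5; lambda <- 1 / 0.3^2
  mode_oracle <- mu * (sqrt(1 + 9 * mu^2 / (4 * lambda^2)) -
                         3 * mu / (2 * lambda))
  mode_num <- optimize(f, c(0.01, 5), maximum = TRUE)$maximum
  expect_equal(mode_num, mode_oracle, tolerance = 1e-4)
  expect_equal(ig_fpt_pdf(-1, 0.5, 0.3), 0)
})

test_that("first-passage CDF matches quadrature of the density", {
  for (t in c(0.5, 1, 3)) {
    quad <- integrate(function(s) ig_fpt_pdf(s, 0.7, 0.25), 0, t,
                      rel.tol = 1e-10)$value
    expect_equal(ig_fpt_cdf(t, 0.7, 0.25), quad, tolerance = 1e-6)
  }
  grid <- seq(0.01, 20, length.out = 1000)
  F <- ig_fpt_cdf(grid, 0.4, 0.5)
  expect_true(all(diff(F) >= 0))
  expect_equal(ig_fpt_cdf(1e6, 0.4, 0.5), 1, tolerance = 1e-6)
  expect_equal(ig_fpt_cdf(0, 0.4, 0.5), 0)
})

test_that("race densities integrate to one and respect symmetry", {
  total <- sapply(0:2, function(i)
    integrate(function(t) race_density(t, i, c(0.5, 0.5, 0.5), 0.3), 0, Inf,
              rel.tol = 1e-8)$value)
  expect_equal(sum(total), 1, tolerance = 1e-4)
  expect_equal(total, rep(1 / 3, 3), tolerance = 1e-4)
})

test_that("race win probability matches an independent sampling oracle", {
  drifts <- c(0.6, 0.3, 0.3)
  p0 <- integrate(function(t) race_density(t, 0, drifts, 0.3), 0, Inf,
                  rel.tol = 1e-8)$value
  set.seed(99)
  n <- 1e5
  fpt <- sapply(drifts, function(d) rinvgauss(n, 1 / d, 1 / 0.3^2))
  wins <- mean(max.col(-fpt) == 1)
  expect_lt(abs(wins - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("trial likelihood mixes race and contaminant components", {
  vals <- c(5, 1, 3); gaz <- c(0.16, 0.62, 0.22)
  pars <- moderate_pars()
  rng <- c(0.5, 4.5)
  # epsilon = 1 collapses to the uniform contaminant density
  expect_equal(trial_likelihood(vals, gaz, 0, 2.0, pars, error_weight = 1,
                                rt_range = rng),
               1 / (3 * diff(rng)))
  # at a time where the race density vanishes, only the contaminant remains
  tiny <- c(1e-10, 4.5)
  expect_equal(trial_likelihood(vals, gaz, 0, 1e-9, pars, error_weight = 0.05,
                                rt_range = tiny),
               0.05 / (3 * diff(tiny)), tolerance = 1e-12)
  # the contaminant density vanishes outside the observed RT interval
  race_only <- trial_likelihood(vals, gaz, 0, 0.2, pars, error_weight = 0,
                                rt_range = rng)
  expect_equal(trial_likelihood(vals, gaz, 0, 0.2, pars, error_weight = 0.05,
                                rt_range = rng),
               0.95 * race_only, tolerance = 1e-12)
  # log and linear scales agree where both are representable
  ll <- trial_likelihood(vals, gaz, 1, 2.3, pars, error_weight = 0.05,
                         rt_range = rng, log = TRUE)
  l <- trial_likelihood(vals, gaz, 1, 2.3, pars, error_weight = 0.05,
                        rt_range = rng)
  expect_equal(ll, log(l), tolerance = 1e-10)
})

test_that("gamma = 1 makes the likelihood exactly gaze-permutation invariant", {
  vals <- c(9, 3, 6)
  pars <- list(v = 0.8, gamma = 1, s = 0.3, tau = 1.2)
  rng <- c(0.5, 5)
  base <- trial_likelihood(vals, c(0.7, 0.2, 0.1), 2, 1.7, pars,
                           rt_range = rng)
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))) {
    expect_identical(trial_likelihood(vals, c(0.7, 0.2, 0.1)[perm], 2, 1.7,
                                      pars, rt_range = rng), base)
  }
})

test_that("the fast pointwise likelihood equals the reference composition", {
  set.seed(21)
  d <- simulate_group("individual", 1, 30, 3, parameters = moderate_pars(),
                      seed = 77)
  m <- glam_model(d, "individual")
  b <- m$blocks[[1]]
  rng <- range(d$rt)
  for (rep in 1:20) {
    pars <- list(v = runif(1, 0.1, 3), gamma = runif(1, -2, 1),
                 s = runif(1, 0.1, 2), tau = runif(1, 0, 8))
    fast <- glamr:::glam_loglik_pointwise(b, pars$v, pars$gamma, pars$s,
                                          pars$tau, 0.05)
    slow <- sapply(seq_len(nrow(d)), function(i)
      trial_likelihood(as.numeric(d[i, paste0("item_value_", 0:2)]),
                       as.numeric(d[i, paste0("gaze_", 0:2)]),
                       d$choice[i], d$rt[i], pars, error_weight = 0.05,
                       rt_range = rng, log = TRUE))
    expect_equal(fast, slow, tolerance = 1e-8)
  }
})

test_that("the full likelihood integrates to one over choices and time", {
  set.seed(31)
  vals <- c(5, 1, 3); gaz <- c(0.16, 0.62, 0.22)
  rng <- c(0.4, 6)
  for (rep in 1:5) {
    pars <- list(v = runif(1, 0.2, 2), gamma = runif(1, -2, 1),
                 s = runif(1, 0.15, 1), tau = runif(1, 0, 5))
    # integrate piecewise around the contaminant support edges
    segments <- list(c(0, rng[1]), rng, c(rng[2], Inf))
    total <- sum(sapply(0:2, function(i) {
      sum(sapply(segments, function(sg)
        integrate(function(t)
          sapply(t, function(tt)
            trial_likelihood(vals, gaz, i, tt, pars, error_weight = 0.05,
                             rt_range = rng)),
          sg[1], sg[2], rel.tol = 1e-7)$value))
    }))
    expect_equal(total, 1, tolerance = 1e-3)
  }
})

test_that("decreasing gamma raises the win probability of the most-gazed item", {
  vals <- c(5, 5, 5)
  gaz <- c(0.6, 0.25, 0.15)
  win0 <- function(gamma) {
    drifts <- glam_drifts(vals, gaz, list(v = 0.8, gamma = gamma, s = 0.3,
                                          tau = 1))
    integrate(function(t) race_density(t, 0, drifts, 0.3), 0, Inf,
              rel.tol = 1e-8)$value
  }
  wins <- sapply(seq(1, -1, by = -0.25), win0)
  expect_true(all(diff(wins) > 0))
})

test_that("doubling v halves the first-passage mean and shortens RTs", {
  gaz <- c(0.5, 0.3, 0.2)
  mean_rt <- function(v) {
    drifts <- glam_drifts(c(5, 3, 2), gaz, list(v = v, gamma = 0.3, s = 0.3,
                                                tau = 1))
    sum(sapply(0:2, function(i)
      integrate(function(t) t * race_density(t, i, drifts, 0.3), 0, Inf,
                rel.tol = 1e-8)$value))
  }
  expect_equal(glam_drifts(c(5, 3, 2), gaz,
                           list(v = 1.4, gamma = 0.3, s = 0.3, tau = 1)),
               2 * glam_drifts(c(5, 3, 2), gaz,
                               list(v = 0.7, gamma = 0.3, s = 0.3, tau = 1)))
  expect_lt(mean_rt(1.4), mean_rt(0.7))
})
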