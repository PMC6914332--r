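test_that("equal evidence yields symmetric choices", {
  set.seed(51)
  sim <- simulate_trial(c(5, 5, 5), rep(1 / 3, 3),
                        list(v = 0.8, gamma = 0.5, s = 0.3, tau = 1),
                        n = 20000)
  freq <- tabulate(sim$choice + 1, 3) / nrow(sim)
  se <- sqrt((1 / 3) * (2 / 3) / nrow(sim))
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
  expect_true(all(sim$rt > 0))
})

test_that("gamma = 1 choices are statistically invariant to gaze permutation", {
  set.seed(52)
  pars <- list(v = 0.8, gamma = 1, s = 0.3, tau = 1)
  vals <- c(9, 3, 6)
  n <- 20000
  a <- simulate_trial(vals, c(0.7, 0.2, 0.1), pars, n = n)
  b <- simulate_trial(vals, c(0.1, 0.2, 0.7), pars, n = n)
  fa <- tabulate(a$choice + 1, 3) / n
  fb <- tabulate(b$choice + 1, 3) / n
  se <- sqrt(fa * (1 - fa) / n + fb * (1 - fb) / n)
  expect_true(all(abs(fa - fb) < 3 * pmax(se, 1e-4)))
})

test_that("analytic sampler matches the race density", {
  pars <- moderate_pars()
  vals <- c(5, 1, 3); gaz <- c(0.16, 0.62, 0.22)
  drifts <- glam_drifts(vals, gaz, pars)
  set.seed(53)
  n <- 20000
  sim <- simulate_trial(vals, gaz, pars, n = n)
  p_win <- sapply(0:2, function(i)
    integrate(function(t) race_density(t, i, drifts, pars$s), 0, Inf,
              rel.tol = 1e-8)$value)
  freq <- tabulate(sim$choice + 1, 3) / n
  expect_true(all(abs(freq - p_win) < 3 * sqrt(p_win * (1 - p_win) / n)))
  # conditional RT distribution of the winning item vs analytic CDF
  rts <- sim$rt[sim$choice == 0]
  grid <- seq(0.01, quantile(rts, 0.999), length.out = 400)
  dens <- race_density(grid, 0, drifts, pars$s)
  cdf <- cumsum(dens) * diff(grid)[1] / p_win[1]
  emp <- ecdf(rts)(grid)
  expect_lt(max(abs(emp - cdf)), 0.02)
})

test_that("simulated cohorts have the requested design", {
  d <- cached_sim("ex1_shape", simulate_group(
    "individual", n_individuals = 30, n_trials = 300, n_items = 3,
    seed = 54))
  expect_equal(nrow(d), 9000)
  expect_equal(sort(unique(d$subject)), 0:29)
  expect_equal(attr(d, "n_items"), 3L)
  gen <- attr(d, "generating_parameters")
  expect_equal(nrow(gen), 30)
  expect_true(all(gen$v > 0 & gen$s > 0 & gen$tau >= 0 & gen$gamma <= 1))
  # fixing gamma = 1 for chosen subjects is recorded in the parameters
  gamma <- gen$gamma
  gamma[1:10] <- 1
  d2 <- simulate_group("individual", 30, 10, 3,
                       parameters = list(v = gen$v, gamma = gamma,
                                         s = gen$s, tau = gen$tau),
                       seed = 55)
  expect_equal(attr(d2, "generating_parameters")$gamma[1:10], rep(1, 10))
})

test_that("simulation is reproducible under a seed", {
  a <- simulate_group("individual", 3, 20, 3, seed = 56)
  b <- simulate_group("individual", 3, 20, 3, seed = 56)
  expect_identical(a, b)
})

test_that("hierarchical cohorts draw subjects from the group distribution", {
  d <- simulate_group("hierarchical", n_individuals = 40, n_trials = 5,
                      n_items = 3,
                      parameters = list(gamma = c(0.7, 0.05)), seed = 57)
  gen <- attr(d, "generating_parameters")
  expect_equal(mean(gen$gamma), 0.7, tolerance = 3 * 0.05 / sqrt(40))
  expect_error(
    simulate_group("hierarchical", 5, 5, 3, parameters = list(gamma = 0.7)),
    "mean, sd")
})

test_that("item count below two is rejected", {
  expect_error(simulate_group("individual", 2, 5, n_items = 1), "n_items")
})

test_that("prediction replays observed trials with fitted parameters", {
  d <- cached_sim("fit_small", {
    dd <- simulate_group("individual", 2, 120, 3,
                         parameters = moderate_pars(), seed = 58)
    fit <- fit_glam(glam_model(dd, "individual"), draws = 600, tune = 600,
                    chains = 2, seed = 59)
    list(data = dd, fit = fit)
  })
  pred <- predict(d$fit, n_repeats = 3, seed = 60)
  expect_equal(nrow(pred), 3 * nrow(d$data))
  expect_true(all(pred$repetition %in% 0:2))
  # provenance columns preserved
  expect_equal(pred$item_value_0[pred$repetition == 0], d$data$item_value_0)
  pred1 <- predict(d$fit, n_repeats = 1, seed = 61)
  expect_equal(nrow(pred1), nrow(d$data))
  # unknown subject in newdata is an error
  nd <- d$data
  nd$subject <- nd$subject + 5
  expect_error(predict(d$fit, newdata = nd), "contiguous|estimates")
})

test_that("predictions from a no-bias fit carry no gaze influence", {
  d <- cached_sim("nobias_fit", {
    dd <- simulate_group("individual", 1, 2500, 3,
                         parameters = list(v = 0.8, gamma = 1, s = 0.25,
                                           tau = 1),
                         error_weight = 0, seed = 62)
    fit <- fit_glam(glam_model(dd, "individual", fixed = list(gamma = 1),
                               error_weight = 0),
                    draws = 600, tune = 600, chains = 2, seed = 63)
    predict(fit, n_repeats = 1, seed = 64)
  })
  agg <- aggregate_subject_level_data(d, 3)
  expect_lt(abs(agg$gaze_influence), 3 * 0.5 / sqrt(2500))
})
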