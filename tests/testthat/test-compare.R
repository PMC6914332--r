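two_variant_fits <- function() {
  cached_sim("cmp_fits", {
    d <- simulate_group("individual", 1, 150, 3,
                        parameters = list(v = 0.7, gamma = 0.2, s = 0.25,
                                          tau = 1),
                        seed = 91)
    full <- fit_glam(glam_model(d, "individual", name = "glam_bias"),
                     draws = 800, tune = 800, chains = 2, seed = 92)
    nobias <- fit_glam(glam_model(d, "individual", fixed = list(gamma = 1),
                                  name = "glam_nobias"),
                       draws = 800, tune = 800, chains = 2, seed = 93)
    list(data = d, full = full, nobias = nobias)
  })
}

test_that("comparing a fit with itself gives zero difference and split weights", {
  fits <- two_variant_fits()
  a <- fits$full
  b <- fits$full
  b$name <- "copy"
  cmp <- compare_models(list(a, b), ic = "WAIC")
  expect_equal(cmp$dWAIC, c(0, 0), tolerance = 1e-9)
  expect_equal(cmp$weight, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-6)
})

test_that("comparison tables carry the standard column schema", {
  fits <- two_variant_fits()
  cmp <- compare_models(list(fits$full, fits$nobias), ic = "WAIC")
  expect_setequal(names(cmp),
                  c("subject", "model", "WAIC", "pWAIC", "dWAIC",
                    "weight", "SE", "dSE", "var_warn"))
  expect_equal(cmp$dWAIC[1], 0)
  expect_true(all(cmp$dSE >= 0))
  loo <- compare_models(list(fits$full, fits$nobias), ic = "LOO")
  expect_true(all(c("LOO", "pLOO", "dLOO") %in% names(loo)))
})

test_that("gaze-biased data prefer the full model variant", {
  fits <- two_variant_fits()
  cmp <- compare_models(list(fits$full, fits$nobias), ic = "WAIC")
  expect_equal(cmp$model[cmp$dWAIC == 0], "glam_bias")
  expect_gt(cmp$dWAIC[cmp$model == "glam_nobias"], 0)
})

test_that("WAIC matches an independent reimplementation on a small fixture", {
  fits <- two_variant_fits()
  L <- glamr:::pointwise_loglik(fits$full, subject = 0)[, 1:10]
  ours <- glamr:::waic_from_loglik(L)
  # independent oracle: lppd - sum of pointwise variances, deviance scale
  S <- nrow(L)
  lppd <- sum(log(colMeans(exp(L))))
  p_waic <- sum(apply(L, 2, var))
  expect_equal(ours$ic, -2 * (lppd - p_waic), tolerance = 1e-6)
  expect_equal(ours$p, p_waic, tolerance = 1e-6)
})

test_that("PSIS-LOO approximates WAIC on well-behaved likelihoods", {
  fits <- two_variant_fits()
  L <- glamr:::pointwise_loglik(fits$full, subject = 0)
  w <- glamr:::waic_from_loglik(L)
  l <- glamr:::loo_from_loglik(L)
  expect_equal(l$ic, w$ic, tolerance = 0.05 * abs(w$ic))
})

test_that("parameter contrasts are antisymmetric and null on self-comparison", {
  res <- cached_sim("cond_fit", {
    d1 <- simulate_group("individual", 3, 60, 3,
                         parameters = list(v = 0.7, gamma = 0.5, s = 0.25,
                                           tau = 1),
                         seed = 94, label = list(block = "early"))
    d2 <- simulate_group("individual", 3, 60, 3,
                         parameters = list(v = 0.7, gamma = 0.5, s = 0.25,
                                           tau = 1),
                         seed = 95, label = list(block = "late"))
    d2$subject <- d1$subject  # same subjects, within-subject factor
    d2$trial <- d2$trial + 60
    d <- rbind(d1, d2)
    fit <- fit_glam(glam_model(d, "individual",
                               depends_on = list(gamma = "block")),
                    draws = 600, tune = 600, chains = 2, seed = 96)
    fit
  })
  self <- compare_parameters(res, "gamma", list(c("early", "early")))
  expect_equal(self$mean_diff, rep(0, 3))
  expect_equal(self$p_gt_0, rep(0.5, 3))

  ab <- compare_parameters(res, "gamma", list(c("early", "late")))
  ba <- compare_parameters(res, "gamma", list(c("late", "early")))
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$p_gt_0, 1 - ba$p_gt_0, tolerance = 1e-6)
  expect_error(compare_parameters(res, "gamma", list(c("early", "never"))),
               "available")
})

test_that("parity split partitions each subject's trials", {
  d <- simulate_group("individual", 2, 300, 3, seed = 97)
  sp <- out_of_sample_split(d)
  expect_equal(nrow(sp$even), 300)
  expect_equal(nrow(sp$odd), 300)
  expect_equal(sort(c(sp$even$trial, sp$odd$trial)), sort(d$trial))
  expect_equal(nrow(merge(sp$even, sp$odd, by = c("subject", "trial"))), 0)
  single <- d[d$subject == 0 & d$trial == 0, ]
  expect_warning(out_of_sample_split(single), "one side")
})

test_that("model recovery classifies simulated no-bias subjects", {
  res <- cached_sim("recovery_small", {
    d <- simulate_group("individual", 2, 150, 3,
                        parameters = list(v = c(0.7, 0.7),
                                          gamma = c(0.2, 1),
                                          s = c(0.25, 0.25), tau = c(1, 1)),
                        seed = 98)
    model_recovery(d, draws = 600, tune = 600, chains = 2, seed = 99)
  })
  expect_equal(nrow(res), 2)
  expect_equal(res$true_variant, c("glam_bias", "glam_nobias"))
  expect_true(res$correct[1])
})
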