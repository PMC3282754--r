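test_that("percent variance explained matches its defining cases", {
  set.seed(131)
  obs <- rnorm(50, 5, 2)
  expect_equal(percent_variance_explained(obs, obs), 100)
  expect_equal(percent_variance_explained(obs, rep(mean(obs), 50)), 0)
  resid <- (obs - mean(obs)) / 2            # sd(resid) = sd(obs) / 2
  expect_equal(percent_variance_explained(obs, obs - resid), 75)
  # invariant to shift and scale of the rates
  expect_equal(percent_variance_explained(obs + 7, obs + 7 - resid), 75)
  expect_equal(percent_variance_explained(3 * obs, 3 * (obs - resid)), 75)
})

test_that("full-span local regression equals a global plane on a linear ramp", {
  geom <- map_geometry(NULL, n = 8)
  x <- matrix(geom$centers, 8, 8)
  y <- matrix(geom$centers, 8, 8, byrow = TRUE)
  m <- flat_map(2 + 0.5 * x - 0.3 * y)
  fit <- fit_spatial_regression(m, span = 1)
  expect_gt(fit$pve, 99)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("span selection prefers small spans for sharp noiseless fields", {
  m <- gaussian_rate_map(c(5, 3), width = 4, arena_radius = 15)
  sel <- select_span_cv(m, seed = 133)
  err <- sel$cv_error
  big <- as.numeric(names(err)) >= 4 * sel$span
  expect_true(all(err[as.character(sel$span)] < err[big]))
  fit <- fit_spatial_regression(m, sel$span)
  expect_gt(fit$pve, 95)
})

test_that("span selection degrades gracefully on structureless maps", {
  set.seed(137)
  m <- flat_map(matrix(rnorm(400), 20, 20))
  sel <- select_span_cv(m, seed = 138)
  expect_length(sel$span, 1)
  expect_true(sel$span %in% c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1))
  # single-element grid returns that span
  expect_equal(select_span_cv(m, span_grid = 0.3, seed = 1)$span, 0.3)
  # fewer valid pixels than folds is an error
  tiny <- flat_map(matrix(rnorm(9), 3, 3))
  expect_error(select_span_cv(tiny, k = 10), class = "pf_error_invalid")
})

test_that("logistic IRLS agrees with the standard fitter and flags separation", {
  set.seed(139)
  n <- 400
  d <- data.frame(isi_peak = rnorm(n, 3, 1.5), group = rbinom(n, 1, 0.5),
                  session2 = rbinom(n, 1, 0.5), session3 = rbinom(n, 1, 0.5))
  d$remap <- rbinom(n, 1, plogis(-1 + 0.2 * d$isi_peak + 0.5 * d$group))
  fit <- fit_remap_logistic(d)
  ref <- glm(remap ~ isi_peak + group + session2 + session3,
             family = binomial, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(all(diff(fit$deviance_trace) <= 1e-8))

  # reduced model drops the ISI peak term
  red <- fit_remap_logistic(d, terms = c("group", "session2", "session3"))
  expect_named(red$coefficients, c("(Intercept)", "group", "session2", "session3"))

  # single-outcome data is rejected
  d1 <- d; d1$remap <- 1
  expect_error(fit_remap_logistic(d1), class = "pf_error_single_class")

  # perfect separation is flagged as non-convergence
  ds <- d; ds$remap <- as.integer(ds$isi_peak > 3)
  expect_warning(sep <- fit_remap_logistic(ds), "separation|converge")
  expect_false(sep$converged)
})

test_that("null predictors yield no spurious logistic effects", {
  hits <- 0L
  for (rep in 1:20) {
    set.seed(1000 + rep)
    n <- 500
    d <- data.frame(isi_peak = rnorm(n, 3, 1.5), group = rbinom(n, 1, 0.5),
                    session2 = rbinom(n, 1, 0.5), session3 = rbinom(n, 1, 0.5))
    d$remap <- rbinom(n, 1, 0.3)
    fit <- fit_remap_logistic(d)
    if (all(abs(fit$z[-1]) < 2)) hits <- hits + 1L
  }
  expect_gte(hits, 14)   # ~0.95^4 of replicates should have all |z| < 2
})
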