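tmpl <- caprine_template()

test_that("transport weights hit the stated endpoints", {
  expect_equal(transport_weight(c("axial", "appendicular"), 0), c(1, 1))
  expect_equal(transport_weight("axial", 1), 0)
  expect_equal(transport_weight("appendicular", -1), 0)
  expect_error(transport_weight("axial", 1.5), "alpha")
})

test_that("survivorship is d^beta with the right limits", {
  expect_equal(survivorship(c(0.3, 0.9), 0), c(1, 1))
  expect_equal(survivorship(1, 7), 1)
  expect_equal(survivorship(0.5, 2), 0.25)
  expect_error(survivorship(0, 1), "positive")
  # strictly decreasing in beta for d < 1
  betas <- seq(0, 8, by = 0.5)
  expect_true(all(diff(survivorship(0.6, betas)) < 0))
})

test_that("expected profiles normalise and concentrate as beta grows", {
  p0 <- expected_profile(tmpl, 0, 0)
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0), tmpl$skeleton_count / sum(tmpl$skeleton_count))
  p_big <- expected_profile(tmpl, 0, 120)
  densest <- tmpl$element[tmpl$density == max(tmpl$density)]
  expect_gt(sum(p_big[densest]), 0.95)
  # 3-element template, hand-normalised
  t3 <- skeleton_template("t", c("a", "b", "c"), c(1L, 2L, 1L),
                          c("axial", "appendicular", "appendicular"),
                          c(0.5, 0.8, 0.4))
  q <- c(1 * 0.5 * 0.5, 2 * 1.5 * 0.8, 1 * 1.5 * 0.4)
  expect_equal(unname(expected_profile(t3, 0.5, 1)), q / sum(q))
  t_ax <- skeleton_template("t", "a", 1L, "axial", 0.5)
  expect_error(expected_profile(t_ax, 1, 0), "degenerate")
})

test_that("log-likelihood peaks at the generating parameters on a grid", {
  p <- expected_profile(tmpl, 0.3, 1.5)
  obs <- round(p * 1e5)  # essentially exact proportions
  grid <- expand.grid(a = seq(-0.9, 0.9, by = 0.1), b = seq(0, 6, by = 0.25))
  ll <- mapply(function(a, b) skeletal_loglik(obs, tmpl, a, b), grid$a, grid$b)
  best <- grid[which.max(ll), ]
  expect_equal(best$a, 0.3, tolerance = 1e-9)
  expect_equal(best$b, 1.5, tolerance = 1e-9)
  # exchangeability: permuting elements leaves the value unchanged
  perm <- sample(length(obs))
  expect_equal(skeletal_loglik(obs[perm], tmpl, 0.2, 1),
               skeletal_loglik(obs, tmpl, 0.2, 1))
  expect_error(skeletal_loglik(c(femur = 1, carpal = 2), tmpl, 0, 0), "carpal")
})

test_that("preservation fraction is 1 at beta 0 and strictly decreasing", {
  expect_equal(preservation_fraction(tmpl, 0), 1)
  t2 <- skeleton_template("t", c("a", "b"), 1L, c("axial", "appendicular"),
                          c(0.5, 0.5))
  expect_equal(preservation_fraction(t2, 1), 0.5)
  pres <- preservation_fraction(tmpl, seq(0, 8, by = 0.5))
  expect_true(all(diff(pres) < 0))
  # heavy attrition leaves a single-digit share of an ibex-like skeleton
  expect_lt(preservation_fraction(tmpl, 5.78), 0.08)
})

test_that("the sampler is reproducible and reports sane diagnostics", {
  obs <- simulate_skeletal_counts(tmpl, 0.1, 1, n = 300, seed = 4)
  f1 <- fit_skeletal_posterior(obs, tmpl, iterations = 4000, burnin = 500,
                               seed = 21)
  f2 <- fit_skeletal_posterior(obs, tmpl, iterations = 4000, burnin = 500,
                               seed = 21)
  expect_identical(f1$draws, f2$draws)
  expect_gt(f1$acceptance_rate, 0.1)
  expect_lt(f1$acceptance_rate, 0.8)
  expect_true(all(f1$draws$alpha >= -1 & f1$draws$alpha <= 1))
  expect_true(all(f1$draws$beta >= 0 & f1$draws$beta <= 12))
  expect_true(all(f1$draws$preservation > 0 & f1$draws$preservation <= 1))
  w <- capture_warnings(
    fit_skeletal_posterior(c(femur = 10, tibia = 12), tmpl,
                           iterations = 200, burnin = 50, seed = 1)
  )
  expect_true(any(grepl("below 50", w)))
})

test_that("null data give credible intervals covering alpha = beta = 0", {
  obs <- simulate_skeletal_counts(tmpl, 0, 0, n = 5000, seed = 31)
  fit <- fit_skeletal_posterior(obs, tmpl, iterations = 8000, burnin = 1000,
                                seed = 32)
  s <- fit$summary
  expect_lte(s$q2.5[s$parameter == "alpha"], 0)
  expect_gte(s$q97.5[s$parameter == "alpha"], 0)
  expect_lte(s$q2.5[s$parameter == "beta"], 0.2)  # boundary parameter
})

test_that("swapping region labels negates the alpha posterior", {
  obs <- simulate_skeletal_counts(tmpl, 0.4, 1, n = 400, seed = 41)
  swapped <- tmpl
  swapped$region <- ifelse(tmpl$region == "axial", "appendicular", "axial")
  f1 <- fit_skeletal_posterior(obs, tmpl, iterations = 8000, burnin = 1000,
                               seed = 42)
  f2 <- fit_skeletal_posterior(obs, swapped, iterations = 8000, burnin = 1000,
                               seed = 42)
  expect_equal(mean(f1$draws$alpha), -mean(f2$draws$alpha), tolerance = 0.05)
  expect_equal(mean(f1$draws$beta), mean(f2$draws$beta), tolerance = 0.1)
})
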