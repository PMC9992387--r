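tmpl <- caprine_template()

test_that("lossless scenarios reproduce skeleton counts and true MNI exactly", {
  sc <- assemblage_scenario(tibble::tibble(taxon = "Capra ibex", n = 4),
                            tmpl, alpha = 0, beta = 0, fragmentation = 1,
                            seed = 61)
  g <- generate_assemblage(sc)
  expect_equal(nrow(g$specimens), 4 * sum(tmpl$skeleton_count))
  q <- quantify_unit(g$specimens, "SYN", tmpl)
  want <- 4 * tmpl$skeleton_count[match(q$mne$element, tmpl$element)]
  expect_equal(q$mne$mne, want)
  expect_equal(q$mni$mni, 4L)
})

test_that("fixed seeds reproduce assemblages byte for byte", {
  sc <- function() assemblage_scenario(
    tibble::tibble(taxon = "Capra ibex", n = 3), tmpl,
    alpha = 0.2, beta = 1.5, fragmentation = 2, seed = 71
  )
  g1 <- generate_assemblage(sc())
  g2 <- generate_assemblage(sc())
  expect_identical(g1$specimens, g2$specimens)
  expect_identical(g1$truth, g2$truth)
})

test_that("strong attrition leaves mostly high-density elements", {
  sc <- assemblage_scenario(tibble::tibble(taxon = "Capra ibex", n = 60),
                            tmpl, alpha = 0, beta = 8, fragmentation = 1,
                            seed = 81)
  g <- generate_assemblage(sc)
  surv <- g$truth$survivors
  dens <- tmpl$density[match(surv$element, tmpl$element)]
  # survival odds per copy, weighted towards the densest elements
  per_copy <- surv$n_surviving /
    (60 * tmpl$skeleton_count[match(surv$element, tmpl$element)])
  expect_gt(stats::cor(dens, per_copy, method = "spearman"), 0.8)
  top <- surv$element[which.max(per_copy)]
  expect_gte(dens[surv$element == top], sort(tmpl$density, decreasing = TRUE)[3])
})

test_that("transport preference shifts the axial/appendicular balance", {
  run <- function(alpha) {
    sc <- assemblage_scenario(tibble::tibble(taxon = "Capra ibex", n = 40),
                              tmpl, alpha = alpha, beta = 0, fragmentation = 1,
                              seed = 91)
    surv <- generate_assemblage(sc)$truth$survivors
    reg <- tmpl$region[match(surv$element, tmpl$element)]
    sum(surv$n_surviving[reg == "appendicular"]) / sum(surv$n_surviving)
  }
  expect_gt(run(0.6), run(0))
  expect_lt(run(-0.6), run(0))
})

test_that("synthetic DEM kinds have their closed-form properties", {
  flat <- generate_dem("flat", nrow = 20, ncol = 20, cellsize = 100)
  expect_true(all(slope_percent(flat)[2:19, 2:19] == 0))
  plane <- generate_dem("plane", nrow = 20, ncol = 20, cellsize = 100,
                        gradient = 0.3)
  expect_equal(unname(slope_percent(plane)[5, 5]), 30, tolerance = 1e-9)
  f1 <- generate_dem("fractal", nrow = 16, ncol = 16, seed = 5)
  f2 <- generate_dem("fractal", nrow = 16, ncol = 16, seed = 5)
  expect_identical(f1$z, f2$z)
  expect_error(generate_dem("volcano"), "arg")
})

test_that("NPP regimes recover their means and stay non-negative", {
  regimes <- tibble::tibble(duration = c(5000, 5000), mean = c(0.33, 0.19),
                            sd = c(0.02, 0.02))
  s <- generate_npp_series(regimes, step = 50, start_bp = 50000, seed = 3)
  expect_equal(nrow(s), 200)
  expect_true(all(s$npp >= 0))
  first <- s$npp[s$year_bp > 45000]
  second <- s$npp[s$year_bp <= 45000]
  se <- 0.02 / sqrt(100)  # ignores autocorrelation; 2 SE is generous anyway
  expect_lt(abs(mean(first) - 0.33), 6 * se)
  expect_lt(abs(mean(second) - 0.19), 6 * se)
  s2 <- generate_npp_series(regimes, step = 50, start_bp = 50000, seed = 3)
  expect_identical(s, s2)
  const <- generate_npp_series(
    tibble::tibble(duration = 1000, mean = 0.3, sd = 0), step = 100,
    start_bp = 42000, seed = 9
  )
  expect_true(all(const$npp == 0.3))
})
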