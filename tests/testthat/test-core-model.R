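test_that("specimen files round-trip field-for-field and keep row order", {
  recs <- specimen_records(
    record_id = c("r1", "r2", "r3"),
    unit = "A2-A1",
    square = c("66d", NA, "77f"),
    taxon = c("Capra ibex", "Capra ibex", NA),
    size_class = c(NA, NA, 3L),
    element = c("femur", "femur", "tibia"),
    portion_codes = list(1:5, c(6L, 7L), c(10L, 11L, 12L)),
    side = c("left", "right", "indeterminate"),
    age_class = c("Ad", "J", "indeterminate"),
    surface_mods = list(c(cut_defleshing = 2L), setNames(integer(0), character(0)),
                        c(percussion_notch = 1L, manganese = 1L)),
    burn_code = list(0L, c(2L, 4L), 3L),
    breakage = c("green", "indeterminate", "dry"),
    is_retoucher = c(FALSE, FALSE, TRUE)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_specimens(recs, f)
  back <- read_specimens(f)
  expect_equal(back$record_id, recs$record_id)
  expect_equal(back$portion_codes, recs$portion_codes)
  expect_equal(back$surface_mods, recs$surface_mods)
  expect_equal(back$burn_code, recs$burn_code)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("an empty specimen file yields an empty record list", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("record_id", "unit", "square", "taxon", "size_class",
                     "element", "portion_codes", "side", "age_class",
                     "surface_mods", "burn_code", "breakage", "is_retoucher"),
                   collapse = ","), f)
  expect_equal(nrow(read_specimens(f)), 0L)
})

test_that("validation names the offending row and field", {
  base <- function(...) specimen_records(record_id = "x", unit = "U", ...)
  expect_error(base(burn_code = list(7L)), "burn_code")
  expect_error(base(taxon = "Capra ibex", size_class = 3L), "taxon")
  expect_error(base(element = "femur", portion_codes = list(c(1L, 25L))),
               "portion_codes")
  expect_error(base(portion_codes = list(1:3)), "portion_codes")  # no element
  expect_error(base(age_class = "adultish"), "age_class")
  expect_error(base(side = "lft"), "side")
  expect_error(base(surface_mods = list(c(chewing = 1L))), "surface_mods")
  expect_error(base(size_class = 9L), "size_class")
})

test_that("templates validate, reject duplicates, and round-trip", {
  tmpl <- caprine_template()
  expect_equal(nrow(tmpl), 20L)
  expect_equal(tmpl$skeleton_count[tmpl$element == "femur"], 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_template(tmpl, f)
  back <- read_template(f)
  expect_equal(as.data.frame(back), as.data.frame(tmpl))

  expect_error(skeleton_template("t", "femur", 2L, "appendicular", 1.2),
               "density")
  expect_error(skeleton_template("t", "femur", 0L, "appendicular", 0.5),
               "skeleton_count")
  expect_error(validate_template(rbind(tmpl, tmpl[1, ])), "duplicate")
})

test_that("generator output always passes validation", {
  tmpl <- caprine_template()
  sc <- assemblage_scenario(tibble::tibble(taxon = "Capra ibex", n = 4),
                            tmpl, alpha = 0.3, beta = 1, fragmentation = 2,
                            seed = 99)
  g <- generate_assemblage(sc)
  expect_silent(validate_specimens(g$specimens))
})

test_that("configuration files read with defaults and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("seed: 7", "diversity_basis: NISP",
               "catchment:", "  slope_threshold: 25"), f)
  cfg <- read_config(f)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$diversity_basis, "NISP")
  expect_equal(cfg$catchment$slope_threshold, 25)
  expect_equal(cfg$catchment$times, c(72, 129))  # untouched default
  writeLines("isochrones: [10]", f)
  expect_error(read_config(f), "unknown configuration key")
})
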