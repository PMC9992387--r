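tmpl <- caprine_template()

test_that("NISP counts identified records only and normalises percentages", {
  recs <- specimen_records(
    record_id = sprintf("r%d", 1:7), unit = "U",
    taxon = c(rep("Capra ibex", 3), rep("Cervus elaphus", 2), NA, NA),
    size_class = c(rep(NA_integer_, 5), 3L, 3L)
  )
  out <- compute_nisp(recs, "U")
  expect_equal(out$nisp[out$taxon == "Capra ibex"], 3L)
  expect_equal(out$nisp[out$taxon == "Cervus elaphus"], 2L)
  expect_equal(nrow(out), 2L)               # size-class records excluded
  expect_equal(sum(out$pct_nisp), 100)
  expect_error(compute_nisp(recs, "nope"), "available")
  # printed-table convention: 136 of 450 identified reads 30.2%
  expect_equal(round_pct <- round(100 * 136 / 450, 1), 30.2)
})

test_that("MNE follows sides, disjoint portions and the published coding logic", {
  mk <- function(codes, side, age = "Ad") {
    as_specimens(tibble::tibble(side = side, age_class = age,
                                portion_codes = codes))
  }
  # same codes on both sides force two elements
  two <- specimen_records(record_id = c("a", "b"), unit = "U",
                          taxon = "Capra ibex", element = "femur",
                          portion_codes = list(1:5, 1:5),
                          side = c("left", "right"), age_class = "Ad")
  expect_equal(compute_mne(two, "Capra ibex", "femur", tmpl), 2L)
  # disjoint portions, one side: one element suffices
  one <- specimen_records(record_id = c("a", "b", "c"), unit = "U",
                          taxon = "Capra ibex", element = "femur",
                          portion_codes = list(c(1L, 2L), c(3L, 4L), 5L),
                          side = "left", age_class = "Ad")
  expect_equal(compute_mne(one, "Capra ibex", "femur", tmpl), 1L)
  # incompatible ages split elements even with disjoint codes repeated
  aged <- specimen_records(record_id = c("a", "b"), unit = "U",
                           taxon = "Capra ibex", element = "femur",
                           portion_codes = list(1:5, 1:5),
                           side = "left", age_class = c("Ad", "J"))
  expect_equal(compute_mne(aged, "Capra ibex", "femur", tmpl), 2L)
  expect_error(compute_mne(two, "Capra ibex", "carpal", tmpl), "carpal")
})

test_that("MNE equals the exhaustive set-partition oracle on random fixtures", {
  set.seed(42)
  for (rep in 1:60) {
    paired <- rep %% 2 == 0
    fix <- random_element_fixture(n = sample(2:8, 1), paired = paired)
    specs <- as_specimens(fix, element = if (paired) "femur" else "cervical")
    got <- compute_mne(specs, "Capra ibex",
                       if (paired) "femur" else "cervical", tmpl)
    want <- oracle_mne(specs, paired)
    expect_equal(got, want,
                 info = sprintf("rep %d (paired=%s)", rep, paired))
  }
})

test_that("MNI handles pairing, age incompatibility and unpaired elements", {
  mk_femora <- function(sides, ages) {
    specimen_records(record_id = sprintf("r%d", seq_along(sides)), unit = "U",
                     taxon = "Capra ibex", element = "femur",
                     portion_codes = rep(list(1:20), length(sides)),
                     side = sides, age_class = ages)
  }
  # 3 left + 1 right, same age
  expect_equal(compute_mni(mk_femora(c("left", "left", "left", "right"),
                                     "Ad"), "Capra ibex", tmpl)$mni, 3L)
  # left adult + right juvenile are different animals
  expect_equal(compute_mni(mk_femora(c("left", "right"), c("Ad", "J")),
                           "Capra ibex", tmpl)$mni, 2L)
  # 7 cervicals of one age are one animal (5 per skeleton -> ceiling)
  cerv <- specimen_records(record_id = sprintf("c%d", 1:7), unit = "U",
                           taxon = "Capra ibex", element = "cervical",
                           portion_codes = rep(list(1:20), 7),
                           side = "indeterminate", age_class = "Ad")
  expect_equal(compute_mni(cerv, "Capra ibex", tmpl)$mni, 2L)  # ceiling(7/5)
  res <- compute_mni(mk_femora(c("left", "right"), c("Ad", "J")),
                     "Capra ibex", tmpl)
  expect_equal(sum(res$by_age) + res$indeterminate, res$mni)
})

test_that("MNI equals the minimal-individuals oracle on unit fixtures", {
  set.seed(7)
  for (rep in 1:40) {
    paired <- rep %% 2 == 0
    k <- if (paired) 2L else 5L
    element <- if (paired) "femur" else "cervical"
    n <- sample(2:6, 1)
    units <- tibble::tibble(
      side = if (paired) sample(c("left", "right", "indeterminate"), n, TRUE)
             else rep("indeterminate", n),
      age = sample(c("J", "Ad", "indeterminate"), n, TRUE)
    )
    specs <- specimen_records(
      record_id = sprintf("u%d", seq_len(n)), unit = "U",
      taxon = "Capra ibex", element = element,
      portion_codes = rep(list(1:20), n),
      side = units$side, age_class = units$age
    )
    got <- compute_mni(specs, "Capra ibex", tmpl)$mni
    want <- oracle_mni(units, k)
    expect_gte(got, want, label = sprintf("rep %d package MNI", rep))
    expect_lte(got - want, 0L, label = sprintf("rep %d package MNI excess", rep))
  }
})

test_that("MAU divides by skeleton counts and %MAU peaks at 100", {
  mne <- tibble::tibble(element = c("femur", "lumbar"), mne = c(4L, 6L))
  out <- compute_mau(mne, tmpl, "Capra ibex")
  expect_equal(out$mau, c(2.0, 1.0))
  expect_equal(out$pct_mau, c(100, 50))
  single <- compute_mau(tibble::tibble(element = "tibia", mne = 3L),
                        tmpl, "Capra ibex")
  expect_equal(single$pct_mau, 100)
  expect_error(compute_mau(tibble::tibble(element = "carpal", mne = 1L),
                           tmpl, "Capra ibex"), "carpal")
})

test_that("merging record sets never decreases NISP, MNE or MNI", {
  set.seed(11)
  sc1 <- assemblage_scenario(tibble::tibble(taxon = "Capra ibex", n = 3),
                             tmpl, alpha = 0.2, beta = 1, fragmentation = 2,
                             seed = 1)
  sc2 <- assemblage_scenario(tibble::tibble(taxon = "Capra ibex", n = 2),
                             tmpl, alpha = -0.2, beta = 0.5, fragmentation = 1.5,
                             seed = 2)
  a <- generate_assemblage(sc1)$specimens
  b <- generate_assemblage(sc2)$specimens
  b$record_id <- paste0("b", b$record_id)
  ab <- validate_specimens(rbind(a, b))
  qa <- quantify_unit(a, "SYN", tmpl)
  qab <- quantify_unit(ab, "SYN", tmpl)
  expect_gte(sum(qab$nisp$nisp), sum(qa$nisp$nisp))
  expect_gte(sum(qab$mne$mne), sum(qa$mne$mne))
  expect_gte(sum(qab$mni$mni), sum(qa$mni$mni))
})
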