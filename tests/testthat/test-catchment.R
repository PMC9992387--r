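test_that("Horn slope has the closed-form values on flat and inclined planes", {
  flat <- generate_dem("flat", nrow = 10, ncol = 10, cellsize = 50)
  sl <- slope_percent(flat)
  expect_true(all(sl[2:9, 2:9] == 0))
  expect_true(all(is.na(sl[1, ])))
  # 3 m rise per 10 m horizontal = 30% slope on interior cells
  inc <- generate_dem("plane", nrow = 12, ncol = 12, cellsize = 10,
                      gradient = 0.3)
  s2 <- slope_percent(inc)
  expect_equal(unname(s2[2:11, 2:11]), matrix(30, 10, 10), tolerance = 1e-9)
  # symmetric ridge gives a symmetric slope field
  hill <- generate_dem("gaussian_hill", nrow = 21, ncol = 21, cellsize = 100,
                       height = 150, width = 400)
  s3 <- slope_percent(hill)
  expect_equal(s3[2:20, 2:20], s3[20:2, 20:2], tolerance = 1e-9)
  tiny <- dem(matrix(0, 2, 2), 10)
  expect_error(slope_percent(tiny), "3 x 3")
})

test_that("ASCII grid files round-trip", {
  d <- generate_dem("fractal", nrow = 12, ncol = 9, cellsize = 25, seed = 3)
  d$z[3, 4] <- NA
  d <- dem(d$z, d$cellsize)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(d, f)
  back <- read_ascii_grid(f)
  expect_equal(back$z, d$z, tolerance = 1e-6)
  expect_equal(back$cellsize, d$cellsize)
  expect_equal(back$nodata, d$nodata)
})

test_that("travel time is 0 at the origin and matches the flat closed form", {
  flat <- generate_dem("flat", nrow = 31, ncol = 31, cellsize = 100)
  tt <- travel_time(flat, c(16, 16))
  expect_equal(tt[16, 16], 0)
  # straight 1 km east at 6 exp(-0.175) km/h
  v <- 6 * exp(-3.5 * 0.05)
  expect_equal(tt[16, 26], 60 / v, tolerance = 1e-9)
  # uphill slower than downhill between the same two cells
  slope <- generate_dem("plane", nrow = 9, ncol = 9, cellsize = 100,
                        gradient = 0.2)
  up <- travel_time(slope, c(5, 2))[5, 8]
  down <- travel_time(slope, c(5, 8))[5, 2]
  expect_gt(up, down)
})

test_that("travel times equal Bellman-Ford relaxation on small rough grids", {
  set.seed(13)
  for (rep in 1:6) {
    d <- generate_dem("fractal", nrow = 4, ncol = 4, cellsize = 80,
                      roughness = 40, seed = 50 + rep)
    if (rep == 6) {  # add a barrier cell
      bar <- matrix(FALSE, 4, 4); bar[2, 2] <- TRUE
      d <- dem(d$z, d$cellsize, barrier = bar)
    }
    got <- travel_time(d, c(1, 1))
    want <- oracle_travel_time(d, c(1, 1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("travel time satisfies the directed triangle inequality", {
  d <- generate_dem("fractal", nrow = 12, ncol = 12, cellsize = 100,
                    roughness = 80, seed = 17)
  cells <- expand.grid(r = c(2, 6, 11), c = c(3, 7, 12))
  tts <- lapply(seq_len(nrow(cells)), function(i) {
    travel_time(d, c(cells$r[i], cells$c[i]))
  })
  for (i in seq_len(nrow(cells))) for (j in seq_len(nrow(cells))) {
    for (k in seq_len(nrow(cells))) {
      t_ij <- tts[[i]][cells$r[j], cells$c[j]]
      t_ik <- tts[[i]][cells$r[k], cells$c[k]]
      t_kj <- tts[[k]][cells$r[j], cells$c[j]]
      expect_lte(t_ij, t_ik + t_kj + 1e-9)
    }
  }
})

test_that("isochrones partition flat terrain as 100% plain and nest in time", {
  flat <- generate_dem("flat", nrow = 41, ncol = 41, cellsize = 150)
  tt <- travel_time(flat, c(21, 21))
  sl <- slope_percent(flat)
  st <- isochrone_stats(tt, sl, c(20, 40), 150)
  expect_equal(st$plain_pct, c(100, 100))
  expect_equal(st$mountain_km2, c(0, 0))
  expect_gte(st$area_km2[2], st$area_km2[1])
  rough <- generate_dem("fractal", nrow = 25, ncol = 25, cellsize = 100,
                        roughness = 120, seed = 23)
  tr <- travel_time(rough, c(13, 13))
  sr <- slope_percent(rough)
  str_ <- isochrone_stats(tr, sr, c(15, 30, 60), 100, slope_threshold = 30)
  expect_true(all(diff(str_$area_km2) >= 0))
  expect_equal(str_$plain_pct + str_$mountain_pct, rep(100, 3))
})

test_that("halving the cell size changes isochrone areas by under 3%", {
  coarse <- generate_dem("gaussian_hill", nrow = 41, ncol = 41, cellsize = 200,
                         height = 120, width = 1500)
  fine <- generate_dem("gaussian_hill", nrow = 81, ncol = 81, cellsize = 100,
                       height = 120, width = 1500)
  a_coarse <- isochrone_stats(travel_time(coarse, c(21, 21)),
                              slope_percent(coarse), 40, 200)$area_km2
  a_fine <- isochrone_stats(travel_time(fine, c(41, 41)),
                            slope_percent(fine), 40, 100)$area_km2
  expect_lt(abs(a_fine - a_coarse) / a_coarse, 0.03)
})
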