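test_that("PIV matches the full-search oracle on integer shifts and is exact on copies", {
  tp <- textured_pair(4, 0, seed = 11)
  f <- piv_displacement(tp$a, tp$b, pixel_size = 1, dt = 600)
  # interior grid points: window fully informative
  int <- f$x >= 15 & f$x <= 45 & f$y >= 15 & f$y <= 45 & f$valid
  oracle <- full_search_oracle(tp$a, tp$b, f$x[int], f$y[int])
  expect_true(all(round(f$u[int]) == oracle[, 1]))
  expect_true(all(round(f$v[int]) == oracle[, 2]))
  expect_true(all(oracle[, 1] == 4))
  # identity: exactly zero
  f0 <- piv_displacement(tp$a, tp$a, 1, 600)
  expect_lt(max(abs(c(f0$u[f0$valid], f0$v[f0$valid]))), 1e-9)
  # featureless window flagged invalid, not zero
  flat <- matrix(5, 64, 64)
  ff <- piv_displacement(flat, flat, 1, 600)
  expect_true(all(!ff$valid))
  expect_true(all(is.na(ff$u)))
})

test_that("sub-pixel shifts are recovered within 0.15 px RMSE", {
  for (sh in c(0.3, 0.5)) {
    tp <- textured_pair(sh, 0, seed = 21)
    f <- piv_displacement(tp$a, tp$b, 1, 600)
    err <- c(f$u[f$valid] - sh, f$v[f$valid])
    expect_lt(sqrt(mean(err^2)), 0.15)
    expect_lt(abs(median(f$u[f$valid]) - sh), 0.1)
  }
})

test_that("speed statistics follow their closed forms and invariances", {
  # uniform |d| = 2 um, dt = 20 min -> 6 um/hr
  fld <- displacement_field(x = c(5, 15), y = c(5, 5), u = c(2, 0),
                            v = c(0, 2), dt = 1200)
  sp <- region_speeds(fld)
  expect_equal(sp$speed_um_hr, c(6, 6))
  expect_equal(mean_speed(fld), 6)
  # zero field -> 0
  f0 <- displacement_field(1, 1, 0, 0, dt = 600)
  expect_equal(mean_speed(f0), 0)
  # rotation invariance of mean speed
  th <- 0.7
  fld2 <- displacement_field(x = 1:4, y = rep(1, 4), u = c(1, 2, 0.5, 3),
                             v = c(0.3, -1, 2, 0.1), dt = 900)
  rot <- displacement_field(x = 1:4, y = rep(1, 4),
                            u = cos(th) * fld2$u - sin(th) * fld2$v,
                            v = sin(th) * fld2$u + cos(th) * fld2$v,
                            dt = 900)
  expect_equal(mean_speed(rot), mean_speed(fld2))
  expect_equal(circular_variance(rot), circular_variance(fld2))
  expect_error(region_speeds(displacement_field(1, 1, NA, NA, dt = 60)),
               "invalid")
})

test_that("circular variance hits its closed forms at machine precision", {
  expect_equal(circular_variance(c(2, 1, 5), c(0, 0, 0)), 0)
  expect_equal(circular_variance(c(1, 0, -1, 0), c(0, 1, 0, -1)), 1)
  expect_equal(circular_variance(c(1, 0), c(0, 1)), 1 - sqrt(2) / 2)
  # zero-length vectors are excluded
  expect_equal(circular_variance(c(1, 0, 0), c(0, 0, 1)), 1 - sqrt(2) / 2)
  expect_error(circular_variance(c(0, 0), c(0, 0)), "no valid")
})

test_that("region classification applies strict thresholds", {
  expect_equal(classify_region(1.0), "non_mover")
  expect_equal(classify_region(4.5), "mover")
  expect_equal(classify_region(c(2, 1.5, 4)),
               c("intermediate", "intermediate", "intermediate"))
  expect_error(classify_region(-1), "non-negative")
})

test_that("photoconversion screen uses strict displacement threshold", {
  s <- screen_photoconverted_region(c(54, 50, 0), elapsed = 18)
  expect_equal(s$mover, c(TRUE, FALSE, FALSE))
  expect_equal(s$rate_um_hr[1], 3)
  expect_error(screen_photoconverted_region(-5), "non-negative")
})

test_that("division axes align with the long axis, not the movement axis", {
  base <- tibble::tibble(cell_id = "m", frame = 1:5, x = 1:5, y = rep(0, 5),
                         orientation = 0, major = 12, minor = 8,
                         parent_id = NA_character_)
  kids0 <- tibble::tibble(cell_id = c("d1", "d2"), frame = 6,
                          x = c(4, 8), y = c(0, 0), orientation = 0,
                          major = 9, minor = 8, parent_id = "m")
  da <- division_axis_alignment(dplyr::bind_rows(base, kids0))
  expect_equal(da$angle_long_axis, 0)
  expect_equal(da$angle_movement_axis, 0)
  kids90 <- dplyr::mutate(kids0, x = c(6, 6), y = c(-2, 2))
  da90 <- division_axis_alignment(dplyr::bind_rows(base, kids90))
  expect_equal(da90$angle_long_axis, 90)
  # near-circular mother: long-axis angle undefined
  round_mom <- dplyr::mutate(base, major = 8.2)
  dar <- division_axis_alignment(dplyr::bind_rows(round_mom, kids0))
  expect_false(dar$long_axis_defined)
  expect_true(is.na(dar$angle_long_axis))
  expect_error(division_axis_alignment(base), "no division")
})

test_that("simulated division cohort obeys Hertwig's rule statistically", {
  tr <- simulate_division_tracks(n_tracks = 200, jitter_deg = 10, seed = 4)
  da <- division_axis_alignment(tr)
  expect_equal(nrow(da), 200)
  expect_lt(median(da$angle_long_axis, na.rm = TRUE), 15)
  # movement axis carries no information: roughly uniform on [0, 90]
  expect_gt(ks.test(da$angle_movement_axis, "punif", 0, 90)$p.value, 0.01)
  expect_gt(median(da$angle_movement_axis), 25)
})
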