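flat_sheet_stack <- function(z0 = 10, n_z = 12, z_step = 2, size = 40,
                             noise = 0, seed = 1) {
  scn <- motion_scenario(function(x, y, t) cbind(0 * x, 0 * y),
                         n_nuclei = 20, n_frames = 2, fov_um = c(size, size),
                         height_fun = function(x, y) rep(z0, length(x)),
                         n_z = n_z, z_step = z_step, noise_sd = noise,
                         seed = seed)
  simulate_tissue_movie(scn)
}

test_that("height map recovers a flat sheet exactly and tracks the brighter sheet", {
  sim <- flat_sheet_stack(z0 = 10)
  hm <- estimate_height_map(sim$stack, "SHG", sigma_xy = 10, sigma_z = 2)
  expect_true(all(hm[[1]] == 10))
  # two candidate sheets: argmax-on-blurred-volume oracle says the brighter
  # (deeper) one wins
  d <- c(20, 20, 10, 1)
  vol <- array(0, dim = d)
  z_um <- (seq_len(10) - 1) * 2
  for (z in seq_len(10))
    vol[, , z, 1] <- 2 * exp(-((z_um[z] - 4)^2) / 8) +
      1 * exp(-((z_um[z] - 14)^2) / 8)
  st <- image_stack(list(SHG = vol), voxel_size = c(1, 1, 2),
                    frame_interval = 1)
  hm2 <- estimate_height_map(st, "SHG", sigma_xy = 4, sigma_z = 2)
  blurred <- behavex:::gauss_blur(vol[, , , 1], c(4, 4, 1))
  oracle <- apply(blurred, c(1, 2), which.max)
  expect_true(all(hm2[[1]] == z_um[oracle]))
  expect_true(all(hm2[[1]] == 4))
  expect_error(estimate_height_map(
    image_stack(list(SHG = array(0, dim = c(4, 4, 3, 1))),
                c(1, 1, 1), 1)), "no surface signal")
})

test_that("sinusoidal membrane is recovered below 1 um RMSE and flattening levels it", {
  hf <- function(x, y) 12 + 5 * sin(2 * pi * x / 100)
  scn <- motion_scenario(function(x, y, t) cbind(0 * x, 0 * y),
                         n_nuclei = 80, n_frames = 2, fov_um = c(100, 100),
                         height_fun = hf, n_z = 15, z_step = 2,
                         noise_sd = 0.02, seed = 2)
  sim <- simulate_tissue_movie(scn)
  hm <- estimate_height_map(sim$stack, "SHG", sigma_xy = 10, sigma_z = 2)
  rmse <- sqrt(mean((hm[[1]] - sim$truth$height_map)^2))
  expect_lt(rmse, 1)
  flat <- flatten_stack(sim$stack, hm)
  shg <- stack_channel(flat, "SHG")
  shg[is.na(shg)] <- 0
  amax <- apply(shg[, , , 1], c(1, 2), which.max)
  expect_lt(sd(amax), 1)                      # within one z-step
  expect_lte(diff(range(amax)), 2)            # +-1 plane around the mode
})

test_that("flattening is an exact z-shift for constant maps and identity for zero maps", {
  sim <- flat_sheet_stack(z0 = 8, noise = 0.01)
  a <- stack_channel(sim$stack, "SHG")
  hm_const <- structure(list(matrix(8, 40, 40)), class = "height_map",
                        z_step = 2)
  flat <- flatten_stack(sim$stack, hm_const)
  b <- stack_channel(flat, "SHG")
  shift <- 8 / 2  # z-steps; reference is the map minimum = 8 um -> 4 planes
  expect_equal(b[, , 1, 1], a[, , 1 + shift, 1])
  # intensity conservation for the in-range planes of an integer shift
  expect_equal(sum(b[, , 1:(12 - shift), 1]), sum(a[, , (1 + shift):12, 1]))
  # zero map: identity
  hm0 <- structure(list(matrix(0, 40, 40)), class = "height_map", z_step = 2)
  flat0 <- flatten_stack(sim$stack, hm0)
  expect_identical(stack_channel(flat0, "SHG"), a)
  # idempotence: flattening an already-flat stack changes nothing
  hm_flat <- estimate_height_map(flat, "SHG", sigma_xy = 10, sigma_z = 2)
  expect_true(all(hm_flat[[1]] == hm_flat[[1]][1, 1]))
  # mismatched extent errors
  hm_bad <- structure(list(matrix(0, 10, 10)), class = "height_map")
  expect_error(flatten_stack(sim$stack, hm_bad), "extent")
})
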