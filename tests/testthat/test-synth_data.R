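test_that("speckle pair generation is seed-deterministic and honors the prescribed map", {
  grid <- build_grid(c(200, 200))
  spec <- speckle_spec(displacement = trans_displacement(3, 2), noise_sd = 0.01, seed = 41)
  a <- gen_speckle_pair(spec, grid = grid)
  b <- gen_speckle_pair(spec, grid = grid)
  expect_identical(a$reference, b$reference)
  expect_identical(a$deformed, b$deformed)

  # rigid motion: constant analytic truth
  expect_true(all(a$truth$u == 3) && all(a$truth$v == 2))

  # zero motion, zero noise: deformed is the reference itself
  idp <- gen_speckle_pair(speckle_spec(displacement = trans_displacement(0, 0), seed = 42))
  expect_equal(idp$deformed, idp$reference, tolerance = 1e-12)

  # homogeneous strain: truth equals the affine map at every node, exactly
  sp <- speckle_spec(displacement = strain_displacement(exx = 0.02), seed = 43)
  p <- gen_speckle_pair(sp, grid = grid)
  cx <- (200 - 1) / 2
  expect_lt(max(abs(p$truth$u - 0.02 * (grid$nodes$x - cx))), 1e-9)
  expect_lt(max(abs(p$truth$v)), 1e-9)
})

test_that("speckle scenes that move spots out of frame are rejected", {
  spec <- speckle_spec(image_shape = c(100L, 100L), n_spots = 30L,
                       displacement = trans_displacement(80, 0), seed = 1)
  expect_error(gen_speckle_pair(spec), "out of frame")
})

test_that("creep sequences sample the Kelvin-Voigt law at every frame time", {
  kv <- default_kv(tau = 7.74)
  spec <- speckle_spec(image_shape = c(96L, 96L), n_spots = 30L, seed = 4)
  s <- gen_creep_sequence(kv, duration = 30, dt = 1, spec = spec)
  expect_length(s$frames, 31)                       # one frame per minute
  expect_equal(s$times, 0:30)
  expect_identical(s$gamma_true, kv_strain(s$times, kv))
  expect_equal(s$tau_true, 7.74)

  # tau >> duration: near-linear ramp, almost constant inter-frame growth
  kv_slow <- kv_params(sigma0 = 770, E1 = 2.2e4, E2 = 1.55e4, eta = 1.55e4 * 3000)
  s2 <- gen_creep_sequence(kv_slow, 30, 5, spec = spec)
  inc <- diff(s2$gamma_true)
  expect_lt(diff(range(inc)) / mean(inc), 0.01)

  expect_error(gen_creep_sequence(kv, duration = 3, dt = 1, spec = spec), "5 frames")
  expect_error(kv_params(770, -1, 1, 1), "positive")
})

test_that("colony series areas track the prescribed radii", {
  # four acquisition times, zero boundary noise: area ~ pi r^2 within 1%
  spec <- colony_spec(r0 = 30, growth_rate = 2, frame_times = c(0, 8, 16, 24),
                      boundary_noise = 0, seed = 11)
  s <- gen_colony_series(spec)
  expect_length(s$frames, 4)
  analytic <- pi * (30 + 2 * s$times)^2
  expect_true(all(abs(s$areas_true - analytic) / analytic < 0.01))

  # zero growth: constant truth
  s0 <- gen_colony_series(colony_spec(r0 = 25, growth_rate = 0, seed = 12))
  expect_true(all(s0$areas_true == s0$areas_true[1]))

  # radius overflowing the frame
  expect_error(gen_colony_series(colony_spec(r0 = 60, growth_rate = 4, seed = 1,
                                             image_shape = c(128L, 128L))),
               "half-size")
  expect_error(colony_spec(r0 = 10, growth_rate = 1, frame_times = c(1, 2), seed = 1),
               "first = 0")
})

test_that("live/dead pairs split counts by the dead fraction", {
  s <- gen_livedead_pair(livedead_spec(n_cells = 100, dead_fraction = 0.1,
                                       image_shape = c(300L, 300L), seed = 21))
  expect_equal(s$NL, 90)
  expect_equal(s$ND, 10)
  s0 <- gen_livedead_pair(livedead_spec(n_cells = 40, dead_fraction = 0,
                                        image_shape = c(256L, 256L), seed = 22))
  expect_equal(s0$ND, 0)
  expect_equal(diff(range(s0$red)), 0)              # red channel empty
  s1 <- gen_livedead_pair(livedead_spec(n_cells = 40, dead_fraction = 1,
                                        image_shape = c(256L, 256L), seed = 23))
  expect_equal(s1$NL, 0)
  expect_equal(diff(range(s1$green)), 0)            # green channel empty
  expect_error(gen_livedead_pair(livedead_spec(n_cells = 5000, dead_fraction = 0.5,
                                               image_shape = c(64L, 64L), seed = 2)),
               "packing")
})

test_that("filament scenes carry exact nuclei and centerline ground truth", {
  s <- gen_filament_scene(filament_spec(n_filaments = 6, total_length = 900,
                                        n_nuclei = 5, seed = 31))
  expect_equal(s$Nn, 5)
  expect_equal(s$arc_length, 900)
  # centerline pixel count is within the chain-code bounds of the arc length
  expect_gt(s$Lf, 0.6 * 900)
  expect_lte(s$Lf, 901)
  expect_error(gen_filament_scene(filament_spec(n_filaments = 1, total_length = 1e6,
                                                seed = 1)),
               "unrealizable")
})

test_that("Ct tables encode fold changes on the Ct scale", {
  spec <- ct_spec(c(control = 1, T4 = 4), ct_noise_sd = 0, replicates = 3, seed = 51)
  ct <- gen_ct_table(spec)
  expect_setequal(unique(ct$gene), c("Gapdh", "Mmp14"))
  # fold 4 in the target group: ddCt = -2 by construction
  fc <- fold_change(ct, "Mmp14", "Gapdh", "control")
  expect_equal(fc$per_sample$delta_delta_ct[fc$per_sample$group == "T4"],
               rep(-2, 3))
  expect_error(ct_spec(c(control = 1, T4 = -2), seed = 1), "> 0")
  expect_error(ct_spec(c(control = 2, T4 = 1), seed = 1), "fold change 1")
})

test_that("ground truths survive a TIFF + JSON sidecar round trip", {
  s <- gen_colony_series(colony_spec(r0 = 20, growth_rate = 1, seed = 61,
                                     image_shape = c(128L, 128L)))
  path <- file.path(tempdir(), "colony_rt.tif")
  write_image_sequence(s$frames, path,
                       meta = list(times = s$times, areas_true = s$areas_true),
                       bits = 32L)
  back <- read_image_sequence(path)
  expect_length(back$frames, length(s$frames))
  expect_equal(back$meta$areas_true, s$areas_true)
  expect_equal(back$meta$times, s$times)
  expect_equal(back$frames[[1]], s$frames[[1]], tolerance = 1e-6)
  unlink(c(path, sub("tif$", "json", path)))
})
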