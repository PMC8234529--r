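test_that("colony segmentation recovers disc areas under either polarity", {
  f <- disc_frame(c(200, 200), 100, 100, 50)
  seg <- segment_colony(f)
  expect_lt(abs(seg$area - pi * 50^2) / (pi * 50^2), 0.02)
  # inverted contrast, explicit polarity flag: same region
  seg_inv <- segment_colony(1 - f, polarity = "dark")
  expect_equal(seg_inv$area, seg$area)
  expect_error(segment_colony(matrix(0.5, 64, 64)), "flat")
})

test_that("progression distance is the equivalent-radius difference", {
  expect_equal(progression_distance(100, 100), 0)
  expect_equal(progression_distance(400 * pi, 100 * pi), 10)   # radii 10 -> 20
  # mm-scale: a 0.75 mm radius area growing to 0.85 mm advances 0.10 mm
  expect_equal(progression_distance(pi * 0.85^2, pi * 0.75^2), 0.10)
  expect_lt(progression_distance(50, 100), 0)                  # shrinkage allowed
  expect_error(progression_distance(0, 10), "> 0")
  # identity and monotonicity over a sweep
  a <- seq(10, 1000, length.out = 50)
  expect_true(all(progression_distance(a, a[1]) == cummax(progression_distance(a, a[1]))))
})

test_that("progression rate is the OLS slope of l_t against time", {
  cm <- colony_measure(times = c(0, 8, 16, 24),
                       areas = pi * (10 + 0.625 * c(0, 8, 16, 24))^2)
  r <- progression_rate(cm)
  expect_equal(r$slope, 0.625, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-9)
  flat <- colony_measure(c(0, 8, 16, 24), rep(500, 4))
  expect_equal(progression_rate(flat)$slope, 0)
  expect_error(progression_rate(colony_measure(c(0, 8), c(100, 200))), "3 time points")
  expect_error(colony_measure(c(1, 2, 3), c(1, 2, 3)), "must be 0")
})

test_that("colony series slope recovery tracks the generated growth rate", {
  s <- gen_colony_series(colony_spec(r0 = 25, growth_rate = 2.5, boundary_noise = 1.5,
                                     seed = 401))
  areas <- vapply(s$frames, function(f) segment_colony(f)$area, numeric(1))
  r <- progression_rate(colony_measure(s$times, areas))
  expect_lt(abs(r$slope - 2.5) / 2.5, 0.05)
})

test_that("LoG blob counting finds well-separated cells and ignores contrast", {
  expect_equal(count_live_cells(matrix(0, 100, 100)), 0)
  s <- gen_livedead_pair(livedead_spec(n_cells = 50, dead_fraction = 0,
                                       image_shape = c(300L, 300L), seed = 411))
  n <- count_live_cells(s$green, cell_diameter = 12)
  expect_gte(n, 48); expect_lte(n, 52)
  expect_identical(count_live_cells(s$green * 0.5 + 0.1, cell_diameter = 12), n)
  expect_error(count_live_cells(s$green, cell_diameter = 2), "> 2")
})

test_that("nuclei counting splits touching blobs by watershed", {
  expect_equal(count_nuclei(matrix(0, 64, 64)), 0)
  # ten disjoint blobs
  set.seed(5)
  img <- matrix(0.02, 256, 256)
  cx <- rep(c(30, 80, 130, 180, 230), 2)
  cy <- rep(c(60, 180), each = 5)
  for (i in 1:10) img <- pmax(img, disc_frame(c(256, 256), cx[i], cy[i], 8, fg = 0.9, bg = 0.02))
  expect_equal(count_nuclei(img, "otsu"), 10)
  expect_equal(count_nuclei(img, "mean"), 10)
  # dumbbell: two partially merged discs with distinct cores -> 2 after watershed
  db <- pmax(disc_frame(c(128, 128), 50, 64, 10, fg = 0.9, bg = 0.02),
             disc_frame(c(128, 128), 66, 64, 10, fg = 0.9, bg = 0.02))
  expect_equal(count_nuclei(db, "otsu"), 2)
})

test_that("viability arithmetic follows the printed formulas", {
  v <- viability(90, 10)
  expect_equal(v$dcr_printed, 0.9)
  expect_equal(v$dead_fraction, 0.1)
  expect_equal(v$dcr_printed + v$dead_fraction, 1)
  v2 <- viability(100, 20, control_total = 100)
  expect_equal(v2$cpr, 1.2)
  expect_equal(viability(90, 10, control_total = 100)$cpr, 1)   # control vs itself
  expect_error(viability(0, 0), "NL")
  expect_error(viability(5, 5, control_total = 0), "control_total")
  # complementarity holds across random counts
  set.seed(6)
  for (i in 1:25) {
    nl <- sample(0:500, 1); nd <- sample(0:500, 1)
    if (nl + nd == 0) nl <- 1
    vv <- viability(nl, nd)
    expect_equal(vv$dcr_printed + vv$dead_fraction, 1)
  }
})

test_that("skeleton length of simple shapes matches geometry", {
  bar <- bar_frame(c(120, 160), 20, 60, 100, 5)
  lf <- actin_length(bar)
  expect_gte(as.numeric(lf), 90); expect_lte(as.numeric(lf), 100)
  expect_equal(as.numeric(actin_length(matrix(0, 64, 64))), 0)
  expect_true(isTRUE(attr(actin_length(matrix(0, 64, 64)), "empty")))
  # additivity of disjoint bars
  two <- bar_frame(c(160, 160), 20, 40, 60, 5)
  two[(101):(105), (21):(60)] <- 0.9                 # second bar, 40 px
  l60 <- as.numeric(actin_length(bar_frame(c(160, 160), 20, 40, 60, 5)))
  l40 <- as.numeric(actin_length(bar_frame(c(160, 160), 20, 100, 40, 5)))
  expect_equal(as.numeric(actin_length(two)), l60 + l40, tolerance = 0.06)
})

test_that("skeletonization thins to unit width and intensity scaling is irrelevant", {
  bar <- bar_frame(c(60, 120), 10, 25, 80, 7)
  sk <- skeletonize(bar > 0.5)
  expect_true(all(colSums(sk[, 20:90]) <= 1))        # single-pixel wide mid-span
  f <- gen_filament_scene(filament_spec(n_filaments = 5, total_length = 800,
                                        seed = 421))$actin
  expect_equal(as.numeric(actin_length(f)), as.numeric(actin_length(f * 0.6 + 0.2)))
})

test_that("filament length per cell is Lf/Nn", {
  expect_equal(lfc(100, 1), 100)
  expect_equal(lfc(100, 4), 25)
  expect_equal(lfc(0, 5), 0)
  expect_error(lfc(100, 0), "Nn")
})

test_that("counts and lengths recover generator ground truth end to end", {
  ld <- gen_livedead_pair(livedead_spec(n_cells = 120, dead_fraction = 0.15,
                                        image_shape = c(360L, 360L), seed = 431))
  NL <- count_live_cells(ld$green, cell_diameter = 12)
  ND <- count_nuclei(ld$red, "otsu")
  expect_lte(abs(NL - ld$NL) / ld$NL, 0.05)
  expect_lte(abs(ND - ld$ND) / ld$ND, 0.05)

  fs <- gen_filament_scene(filament_spec(n_filaments = 8, total_length = 1500,
                                         thickness = 3, n_nuclei = 12, seed = 432))
  expect_lte(abs(as.numeric(actin_length(fs$actin)) - fs$Lf) / fs$Lf, 0.1)
  expect_equal(count_nuclei(fs$nuclei, "mean"), 12)
})
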