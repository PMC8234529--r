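test_that("grid construction respects margins and spacing arithmetic", {
  g <- build_grid(c(200, 200), subset_size = 31, spacing = 16, search_radius = 10)
  margin <- (31 - 1) / 2 + 10
  expect_true(all(g$nodes$x >= margin & g$nodes$x <= 199 - margin))
  expect_true(all(g$nodes$y >= margin & g$nodes$y <= 199 - margin))
  expect_equal(g$node_x, seq(25, 169, by = 16))
  expect_error(build_grid(c(60, 60)), "3x3")
  expect_error(build_grid(c(200, 200), roi = c(90, 110, 90, 110)), "3x3")
  expect_error(build_grid(c(200, 200), subset_size = 30), "odd")
})

test_that("subset matching recovers identity, integer and subpixel shifts", {
  spec <- speckle_spec(image_shape = c(128L, 128L), n_spots = 60L,
                       displacement = trans_displacement(0, 0), seed = 71)
  p <- gen_speckle_pair(spec)
  node <- c(63, 63)
  m0 <- match_subset(p$reference, p$reference, node)
  expect_equal(c(m0$u, m0$v), c(0, 0))
  expect_equal(m0$peak_corr, 1, tolerance = 1e-12)

  # integer rigid shift: exact (3, 2), perfect correlation
  p3 <- gen_speckle_pair(speckle_spec(image_shape = c(128L, 128L), n_spots = 60L,
                                      displacement = trans_displacement(3, 2), seed = 72))
  m3 <- match_subset(p3$reference, p3$deformed, node)
  expect_equal(c(m3$u, m3$v), c(3, 2))
  expect_equal(m3$peak_corr, 1, tolerance = 1e-9)

  # half-pixel shift through interpolation: refined estimate inside [2.3, 2.7]
  ph <- gen_speckle_pair(speckle_spec(image_shape = c(128L, 128L), n_spots = 60L,
                                      displacement = trans_displacement(2.5, 0), seed = 73))
  mh <- match_subset(ph$reference, ph$deformed, node)
  expect_gt(mh$u, 2.3); expect_lt(mh$u, 2.7)
  expect_lt(abs(mh$v), 0.3)

  # flat texture is unmatchable
  flat <- matrix(0.5, 128, 128)
  expect_error(match_subset(flat, flat, node), "unmatchable")
})

test_that("integer-lattice matches equal a brute-force NCC argmax", {
  # dual route: compiled ZNCC search vs direct R enumeration with cor()
  set.seed(81)
  for (i in 1:8) {
    disp <- if (i %% 2 == 0) trans_displacement(runif(1, -4, 4), runif(1, -4, 4))
            else strain_displacement(exx = runif(1, -0.02, 0.02),
                                     eyy = runif(1, -0.02, 0.02))
    p <- gen_speckle_pair(speckle_spec(image_shape = c(128L, 128L), n_spots = 60L,
                                       displacement = disp, noise_sd = 0.01,
                                       seed = 800 + i))
    for (node in list(c(50, 50), c(63, 70), c(80, 55))) {
      m <- match_subset(p$reference, p$deformed, node, 21, 7)
      bf <- brute_force_match(p$reference, p$deformed, node, 21, 7)
      expect_equal(c(m$u_int, m$v_int), bf[1:2])
      expect_equal(m$peak_corr, bf[3], tolerance = 1e-10)
    }
  }
})

test_that("displacement fields recover rigid and homogeneous motion", {
  g <- build_grid(c(160, 160))
  p <- gen_speckle_pair(speckle_spec(image_shape = c(160L, 160L), n_spots = 90L,
                                     displacement = trans_displacement(3, 2), seed = 91),
                        grid = g)
  df <- displacement_field(p$reference, p$deformed, g)
  expect_true(all(df$field$valid))
  expect_equal(df$field$u, rep(3, nrow(df$field)))
  expect_equal(df$field$v, rep(2, nrow(df$field)))

  ps <- gen_speckle_pair(speckle_spec(image_shape = c(160L, 160L), n_spots = 90L,
                                      displacement = strain_displacement(exx = 0.02),
                                      seed = 92),
                         grid = g)
  dfs <- displacement_field(ps$reference, ps$deformed, g)
  expect_lt(median(abs(dfs$field$u - ps$truth$u)), 0.2)
})

test_that("translation equivariance: an added integer shift moves u,v, not strain", {
  # keep search windows clear of the border band the shift empties
  g <- build_grid(c(160, 160), search_radius = 12, roi = c(40, 120, 40, 120))
  base <- gen_speckle_pair(speckle_spec(image_shape = c(160L, 160L), n_spots = 90L,
                                        displacement = strain_displacement(exx = 0.015),
                                        seed = 95))
  df1 <- displacement_field(base$reference, base$deformed, g)
  # shift the deformed frame by an exact integer (4, 3)
  shifted <- matrix(0.5, 160, 160)
  shifted[(1 + 3):160, (1 + 4):160] <- base$deformed[1:(160 - 3), 1:(160 - 4)]
  df2 <- displacement_field(base$reference, shifted, g)
  expect_equal(df2$field$u, df1$field$u + 4, tolerance = 1e-6)
  expect_equal(df2$field$v, df1$field$v + 3, tolerance = 1e-6)
  s1 <- green_lagrange(df1)$strain; s2 <- green_lagrange(df2)$strain
  expect_equal(s2$sxx, s1$sxx, tolerance = 1e-8)
  expect_equal(s2$sxy, s1$sxy, tolerance = 1e-8)
})

test_that("Green-Lagrange strain matches the finite-strain formulas", {
  g <- build_grid(c(200, 200))
  # uniform translation: all components zero
  tr <- structure(list(field = data.frame(node_x = g$nodes$x, node_y = g$nodes$y,
                                          u = 5, v = -3, peak_corr = 1, valid = TRUE),
                       grid = g), class = "displacement_field")
  st <- green_lagrange(tr)$strain
  expect_true(all(abs(c(st$sxx, st$syy, st$sxy)) < 1e-12))

  # u = 0.02 x: Sxx = 0.02 + 0.5 * 0.02^2 exactly (linear field, exact FD)
  lin <- structure(list(field = data.frame(node_x = g$nodes$x, node_y = g$nodes$y,
                                           u = 0.02 * g$nodes$x, v = 0,
                                           peak_corr = 1, valid = TRUE),
                        grid = g), class = "displacement_field")
  sl <- green_lagrange(lin)$strain
  expect_equal(sl$sxx, rep(0.0202, nrow(sl)), tolerance = 1e-12)
  expect_true(all(abs(sl$syy) < 1e-12) && all(abs(sl$sxy) < 1e-12))

  # exact rigid rotation: all components vanish (rotation invariance)
  rot <- rotation_field(g, angle = 0.3)
  sr <- green_lagrange(rot)$strain
  expect_lt(max(abs(c(sr$sxx, sr$syy, sr$sxy))), 1e-10)
})

test_that("representative strain is the norm of the median normal strains", {
  g <- build_grid(c(200, 200))
  n <- nrow(g$nodes)
  fake <- structure(list(strain = data.frame(node_x = g$nodes$x, node_y = g$nodes$y,
                                             sxx = rep(0.3, n), syy = rep(0.4, n),
                                             sxy = rep(9, n)),
                         grid = g), class = "strain_field")
  expect_equal(representative_strain(fake), 0.5)        # 3-4-5; shear excluded
  expect_equal(representative_strain(fake, convention = "sum_of_squares"), 0.25)

  zero <- fake; zero$strain$sxx <- 0; zero$strain$syy <- 0
  expect_equal(representative_strain(zero), 0)

  # outliers that do not move the medians leave the result unchanged;
  # invariance under node reordering
  out <- fake
  out$strain$sxx[1:3] <- 50; out$strain$syy[1:3] <- -50
  expect_equal(representative_strain(out), 0.5)
  perm <- out; idx <- sample(n)
  perm$strain <- perm$strain[idx, ]
  expect_equal(representative_strain(perm), representative_strain(out))
})

test_that("strain recovery from images holds under moderate noise", {
  g <- build_grid(c(160, 160))
  applied <- c(0.01, 0.03, -0.02)
  for (i in seq_along(applied)) {
    p <- gen_speckle_pair(speckle_spec(image_shape = c(160L, 160L), n_spots = 90L,
                                       displacement = strain_displacement(exx = applied[i]),
                                       noise_sd = 0.02, seed = 960 + i))
    st <- green_lagrange(displacement_field(p$reference, p$deformed, g))
    med <- median(st$strain$sxx, na.rm = TRUE)
    truth <- applied[i] + 0.5 * applied[i]^2
    expect_lt(abs(med - truth) / abs(truth), 0.1)
  }
})

test_that("field CSV export writes the documented tidy schema", {
  g <- build_grid(c(128, 128))
  p <- gen_speckle_pair(speckle_spec(image_shape = c(128L, 128L), n_spots = 60L,
                                     displacement = trans_displacement(1, 1), seed = 99))
  df <- displacement_field(p$reference, p$deformed, g)
  st <- green_lagrange(df)
  path <- file.path(tempdir(), "field.csv")
  write_field_csv(df, st, path)
  back <- read.csv(path)
  expect_named(back, c("node_x", "node_y", "u", "v", "corr", "sxx", "syy", "sxy"))
  expect_equal(nrow(back), nrow(g$nodes))
  unlink(path)
})
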