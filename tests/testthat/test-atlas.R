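test_that("Procrustes alignment recovers exact and noisy transforms", {
  set.seed(1)
  lm <- matrix(rnorm(18, sd = 3), 6, 3)

  tf0 <- rigid_align(lm, lm)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-9)

  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  target <- sweep(lm %*% t(R), 2, c(1, 2, 3), `+`)
  tf <- rigid_align(lm, target)
  expect_equal(tf$rotation, R, tolerance = 1e-9)
  expect_equal(tf$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(transform_points(lm, tf), target, tolerance = 1e-9)

  # landmark noise SD 0.05 mm: residual RMS stays within 3x the noise SD
  for (s in 1:10) {
    set.seed(100 + s)
    noisy <- target + matrix(rnorm(18, sd = 0.05), 6, 3)
    tfn <- rigid_align(lm, noisy)
    expect_lt(tfn$rmse, 3 * 0.05)
  }

  expect_error(rigid_align(cbind(1:5, 1:5, 1:5), cbind(1:5, 2:6, 1:5)),
               "collinear")
})

test_that("Procrustes fit beats random rigid perturbations", {
  set.seed(2)
  lm <- matrix(rnorm(18, sd = 3), 6, 3)
  target <- sweep(lm %*% t(random_rigid()$rotation), 2, c(4, -1, 2), `+`)
  tf <- rigid_align(lm, target)
  sse <- sum((transform_points(lm, tf) - target)^2)
  for (i in 1:100) {
    perturbed <- random_rigid()
    sse_p <- sum((transform_points(lm, perturbed) - target)^2)
    expect_lte(sse, sse_p + 1e-9)
  }
})

test_that("mean model is idempotent, permutation-invariant and geometric", {
  s10 <- make_sphere(10, n = 28)
  # averaging copies of one mesh reproduces it exactly
  expect_equal(mean_model(list(s10, s10, s10))$vertices, s10$vertices,
               tolerance = 1e-12)

  s9 <- make_sphere(9, n = 28)
  s11 <- make_sphere(11, n = 28)
  mm <- mean_model(list(s9, s11, s10), template = 3)
  rr <- sqrt(rowSums(mm$vertices^2))
  # tessellation chord error bound at n = 28: well under 0.05
  expect_true(all(abs(rr - 10) < 0.05))

  mm2 <- mean_model(list(s10, s9, s11), template = 1)
  mm3 <- mean_model(list(s9, s11, s10), template = 3)
  expect_equal(mm2$vertices, mm3$vertices, tolerance = 1e-12)

  expect_error(mean_model(list(s10)), "at least 2")
})

test_that("signed distance map: zero case, sign, clamping, antisymmetry", {
  s10 <- make_sphere(10, n = 24)
  s11 <- make_sphere(11, n = 24)

  cm0 <- distance_colour_map(s10, s10)
  expect_true(all(cm0$distance == 0))
  expect_true(all(cm0$rgb[, 2] == 255L & cm0$rgb[, 1] == 0L &
                    cm0$rgb[, 3] == 0L))

  cm <- distance_colour_map(s11, s10)
  expect_true(all(cm$distance > 0.95 & cm$distance < 1.05))
  expect_true(all(cm$rgb[, 1] > 0 & cm$rgb[, 3] == 0))  # red half

  big <- s10
  big$vertices <- big$vertices * 1.6                     # +6 mm offset
  cmb <- distance_colour_map(big, s10)
  expect_true(all(cmb$rgb[, 1] == 255L & cmb$rgb[, 2] == 0L &
                    cmb$rgb[, 3] == 0L))                 # clamped pure red
  small <- s10
  small$vertices <- small$vertices * 0.4
  cms <- distance_colour_map(small, s10)
  expect_true(all(cms$rgb[, 3] == 255L & cms$rgb[, 2] == 0L))  # pure blue

  # swapping model and reference negates distances up to tessellation error
  edge <- 2 * pi * 10 / 48
  cm_r <- distance_colour_map(s10, s11)
  expect_lt(max(abs(cm_r$distance + mean(cm$distance))), edge)

  expect_error(distance_colour_map(list(vertices = matrix(0, 0, 3),
                                        faces = matrix(0L, 0, 3)), s10),
               "empty")
})

test_that("colour ramp is monotone with the stated anchors", {
  d <- seq(-2, 2, by = 0.05)
  rgbm <- distance_colours(d, bound = 1.145)
  expect_equal(rgbm[d == 0, ], c(red = 0L, green = 255L, blue = 0L))
  expect_true(all(rgbm[d <= -1.145, 3] == 255L))
  expect_true(all(rgbm[d >= 1.145, 1] == 255L))
  expect_true(all(diff(rgbm[, 1]) >= 0))   # red channel non-decreasing
  expect_true(all(diff(rgbm[, 3]) <= 0))   # blue channel non-increasing
})

test_that("end-to-end atlas contrasts normal vs conical anatomy", {
  res <- c(20L, 20L)
  nrt <- lapply(sample_tooth_profiles(2, "normal", seed = 4,
                                      mesh_resolution = res),
                generate_tooth)
  crt <- lapply(sample_tooth_profiles(2, "conical", seed = 5,
                                      mesh_resolution = res),
                generate_tooth)
  # misalign one mesh deliberately; registration must undo it
  tf <- random_rigid()
  nrt[[2]] <- transform_points(nrt[[2]], tf)
  at <- shape_atlas(nrt, crt)
  # mid-root: normal roots lie outside the conical reference (red side)
  midroot <- at$map$reference$vertices[, 3] > -8 &
    at$map$reference$vertices[, 3] < -3
  expect_gt(mean(at$map$distance[midroot] > 0), 0.8)
})
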