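test_that("profile validation enforces the stated invariants", {
  expect_error(tooth_profile("normal", root_length = -1), "root_length")
  expect_error(tooth_profile("normal", cervical_halfwidth_md = 0),
               "halfwidths")
  expect_error(tooth_profile("normal", mesh_resolution = c(4, 64)),
               "mesh_resolution")
  expect_error(tooth_profile("normal", apex_radius = 20), "apex_radius")
})

test_that("conical taper is strictly narrower than normal at equal dims", {
  pn <- tooth_profile("normal", root_length = 12, cervical_halfwidth_md = 4,
                      cervical_halfwidth_bl = 4, apex_radius = 0)
  pc <- tooth_profile("conical", root_length = 12, cervical_halfwidth_md = 4,
                      cervical_halfwidth_bl = 4, apex_radius = 0)
  z <- seq(-11.9, -0.1, length.out = 50)
  expect_true(all(rootmorph:::profile_g(pc, z) <
                    rootmorph:::profile_g(pn, z)))
  expect_lt(rootmorph:::profile_volume(pc, -12, 0),
            rootmorph:::profile_volume(pn, -12, 0))
})

test_that("sharp circular cone reproduces the closed forms exactly", {
  pr <- tooth_profile("conical", root_length = 12, cervical_halfwidth_md = 4,
                      cervical_halfwidth_bl = 4, crown_height = 0,
                      apex_radius = 0, mesh_resolution = c(64, 64))
  gt <- profile_ground_truth(pr)
  expect_equal(gt$root_lateral_area, pi * 4 * sqrt(160), tolerance = 1e-7)
  expect_equal(gt$root_volume, pi * 16 * 12 / 3, tolerance = 1e-9)
  expect_equal(gt$RL, 12)
})

test_that("mesh area/volume match the independent Riemann oracle", {
  # elliptical paraboloid-like profile, p = 0.5, a = 4, b = 3, L = 12
  pr <- tooth_profile("normal", root_length = 12, cervical_halfwidth_md = 4,
                      cervical_halfwidth_bl = 3, crown_height = 0,
                      apex_radius = 0, mesh_resolution = c(200, 200))
  oracle <- riemann_profile_oracle(4, 3, 12, 0.5)
  gt <- profile_ground_truth(pr)
  expect_equal(gt$root_lateral_area, oracle$area, tolerance = 1e-4)
  expect_equal(gt$root_volume, oracle$volume, tolerance = 1e-5)

  m <- generate_tooth(pr)
  base_area <- pi * 4 * 3                 # flat CEJ disc closes the solid
  expect_equal(surface_area(m) - base_area, oracle$area, tolerance = 0.005)
  expect_equal(enclosed_volume(m), oracle$volume, tolerance = 0.005)
})

test_that("mesh metrics converge to ground truth on a doubling ladder", {
  pr0 <- tooth_profile("normal", root_length = 12, cervical_halfwidth_md = 4,
                       cervical_halfwidth_bl = 3, crown_height = 0,
                       apex_radius = 0)
  gt <- profile_ground_truth(pr0)
  errs <- vapply(c(25, 50, 100, 200), function(n) {
    pr <- tooth_profile("normal", root_length = 12,
                        cervical_halfwidth_md = 4, cervical_halfwidth_bl = 3,
                        crown_height = 0, apex_radius = 0,
                        mesh_resolution = c(n, n))
    m <- generate_tooth(pr)
    abs(enclosed_volume(m) / gt$root_volume - 1)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[length(errs)], 0.005)
})

test_that("generated teeth are watertight with on-surface landmarks", {
  for (cls in c("normal", "conical")) {
    m <- generate_tooth(tooth_profile(cls, mesh_resolution = c(24, 24)))
    expect_true(is_closed_mesh(m))
    for (lmk in m$landmarks) {
      cp <- closest_on_mesh(rbind(lmk), m)
      expect_lt(cp$distance, 1.0)
    }
    # apex strictly on the root side of the CEJ plane
    expect_lt(m$landmarks$apex[3], 0)
  }
})

test_that("cohort generator honours the degenerate and determinism contracts", {
  spec0 <- population_spec(n_nrt = 5, n_crt = 4,
                           nrt_sd = c(RL = 0, PRW = 0, RSA = 0, RV = 0,
                                      RSA_RL = 0, RV_RL = 0),
                           crt_sd = c(RL = 0, PRW = 0, RSA = 0, RV = 0,
                                      RSA_RL = 0, RV_RL = 0), seed = 3)
  ch <- generate_cohort(spec0)
  expect_true(all(ch$RSA[ch$group == "NRT"] == 236.88))
  expect_true(all(ch$RV_RL[ch$group == "CRT"] == 21.76))

  a <- generate_cohort(population_spec(seed = 11))
  b <- generate_cohort(population_spec(seed = 11))
  expect_identical(a, b)
  c2 <- generate_cohort(population_spec(seed = 12))
  expect_false(identical(a, c2))

  expect_error(generate_cohort(population_spec(n_nrt = 1)), "> 1")
})

test_that("replicated cohorts recover the reference NRT RSA mean", {
  n_rep <- 10000L
  tot <- 0
  for (i in seq_len(n_rep)) {
    ch <- generate_cohort(population_spec(seed = 20000 + i))
    tot <- tot + sum(ch$RSA[ch$group == "NRT"])
  }
  se <- 27.93 / sqrt(54 * n_rep)
  expect_lt(abs(tot / (54 * n_rep) - 236.88), 3 * se)
})

test_that("correlated draws honour the requested correlation", {
  cor6 <- diag(6)
  cor6[1, 2] <- cor6[2, 1] <- 0.8
  sp <- population_spec(n_nrt = 4000, n_crt = 2, correlation = cor6,
                        seed = 9)
  ch <- generate_cohort(sp)
  nrt <- ch[ch$group == "NRT", ]
  expect_equal(cor(nrt$RL, nrt$PRW), 0.8, tolerance = 0.05)
  expect_lt(abs(cor(nrt$RSA, nrt$RV)), 0.08)
})

test_that("projection produces PRW-ready silhouettes", {
  # straight-sided cone: silhouette margins coincide with the chords
  cone <- generate_tooth(tooth_profile("conical", root_length = 12,
                                       cervical_halfwidth_md = 2,
                                       cervical_halfwidth_bl = 2,
                                       crown_height = 0, apex_radius = 0,
                                       mesh_resolution = c(100, 100)))
  p0 <- prw(project_to_radiograph(cone))
  expect_equal(p0$prw, 0, tolerance = 1e-9)

  # parabolic profile, cervical width W = 4: closed-form margin
  # x(y) = (W/2) sqrt(1 - y/L) gives PRW = (W/2)(sqrt(2) - 1)/sqrt(2)... =
  # ((sqrt(0.5) - 0.5) * W)/2 at the mid-chord level
  par <- generate_tooth(tooth_profile("normal", root_length = 12,
                                      cervical_halfwidth_md = 2,
                                      cervical_halfwidth_bl = 2,
                                      crown_height = 0, apex_radius = 0,
                                      mesh_resolution = c(200, 100)))
  p1 <- prw(project_to_radiograph(par))
  expect_equal(p1$prw, (2 * sqrt(2) - 2) / 2, tolerance = 0.005)

  # rotating the mesh about the projection axis leaves PRW unchanged
  th <- 0.7
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  tf <- structure(list(rotation = R, translation = c(0, 0, 0), rmse = 0),
                  class = "rigid_transform")
  rot <- transform_points(par, tf)
  p2 <- prw(project_to_radiograph(rot))
  expect_equal(p2$prw, p1$prw, tolerance = 1e-6)

  expect_error(project_to_radiograph(par, direction = c(1, 0, 0)),
               "mesiodistal")
})
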