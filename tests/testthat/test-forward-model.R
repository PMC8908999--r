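canon <- microstructure_params(0.4, 0.45, 0.15)

test_that("compartment attenuations follow the stick/zeppelin/ball closed forms", {
  expect_equal(compartment_signal(canon, 0, c(1, 0, 0)),
               c(intra = 1, extra = 1, free = 1))
  # ball: exp(-b D_f)
  expect_equal(compartment_signal(canon, 1, c(1, 0, 0))[["free"]], exp(-3))
  # stick symmetry: perpendicular gradient sees no attenuation,
  # parallel sees exp(-b D_i)
  expect_equal(compartment_signal(canon, 1, c(1, 0, 0))[["intra"]], 1)
  expect_equal(compartment_signal(canon, 1, c(0, 0, 1))[["intra"]], exp(-2))
  # zeppelin: perp and parallel limits
  expect_equal(compartment_signal(canon, 1, c(1, 0, 0))[["extra"]], exp(-0.5))
  expect_equal(compartment_signal(canon, 1, c(0, 0, 1))[["extra"]], exp(-1.5))

  expect_error(compartment_signal(canon, -1, c(1, 0, 0)), "non-negative")
  expect_error(compartment_signal(canon, 1, c(1, 1, 0)), "unit")
})

test_that("microstructure parameters are validated", {
  expect_error(microstructure_params(0.5, 0.5, 0.5), "sum to 1")
  expect_error(microstructure_params(-0.1, 0.9, 0.2), "\\[0, 1\\]")
  expect_error(microstructure_params(0.3, 0.3, 0.4, D_e_par = 0.4,
                                     D_e_perp = 0.6), "D_e_perp")
  expect_error(microstructure_params(0.3, 0.3, 0.4, s0 = 0), "s0")
  expect_error(microstructure_params(0.3, 0.3, 0.4,
                                     orientation = c(1, 1, 0)), "unit")
})

test_that("voxel signal collapses, normalizes and decays as expected", {
  sch <- the_scheme
  # single-compartment collapse to the ball
  ball <- microstructure_params(0, 0, 1)
  s <- voxel_signal(ball, sch)
  expect_equal(s[sch$bvalues == 1], rep(exp(-3), 30))
  # b = 0 volumes give exactly s0
  p2 <- microstructure_params(0.4, 0.45, 0.15, s0 = 7)
  expect_equal(voxel_signal(p2, sch)[sch$bvalues == 0], 7)
  # fixed direction, increasing b: non-increasing signal
  g <- sch$directions[2, ]
  tri <- acquisition_scheme(c(0, 1, 2), rbind(c(0, 0, 0), g, g))
  s3 <- voxel_signal(canon, tri)
  expect_true(all(diff(s3) <= 0))
})

test_that("voxel signal is invariant under joint rotation of orientation and gradients", {
  sch <- the_scheme
  base <- voxel_signal(canon, sch)
  withr::with_seed(11, {
    for (k in 1:5) {
      rot <- dmisim:::random_rotation()
      p_rot <- microstructure_params(0.4, 0.45, 0.15,
                                     orientation = as.numeric(rot %*% c(0, 0, 1)))
      sch_rot <- acquisition_scheme(sch$bvalues, sch$directions %*% t(rot))
      expect_equal(voxel_signal(p_rot, sch_rot), base, tolerance = 1e-10)
    }
  })
})

test_that("voxel signal is linear in the volume fractions", {
  sch <- the_scheme
  pa <- microstructure_params(1, 0, 0)
  pb <- microstructure_params(0, 1, 0)
  pc <- microstructure_params(0, 0, 1)
  mix <- microstructure_params(0.2, 0.5, 0.3)
  expect_equal(voxel_signal(mix, sch),
               0.2 * voxel_signal(pa, sch) + 0.5 * voxel_signal(pb, sch) +
                 0.3 * voxel_signal(pc, sch),
               tolerance = 1e-12)
})

test_that("spherical means match the quadrature oracle", {
  # frozen value from the quadrature oracle: b = 1, D_i = 2
  expect_equal(spherical_mean(canon, 1)[["intra"]], 0.59814, tolerance = 1e-4)
  expect_equal(spherical_mean(canon, 1)[["intra"]],
               quadrature_stick_mean(1, 2), tolerance = 1e-5)
  # isotropic zeppelin limit
  iso <- microstructure_params(0.4, 0.45, 0.15, D_e_par = 1, D_e_perp = 1)
  expect_equal(spherical_mean(iso, 1)[["extra"]], exp(-1))
  # ball is its own spherical mean
  expect_equal(spherical_mean(canon, 1)[["free"]], exp(-3))
  expect_error(spherical_mean(canon, 0), "positive")
  # continuity across the small-anisotropy switch of the zeppelin
  near <- microstructure_params(0.4, 0.45, 0.15, D_e_par = 1 + 1e-9,
                                D_e_perp = 1)
  expect_equal(spherical_mean(near, 1)[["extra"]], exp(-1), tolerance = 1e-8)
})

test_that("powder average of the voxel signal equals the fraction-weighted spherical means", {
  dirs <- dmisim:::fibonacci_sphere(4000)
  for (b in c(1, 2)) {
    # the dense shell of interest plus one extra volume to satisfy the
    # two-shell scheme invariant
    sch <- acquisition_scheme(c(0, rep(b, 4000), b + 1),
                              rbind(c(0, 0, 0), dirs, c(0, 0, 1)))
    s <- voxel_signal(canon, sch)
    powder <- mean(s[2:4001])
    sm <- spherical_mean(canon, b)
    expect_equal(powder,
                 0.4 * sm[["intra"]] + 0.45 * sm[["extra"]] + 0.15 * sm[["free"]],
                 tolerance = 1e-3)
  }
})

test_that("Rician noise is degenerate at sigma 0, seeded, and has the Rice second moment", {
  s <- rep(1, 1e5)
  expect_identical(add_rician_noise(s, 0, seed = 1), s)
  n1 <- add_rician_noise(s, 0.05, seed = 7)
  n2 <- add_rician_noise(s, 0.05, seed = 7)
  expect_identical(n1, n2)
  expect_error(add_rician_noise(s, -0.1, seed = 1), "non-negative")
  # E[M^2] = S^2 + 2 sigma^2
  expect_equal(mean(n1^2), 1 + 2 * 0.05^2, tolerance = 1e-3)
})
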