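test_that("structural mean and RSD evaluate their closed forms", {
  m <- ivsd_model()
  # hand arithmetic: 6.055 * 1.76^-0.020 + 0.031 * 13
  expect_equal(structural_mean(m, 1.76, 13),
               6.055 * exp(-0.020 * log(1.76)) + 0.403, tolerance = 1e-12)
  expect_equal(round(structural_mean(m, 1.76, 13), 3), 6.390)
  # BSA = 1, age = 0: exponent term collapses to a
  expect_equal(structural_mean(m, 1, 0), 6.055, tolerance = 1e-12)
  # alternative parse places age in the exponent: 6.055 * 1.76^0.383
  me <- ivsd_model(mean_form = "exponent_age")
  expect_equal(structural_mean(me, 1.76, 13),
               6.055 * exp(0.383 * log(1.76)), tolerance = 1e-12)
  expect_equal(round(structural_mean(me, 1.76, 13), 4), 7.5187)
  # RSD hand arithmetic
  expect_equal(structural_rsd(m, 1.76, 13), 1.10512, tolerance = 1e-12)
  expect_equal(structural_rsd(m, 1.0, 18), 1.018, tolerance = 1e-12)
  hom <- structural_model("x", a = 5, b = 0.3, c = 0.1, d = 0.7, e = 0, f = 0)
  expect_equal(structural_rsd(hom, 1.3, 15), 0.7)
  expect_error(structural_mean(m, -1, 13), "positive")
})

test_that("functional mean and RSD evaluate their closed forms", {
  m <- eeprime_model()
  expect_equal(functional_mean(m, 15), 0.009 * 225 - 0.418 * 15 + 10.485,
               tolerance = 1e-12)
  expect_equal(round(functional_mean(m, 15), 2), 6.24)
  expect_equal(round(functional_mean(m, 11), 3), 6.976)
  const <- functional_model("k", a = 0, b = 0, c = 4.2, d = 1, e = 0, unit = "")
  expect_equal(functional_mean(const, c(11, 18)), c(4.2, 4.2))
  expect_equal(functional_rsd(m, 15), 1.038, tolerance = 1e-12)
  expect_equal(functional_rsd(m, 18), 0.963, tolerance = 1e-12)
  expect_equal(functional_rsd(const, 13), 1)
})

test_that("compute_z reproduces the published worked examples", {
  z1 <- compute_z(8.5, ivsd_model(), bsa = 1.76, age = 13)
  expect_equal(round(z1$z, 2), 1.91)
  expect_false(z1$out_of_range)
  expect_false(z1$hr_caution)
  # the exponent-age parse does not reproduce the printed example
  z1e <- compute_z(8.5, ivsd_model("exponent_age"), bsa = 1.76, age = 13)
  expect_equal(round(z1e$z, 2), 0.89)

  z2 <- compute_z(4.3, eeprime_model(), age = 15)
  expect_equal(round(z2$z, 2), -1.87)  # signed; the printed value is |z|
  expect_equal(round(abs(z2$z), 2), 1.87)

  # observation at the mean: z = 0, centile 50
  mu <- structural_mean(ivsd_model(), 1.5, 14)
  z0 <- compute_z(mu, ivsd_model(), bsa = 1.5, age = 14)
  expect_equal(z0$z, 0)
  expect_equal(z0$centile, 50)
})

test_that("compute_z enforces covariates, flags, and the LVEF rule", {
  expect_error(compute_z(8.5, ivsd_model(), age = 13), "bsa")
  expect_error(compute_z(4.3, eeprime_model()), "age")
  # HR-dependent measures carry the caution flag
  a_mod <- functional_model("A", a = 0.05, b = -2, c = 70, d = 10, e = -0.1)
  expect_true(compute_z(50, a_mod, age = 14)$hr_caution)
  expect_false(compute_z(4.3, eeprime_model(), age = 15)$hr_caution)
  # out-of-range and envelope flags
  zz <- compute_z(12, ivsd_model(), bsa = 1.5, age = 14)
  expect_true(zz$out_of_range)
  expect_false(zz$out_of_envelope)
  expect_true(compute_z(8, ivsd_model(), bsa = 0.5, age = 14)$out_of_envelope)
  # LVEF: z from constant mean/SD; limit at mean - 2 SD
  lv <- lvef_model(60, 5.8)
  expect_equal(lv$lower_reference_limit, 48.4)
  expect_equal(compute_z(48.4, lv)$z, -2)
  expect_equal(lvef_model(60, 5.8, n_sd = 1.96)$lower_reference_limit,
               60 - 1.96 * 5.8)
  expect_error(lvef_model(10, 20), "lower reference limit")
})

test_that("model constructors reject SD surfaces invalid on the envelope", {
  expect_error(structural_model("bad", a = 5, b = 0.3, c = 0.1,
                                d = 0.1, e = 0.02, f = -0.02),
               "non-positive")
  expect_error(functional_model("bad", a = 0, b = 0, c = 5, d = 0.3, e = -0.02),
               "non-positive")
  expect_error(structural_model("bad", a = -1, b = 0.3, c = 0.1,
                                d = 1, e = 0, f = 0), "positive")
})

test_that("invert_z is the exact inverse of compute_z", {
  m <- ivsd_model()
  expect_equal(invert_z(m, 0, bsa = 1.76, age = 13),
               structural_mean(m, 1.76, 13), tolerance = 1e-12)
  expect_equal(invert_z(m, 2, bsa = 1.76, age = 13),
               structural_mean(m, 1.76, 13) + 2 * 1.10512, tolerance = 1e-12)
  expect_equal(round(invert_z(m, 2, bsa = 1.76, age = 13), 3), 8.600)
  # property sweep across both families and a covariate grid
  fm <- eeprime_model()
  for (z in c(-2.5, -1.3, 0, 0.7, 2.2)) {
    for (bsa in c(0.9, 1.6, 2.3)) {
      for (age in c(11, 14.5, 18)) {
        obs <- invert_z(m, z, bsa = bsa, age = age)
        expect_equal(compute_z(obs, m, bsa = bsa, age = age)$z, z,
                     tolerance = 1e-12)
      }
    }
    obs <- invert_z(fm, z, age = 16)
    expect_equal(compute_z(obs, fm, age = 16)$z, z, tolerance = 1e-12)
  }
})

test_that("z is invariant to unit rescaling with rescaled coefficients", {
  m_mm <- ivsd_model()
  m_cm <- structural_model("IVSd", a = 6.055 / 10, b = -0.020, c = 0.031 / 10,
                           d = 1.100 / 10, e = 0.062 / 10, f = -0.008 / 10,
                           unit = "cm")
  for (bsa in c(1.0, 1.76, 2.2)) {
    for (age in c(11, 13, 18)) {
      obs <- 8.5
      expect_equal(compute_z(obs, m_mm, bsa = bsa, age = age)$z,
                   compute_z(obs / 10, m_cm, bsa = bsa, age = age)$z,
                   tolerance = 1e-12)
    }
  }
})

test_that("nomogram tables match pointwise inversion and are monotone in z", {
  m <- ivsd_model()
  one <- nomogram_table(m, tibble::tibble(bsa = 1.5, age = 14), z_lines = 0)
  expect_equal(nrow(one), 1)
  expect_equal(one$value, structural_mean(m, 1.5, 14), tolerance = 1e-12)

  tab <- nomogram_table(m, c(1.0, 1.5, 2.0), age = 14)
  expect_equal(nrow(tab), 15)
  for (b in unique(tab$bsa)) {
    expect_true(all(diff(tab$value[tab$bsa == b]) > 0))
  }

  fm <- eeprime_model()
  ftab <- nomogram_table(fm, 11:18)
  expect_equal(nrow(ftab), 40)
  expect_equal(ftab$value,
               functional_mean(fm, ftab$age) + ftab$z * functional_rsd(fm, ftab$age),
               tolerance = 1e-12)
  expect_error(nomogram_table(m, tibble::tibble(bsa = numeric(), age = numeric())),
               "empty")
})
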