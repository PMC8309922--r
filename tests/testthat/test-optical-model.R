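# Chromophore mixtures and per-layer absorption coefficients.

tab <- chromophore_table()

test_that("baseline and melanin power laws evaluate correctly", {
  expect_equal(baseline_absorption(660), 7.84e7 * 660^-3.255,
               tolerance = 1e-10)
  expect_equal(baseline_absorption(660), 0.052084, tolerance = 1e-4)
  expect_equal(baseline_absorption(940), 0.016473, tolerance = 1e-4)
  expect_equal(melanin_absorption(660), 6.6e10 * 660^-3.3, tolerance = 1e-10)
  expect_equal(melanin_absorption(660), 32.7378, tolerance = 1e-4)
  expect_equal(melanin_absorption(940), 10.1911, tolerance = 1e-4)
  lam <- seq(500, 1000, by = 25)
  expect_true(all(diff(baseline_absorption(lam)) < 0))
  expect_true(all(diff(melanin_absorption(lam)) < 0))
  expect_warning(baseline_absorption(350), "band")
})

test_that("blood absorption mixes hemoglobins and the glucose term", {
  expect_equal(arterial_blood_absorption(940, 1.0, 0, tab), 0.1728)
  expect_equal(arterial_blood_absorption(660, 0, 0, tab), 0.065)
  expect_equal(arterial_blood_absorption(940, 0.97, 0, tab),
               0.97 * 0.1728 + 0.03 * 0.037, tolerance = 1e-10)
  expect_equal(venous_blood_absorption(940, 0.87, 0, tab),
               0.87 * 0.1728 + 0.13 * 0.037, tolerance = 1e-10)
  # identical functional form for arterial and venous
  expect_equal(arterial_blood_absorption(660, 0.8, 0.005, tab),
               venous_blood_absorption(660, 0.8, 0.005, tab))
  # glucose term: 0.1 * eps_g * cg (cm^-1 -> mm^-1)
  expect_equal(arterial_blood_absorption(940, 0.9, 0.008, tab) -
                 arterial_blood_absorption(940, 0.9, 0, tab),
               0.1 * 0.001 * 0.008, tolerance = 1e-6)
  expect_error(arterial_blood_absorption(800, 0.9, 0, tab), "800")
})

test_that("epidermis absorption composes melanin, water and baseline", {
  expect_equal(epidermis_absorption(660, 0.10, 0.20, tab),
               0.10 * melanin_absorption(660) + 0.20 * 0.00041 +
                 0.70 * baseline_absorption(660), tolerance = 1e-10)
  expect_equal(epidermis_absorption(660, 0.10, 0.20, tab), 3.3110,
               tolerance = 1e-3)
  expect_equal(epidermis_absorption(660, 0, 0, tab),
               baseline_absorption(660))
  expect_equal(epidermis_absorption(660, 1, 0, tab),
               melanin_absorption(660))
  expect_error(epidermis_absorption(660, 0.6, 0.5, tab), "exceed 1")
})

test_that("stratum corneum absorption matches its closed form", {
  expect_equal(stratum_corneum_absorption(660, 0.05, tab),
               ((0.1 - 0.3e-4 * 660) + 0.125 * baseline_absorption(660)) *
                 0.95 + 0.05 * 0.00041, tolerance = 1e-10)
  expect_equal(stratum_corneum_absorption(660, 0.05, tab), 0.08240,
               tolerance = 1e-4)
  expect_equal(stratum_corneum_absorption(940, 1, tab), 0.00181811)
  for (wl in c(660, 940))
    expect_gte(stratum_corneum_absorption(wl, 0.05, tab), 0)
})

test_that("dermal absorption composes its four constituents", {
  st <- physio_state(sao2 = 0.97, cg_mol_per_l = 0)
  got <- dermal_absorption(940, 0.025, 0.025, 0.5, st, tab)
  want <- 0.025 * (0.97 * 0.1728 + 0.03 * 0.037) +
    0.025 * (0.87 * 0.1728 + 0.13 * 0.037) +
    0.5 * 0.00181811 + 0.45 * baseline_absorption(940)
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(got, 0.01642, tolerance = 1e-3)
  expect_equal(dermal_absorption(660, 0, 0, 0, st, tab),
               baseline_absorption(660))
  expect_error(dermal_absorption(660, 0.5, 0.4, 0.2, st, tab), "sum")
  # strictly increasing in glucose
  mus <- sapply(c(0, 0.004, 0.008), function(cg)
    dermal_absorption(940, 0.1, 0.1, 0.6,
                      physio_state(0.97, cg), tab))
  expect_true(all(diff(mus) > 0))
})

test_that("physio_state derives and clamps the venous saturation", {
  expect_equal(physio_state(0.95, 0)$svo2, 0.85)
  expect_equal(physio_state(0.05, 0)$svo2, 0)
  expect_error(physio_state(1.2, 0), "svo2")
  expect_error(physio_state(0.9, -1), "glucose")
})

test_that("build_medium assigns per-layer optics in analytic mode", {
  m <- default_finger_model()
  st <- reference_state()
  med <- build_medium(m, 940, st, mode = "analytic")
  expect_equal(nrow(med), 9)
  expect_equal(med$mua[9], 0.0457)    # bone: fixed printed value
  expect_equal(med$mus, m$layers$mus_940)
  expect_equal(med$n, m$layers$n)
  # at 660 nm the melanin-rich epidermis dominates the skin sublayers
  med660 <- build_medium(m, 660, st)
  expect_equal(which.max(med660$mua[1:6]), 2)
  # glucose only perturbs the four blood-bearing dermal layers
  lo <- build_medium(m, 940, physio_state(0.97, 0.003))
  hi <- build_medium(m, 940, physio_state(0.97, 0.008))
  expect_equal(which(lo$mua != hi$mua), 3:6)
})

test_that("table5_anchored mode pins printed values at the reference state", {
  m <- default_finger_model()
  med <- build_medium(m, 660, reference_state(), mode = "table5_anchored")
  expect_equal(med$mua[3], 0.04624)   # papillary dermis
  expect_equal(med$mua, m$layers$mua_table5_660)
  # sensitivity to saturation is retained away from the reference
  med2 <- build_medium(m, 940, physio_state(0.80, 5.5e-3),
                       mode = "table5_anchored")
  ref2 <- build_medium(m, 940, reference_state(), mode = "table5_anchored")
  expect_true(all(med2$mua[3:6] < ref2$mua[3:6]))  # less HbO2 at 940
  expect_equal(med2$mua[c(1, 2, 7, 8, 9)], ref2$mua[c(1, 2, 7, 8, 9)])
})

test_that("glucose sensitivity of layer absorption is exactly Vb*0.1*eps_g", {
  m <- default_finger_model()
  for (mode in c("analytic", "table5_anchored")) {
    for (wl in c(660, 940)) {
      eps <- tab$eps_glucose[match(wl, tab$wavelength_nm)]
      lo <- build_medium(m, wl, physio_state(0.9, 0.002), mode = mode)
      hi <- build_medium(m, wl, physio_state(0.9, 0.007), mode = mode)
      slope <- (hi$mua - lo$mua) / 0.005
      expect_equal(slope[3:6], m$layers$vb[3:6] * 0.1 * eps,
                   tolerance = 1e-9)
    }
  }
})

test_that("absorption stays finite and nonnegative over the state grid", {
  m <- default_finger_model()
  for (wl in c(660, 940))
    for (sao2 in c(0.7, 0.85, 1.0))
      for (cg in c(0, 0.005, 0.01)) {
        med <- build_medium(m, wl, physio_state(sao2, cg))
        expect_true(all(is.finite(med$mua)) && all(med$mua >= 0))
      }
})
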