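# Transport primitives and whole-simulation oracles.

test_that("step sampling follows -ln(xi)/(mua+mus)", {
  expect_equal(sample_step(exp(-1), 5, 5), 0.1)
  expect_equal(sample_step(0.5, 1, 1), log(2) / 2)
  expect_equal(sample_step(1 - 1e-12, 2, 8), 1e-12 / 10, tolerance = 1e-3)
  expect_identical(sample_step(0.5, 0, 0), Inf)
  expect_error(sample_step(0, 1, 1))
})

test_that("step lengths in a homogeneous medium are exponential", {
  set.seed(11)
  l <- sample_step(runif(1e5), 2, 8)
  ks <- suppressWarnings(stats::ks.test(l, stats::pexp, rate = 10))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(l), 1 / 10, tolerance = 0.02)
})

test_that("Henyey-Greenstein cosine sampling matches the inverse transform", {
  expect_equal(sample_scatter_cosine(0, 0.25), 0.5)  # isotropic branch
  g <- 0.9
  xi <- 0.5
  t <- (1 - g^2) / (1 - g + 2 * g * xi)
  expect_equal(sample_scatter_cosine(g, xi), (1 + g^2 - t^2) / (2 * g),
               tolerance = 1e-12)
  expect_equal(sample_scatter_cosine(0.9, 0.5), 0.98550, tolerance = 1e-5)
  expect_true(all(abs(sample_scatter_cosine(0.99, runif(1000))) <= 1))
})

test_that("HG sample moments match anisotropy and the density integral", {
  set.seed(4)
  for (g in c(0, 0.8)) {
    x <- sample_scatter_cosine(g, runif(1e6))
    expect_lt(abs(mean(x) - g), 3 * sd(x) / sqrt(length(x)))
    # independent oracle: numerical second moment of the HG density
    if (g == 0) {
      m2 <- 1 / 3
    } else {
      dens <- function(c) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * c)^1.5
      m2 <- stats::integrate(function(c) c^2 * dens(c), -1, 1,
                             rel.tol = 1e-10)$value
    }
    se2 <- sd(x^2) / sqrt(length(x))
    expect_lt(abs(mean(x^2) - m2), 3 * se2)
  }
})

test_that("direction rotation preserves the deflection cosine and norm", {
  expect_equal(rotate_direction(c(0, 0, 1), 1, 2.1), c(0, 0, 1))
  expect_equal(rotate_direction(c(0, 0, 1), -1, 0.3), c(0, 0, -1))
  expect_equal(rotate_direction(c(0, 0, -1), 0.5, 0)[3], -0.5)
  set.seed(5)
  for (i in 1:200) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    ct <- runif(1, -1, 1); psi <- runif(1, 0, 2 * pi)
    v <- rotate_direction(u, ct, psi)
    expect_equal(sum(v^2), 1, tolerance = 1e-9)
    expect_equal(sum(u * v), ct, tolerance = 1e-9)
  }
})

test_that("Fresnel interaction reproduces closed-form reflectances", {
  # normal incidence air -> glass-like skin: ((1-1.5)/(1+1.5))^2 = 0.04
  f <- fresnel_interaction(1, 1.5, c(0, 0, 1), c(0, 0, 1), xi = 0.039)
  expect_equal(f$reflectance, 0.04)
  expect_equal(f$action, "reflect")
  f <- fresnel_interaction(1, 1.5, c(0, 0, 1), c(0, 0, 1), xi = 0.041)
  expect_equal(f$action, "transmit")
  expect_equal(f$direction, c(0, 0, 1))  # no bending at normal incidence
  # matched media: always transmit, direction unchanged
  d <- c(0.6, 0, 0.8)
  f <- fresnel_interaction(1.4, 1.4, d, c(0, 0, 1), xi = 0.999999)
  expect_equal(f$action, "transmit")
  expect_equal(f$direction, d)
  expect_equal(f$reflectance, 0)
  # total internal reflection beyond asin(1/1.5) = 41.8 deg
  d60 <- c(sin(pi / 3), 0, cos(pi / 3))
  f <- fresnel_interaction(1.5, 1.0, d60, c(0, 0, 1), xi = 0.999999)
  expect_equal(f$reflectance, 1)
  expect_equal(f$action, "reflect")
  expect_equal(f$direction, c(sin(pi / 3), 0, -cos(pi / 3)))
  # Snell refraction angle for a transmitted ray
  d30 <- c(sin(pi / 6), 0, cos(pi / 6))
  f <- fresnel_interaction(1.0, 1.5, d30, c(0, 0, 1), xi = 0.9)
  expect_equal(f$direction[1], sin(pi / 6) / 1.5, tolerance = 1e-12)
})

test_that("Beer-Lambert limit: pure absorber transmits exp(-mua*L)", {
  m <- slab_model(thickness_mm = 1, lateral_mm = 50)
  med <- slab_medium(mua = 1, mus = 0)
  set.seed(21)
  n <- 1e5
  r <- run_simulation(m, med, sim_config(n_launch = n))
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(r$transmitted_weight / n - p), 3 * se)
  # no attenuation at all: everything transmits
  med0 <- slab_medium(mua = 0, mus = 0)
  set.seed(22)
  r0 <- suppressWarnings(run_simulation(m, med0, sim_config(n_launch = 1000)))
  expect_equal(r0$transmitted_weight, 1000)
})

test_that("energy bookkeeping closes to 1e-6 relative", {
  m <- slab_model(thickness_mm = 1, lateral_mm = 10)
  # conservative scatterer: all launched weight must exit
  set.seed(31)
  r <- suppressWarnings(run_simulation(
    m, slab_medium(mua = 0, mus = 5, g = 0.8),
    sim_config(n_launch = 2e4)))
  expect_lt(energy_balance(r)$relative_imbalance, 1e-6)
  expect_equal(r$absorbed_weight, 0)
  exits <- r$reflected_weight + r$transmitted_weight +
    r$escaped_side_weight + r$detected_weight_total
  expect_equal(exits, r$n_launched, tolerance = 1e-9)
  # absorbing, mismatched-index heterogeneous medium with roulette active
  fm <- default_finger_model()
  med <- build_medium(fm, 660, reference_state())
  set.seed(32)
  r2 <- run_simulation(fm, med, sim_config(n_launch = 5e3))
  expect_lt(energy_balance(r2)$relative_imbalance, 1e-6)
  expect_true(r2$absorbed_weight > 0 && r2$specular_weight > 0)
})

test_that("simulations are bitwise reproducible for a fixed seed", {
  fm <- default_finger_model()
  med <- build_medium(fm, 940, reference_state())
  cfg <- sim_config(n_launch = 2000)
  set.seed(99); a <- run_simulation(fm, med, cfg)
  set.seed(99); b <- run_simulation(fm, med, cfg)
  expect_identical(a, b)
  set.seed(100); c <- run_simulation(fm, med, cfg)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("detected intensity falls when absorption rises (common seeds)", {
  fm <- default_finger_model()
  med <- build_medium(fm, 660, reference_state())
  med10 <- med; med10$mua <- med$mua * 10
  set.seed(7); lo <- run_simulation(fm, med, sim_config(n_launch = 5e3))
  set.seed(7); hi <- run_simulation(fm, med10, sim_config(n_launch = 5e3))
  expect_gt(lo$intensity, 0)
  expect_lt(lo$intensity, 1)
  expect_lt(hi$intensity, lo$intensity)
})

test_that("the detection-target stopping rule halts early", {
  fm <- default_finger_model()
  med <- build_medium(fm, 940, reference_state())
  set.seed(13)
  r <- run_simulation(fm, med, sim_config(n_launch = 1e5,
                                          n_detect_target = 50))
  expect_gte(r$n_detected, 50)
  expect_lt(r$n_launched, 1e5)
  expect_equal(r$intensity, r$detected_weight_total / r$n_launched)
})

test_that("fluence accounting matches the absorbed weight", {
  m <- slab_model(thickness_mm = 2, lateral_mm = 10)
  set.seed(41)
  r <- suppressWarnings(run_simulation(
    m, slab_medium(mua = 0.5, mus = 10, g = 0.9),
    sim_config(n_launch = 3000, record_fluence = TRUE,
               fluence_voxel_edge_mm = 0.25)))
  expect_equal(sum(r$fluence_deposited), r$absorbed_weight,
               tolerance = 1e-12)
  # no absorption -> empty map
  set.seed(42)
  r0 <- suppressWarnings(run_simulation(
    m, slab_medium(mua = 0, mus = 10, g = 0.9),
    sim_config(n_launch = 500, record_fluence = TRUE,
               fluence_voxel_edge_mm = 0.25)))
  expect_true(all(r0$fluence_deposited == 0))
})

test_that("fluence peaks near the source entry for the finger medium", {
  fm <- default_finger_model()
  med <- build_medium(fm, 660, reference_state())
  set.seed(43)
  r <- run_simulation(fm, med,
                      sim_config(n_launch = 2e4, record_fluence = TRUE,
                                 fluence_voxel_edge_mm = 0.5))
  peak <- arrayInd(which.max(r$fluence_deposited),
                   dim(r$fluence_deposited))
  mid <- ceiling(dim(r$fluence_deposited)[1] / 2)
  expect_lte(abs(peak[1] - mid), 1)   # under the source laterally
  expect_lte(abs(peak[2] - mid), 1)
  expect_lte(peak[3], 2)              # in the topmost planes
  # normalized fluence exists and is finite
  expect_true(all(is.finite(r$fluence)))
})
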