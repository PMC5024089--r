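test_that("power-law fit recovers the generating (K, n) on noise-free sweeps", {
  for (K in c(0.5, 12, 300)) {
    for (n in c(0.26, 0.3, 0.7)) {
      d <- gen_powerlaw_curve(K, n)
      fit <- fit_power_law(d$shear_rates, d$viscosities)
      expect_equal(fit$n, n, tolerance = 1e-9)
      expect_equal(fit$K, K, tolerance = 1e-9)
      expect_lt(fit$residual, 1e-18)
    }
  }
})

test_that("constant viscosity fits as Newtonian (n = 1)", {
  g <- 10^seq(-2, 2, length.out = 20)
  fit <- fit_power_law(g, rep(3.5, 20))
  expect_equal(fit$n, 1, tolerance = 1e-12)
  expect_equal(fit$K, 3.5, tolerance = 1e-12)
})

test_that("power-law fit under multiplicative noise stays near the truth", {
  d <- gen_powerlaw_curve(12, 0.3, points = 50, noise_sd = 0.05, seed = 42)
  fit <- fit_power_law(d$shear_rates, d$viscosities)
  # analytic OLS slope SE on the log-log design with sigma = 0.05
  lx <- log(d$shear_rates)
  se <- 0.05 / sqrt(sum((lx - mean(lx))^2))
  expect_lt(abs(fit$n - 0.3), 4 * se)
})

test_that("power-law fit rejects degenerate input", {
  expect_error(fit_power_law(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_power_law(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(fit_power_law(c(1, 2, 3), c(1, 0, 3)), "positive")
})

test_that("crossover detection matches the analytic log-linear intersection", {
  # two straight lines in log10 space; closed-form intersection
  for (tx in c(27.3, 35, 41.11)) {
    cu <- gen_gelation_curve(T_x = tx, slopes = c(0.2, 0.04),
                             T_range = c(20, 50), step = 0.5)
    expect_equal(find_crossover(cu), tx, tolerance = 1e-9)
  }
  # generic non-constructed lines: log10 G' = 6 - 0.12 T, log10 G'' = 3.4 - 0.04 T
  temp <- seq(20, 50, by = 0.5)
  cu <- rheology_curve(temp, 10^(6 - 0.12 * temp), 10^(3.4 - 0.04 * temp))
  expect_equal(find_crossover(cu), (6 - 3.4) / (0.12 - 0.04),
               tolerance = 1e-9)
})

test_that("crossover is NULL when G'' dominates everywhere", {
  temp <- seq(20, 50, by = 1)
  cu <- rheology_curve(temp, rep(10, length(temp)), rep(100, length(temp)))
  expect_null(find_crossover(cu))
})

test_that("with multiple crossings the highest-temperature one is returned", {
  # sign pattern of log G' - log G'': + - + - over temperature
  temp <- c(20, 25, 30, 35)
  d <- c(1, -1, 1, -1)
  cu <- rheology_curve(temp, 100 * exp(d), rep(100, 4))
  expect_equal(find_crossover(cu), 32.5)
})

test_that("modulus fit recovers E and ignores points beyond the window", {
  cu <- gen_stress_strain(500.4)
  expect_equal(fit_modulus(cu), 500.4, tolerance = 1e-9)
  # strain-hardening tail must not influence the small-strain slope
  eps <- seq(0, 0.15, length.out = 100)
  sig <- ifelse(eps <= 0.04, 120 * eps, 120 * 0.04 + 5000 * (eps - 0.04)^2)
  cu2 <- stress_strain(eps, sig)
  expect_equal(fit_modulus(cu2), 120, tolerance = 1e-9)
  expect_equal(fit_modulus(gen_stress_strain(0)), 0)
  expect_error(fit_modulus(cu, strain_window = c(0.2, 0.3)), "window")
})

test_that("free-intercept modulus fit recovers the slope under offset", {
  eps <- seq(0, 0.04, length.out = 20)
  cu <- stress_strain(eps, 2 + 250 * eps)
  expect_equal(fit_modulus(cu, intercept = TRUE), 250, tolerance = 1e-9)
})

test_that("series conductivity equals the length-weighted harmonic mean", {
  segs <- list(conductivity_segment("a", 1, 1),
               conductivity_segment("b", 1, 3))
  expect_equal(series_conductivity(segs), 1.5, tolerance = 1e-12)
  uniform <- list(conductivity_segment("a", 4, 2.2),
                  conductivity_segment("b", 8, 2.2))
  expect_equal(series_conductivity(uniform), 2.2, tolerance = 1e-12)
  expect_error(series_conductivity(
    list(conductivity_segment("a", 1, 1),
         structure(list(ink_id = "b", length = 1, sigma = -1),
                   class = "conductivity_segment"))), "> 0")
})

test_that("series conductivity is bounded by the segment extremes", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    segs <- lapply(seq_len(k), function(j)
      conductivity_segment("x", runif(1, 0.5, 10), runif(1, 0.01, 5)))
    sig <- vapply(segs, function(s) s$sigma, numeric(1))
    eff <- series_conductivity(segs)
    expect_gte(eff, min(sig) - 1e-12)
    expect_lte(eff, max(sig) + 1e-12)
  }
})

test_that("conductivity decreases as the low-conductivity middle lengthens", {
  sig_AC3 <- 0.5; sig_AC1 <- 0.1
  eff <- vapply(c(4, 8, 12), function(mid) {
    fil <- gen_three_segment_filament(24, mid)
    segs <- lapply(fil$segments, function(s)
      conductivity_segment(s$ink_id, s$length,
                           if (s$ink_id == "AC1") sig_AC1 else sig_AC3))
    series_conductivity(segs)
  }, numeric(1))
  expect_true(all(diff(eff) < 0))
  expect_true(all(eff > sig_AC1 & eff < sig_AC3))
})

test_that("specific conductivity from resistance follows sigma = L / (R A)", {
  expect_equal(specific_conductivity_from_resistance(1e6, 24, 0.5),
               0.024 / (1e6 * pi * 0.00025^2), tolerance = 1e-12)
  expect_equal(specific_conductivity_from_resistance(1e6, 24, 0.5), 0.1222,
               tolerance = 1e-3)
  expect_equal(specific_conductivity_from_resistance(1e6, 48, 0.5),
               2 * specific_conductivity_from_resistance(1e6, 24, 0.5))
  expect_error(specific_conductivity_from_resistance(-1, 24, 0.5), "> 0")
})

test_that("resistance <-> conductivity round-trips through the series model", {
  fil <- gen_three_segment_filament(24, 8)
  segs <- lapply(fil$segments, function(s)
    conductivity_segment(s$ink_id, s$length,
                         if (s$ink_id == "AC1") 0.1 else 0.5))
  eff <- series_conductivity(segs)
  R <- resistance_from_specific_conductivity(eff, 24, 0.5)
  expect_equal(specific_conductivity_from_resistance(R, 24, 0.5), eff,
               tolerance = 1e-12)
})

test_that("printability window sits above every gel point and below the ceiling", {
  a_series <- lapply(c(A1 = 28, A2 = 32, A3 = 36, A4 = 40), function(tx)
    ink_spec("x", crossover_T = tx))
  win <- printability_window(a_series, margin = 5, ceiling = 60)
  expect_equal(unname(win), c(45, 60))
  expect_true(win[1] <= 50 && 50 <= win[2])  # standard reservoir setting
  bio <- list(ink_spec("AS3", crossover_T = 35),
              ink_spec("A-NIH", crossover_T = 35))
  win2 <- printability_window(bio, margin = 3, ceiling = 38)
  expect_equal(unname(win2), c(38, 38))     # the bio-ink operating point
  hot <- list(ink_spec("X", crossover_T = 59))
  expect_error(printability_window(hot, margin = 5, ceiling = 60), "empty")
})

test_that("switching cooling follows the lumped closed form and is monotone", {
  expect_equal(switching_temperature_drop(50, 25, 0, 30), 50)
  expect_equal(switching_temperature_drop(50, 25, 1e9, 30), 25,
               tolerance = 1e-6)
  expect_equal(switching_temperature_drop(50, 25, 3, 30),
               25 + 25 * exp(-0.1), tolerance = 1e-12)
  times <- seq(0, 60, by = 5)
  temps <- vapply(times, function(t)
    switching_temperature_drop(50, 25, t, 30), numeric(1))
  expect_true(all(diff(temps) < 0))
  expect_error(switching_temperature_drop(50, 25, 3, 0), "tau")
})

test_that("gelation risk flags only inks whose crossover exceeds the cooled temperature", {
  inks <- list(ink_spec("A2", crossover_T = 32),
               ink_spec("AC5", crossover_T = 48))
  risk <- gelation_risk(inks, T0 = 50, T_env = 25, elapsed = 3, tau = 30)
  expect_equal(risk$temperature, 25 + 25 * exp(-0.1), tolerance = 1e-12)
  expect_identical(risk$at_risk, "AC5")
  none <- gelation_risk(inks[1], T0 = 50, T_env = 25, elapsed = 3, tau = 30)
  expect_length(none$at_risk, 0)
})

test_that("CSV readers reconstruct the characterization containers", {
  d <- gen_powerlaw_curve(12, 0.3, points = 10)
  p1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(shear_rate = d$shear_rates,
                              viscosity = d$viscosities),
                   p1, row.names = FALSE)
  back <- read_shear_sweep(p1)
  expect_equal(back$viscosities, d$viscosities)

  cu <- gen_gelation_curve(35)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(temperature = cu$temperature,
                              G_storage = cu$G_storage,
                              G_loss = cu$G_loss), p2, row.names = FALSE)
  expect_equal(find_crossover(read_rheology_curve(p2)), 35,
               tolerance = 1e-9)

  ss <- gen_stress_strain(100, points = 10)
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(strain = ss$strain, stress = ss$stress),
                   p3, row.names = FALSE)
  expect_equal(fit_modulus(read_stress_strain(p3)), 100, tolerance = 1e-9)
})
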