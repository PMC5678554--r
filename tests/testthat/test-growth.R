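test_that("thermal time accumulates the clamped excess over the base", {
  tt <- thermal_time(data.frame(day = 1:3, mean_temp_c = c(13.5, 3.5, 2.0)))
  expect_equal(tt$tt, c(10, 10, 10))   # 10, +0 at base, +0 clamped below base
  tt2 <- thermal_time(data.frame(day = 1:4, mean_temp_c = c(20, 25, 18, 23.5)),
                      base = 3.5)
  expect_equal(tt2$tt, cumsum(c(16.5, 21.5, 14.5, 20)))
  expect_error(thermal_time(data.frame(day = c(1, 1), mean_temp_c = c(5, 6))),
               "increasing")
})

test_that("RER is the log-area slope against thermal time", {
  s <- growth_series("p", tt = c(0, 1), area_cm2 = c(10, 20))
  expect_equal(rer(s)$rer, log(2))
  expect_equal(rer(s)$mean_area_cm2, 15)
  # constant area -> zero rate
  s2 <- growth_series("p", tt = c(0, 5, 10), area_cm2 = c(30, 30, 30))
  expect_equal(rer(s2)$rer, c(0, 0))
  # an exactly exponential series returns the generating constant exactly
  r0 <- 0.0134
  tts <- seq(0, 200, by = 25)
  s3 <- growth_series("p", tt = tts, area_cm2 = 10 * exp(r0 * tts))
  expect_equal(rer(s3)$rer, rep(r0, length(tts) - 1), tolerance = 1e-12)
  # zero thermal-time increment is signalled per interval
  s4 <- growth_series("p", tt = c(0, 10, 10, 20), area_cm2 = c(10, 20, 21, 30))
  expect_warning(r4 <- rer(s4), "zero thermal-time")
  expect_true(is.na(r4$rer[2]) && !anyNA(r4$rer[-2]))
})

test_that("RER of an Euler-integrated trajectory matches the rate model", {
  alpha <- -4.55; beta <- -2.127e-3
  ser <- oracle_euler_series(alpha, beta, tt_max = 300)
  obs <- ser[ser$tt %% 30 == 0, ]
  r <- rer(growth_series("p", tt = obs$tt, area_cm2 = obs$area_cm2))
  # piecewise RER should track exp(alpha + beta * mean area) up to
  # discretization error of the 1 degree-day Euler steps
  expect_equal(r$rer, exp(alpha + beta * r$mean_area_cm2), tolerance = 0.02)
})

test_that("overlap correction follows the disk-in-square geometry", {
  # r <= 15: untouched
  expect_equal(overlap_correct(pi * 10^2), pi * 10^2)
  expect_equal(overlap_correct(1), 1)
  # disk circumscribing the cell: full 900 cm^2
  expect_equal(overlap_correct(pi * (15 * sqrt(2))^2), 900)
  expect_equal(overlap_correct(2000), 900)
  # intermediate radius against the grid quadrature oracle
  for (r in c(15.5, 16, 18, 20)) {
    expect_equal(overlap_correct(pi * r^2), oracle_disk_square(r),
                 tolerance = 1e-3)
  }
  # continuity at both branch points
  eps <- 1e-9
  expect_equal(overlap_correct(pi * (15 + eps)^2), pi * 15^2,
               tolerance = 1e-6)
  expect_equal(overlap_correct(pi * (15 * sqrt(2) - eps)^2), 900,
               tolerance = 1e-6)
  expect_error(overlap_correct(-5), "positive")
})

test_that("overlap correction is monotone and capped at the cell area", {
  areas <- seq(1, 2500, length.out = 400)
  corr <- overlap_correct(areas)
  expect_true(all(diff(corr) >= -1e-9))
  expect_true(all(corr <= 900 + 1e-9))
  expect_true(all(corr <= areas + 1e-9))
})

test_that("intercepted radiation sums mean area times interval radiation", {
  day <- as.POSIXct("2015-07-21", tz = "UTC")
  # one interval, areas 10 -> 20 cm^2, 5 mol m^-2 incident
  rad <- data.frame(time = day + c(1, 2, 3) * 3600, mol_m2 = c(2, 2, 1))
  got <- intercepted_radiation(times = day + 4 * 3600, areas_cm2 = 20,
                               radiation = rad, planting_time = day,
                               initial_area_cm2 = 10)
  expect_equal(got, 15 / 1e4 * 5, tolerance = 1e-12)
  # constant area A over the cycle: (A/1e4) * total
  radc <- data.frame(time = day + seq(1, 96) * 3600,
                     mol_m2 = rep(0.5, 96))
  gotc <- intercepted_radiation(times = day + c(24, 48, 96) * 3600,
                                areas_cm2 = c(50, 50, 50),
                                radiation = radc, planting_time = day,
                                initial_area_cm2 = 50)
  expect_equal(gotc, 50 / 1e4 * 48, tolerance = 1e-12)
})

test_that("three-interval budget equals the hand-summed oracle", {
  day <- as.POSIXct("2015-07-21", tz = "UTC")
  tA <- day + c(5, 11, 20) * 86400
  areas <- c(35, 180, 520)
  rad <- data.frame(
    time = day + (1:20) * 86400 - 3600,       # one record per day, 23:00
    mol_m2 = c(rep(2, 5), rep(3, 6), rep(1.5, 9)))
  # hand computation: A0=10; intervals get 5*2=10, 6*3=18, 9*1.5=13.5
  oracle <- (10 + 35) / 2e4 * 10 + (35 + 180) / 2e4 * 18 +
    (180 + 520) / 2e4 * 13.5
  got <- intercepted_radiation(tA, areas, rad, planting_time = day)
  expect_equal(got, oracle, tolerance = 1e-12)
  # linearity in the radiation series
  rad2 <- rad; rad2$mol_m2 <- 3 * rad2$mol_m2
  expect_equal(intercepted_radiation(tA, areas, rad2, planting_time = day),
               3 * got, tolerance = 1e-12)
  # invariance to splitting records into finer steps
  radf <- data.frame(
    time = rep(rad$time, each = 4) - rep(c(10800, 7200, 3600, 0), 20),
    mol_m2 = rep(rad$mol_m2 / 4, each = 4))
  expect_equal(intercepted_radiation(tA, areas, radf, planting_time = day),
               got, tolerance = 1e-12)
  # coverage gap inside an interval is an explicit error
  radg <- rad[rad$time < tA[2] - 6 * 86400 | rad$time > tA[2], ]
  expect_error(intercepted_radiation(tA, areas, radg, planting_time = day),
               "coverage gap")
})

test_that("RIE and RUE are the stated ratios", {
  day <- as.POSIXct("2015-07-21", tz = "UTC")
  radc <- data.frame(time = day + seq(1, 96) * 3600, mol_m2 = rep(0.5, 96))
  A <- 50
  inter <- intercepted_radiation(day + c(24, 96) * 3600, c(A, A), radc,
                                 planting_time = day, initial_area_cm2 = A)
  # constant area: RIE equals the plant area in m^2
  expect_equal(rie(inter, sum(radc$mol_m2)), A / 1e4, tolerance = 1e-12)
  # doubling radiation leaves RIE unchanged
  rad2 <- radc; rad2$mol_m2 <- 2 * rad2$mol_m2
  inter2 <- intercepted_radiation(day + c(24, 96) * 3600, c(A, A), rad2,
                                  planting_time = day, initial_area_cm2 = A)
  expect_equal(rie(inter2, sum(rad2$mol_m2)), rie(inter, sum(radc$mol_m2)))
  # normalized variant divides by the 0.09 m^2 ground cell
  expect_equal(rie(inter, sum(radc$mol_m2), normalize = TRUE),
               A / 1e4 / 0.09)
  expect_error(rie(1, 0), "positive")
  expect_equal(rue(12, 6), 2)
  expect_equal(rue(0, 6), 0)
  expect_error(rue(12, 0), "positive")
})
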