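test_that("tight binding saturates at the stoichiometric heat with the equivalence point at mole ratio 1", {
  sch <- titration_schedule(v0_ul = 170, dv_ul = rep(2, 30),
                            syringe_um = 300, cell_um = 35)
  tg <- simulate_titration(one_site_params(kd_um = 1e-6, dh_kcal = -5),
                           sch, sign = "exothermic_negative")
  # the bound fraction saturates: cumulative heat reaches the
  # stoichiometric limit for the (dilution-corrected) cell content
  Q <- hdxbind:::.itc_cumulative_heat(1 / 1e-12, -5, 1, sch)
  v <- cumsum(sch$dv_ul) / sch$v0_ul
  mt_last <- 35e-6 * (1 - v[30] / 2) / (1 + v[30] / 2)
  expect_equal(Q[30], mt_last * 170e-6 * (-5000) * 1e6, tolerance = 1e-6)
  # total measured heat is within 10% of the nominal N*M0*V0*dH (part of
  # the bound complex is displaced out of the overflow cell)
  Q_inf <- 35e-6 * 170e-6 * (-5000) * 1e6   # ucal
  expect_equal(sum(tg$q), Q_inf, tolerance = 0.1)
  expect_lte(abs(sum(tg$q)), abs(Q_inf))
  # per-injection heat collapses right at the equivalence point
  v <- cumsum(sch$dv_ul) / sch$v0_ul
  ratio <- (sch$syringe_um * v / (1 + v / 2)) /
    (sch$cell_um * (1 - v / 2) / (1 + v / 2))
  drop <- which(abs(tg$q) < 0.5 * max(abs(tg$q)))[1]
  expect_lt(abs(ratio[drop] - 1), 0.15)
})

test_that("zero enthalpy leaves only the dilution offset", {
  tg <- simulate_titration(one_site_params(kd_um = 10, dh_kcal = 0,
                                           dilution_offset = 0.7),
                           sign = "exothermic_negative")
  expect_equal(tg$q, rep(0.7, 20))
})

test_that("dilution-heat subtraction removes the trailing-injection mean", {
  sch <- titration_schedule(dv_ul = rep(2, 6))
  tg <- structure(list(q = c(5, 3, 1, 0.1, 0.12, 0.08), schedule = sch,
                       sign = "exothermic_positive"), class = "thermogram")
  corr <- subtract_dilution_heat(tg, k_last = 3)
  expect_equal(corr$dilution_offset_subtracted, 0.1)
  expect_equal(corr$q, tg$q - 0.1)

  flat <- structure(list(q = rep(2, 6), schedule = sch,
                         sign = "exothermic_positive"), class = "thermogram")
  expect_equal(subtract_dilution_heat(flat)$q, rep(0, 6))
  expect_error(subtract_dilution_heat(flat, 6), "smaller")

  # adding a constant offset then subtracting restores the shape
  shift <- tg; shift$q <- tg$q + 1.5
  expect_equal(subtract_dilution_heat(shift, 3)$q,
               subtract_dilution_heat(tg, 3)$q)
})

test_that("noise-free one-site refit recovers the simulated parameters", {
  params <- one_site_params(kd_um = 16.46, dh_kcal = -5)
  tg <- simulate_titration(params)
  fit <- fit_one_site(tg)
  expect_lt(abs(fit$params$kd_um - 16.46) / 16.46, 1e-3)
  expect_lt(abs(fit$params$dh_kcal - (-5)) / 5, 1e-3)
  expect_equal(fit$params$n, 1)
  # Kd * Ka = 1 exactly in the report
  expect_identical(fit$params$kd_um * 1e-6 * fit$params$ka_Minv, 1)
  # round trip: simulating from the fit reproduces the thermogram
  tg2 <- simulate_titration(fit$params, tg$schedule)
  expect_equal(tg2$q, tg$q, tolerance = 1e-4)
})

test_that("fits are invariant to the declared sign convention", {
  params <- one_site_params(kd_um = 30, dh_kcal = -4)
  pos <- simulate_titration(params, sign = "exothermic_positive")
  neg <- simulate_titration(params, sign = "exothermic_negative")
  expect_equal(pos$q, -neg$q)
  fp <- fit_one_site(pos); fn <- fit_one_site(neg)
  expect_equal(fp$params$kd_um, fn$params$kd_um, tolerance = 1e-8)
  expect_equal(fp$params$dh_kcal, fn$params$dh_kcal, tolerance = 1e-8)
})

test_that("degenerate thermograms are rejected with diagnostics", {
  sch <- titration_schedule(dv_ul = rep(2, 10))
  zero <- structure(list(q = rep(0, 10), schedule = sch,
                         sign = "exothermic_positive"), class = "thermogram")
  expect_error(fit_one_site(zero), "no signal")
  short <- structure(list(q = c(1, 2), schedule = titration_schedule(dv_ul = rep(2, 2)),
                          sign = "exothermic_positive"), class = "thermogram")
  expect_error(fit_one_site(short), "at least 5")
  # weak c-value triggers a warning but still fits
  weak <- simulate_titration(one_site_params(kd_um = 5000, dh_kcal = -5),
                             titration_schedule(dv_ul = rep(2, 25)))
  expect_warning(fit_one_site(weak), "c-value")
})

test_that("itc_fit methods expose coefficients, predictions and residuals", {
  tg <- simulate_titration(one_site_params(kd_um = 16.46, dh_kcal = -5),
                           noise_sd = 0.2, seed = 3)
  fit <- fit_one_site(tg)
  cf <- coef(fit)
  expect_named(cf, c("ka_Minv", "kd_um", "dh_kcal", "n"))
  expect_equal(length(residuals(fit)), 20L)
  expect_equal(predict(fit), as.numeric(fit$fitted), tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "thermogram")
})

test_that("signed fold of affinity change follows the table convention", {
  expect_identical(fold_affinity_change(16.46, 531.55), -32.29)
  expect_identical(fold_affinity_change(3.64, 2.14), 1.70)
  expect_identical(fold_affinity_change(5, 5), 1)
  expect_error(fold_affinity_change(-1, 5), "positive")
  # antisymmetry and magnitude floor
  set.seed(61)
  for (i in 1:30) {
    a <- runif(1, 0.5, 50); b <- runif(1, 0.5, 50)
    f <- fold_affinity_change(a, b)
    expect_gte(abs(f), 1)
    if (abs(f) != 1)
      expect_equal(fold_affinity_change(b, a), -f, tolerance = 0.015)
  }
})

test_that("affinity comparison matches the reference unpaired t-test", {
  expect_equal(compare_affinities(c(3.5, 3.7, 3.8), c(11.5, 12.0, 11.9)),
               1.3229625942191e-06, tolerance = 1e-10)
  expect_equal(compare_affinities(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_equal(compare_affinities(c(2, 2), c(2, 2)), 1)
  expect_error(compare_affinities(1, c(1, 2)), "replicate")
})

test_that("thermogram CSV dialect round-trips with metadata", {
  tg <- simulate_titration(one_site_params(kd_um = 16.46, dh_kcal = -5),
                           noise_sd = 0.1, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_thermogram_csv(tg, f)
  tg2 <- read_thermogram_csv(f)
  expect_equal(tg2$q, as.numeric(sprintf("%.6g", tg$q)))
  expect_equal(tg2$sign, tg$sign)
  expect_equal(tg2$schedule$v0_ul, tg$schedule$v0_ul)
  # missing metadata is rejected
  lines <- readLines(f)
  writeLines(lines[-1], f)
  expect_error(read_thermogram_csv(f), "metadata")
})
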