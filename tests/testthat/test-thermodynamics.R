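test_that("Gibbs free energy follows R T ln(aw)", {
  expect_equal(gibbs_free_energy(0.5, 303.15), 8.314 * 303.15 * log(0.5))
  expect_lt(abs(gibbs_free_energy(0.5, 303.15) + 1746.9), 0.5)
  expect_equal(gibbs_free_energy(1 - 1e-15, 300), 0, tolerance = 1e-9)
  aw <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(gibbs_free_energy(aw, 310)) > 0))
  expect_error(gibbs_free_energy(0, 300), class = "sorptherm_domain_error")
  expect_error(gibbs_free_energy(1, 300), class = "sorptherm_domain_error")
})

test_that("harmonic mean temperature matches hand arithmetic", {
  tk <- c(303.15, 313.15, 323.15)
  expect_equal(harmonic_mean_temperature(tk), 3 / sum(1 / tk))
  expect_equal(round(harmonic_mean_temperature(tk), 2), 312.94)
  expect_error(harmonic_mean_temperature(c(300, -1)),
               class = "sorptherm_domain_error")
})

test_that("a constructed ln(aw)-linear-in-1/T system is recovered exactly", {
  # direct regression-level oracle: exact line with q = 20 kJ/mol, s = 50
  q <- 20e3; s <- 50; R <- 8.314
  tk <- c(303.15, 313.15, 323.15)
  aw <- exp(-(q / R) / tk + s / R)
  line <- stats::lm(log(aw) ~ I(1 / tk))
  expect_equal(-R * coef(line)[[2]], q, tolerance = 1e-9)
  expect_equal(R * coef(line)[[1]], s, tolerance = 1e-9)

  # end-to-end: GAB multilayer factor scaled across temperature so that
  # B * aw is temperature-invariant at constant moisture
  q2 <- 10e3
  sim <- simulate_sorption(clausius_params(q = q2), sigma = 0, seed = 1,
                           aw = c(0.1, 0.25, 0.4, 0.55, 0.7, 0.85))
  th <- fit_isotherms(sim$data, models = "gab") |> isosteric_heat(grid = 8:20)
  expect_equal(nrow(th), 13)
  expect_true(all(abs(th$qst_kj_mol - q2 / 1000) / (q2 / 1000) < 1e-6))
  aw40 <- vapply(th$activity, function(a) a$aw[a$temperature_c == 40],
                 numeric(1))
  s_expected <- R * log(aw40) + q2 / 313.15
  expect_equal(th$ds_j_mol_k, s_expected, tolerance = 1e-6)
})

test_that("a temperature-independent isotherm has zero isosteric heat", {
  p <- c(A = 10, B = 0.8, C = 8)
  sim <- simulate_sorption(list(`30` = p, `40` = p, `50` = p), sigma = 0,
                           seed = 1, aw = c(0.1, 0.3, 0.5, 0.7, 0.85))
  th <- fit_isotherms(sim$data, models = "gab") |> isosteric_heat(grid = 10:20)
  expect_true(all(abs(th$qst_kj_mol) < 1e-6))
})

test_that("unattainable grid points are dropped with a warning", {
  sim <- noiseless_sim()
  fits <- fit_isotherms(sim$data, models = "gab")
  expect_warning(th <- isosteric_heat(fits, grid = c(15, 1e4)), "attainable")
  expect_equal(th$xeq, 15)
})

test_that("polynomial smoothing recovers exact generators", {
  x <- 1:10
  y <- 5 - 2 * x + 0 * x^2 + 1 * x^3
  sm <- smooth_polynomial(x, y, degree = 3)
  expect_equal(sm$coefficients, c(5, -2, 0, 1), tolerance = 1e-8)
  expect_equal(sm$r, 1)
  expect_equal(predict(sm, 2.5), 5 - 2 * 2.5 + 2.5^3, tolerance = 1e-8)

  sm0 <- smooth_polynomial(x, y, degree = 0)
  expect_equal(sm0$coefficients, mean(y))

  expect_error(smooth_polynomial(1:3, 1:3, degree = 3),
               class = "sorptherm_validation_error")
  expect_error(smooth_polynomial(1:4, 1:3, degree = 2),
               class = "sorptherm_validation_error")
})

test_that("compensation regression recovers an exact enthalpy-entropy line", {
  ds <- seq(20, 200, by = 20)
  q_j <- 350 * ds + 800
  thermo <- tibble::tibble(
    sample_id = "s", mode = "desorption", xeq = seq_along(ds),
    qst_kj_mol = q_j / 1000, ds_j_mol_k = ds, r2 = 1, n_temps = 3,
    activity = list(tibble::tibble(temperature_c = c(30, 40, 50),
                                   aw = 0.5, ln_aw = log(0.5),
                                   dg_j_mol = -1)))
  comp <- compensation_analysis(thermo)
  expect_equal(comp$t_beta_k, 350, tolerance = 1e-10)
  expect_equal(comp$dg_beta_j_mol, 800, tolerance = 1e-8)
  expect_equal(comp$r, 1)
  expect_equal(round(comp$t_hm_k, 2), 312.94)
  expect_equal(comp$spontaneity, "non-spontaneous")
  expect_true(comp$valid_compensation)

  neg <- dplyr::mutate(thermo, qst_kj_mol = (350 * ds - 500) / 1000)
  expect_equal(compensation_analysis(neg)$spontaneity, "spontaneous")

  flat <- dplyr::mutate(thermo, ds_j_mol_k = 5)
  expect_error(compensation_analysis(flat), class = "sorptherm_regression_error")
  expect_error(compensation_analysis(thermo[1:2, ]),
               class = "sorptherm_validation_error")
})

test_that("grid spacing barely moves the isokinetic temperature", {
  d <- dplyr::filter(cherry_sorption(), sample_id == "Napoleon",
                     mode == "adsorption")
  fits <- fit_isotherms(d, models = "gab")
  t1 <- compensation_analysis(isosteric_heat(fits, grid = seq(10, 30, 1)))
  t2 <- compensation_analysis(isosteric_heat(fits, grid = seq(10, 30, 2)))
  expect_lt(abs(t1$t_beta_k - t2$t_beta_k) / t1$t_beta_k, 0.02)
})
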