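test_that("goodness of fit matches hand arithmetic and limiting cases", {
  x <- c(14, 17, 22, 48, 79, 93)
  ident <- goodness_of_fit(x, x)
  expect_equal(ident$r, 1)
  expect_equal(ident$mre, 0)
  null <- goodness_of_fit(x, rep(mean(x), 6))
  expect_equal(null$r, 0)
  hand <- goodness_of_fit(c(10, 20), c(11, 18))
  expect_equal(hand$mre, 10)  # (100/2)(0.1 + 0.1)
  expect_true(hand$r >= 0 && hand$r <= 1)
  expect_warning(goodness_of_fit(c(0, 10), c(1, 9)), "excluded")
  expect_error(goodness_of_fit(1:3, 1:2), class = "sorptherm_validation_error")
})

test_that("noise-free synthetic data recover the generating parameters", {
  sim <- noiseless_sim()
  truth <- sim$truth
  for (tt in c(30, 40, 50)) {
    fit <- fit_isotherm(dplyr::filter(sim$data, temperature_c == tt), "gab")
    true_p <- truth$value[truth$temperature_c == tt]
    expect_true(fit$converged)
    expect_equal(unname(fit$params), true_p, tolerance = 1e-6)
    expect_equal(fit$r, 1, tolerance = 1e-10)
    expect_lt(fit$mre, 1e-6)
  }
})

test_that("fitting is deterministic: identical inputs give identical fits", {
  d <- dplyr::filter(cherry_sorption(), sample_id == "Van",
                     mode == "desorption", temperature_c == 40)
  f1 <- fit_isotherm(d, "gab")
  f2 <- fit_isotherm(d, "gab")
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sse, f2$sse)
})

test_that("undersized series are rejected per model parameter count", {
  d <- tibble::tibble(aw = c(0.1, 0.3, 0.5, 0.7),
                      xeq_percent_db = c(5, 8, 12, 20))
  expect_s3_class(fit_isotherm(d, "gab"), "isotherm_fit")  # 4 points, 3 params
  expect_error(fit_isotherm(d, "peleg"), class = "sorptherm_validation_error")
  expect_error(fit_isotherm(d, "enderby"), class = "sorptherm_validation_error")
  d3 <- d[1:3, ]
  expect_error(fit_isotherm(d3, "gab"), class = "sorptherm_validation_error")
})

test_that("fit tables carry one row per series and model", {
  sim <- noiseless_sim()
  fits <- fit_isotherms(sim$data)
  expect_equal(nrow(fits), 3 * 3)  # 3 temperatures x 3 models
  expect_true(all(fits$converged))
  expect_true(all(c("r", "mre", "params", "fit") %in% names(fits)))
})

test_that("model selection ranks by r (3 decimals) then breaks ties by MRE", {
  fits <- tibble::tibble(
    sample_id = "s", mode = "desorption", temperature_c = 30,
    model = c("gab", "peleg", "enderby"),
    converged = TRUE,
    r = c(0.9991, 0.9994, 0.95),  # gab and peleg tie at 0.999
    mre = c(2.0, 3.5, 1.0))
  best <- select_best_model(fits)
  expect_equal(best$model, "gab")  # tie on rounded r, lower MRE wins
  expect_true(best$acceptable)

  single <- fits[2, ]
  expect_equal(select_best_model(single)$model, "peleg")

  none <- dplyr::mutate(fits, converged = FALSE)
  expect_error(select_best_model(none), class = "sorptherm_selection_error")

  high <- dplyr::mutate(fits, mre = mre + 10)
  expect_false(any(select_best_model(high)$acceptable))
})

test_that("broom-style accessors expose parameters and fit statistics", {
  sim <- noiseless_sim()
  fit <- fit_isotherm(dplyr::filter(sim$data, temperature_c == 40), "gab")
  td <- tidy(fit)
  expect_equal(td$term, c("A", "B", "C"))
  gl <- glance(fit)
  expect_equal(gl$model, "gab")
  expect_equal(gl$n, 6L)
  au <- augment(fit)
  expect_equal(au$.resid, au$xeq_percent_db - au$.fitted)
  expect_s3_class(autoplot(fit), "ggplot")
  pred <- predict(fit, c(0.2, 0.5))
  expect_equal(pred, gab_moisture(c(0.2, 0.5), fit$params))
})

test_that("monolayer recovery stays accurate under realistic noise", {
  rr <- recovery_report(n_reps = 20, sigma = 0.02, seed = 11,
                        downstream = FALSE)
  a_rows <- rr[rr$quantity == "A", ]
  expect_equal(nrow(a_rows), 3)
  expect_true(all(a_rows$median_abs_rel_err < 0.10))
})
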