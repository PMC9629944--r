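test_that("equilibrium moisture content follows the gravimetric definition", {
  expect_equal(compute_emc(2.0, 1.0), 1.0)
  expect_equal(compute_emc(1.0, 1.0), 0.0)
  expect_equal(compute_emc(8.72, 4.36), 1.0)
  expect_equal(compute_emc(c(2, 3), c(1, 2)), c(1, 0.5))
  expect_error(compute_emc(1, 0), class = "sorptherm_domain_error")
  expect_error(compute_emc(1, -1), class = "sorptherm_domain_error")
  expect_error(compute_emc(0.9, 1), class = "sorptherm_validation_error")
})

test_that("the cherry fixture has the full factorial shape and verbatim cells", {
  d <- cherry_sorption()
  expect_equal(nrow(d), 180)
  series <- dplyr::count(d, sample_id, mode, temperature_c)
  expect_equal(nrow(series), 30)  # 5 cultivars x 2 modes x 3 temperatures
  expect_true(all(series$n == 6))
  expect_setequal(unique(d$temperature_c), c(30, 40, 50))

  cell <- function(s, m, tt, a) {
    d$xeq_percent_db[d$sample_id == s & d$mode == m &
                     d$temperature_c == tt & d$aw == a]
  }
  expect_equal(cell("Burlat", "desorption", 30, 0.0738), 14.47)
  expect_equal(cell("Burlat", "desorption", 30, 0.898), 92.88)
  expect_equal(cell("Napoleon", "adsorption", 30, 0.898), 71.93)
  expect_equal(cell("Cerisette", "desorption", 40, 0.3259), 13.30)
  expect_equal(cell("Coeur pigeon", "adsorption", 50, 0.8823), 65.75)
  expect_equal(cell("Van", "desorption", 50, 0.0572), 11.84)
})

test_that("sorption CSV I/O round-trips field for field", {
  d <- cherry_sorption()
  f <- withr::local_tempfile(fileext = ".csv")
  write_sorption_csv(d, f)
  expect_equal(as.data.frame(read_sorption_csv(f)), as.data.frame(d))
})

test_that("record validation rejects out-of-range and duplicated rows", {
  good <- tibble::tibble(sample_id = "s", mode = "desorption",
                         temperature_c = 30, aw = c(0.2, 0.4),
                         xeq_percent_db = c(10, 20))
  expect_silent(validate_sorption_data(good))
  bad_aw <- good; bad_aw$aw[1] <- 1.2
  expect_error(validate_sorption_data(bad_aw), class = "sorptherm_validation_error")
  bad_x <- good; bad_x$xeq_percent_db[2] <- -1
  expect_error(validate_sorption_data(bad_x), class = "sorptherm_validation_error")
  dup <- dplyr::bind_rows(good, good[1, ])
  expect_error(validate_sorption_data(dup), class = "sorptherm_validation_error")
  bad_mode <- good; bad_mode$mode <- "drying"
  expect_error(validate_sorption_data(bad_mode), class = "sorptherm_validation_error")
})

test_that("CSV reading reports malformed rows and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,mode,temperature_c,aw,xeq_percent_db",
               "s,desorption,30,0.2,10",
               "s,desorption,30,not_a_number,12"), f)
  expect_error(read_sorption_csv(f), "row", class = "sorptherm_validation_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,mode,temperature_c,aw,xeq_percent_db", empty)
  expect_warning(res <- read_sorption_csv(empty), "no records")
  expect_equal(nrow(res), 0)

  expect_error(read_sorption_csv("does/not/exist.csv"),
               class = "sorptherm_io_error")
})

test_that("salt water activities look up exactly and interpolate linearly", {
  expect_equal(salt_aw("KOH", 30), 0.0738)
  expect_equal(salt_aw("BaCl2.2H2O", 50), 0.8823)
  expect_equal(salt_aw("KOH", 35), (0.0738 + 0.0626) / 2)  # 0.0682
  expect_error(salt_aw("NaCl", 30), class = "sorptherm_key_error")
  expect_error(salt_aw("KOH", 25), class = "sorptherm_domain_error")
  # each salt's water activity decreases weakly with temperature
  ref <- salt_reference()
  for (s in unique(ref$salt)) {
    tab <- ref[ref$salt == s, ]
    tab <- tab[order(tab$temperature_c), ]
    expect_true(all(diff(tab$aw) <= 0), info = s)
  }
})

test_that("desorption exceeds adsorption on average in every fixture condition", {
  d <- cherry_sorption()
  wide <- tidyr::pivot_wider(d, names_from = mode,
                             values_from = xeq_percent_db)
  gap <- dplyr::summarise(
    dplyr::group_by(wide, sample_id, temperature_c),
    mean_hysteresis = mean(desorption - adsorption), .groups = "drop")
  expect_true(all(gap$mean_hysteresis > 0))
})
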