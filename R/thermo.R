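#' Gibbs free energy of sorption
#'
#' `dG = R T ln(a_w)` (J/mol), negative for water activity below one.
#'
#' @param aw Water activity, strictly in (0, 1).
#' @param temperature_k Absolute temperature in Kelvin.
#' @return Free energy change in J/mol.
#' @examples
#' gibbs_free_energy(0.5, 303.15)  # about -1746.9 J/mol
#' @export
gibbs_free_energy <- function(aw, temperature_k) {
  if (any(aw <= 0) || any(aw >= 1)) {
    abort("water activity must be strictly in (0, 1)",
          class = "sorptherm_domain_error")
  }
  .gas_constant * temperature_k * log(aw)
}

#' Harmonic mean of a set of absolute temperatures
#'
#' `T_hm = n / sum(1 / T_i)` (Kelvin). The enthalpy-entropy compensation is
#' considered statistically meaningful only when the isokinetic temperature
#' differs from this value.
#'
#' @param temperature_k Absolute temperatures in Kelvin.
#' @return Harmonic mean temperature in Kelvin.
#' @examples
#' harmonic_mean_temperature(c(30, 40, 50) + 273.15)  # 312.94 K
#' @export
harmonic_mean_temperature <- function(temperature_k) {
  if (any(temperature_k <= 0)) {
    abort("temperatures must be positive Kelvin", class = "sorptherm_domain_error")
  }
  length(temperature_k) / sum(1 / temperature_k)
}

#' Net isosteric heat and differential entropy over a moisture grid
#'
#' For each series (sample x mode) with fits at several temperatures, reads
#' the water activity at constant moisture from the fitted isotherm inverses,
#' regresses `ln a_w` on `1/T` (Kelvin) by ordinary least squares, and
#' converts slope and intercept via the Clausius-Clapeyron relation:
#' net isosteric heat `q_st = -R * slope` (reported in kJ/mol) and
#' differential entropy `dS = R * intercept` (J/(mol K)). Grid points not
#' attainable at every temperature are dropped with a warning.
#'
#' @param fits A fits table from [fit_isotherms()]; typically the GAB rows.
#'   Each (sample, mode) group must hold one converged fit per temperature,
#'   at three or more temperatures.
#' @param grid Moisture grid in percent dry basis (default 10 to 30, step 1).
#' @param aw_max Inversion cap on water activity (default 0.95).
#' @return A tibble with one row per series x retained grid point:
#'   `sample_id`, `mode`, `xeq`, `qst_kj_mol`, `ds_j_mol_k`, `r2` (of the
#'   `ln a_w` vs `1/T` line), `n_temps`, and a nested `activity` tibble with
#'   per-temperature `aw`, `ln_aw` and `dg_j_mol` (Gibbs free energy).
#' @examples
#' thermo <- cherry_sorption() |>
#'   dplyr::filter(sample_id == "Burlat") |>
#'   fit_isotherms(models = "gab") |>
#'   isosteric_heat()
#' @export
isosteric_heat <- function(fits, grid = seq(10, 30, by = 1), aw_max = 0.95) {
  if (length(unique(fits$model)) > 1) {
    abort("isosteric_heat() expects fits from a single model; filter first",
          class = "sorptherm_validation_error")
  }
  fits <- filter(fits, .data$converged)
  groups <- fits |>
    group_by(.data$sample_id, .data$mode) |>
    tidyr::nest(.key = "tfits") |>
    ungroup()
  out <- pmap(list(groups$sample_id, groups$mode, groups$tfits),
              function(sid, md, tf) {
    if (anyDuplicated(tf$temperature_c)) {
      abort("multiple fits at the same temperature within a series",
            class = "sorptherm_validation_error")
    }
    if (nrow(tf) < 3) {
      abort("need fits at three or more temperatures",
            class = "sorptherm_validation_error")
    }
    tk <- tf$temperature_c + 273.15
    rows <- map(grid, function(X) {
      aw <- vapply(tf$fit, function(f) {
        tryCatch(invert_isotherm(f$model, f$params, X, aw_max = aw_max),
                 sorptherm_range_error = function(e) NA_real_)
      }, numeric(1))
      if (any(is.na(aw)) || any(aw <= 0) || any(aw >= 1)) return(NULL)
      ln_aw <- log(aw)
      line <- lm(ln_aw ~ I(1 / tk))
      cf <- coef(line)
      sst <- sum((ln_aw - mean(ln_aw))^2)
      r2 <- if (sst > 0) 1 - sum(line$residuals^2) / sst else NA_real_
      tibble(sample_id = sid, mode = md, xeq = X,
             qst_kj_mol = -.gas_constant * cf[[2]] / 1000,
             ds_j_mol_k = .gas_constant * cf[[1]],
             r2 = r2, n_temps = nrow(tf),
             activity = list(tibble(temperature_c = tf$temperature_c,
                                    aw = aw, ln_aw = ln_aw,
                                    dg_j_mol = gibbs_free_energy(aw, tk))))
    })
    dropped <- sum(vapply(rows, is.null, logical(1)))
    if (dropped > 0) {
      warn(sprintf("%s/%s: %d grid point(s) outside the jointly attainable range",
                   sid, md, dropped))
    }
    list_rbind(rows[!vapply(rows, is.null, logical(1))])
  })
  list_rbind(out)
}

#' Polynomial smoothing of a thermodynamic curve
#'
#' Ordinary least-squares polynomial fit (default cubic) used to summarise
#' the dependence of isosteric heat or differential entropy on moisture
#' content.
#'
#' @param x Grid values (moisture content, percent dry basis).
#' @param y Response (e.g. `qst_kj_mol` or `ds_j_mol_k`).
#' @param degree Polynomial degree (default 3).
#' @return An object of class `poly_smooth`: list with `coefficients`
#'   (ascending powers, length `degree + 1`), `degree` and `r`
#'   (`sqrt(1 - SSE/SST)` of the fit).
#' @examples
#' s <- smooth_polynomial(1:10, (1:10)^3 - 2 * (1:10) + 5)
#' s$coefficients  # 5, -2, 0, 1
#' @export
smooth_polynomial <- function(x, y, degree = 3) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "sorptherm_validation_error")
  }
  if (length(x) < degree + 1) {
    abort("underdetermined: need at least degree + 1 points",
          class = "sorptherm_validation_error")
  }
  fit <- if (degree == 0) lm(y ~ 1) else lm(y ~ poly(x, degree, raw = TRUE))
  cf <- unname(coef(fit))
  sst <- sum((y - mean(y))^2)
  sse <- sum(fit$residuals^2)
  r <- if (sst > 0) sqrt(min(1, max(0, 1 - sse / sst))) else 1
  structure(list(coefficients = cf, degree = degree, r = r),
            class = "poly_smooth")
}

#' @export
predict.poly_smooth <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  drop(outer(x, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.poly_smooth <- function(x, ...) {
  terms <- sprintf("%.4g*x^%d", x$coefficients, 0:x$degree)
  cat("<poly_smooth> y =", paste(terms, collapse = " + "),
      sprintf(" (r = %.4f)\n", x$r))
  invisible(x)
}

#' Enthalpy-entropy compensation analysis
#'
#' Regresses the net isosteric heat (J/mol) on the differential entropy
#' (J/(mol K)) over the moisture grid, per series. The slope is the
#' isokinetic temperature `T_beta` (K) and the intercept the free energy at
#' the isokinetic temperature, `dG_beta` (J/mol); a positive `dG_beta` marks
#' a non-spontaneous sorption process. The compensation is deemed valid when
#' `T_beta` differs from the harmonic mean of the experimental temperatures.
#'
#' @param thermo A table from [isosteric_heat()].
#' @return A tibble with one row per series: `t_beta_k`, `dg_beta_j_mol`,
#'   `r` of the compensation line, `t_hm_k`, `spontaneity`
#'   (`"spontaneous"`/`"non-spontaneous"`) and `valid_compensation`.
#' @examples
#' cherry_sorption() |>
#'   dplyr::filter(sample_id == "Burlat", mode == "desorption") |>
#'   fit_isotherms(models = "gab") |>
#'   isosteric_heat() |>
#'   compensation_analysis()
#' @export
compensation_analysis <- function(thermo) {
  thermo |>
    group_by(.data$sample_id, .data$mode) |>
    tidyr::nest(.key = "pts") |>
    ungroup() |>
    mutate(res = map(.data$pts, function(p) {
      if (nrow(p) < 3) {
        abort("need at least 3 retained grid points for compensation",
              class = "sorptherm_validation_error")
      }
      ds <- p$ds_j_mol_k
      q <- p$qst_kj_mol * 1000
      if (stats::sd(ds) < 1e-12) {
        abort("degenerate differential-entropy spread",
              class = "sorptherm_regression_error")
      }
      line <- lm(q ~ ds)
      cf <- coef(line)
      sst <- sum((q - mean(q))^2)
      r <- sqrt(min(1, max(0, 1 - sum(line$residuals^2) / sst)))
      tk <- unique(unlist(map(p$activity, "temperature_c"))) + 273.15
      t_hm <- harmonic_mean_temperature(tk)
      tibble(t_beta_k = cf[[2]], dg_beta_j_mol = cf[[1]], r = r,
             t_hm_k = t_hm,
             spontaneity = if (cf[[1]] > 0) "non-spontaneous" else "spontaneous",
             valid_compensation = cf[[2]] != t_hm,
             n_points = nrow(p))
    })) |>
    select(-"pts") |>
    tidyr::unnest("res")
}
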