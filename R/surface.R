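#' Spreading pressure from the GAB closed form
#'
#' Surface excess free energy of the sorbed water film,
#' `pi = (k_B T / A_m) * ln((1 - B a_w + C B a_w) / (1 - B a_w))` (J/m^2),
#' the analytic integral of `(k_B T / A_m) * theta / a_w` with
#' `theta = X/X_m` under the GAB isotherm. Constants: Boltzmann
#' `k_B = 1.380e-23` J/K and water molecule area `A_m = 1.06e-19` m^2.
#'
#' @param aw Water activity, `0 <= aw < 1/B`.
#' @param temperature_k Absolute temperature in Kelvin.
#' @param params Named GAB parameter vector (`A`, `B`, `C`).
#' @return Spreading pressure in J/m^2.
#' @examples
#' spreading_pressure(0.5, 303.15, c(A = 10, B = 0.8, C = 5))
#' @export
spreading_pressure <- function(aw, temperature_k, params) {
  p <- .check_params("gab", unlist(params))
  if (any(aw < 0)) abort("negative water activity", class = "sorptherm_domain_error")
  if (any(p[["B"]] * aw >= 1)) {
    abort("B * aw >= 1: GAB pole crossed", class = "sorptherm_domain_error")
  }
  ba <- p[["B"]] * aw
  (.boltzmann * temperature_k / .water_molecule_area) *
    log((1 - ba + p[["C"]] * ba) / (1 - ba))
}

#' Spreading pressure by adaptive quadrature
#'
#' Numerical integration of `(k_B T / A_m) * integral_0^aw theta(u)/u du`
#' with `theta = X(u)/X_m` under the GAB isotherm; the integrand is finite at
#' zero (limit `B C`). Serves as the independent check of the closed form
#' [spreading_pressure()].
#'
#' @inheritParams spreading_pressure
#' @param rel_tol Relative tolerance of the quadrature.
#' @return Spreading pressure in J/m^2.
#' @export
spreading_pressure_numeric <- function(aw, temperature_k, params,
                                       rel_tol = 1e-10) {
  p <- .check_params("gab", unlist(params))
  if (any(aw < 0)) abort("negative water activity", class = "sorptherm_domain_error")
  if (any(p[["B"]] * aw >= 1)) {
    abort("B * aw >= 1: GAB pole crossed", class = "sorptherm_domain_error")
  }
  # theta(u)/u = B C / ((1 - B u)(1 - B u + C B u)); continuous on [0, aw]
  integrand <- function(u) {
    bu <- p[["B"]] * u
    p[["B"]] * p[["C"]] / ((1 - bu) * (1 - bu + p[["C"]] * bu))
  }
  vapply(aw, function(a) {
    if (a == 0) return(0)
    val <- tryCatch(
      integrate(integrand, 0, a, rel.tol = rel_tol, abs.tol = 0)$value,
      error = function(e) abort(paste0("quadrature failed: ", conditionMessage(e)),
                                class = "sorptherm_numeric_error"))
    (.boltzmann * temperature_k / .water_molecule_area) * val
  }, numeric(1))
}

#' Spreading-pressure curve of a fitted GAB isotherm
#'
#' Evaluates the closed-form spreading pressure on a reporting grid of water
#' activities for one fitted series.
#'
#' @param fit An `isotherm_fit` object for the GAB model.
#' @param aw Water-activity grid (default 0.05 to 0.90 in steps of 0.05).
#' @return A tibble with the series key, `aw` and `pi_j_m2`.
#' @export
spreading_pressure_curve <- function(fit, aw = seq(0.05, 0.90, by = 0.05)) {
  stopifnot(inherits(fit, "isotherm_fit"))
  if (!identical(fit$model, "gab")) {
    abort("spreading pressure uses the GAB closed form; fit the GAB model",
          class = "sorptherm_validation_error")
  }
  tk <- fit$key$temperature_c + 273.15
  tibble(sample_id = fit$key$sample_id, mode = fit$key$mode,
         temperature_c = fit$key$temperature_c, aw = aw,
         pi_j_m2 = spreading_pressure(aw, tk, fit$params))
}

#' Sorption surface area from monolayer moisture
#'
#' `S0 = 3.5e3 * M_m` square metres per gram of dry solid, where `M_m` is the
#' fractional monolayer moisture (kg water per kg dry solid). The constant
#' collects the molecular weight of water (18 g/mol), Avogadro's number and
#' the area of a water molecule (1.06e-19 m^2).
#'
#' @param m_m Monolayer moisture content, fractional dry basis; must be
#'   positive.
#' @return Surface area in m^2/g.
#' @examples
#' surface_area(0.1)  # 350
#' @export
surface_area <- function(m_m) {
  if (any(!is.finite(m_m)) || any(m_m <= 0)) {
    abort("monolayer moisture must be positive", class = "sorptherm_domain_error")
  }
  3.5e3 * m_m
}

#' Surface properties of every fitted series
#'
#' Computes the sorption surface area (from the GAB monolayer) and the
#' spreading-pressure curve for each converged GAB fit in a fits table.
#'
#' @param fits A fits table from [fit_isotherms()] (GAB rows are used).
#' @param aw Water-activity grid for the spreading-pressure curves.
#' @return A tibble with one row per series: the key, `m_m` (fractional
#'   monolayer moisture), `s0_m2_g`, and a nested `pressure_curve`.
#' @export
surface_properties <- function(fits, aw = seq(0.05, 0.90, by = 0.05)) {
  gab <- filter(fits, .data$model == "gab", .data$converged)
  if (nrow(gab) == 0) {
    abort("no converged GAB fits in the table", class = "sorptherm_validation_error")
  }
  gab |>
    mutate(
      m_m = map_dbl(.data$fit, monolayer_moisture),
      s0_m2_g = surface_area(.data$m_m),
      pressure_curve = map(.data$fit, spreading_pressure_curve, aw = .env$aw)
    ) |>
    select(all_of(c("sample_id", "mode", "temperature_c", "m_m", "s0_m2_g",
                    "pressure_curve")))
}

#' Optimal storage humidity from the cubic sorption curve
#'
#' Fits a cubic `X = c3 a^3 + c2 a^2 + c1 a + c0` to one isotherm and returns
#' its inflection point `a_w = -c2 / (3 c3)` — the water activity where the
#' curvature changes between the two limbs of the sigmoid — together with the
#' moisture content there. The reading is method-inferred: it summarises the
#' fitted cubic, not a measured optimum.
#'
#' @param data Sorption records of a single series (columns `aw`,
#'   `xeq_percent_db`; at least 4 points).
#' @return A tibble with `aw_op`, `xeq_op` and the cubic coefficients
#'   (ascending powers) in a list-column `coefficients`.
#' @examples
#' van50 <- dplyr::filter(cherry_sorption(), sample_id == "Van",
#'                        mode == "desorption", temperature_c == 50)
#' optimal_storage(van50)
#' @export
optimal_storage <- function(data) {
  data <- as_tibble(data)
  if (nrow(data) < 4) {
    abort("need at least 4 points for a cubic", class = "sorptherm_validation_error")
  }
  sm <- smooth_polynomial(data$aw, data$xeq_percent_db, degree = 3)
  c3 <- sm$coefficients[4]
  c2 <- sm$coefficients[3]
  if (abs(c3) < 1e-10 * max(1, abs(c2))) {
    abort("cubic coefficient is numerically zero: no inflection point",
          class = "sorptherm_analysis_error")
  }
  aw_op <- -c2 / (3 * c3)
  tibble(aw_op = aw_op,
         xeq_op = predict(sm, aw_op),
         coefficients = list(sm$coefficients))
}
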