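#' Run the full sorption analysis pipeline
#'
#' End-to-end orchestration: load (or accept) a sorption table, fit all
#' requested isotherm models per series, select the best model, derive the
#' isosteric heat / differential entropy grid, the enthalpy-entropy
#' compensation, the surface properties (monolayer surface area and
#' spreading-pressure curves) and the cubic optimal-storage reading, and
#' write the report bundle to `outdir`:
#' `fits.csv`, `thermo.csv`, `compensation.csv`, `surface.csv`,
#' `pressure_curves.csv`, `storage.csv` and `summary.json`.
#' CSV numbers are rounded to 4 decimals for table-style reading; the JSON
#' summary keeps full precision. Re-running on identical input and
#' configuration gives byte-identical outputs.
#'
#' @param input A data frame of sorption records, a CSV path, or
#'   `"fixture:cherry"` for the packaged cherry dataset.
#' @param outdir Output directory (created if missing). `NULL` skips writing
#'   and just returns the bundle.
#' @param models Models to fit (default all three).
#' @param grid Moisture grid for the isosteric analysis (percent dry basis).
#' @param poly_degree Degree for the q_st and dS polynomial smooths.
#' @param aw_curve Water-activity grid for spreading-pressure curves.
#' @param storage_temperature_c,storage_mode Series used for the cubic
#'   optimal-storage analysis (default desorption at 50 degrees Celsius).
#' @return Invisibly, a named list of tibbles (`fits`, `selection`, `thermo`,
#'   `smooths`, `compensation`, `surface`, `storage`) plus `overall_model`.
#' @examples
#' \donttest{
#' bundle <- run_sorption_pipeline("fixture:cherry", outdir = tempdir())
#' }
#' @export
run_sorption_pipeline <- function(input, outdir = NULL,
                                  models = c("gab", "peleg", "enderby"),
                                  grid = seq(10, 30, by = 1),
                                  poly_degree = 3,
                                  aw_curve = seq(0.05, 0.90, by = 0.05),
                                  storage_temperature_c = 50,
                                  storage_mode = "desorption") {
  data <- if (is.data.frame(input)) {
    validate_sorption_data(input)
  } else if (identical(input, "fixture:cherry")) {
    cherry_sorption()
  } else if (is.character(input)) {
    read_sorption_csv(input)
  } else {
    abort("input must be a data frame, a CSV path, or 'fixture:cherry'",
          class = "sorptherm_validation_error")
  }

  fits <- fit_isotherms(data, models = models)
  selection <- select_best_model(fits)
  overall <- overall_best_model(fits)

  gab_fits <- filter(fits, .data$model == "gab")
  thermo <- suppressWarnings(isosteric_heat(gab_fits, grid = grid))
  smooths <- thermo |>
    group_by(.data$sample_id, .data$mode) |>
    tidyr::nest(.key = "pts") |>
    ungroup() |>
    mutate(res = map(.data$pts, function(p) {
      qs <- smooth_polynomial(p$xeq, p$qst_kj_mol, degree = poly_degree)
      ds <- smooth_polynomial(p$xeq, p$ds_j_mol_k, degree = poly_degree)
      tibble(response = c("qst_kj_mol", "ds_j_mol_k"),
             degree = poly_degree,
             coefficients = list(qs$coefficients, ds$coefficients),
             r = c(qs$r, ds$r))
    })) |>
    select(-"pts") |>
    tidyr::unnest("res")
  compensation <- compensation_analysis(thermo)
  surface <- surface_properties(fits, aw = aw_curve)
  curves <- list_rbind(surface$pressure_curve)

  storage <- data |>
    filter(.data$mode == storage_mode,
           .data$temperature_c == storage_temperature_c) |>
    group_by(.data$sample_id) |>
    tidyr::nest(.key = "rec") |>
    ungroup() |>
    mutate(res = map(.data$rec, optimal_storage)) |>
    select(-"rec") |>
    tidyr::unnest("res") |>
    mutate(method_inferred = TRUE,
           in_range = .data$aw_op > 0 & .data$aw_op < 1)

  bundle <- list(
    fits = fits, selection = selection, overall_model = overall,
    thermo = thermo, smooths = smooths, compensation = compensation,
    surface = surface, pressure_curves = curves, storage = storage)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    round4 <- function(df) mutate(df, across(dplyr::where(is.numeric),
                                             function(x) round(x, 4)))
    fits_flat <- fits |>
      mutate(par = map(.data$params, function(p) {
        as_tibble(as.list(p))
      })) |>
      select(-all_of(c("fit", "params"))) |>
      tidyr::unnest("par")
    readr::write_csv(round4(fits_flat), file.path(outdir, "fits.csv"),
                     progress = FALSE)
    readr::write_csv(round4(select(thermo, -"activity")),
                     file.path(outdir, "thermo.csv"), progress = FALSE)
    readr::write_csv(round4(compensation),
                     file.path(outdir, "compensation.csv"), progress = FALSE)
    readr::write_csv(round4(select(surface, -"pressure_curve")),
                     file.path(outdir, "surface.csv"), progress = FALSE)
    readr::write_csv(mutate(curves, pi_j_m2 = signif(.data$pi_j_m2, 6)),
                     file.path(outdir, "pressure_curves.csv"), progress = FALSE)
    readr::write_csv(round4(select(storage, -"coefficients")),
                     file.path(outdir, "storage.csv"), progress = FALSE)
    summary <- list(
      overall_model = overall,
      selection = selection,
      parameters = fits_flat,
      compensation = compensation,
      surface = select(surface, -"pressure_curve"),
      storage = select(storage, -"coefficients"),
      smooths = mutate(smooths, coefficients = map(.data$coefficients,
                                                   unname)))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
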