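#' Equilibrium moisture content from wet and dry mass
#'
#' Computes the gravimetric equilibrium moisture content on a dry basis,
#' `(mass_wet - mass_dry) / mass_dry`. The value is fractional
#' (kg water per kg dry solid); multiply by 100 for percent dry basis.
#'
#' @param mass_wet Sample mass before oven drying, in grams.
#' @param mass_dry Sample mass after oven drying, in grams. Must be positive.
#' @return Numeric vector of fractional dry-basis moisture contents.
#' @examples
#' compute_emc(2.0, 1.0)          # 1.0, i.e. 100% d.b.
#' 100 * compute_emc(8.72, 4.36)  # 100% d.b.
#' @export
compute_emc <- function(mass_wet, mass_dry) {
  if (any(!is.finite(mass_wet)) || any(!is.finite(mass_dry))) {
    abort("masses must be finite numbers", class = "sorptherm_domain_error")
  }
  if (any(mass_dry <= 0)) {
    abort("mass_dry must be > 0", class = "sorptherm_domain_error")
  }
  if (any(mass_wet < mass_dry)) {
    abort("mass_wet must be >= mass_dry (negative moisture)",
          class = "sorptherm_validation_error")
  }
  (mass_wet - mass_dry) / mass_dry
}

.sorption_cols <- c("sample_id", "mode", "temperature_c", "aw", "xeq_percent_db")

#' Validate a table of sorption records
#'
#' Checks the canonical record schema (`sample_id`, `mode`, `temperature_c`,
#' `aw`, `xeq_percent_db`), the admissible ranges (water activity strictly in
#' (0, 1), moisture content non-negative, mode one of
#' `"desorption"`/`"adsorption"`), and that no (series, a_w) point is
#' duplicated. Returns the data sorted by series and water activity.
#'
#' @param data A data frame of sorption records.
#' @return A validated tibble sorted by `sample_id`, `mode`, `temperature_c`,
#'   `aw`.
#' @export
validate_sorption_data <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(.sorption_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "sorptherm_validation_error")
  }
  bad_mode <- !data$mode %in% c("desorption", "adsorption")
  if (any(bad_mode)) {
    abort(paste0("invalid mode in row(s) ", paste(which(bad_mode), collapse = ", "),
                 " (must be 'desorption' or 'adsorption')"),
          class = "sorptherm_validation_error")
  }
  bad_aw <- !is.finite(data$aw) | data$aw <= 0 | data$aw >= 1
  if (any(bad_aw)) {
    abort(paste0("water activity outside (0, 1) in row(s) ",
                 paste(which(bad_aw), collapse = ", ")),
          class = "sorptherm_validation_error")
  }
  bad_x <- !is.finite(data$xeq_percent_db) | data$xeq_percent_db < 0
  if (any(bad_x)) {
    abort(paste0("negative or non-finite moisture content in row(s) ",
                 paste(which(bad_x), collapse = ", ")),
          class = "sorptherm_validation_error")
  }
  dup <- duplicated(data[, c("sample_id", "mode", "temperature_c", "aw")])
  if (any(dup)) {
    abort(paste0("duplicate (sample, mode, temperature, a_w) in row(s) ",
                 paste(which(dup), collapse = ", ")),
          class = "sorptherm_validation_error")
  }
  arrange(data, .data$sample_id, .data$mode, .data$temperature_c, .data$aw)
}

#' Read sorption records from CSV
#'
#' Reads a CSV file with header
#' `sample_id,mode,temperature_c,aw,xeq_percent_db` (UTF-8, `.` decimal
#' separator), validates it with [validate_sorption_data()], and reports
#' malformed rows by row number.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of sorption records.
#' @export
read_sorption_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "sorptherm_io_error")
  }
  # readr's own parse warning is redundant: problems() is turned into an
  # error with row numbers below
  data <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      mode = readr::col_character(),
      temperature_c = readr::col_double(),
      aw = readr::col_double(),
      xeq_percent_db = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(paste0("malformed value(s) at data row(s) ",
                 paste(unique(probs$row), collapse = ", "), " of ", path),
          class = "sorptherm_validation_error")
  }
  if (nrow(data) == 0) {
    warn(paste0("no records in ", path))
    return(as_tibble(data))
  }
  validate_sorption_data(data)
}

#' Write sorption records to CSV
#'
#' Writes the canonical record schema so that
#' `read_sorption_csv(write_sorption_csv(x, f))` round-trips field for field.
#'
#' @param data A data frame of sorption records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sorption_csv <- function(data, path) {
  data <- validate_sorption_data(data)
  readr::write_csv(data[, .sorption_cols], path, progress = FALSE)
  invisible(path)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "sorptherm")
  if (identical(path, "")) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Sweet cherry sorption reference dataset
#'
#' Equilibrium moisture content (percent dry basis) versus water activity for
#' five sweet cherry cultivars (Burlat, Van, Napoleon, Cerisette, Coeur
#' pigeon), both desorption and adsorption, at 30, 40 and 50 degrees Celsius;
#' six saturated-salt design points per isotherm (180 records, 30 series).
#'
#' @return A tibble of validated sorption records.
#' @examples
#' cherry_sorption() |> head()
#' @export
cherry_sorption <- function() {
  read_sorption_csv(.extdata("cherry_sorption.csv"))
}

#' Cultivar metadata for the cherry dataset
#'
#' Soluble solids (degrees Brix) and fresh moisture (percent, wet basis) of
#' the five cultivars.
#'
#' @return A tibble with columns `sample_id`, `brix`, `moisture_percent`.
#' @export
cultivar_meta <- function() {
  readr::read_csv(.extdata("cultivar_meta.csv"),
                  col_types = "cdd", progress = FALSE)
}

#' Saturated-salt water activity reference table
#'
#' Standard water activities of the six saturated salt solutions used to
#' condition the sorption atmospheres, tabulated at 30, 40 and 50 degrees
#' Celsius.
#'
#' @return A tibble with columns `salt`, `temperature_c`, `aw`.
#' @export
salt_reference <- function() {
  readr::read_csv(.extdata("salt_aw.csv"), col_types = "cdd", progress = FALSE)
}

#' Water activity of a saturated salt solution
#'
#' Exact lookup at the tabulated temperatures (30, 40, 50 degrees Celsius) and
#' linear interpolation in between.
#'
#' @param salt Salt name as it appears in [salt_reference()] (e.g. `"KOH"`,
#'   `"BaCl2.2H2O"`).
#' @param temperature_c Temperature in degrees Celsius, within \[30, 50\].
#' @return Water activity (dimensionless).
#' @examples
#' salt_aw("KOH", 30)   # 0.0738
#' salt_aw("KOH", 35)   # midpoint of the 30 and 40 degree values
#' @export
salt_aw <- function(salt, temperature_c) {
  ref <- salt_reference()
  tab <- ref[ref$salt == salt, ]
  if (nrow(tab) == 0) {
    abort(paste0("unknown salt: ", salt), class = "sorptherm_key_error")
  }
  rng <- range(tab$temperature_c)
  if (temperature_c < rng[1] || temperature_c > rng[2]) {
    abort(paste0("temperature ", temperature_c, " outside tabulated range [",
                 rng[1], ", ", rng[2], "]"), class = "sorptherm_domain_error")
  }
  stats::approx(tab$temperature_c, tab$aw, xout = temperature_c)$y
}
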