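#' Plot sorption isotherms
#'
#' Equilibrium moisture content against water activity, coloured by
#' temperature, with desorption and adsorption as line types, faceted by
#' sample.
#'
#' @param data A table of sorption records.
#' @return A ggplot object.
#' @export
plot_isotherms <- function(data) {
  data <- validate_sorption_data(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$aw, y = .data$xeq_percent_db,
                                     colour = factor(.data$temperature_c),
                                     linetype = .data$mode)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = "Water activity", y = "EMC (% dry basis)",
                  colour = "T (°C)", linetype = NULL)
}

#' Plot the net isosteric heat (and entropy) against moisture
#'
#' @param thermo A table from [isosteric_heat()].
#' @return A ggplot object.
#' @export
plot_isosteric_heat <- function(thermo) {
  ggplot2::ggplot(thermo, ggplot2::aes(x = .data$xeq, y = .data$qst_kj_mol,
                                       colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = "EMC (% dry basis)",
                  y = expression(q[st] ~ "(kJ/mol)"), colour = NULL)
}

#' Plot the enthalpy-entropy compensation lines
#'
#' Net isosteric heat against differential entropy per series; the slope of
#' each line is the isokinetic temperature.
#'
#' @param thermo A table from [isosteric_heat()].
#' @return A ggplot object.
#' @export
plot_compensation <- function(thermo) {
  ggplot2::ggplot(thermo, ggplot2::aes(x = .data$ds_j_mol_k,
                                       y = 1000 * .data$qst_kj_mol,
                                       colour = .data$sample_id,
                                       shape = .data$mode)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = expression(Delta * S ~ "(J/(mol K))"),
                  y = expression(q[st] ~ "(J/mol)"),
                  colour = NULL, shape = NULL)
}
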