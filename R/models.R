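#' Isotherm model registry
#'
#' Metadata for the three supported sorption isotherm models: parameter
#' names, box constraints used by the fitter, and parameter counts.
#' The GAB amplitude `A` is the monolayer moisture in percent dry basis,
#' `B` the multilayer (K) factor and `C` the Guggenheim energy constant.
#'
#' @param model One of `"gab"`, `"peleg"`, `"enderby"`; if missing, the whole
#'   registry is returned.
#' @return A tibble with columns `model`, `n_params`, `params` (list of
#'   parameter names), `lower` and `upper` (list of bound vectors).
#' @export
isotherm_model_info <- function(model = NULL) {
  eps <- 1e-8
  info <- tibble(
    model = c("gab", "peleg", "enderby"),
    n_params = c(3L, 4L, 4L),
    params = list(c("A", "B", "C"), c("A", "B", "C", "D"), c("A", "B", "C", "D")),
    lower = list(c(A = eps, B = eps, C = eps),
                 c(A = eps, B = eps, C = eps, D = eps),
                 c(A = 0, B = eps, C = 0, D = eps)),
    upper = list(c(A = Inf, B = 1 - eps, C = Inf),
                 c(A = Inf, B = Inf, C = Inf, D = Inf),
                 c(A = Inf, B = 1 - eps, C = Inf, D = 1 - eps))
  )
  if (is.null(model)) return(info)
  model <- match.arg(tolower(model), info$model)
  info[info$model == model, ]
}

.check_params <- function(model, params) {
  inf <- isotherm_model_info(model)
  need <- inf$params[[1]]
  if (!all(need %in% names(params))) {
    abort(paste0(model, " requires parameters ", paste(need, collapse = ", ")),
          class = "sorptherm_validation_error")
  }
  params[need]
}

#' GAB sorption isotherm
#'
#' Guggenheim-Anderson-de Boer multilayer sorption model
#' `X = A B C a_w / ((1 - B a_w) (1 - B a_w + C B a_w))`,
#' valid over nearly the whole water-activity range. `A` is the monolayer
#' moisture (same unit as the response, here percent dry basis), `B` in (0, 1)
#' the multilayer factor and `C > 0` the Guggenheim constant.
#'
#' @param aw Water activity, `0 <= aw < 1/B`.
#' @param params Named vector or list with elements `A`, `B`, `C`.
#' @return Predicted equilibrium moisture content (percent dry basis).
#' @examples
#' gab_moisture(0.5, c(A = 10, B = 0.8, C = 5))  # 12.8205...
#' @export
gab_moisture <- function(aw, params) {
  p <- .check_params("gab", unlist(params))
  if (any(aw < 0)) abort("negative water activity", class = "sorptherm_domain_error")
  if (any(p[["B"]] * aw >= 1)) {
    abort("B * aw >= 1: GAB pole crossed", class = "sorptherm_domain_error")
  }
  ba <- p[["B"]] * aw
  p[["A"]] * p[["C"]] * ba / ((1 - ba) * (1 - ba + p[["C"]] * ba))
}

#' Peleg sorption isotherm
#'
#' Double power-law model `X = A a_w^C + B a_w^D` with all four parameters
#' positive.
#'
#' @param aw Water activity in `[0, 1)`.
#' @param params Named vector or list with elements `A`, `B`, `C`, `D`.
#' @return Predicted equilibrium moisture content (percent dry basis).
#' @examples
#' peleg_moisture(0.25, c(A = 20, B = 80, C = 0.5, D = 4))  # 10.3125
#' @export
peleg_moisture <- function(aw, params) {
  p <- .check_params("peleg", unlist(params))
  if (any(aw < 0)) abort("negative water activity", class = "sorptherm_domain_error")
  p[["A"]] * aw^p[["C"]] + p[["B"]] * aw^p[["D"]]
}

#' Enderby sorption isotherm
#'
#' Sum of two hyperbolic terms, `X = (A / (1 - B a_w) + C / (1 - D a_w)) a_w`,
#' with both poles (`1/B`, `1/D`) outside the physical water-activity range.
#'
#' @param aw Water activity; requires `B * aw < 1` and `D * aw < 1`.
#' @param params Named vector or list with elements `A`, `B`, `C`, `D`.
#' @return Predicted equilibrium moisture content (percent dry basis).
#' @examples
#' enderby_moisture(0.5, c(A = 4, B = 0.5, C = 2, D = 0.8))  # 4.3333...
#' @export
enderby_moisture <- function(aw, params) {
  p <- .check_params("enderby", unlist(params))
  if (any(aw < 0)) abort("negative water activity", class = "sorptherm_domain_error")
  if (any(p[["B"]] * aw >= 1) || any(p[["D"]] * aw >= 1)) {
    abort("pole crossed in Enderby model", class = "sorptherm_domain_error")
  }
  (p[["A"]] / (1 - p[["B"]] * aw) + p[["C"]] / (1 - p[["D"]] * aw)) * aw
}

# validation-free evaluators used inside optimisation loops, where the box
# constraints already guarantee the domain conditions
.model_fun_raw <- function(model) {
  switch(model,
    gab = function(aw, p) {
      ba <- p[[2]] * aw
      p[[1]] * p[[3]] * ba / ((1 - ba) * (1 - ba + p[[3]] * ba))
    },
    peleg = function(aw, p) p[[1]] * aw^p[[3]] + p[[2]] * aw^p[[4]],
    enderby = function(aw, p) {
      (p[[1]] / (1 - p[[2]] * aw) + p[[3]] / (1 - p[[4]] * aw)) * aw
    }
  )
}

.model_fun <- function(model) {
  switch(model,
    gab = gab_moisture,
    peleg = peleg_moisture,
    enderby = enderby_moisture,
    abort(paste0("unknown model: ", model), class = "sorptherm_validation_error")
  )
}

#' Invert an isotherm model for water activity
#'
#' Finds the water activity at which the model predicts a given equilibrium
#' moisture content, by bracketed root finding on the (strictly increasing)
#' model curve. Needed to read a_w at constant moisture across temperatures
#' for the Clausius-Clapeyron analysis.
#'
#' @param model Model id (`"gab"`, `"peleg"`, `"enderby"`).
#' @param params Named parameter vector for the model.
#' @param xeq_target Target moisture content (percent dry basis).
#' @param aw_max Upper end of the admissible water-activity interval
#'   (default 0.95; values beyond the last datum are extrapolation).
#' @return Water activity in `[0, aw_max]`.
#' @examples
#' p <- c(A = 10, B = 0.8, C = 5)
#' invert_isotherm("gab", p, gab_moisture(0.5, p))  # 0.5
#' @export
invert_isotherm <- function(model, params, xeq_target, aw_max = 0.95) {
  f <- .model_fun(model)
  if (xeq_target < 0) {
    abort("target moisture must be >= 0", class = "sorptherm_range_error")
  }
  if (xeq_target == 0) return(0)
  p <- unlist(params)
  hi <- aw_max
  if (model %in% c("gab", "enderby")) {
    hi <- min(hi, 1 / p[["B"]] - 1e-9)
  }
  if (model == "enderby") hi <- min(hi, 1 / p[["D"]] - 1e-9)
  x_hi <- f(hi, p)
  if (xeq_target > x_hi) {
    abort(sprintf("target %.4g above attainable range (max %.4g at aw = %.4g)",
                  xeq_target, x_hi, hi), class = "sorptherm_range_error")
  }
  g <- function(a) f(a, p) - xeq_target
  root <- uniroot(g, lower = 0, upper = hi, tol = 1e-13)$root
  # bisection polish to machine precision: fitted curves can be steep enough
  # near the pole that the uniroot interval alone leaves a visible residual
  tol <- 1e-10 * max(1, xeq_target)
  if (abs(g(root)) >= tol) {
    lo <- 0; up <- hi
    for (i in 1:200) {
      mid <- (lo + up) / 2
      if (mid == lo || mid == up) break
      if (g(mid) > 0) up <- mid else lo <- mid
      root <- mid
      if (abs(g(root)) < tol) break
    }
    if (abs(g(root)) >= tol) {
      abort("inversion failed to reach residual tolerance",
            class = "sorptherm_numeric_error")
    }
  }
  root
}

#' Monolayer moisture from a GAB parameter vector
#'
#' Converts the GAB amplitude `A` (percent dry basis) to the fractional
#' monolayer moisture content `M_m` (kg water per kg dry solid) used by the
#' sorption surface-area relation.
#'
#' @param params Named GAB parameter vector (or an `isotherm_fit` object from
#'   [fit_isotherm()]).
#' @return Monolayer moisture, fractional dry basis.
#' @examples
#' monolayer_moisture(c(A = 4.99, B = 0.8, C = 5))  # 0.0499
#' @export
monolayer_moisture <- function(params) {
  if (inherits(params, "isotherm_fit")) {
    if (!identical(params$model, "gab")) {
      abort("monolayer moisture is defined for GAB fits only",
            class = "sorptherm_validation_error")
    }
    params <- params$params
  }
  p <- .check_params("gab", unlist(params))
  p[["A"]] / 100
}
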