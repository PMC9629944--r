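#' Goodness of fit for an isotherm prediction
#'
#' Computes the correlation coefficient `r = sqrt(1 - SSE/SST)` (clipped to
#' `[0, 1]`) and the mean relative error
#' `MRE = (100/N) * sum(|X_obs - X_pred| / X_obs)` in percent. Observations
#' equal to zero are excluded from the MRE with a warning (division guard).
#'
#' @param observed Observed moisture contents (percent dry basis).
#' @param predicted Model predictions at the same points.
#' @return A tibble with columns `r`, `mre`, `sse`, `n`.
#' @examples
#' goodness_of_fit(c(10, 20), c(11, 18))  # MRE = 10
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("observed and predicted must have equal length",
          class = "sorptherm_validation_error")
  }
  e <- observed - predicted
  sse <- sum(e^2)
  sst <- sum((observed - mean(observed))^2)
  r <- if (sst > 0) sqrt(min(1, max(0, 1 - sse / sst))) else 0
  keep <- observed != 0
  if (!all(keep)) warn("zero observations excluded from MRE")
  mre <- 100 * mean(abs(e[keep]) / observed[keep])
  tibble(r = r, mre = mre, sse = sse, n = length(observed))
}

.start_grid <- function(model, aw, xeq) {
  near <- function(target) xeq[which.min(abs(aw - target))]
  switch(model,
    gab = {
      a0 <- near(0.32)
      expand.grid(A = c(a0, a0 / 2, a0 * 2), B = c(0.5, 0.7, 0.9),
                  C = c(1, 5, 20), KEEP.OUT.ATTRS = FALSE)
    },
    peleg = {
      # endpoint heuristic: model value at aw = 1 is A + B
      xe <- xeq[which.max(aw)]
      expand.grid(A = c(xe / 2, xe), B = c(xe / 2, xe),
                  C = c(0.5, 1), D = c(2, 5), KEEP.OUT.ATTRS = FALSE)
    },
    enderby = {
      a3 <- near(0.3)
      expand.grid(A = a3 / 2, B = c(0.3, 0.7, 0.9),
                  C = a3 / 2, D = c(0.3, 0.7, 0.9), KEEP.OUT.ATTRS = FALSE)
    }
  )
}

#' Fit one isotherm model to one sorption series
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints,
#' cost tolerance 1e-10) minimising the plain sum of squared deviations
#' between observed and predicted moisture content. A deterministic
#' multi-start grid guards against local minima; the best converged start
#' wins, so identical inputs always give identical fits.
#'
#' @param data A data frame with columns `aw` and `xeq_percent_db` (a single
#'   series: one sample, mode and temperature).
#' @param model `"gab"`, `"peleg"` or `"enderby"`.
#' @return An object of class `isotherm_fit`: a list with elements `model`,
#'   `params` (named vector), `data`, `fitted`, `r`, `mre`, `sse`,
#'   `converged`, `n_starts_used`, `key`.
#' @examples
#' burlat30 <- dplyr::filter(cherry_sorption(), sample_id == "Burlat",
#'                           mode == "desorption", temperature_c == 30)
#' fit_isotherm(burlat30, "gab")
#' @export
fit_isotherm <- function(data, model = c("gab", "peleg", "enderby")) {
  model <- match.arg(tolower(model[1]), c("gab", "peleg", "enderby"))
  data <- as_tibble(data)
  if (!all(c("aw", "xeq_percent_db") %in% names(data))) {
    abort("data must have columns aw and xeq_percent_db",
          class = "sorptherm_validation_error")
  }
  data <- arrange(data, .data$aw)
  aw <- data$aw
  xeq <- data$xeq_percent_db
  if (anyDuplicated(aw)) {
    abort("duplicate water activities within a series",
          class = "sorptherm_validation_error")
  }
  inf <- isotherm_model_info(model)
  if (length(aw) < inf$n_params + 1L) {
    abort(sprintf("series too small: %d points for a %d-parameter model",
                  length(aw), inf$n_params),
          class = "sorptherm_validation_error")
  }
  f_raw <- .model_fun_raw(model)
  resid_fun <- function(p) {
    pred <- f_raw(aw, p)
    if (any(!is.finite(pred))) return(rep(1e8, length(xeq)))
    xeq - pred
  }
  starts <- .start_grid(model, aw, xeq)
  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    st <- unlist(starts[i, ])
    fitted <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = inf$lower[[1]], upper = inf$upper[[1]],
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                             maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fitted) || !fitted$info %in% 1:4) next
    n_used <- n_used + 1L
    if (is.null(best) || fitted$deviance < best$deviance) best <- fitted
  }
  key_cols <- intersect(c("sample_id", "mode", "temperature_c"), names(data))
  key <- if (length(key_cols)) as.list(distinct(data[, key_cols])) else list()
  if (is.null(best)) {
    out <- list(model = model, params = setNames(rep(NA_real_, inf$n_params),
                                                 inf$params[[1]]),
                data = data, fitted = rep(NA_real_, length(aw)),
                r = NA_real_, mre = NA_real_, sse = NA_real_,
                converged = FALSE, n_starts_used = 0L, key = key)
    return(structure(out, class = "isotherm_fit"))
  }
  params <- setNames(coef(best), inf$params[[1]])
  pred <- .model_fun(model)(aw, params)
  gof <- goodness_of_fit(xeq, pred)
  structure(list(model = model, params = params, data = data, fitted = pred,
                 r = gof$r, mre = gof$mre, sse = gof$sse,
                 converged = TRUE, n_starts_used = n_used, key = key),
            class = "isotherm_fit")
}

#' Fit isotherm models to every series of a sorption table
#'
#' Splits the records into series (one per `sample_id` x `mode` x
#' `temperature_c`), fits each requested model to each series with
#' [fit_isotherm()], and returns one row per series x model.
#'
#' @param data A validated table of sorption records (see
#'   [validate_sorption_data()]).
#' @param models Character vector of model ids to fit.
#' @return A tibble with the series key, `model`, `converged`,
#'   `n_starts_used`, goodness-of-fit columns `r` and `mre`, the parameter
#'   estimates in a list-column `params`, and the full `isotherm_fit` object
#'   in list-column `fit`.
#' @examples
#' fits <- cherry_sorption() |> fit_isotherms(models = "gab")
#' @export
fit_isotherms <- function(data, models = c("gab", "peleg", "enderby")) {
  data <- validate_sorption_data(data)
  models <- match.arg(tolower(models), c("gab", "peleg", "enderby"),
                      several.ok = TRUE)
  series <- data |>
    group_by(.data$sample_id, .data$mode, .data$temperature_c) |>
    tidyr::nest(.key = "records") |>
    ungroup()
  grid <- tidyr::expand_grid(series, model = models)
  fits <- pmap(list(grid$records, grid$model, grid$sample_id, grid$mode,
                    grid$temperature_c), function(rec, m, sid, md, tc) {
    f <- fit_isotherm(rec, m)
    f$key <- list(sample_id = sid, mode = md, temperature_c = tc)
    f
  })
  grid |>
    mutate(
      fit = fits,
      converged = map_dbl(fits, function(f) f$converged) > 0,
      n_starts_used = map_dbl(fits, function(f) f$n_starts_used),
      r = map_dbl(fits, function(f) f$r),
      mre = map_dbl(fits, function(f) f$mre),
      params = map(fits, function(f) f$params)
    ) |>
    select(-"records")
}

#' Best model per series and overall
#'
#' Ranks converged fits within each series by higher correlation coefficient
#' (rounded to 3 decimals, the table-reporting precision; ties broken by
#' lower mean relative error) and flags fits with MRE above 10 percent as
#' unacceptable.
#'
#' @param fits A fits table from [fit_isotherms()].
#' @param mre_threshold Acceptability threshold on MRE, percent (default 10).
#' @return A tibble with one row per series: the winning `model`, its `r`
#'   and `mre`, and `acceptable`.
#' @seealso [overall_best_model()]
#' @export
select_best_model <- function(fits, mre_threshold = 10) {
  conv <- filter(fits, .data$converged)
  if (nrow(conv) == 0) {
    abort("no converged fit to select from", class = "sorptherm_selection_error")
  }
  conv |>
    group_by(.data$sample_id, .data$mode, .data$temperature_c) |>
    arrange(dplyr::desc(round(.data$r, 3)), .data$mre, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(acceptable = .data$mre <= mre_threshold) |>
    select(all_of(c("sample_id", "mode", "temperature_c", "model", "r", "mre",
                    "acceptable")))
}

#' Overall winning model across all series
#'
#' The model selected for the most series by [select_best_model()]; ties are
#' broken by the lower mean MRE across all series.
#'
#' @inheritParams select_best_model
#' @return A single model id.
#' @export
overall_best_model <- function(fits, mre_threshold = 10) {
  per_series <- select_best_model(fits, mre_threshold)
  mean_mre <- fits |>
    filter(.data$converged) |>
    group_by(.data$model) |>
    summarise(mean_mre = mean(.data$mre), .groups = "drop")
  score <- per_series |>
    group_by(.data$model) |>
    summarise(wins = n(), .groups = "drop") |>
    left_join(mean_mre, by = "model") |>
    arrange(dplyr::desc(.data$wins), .data$mean_mre)
  score$model[1]
}

#' @export
print.isotherm_fit <- function(x, ...) {
  key <- if (length(x$key)) paste(unlist(x$key), collapse = " / ") else "<series>"
  cat(sprintf("<isotherm_fit> %s: %s\n", toupper(x$model), key))
  if (x$converged) {
    cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                           collapse = ", "), "\n")
    cat(sprintf("  r = %.4f, MRE = %.3f%% (n = %d, %d starts converged)\n",
                x$r, x$mre, nrow(x$data), x$n_starts_used))
  } else {
    cat("  fit did not converge\n")
  }
  invisible(x)
}

#' @export
predict.isotherm_fit <- function(object, newdata = NULL, ...) {
  aw <- if (is.null(newdata)) object$data$aw else {
    if (is.data.frame(newdata)) newdata$aw else newdata
  }
  .model_fun(object$model)(aw, object$params)
}

#' @rdname fit_isotherm
#' @param x,object An `isotherm_fit` object.
#' @param ... Unused.
#' @method tidy isotherm_fit
#' @export
tidy.isotherm_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_isotherm
#' @method glance isotherm_fit
#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble(model = x$model, r = x$r, mre = x$mre, sse = x$sse,
         n = nrow(x$data), converged = x$converged,
         n_starts_used = x$n_starts_used)
}

#' @rdname fit_isotherm
#' @method augment isotherm_fit
#' @export
augment.isotherm_fit <- function(x, ...) {
  mutate(x$data, .fitted = x$fitted, .resid = .data$xeq_percent_db - x$fitted)
}

#' @rdname fit_isotherm
#' @method autoplot isotherm_fit
#' @export
autoplot.isotherm_fit <- function(object, ...) {
  curve_aw <- seq(min(object$data$aw), max(object$data$aw), length.out = 200)
  curve <- tibble(aw = curve_aw, xeq = predict(object, curve_aw))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$aw, y = .data$xeq_percent_db)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$xeq)) +
    ggplot2::labs(x = "Water activity", y = "EMC (% dry basis)",
                  title = sprintf("%s fit (r = %.3f, MRE = %.2f%%)",
                                  toupper(object$model), object$r, object$mre))
}
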