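#' Default ground-truth parameters for the synthetic generator
#'
#' A GAB parameter set with the monolayer amplitude decreasing in temperature
#' (less hygroscopic material when warmer), producing type-II isotherms whose
#' moisture decreases with temperature at fixed water activity.
#'
#' @param temperatures Temperatures in degrees Celsius.
#' @return A named list (one element per temperature) of GAB parameter
#'   vectors.
#' @export
default_true_params <- function(temperatures = c(30, 40, 50)) {
  a <- stats::approx(c(30, 40, 50), c(12, 9, 7), xout = temperatures)$y
  setNames(lapply(seq_along(temperatures),
                  function(i) c(A = a[i], B = 0.85, C = 8)),
           as.character(temperatures))
}

.default_design <- function(temperatures) {
  ref <- salt_reference()
  setNames(lapply(temperatures, function(tt) {
    sort(ref$aw[ref$temperature_c == tt])
  }), as.character(temperatures))
}

#' Generate synthetic sorption data with known ground truth
#'
#' Draws equilibrium moisture contents from an isotherm model with
#' multiplicative Gaussian noise, `x = model(a_w) * (1 + eps)` with
#' `eps ~ N(0, sigma^2)` truncated at three standard deviations, floored at
#' 0.1 percent dry basis. The default design mirrors a saturated-salt
#' experiment: six water activities per temperature at 30, 40 and 50 degrees
#' Celsius. Multiplicative noise reflects how sorption balances err in
#' proportion to sample mass and keeps small moisture values positive.
#'
#' @param true_params Named list (one element per temperature, names are the
#'   temperatures) of model parameter vectors; default
#'   [default_true_params()].
#' @param model Model id (default `"gab"`).
#' @param temperatures Temperatures in degrees Celsius.
#' @param aw Water-activity design: a numeric vector used at every
#'   temperature, or a named list per temperature; default the tabulated
#'   saturated-salt values.
#' @param sigma Multiplicative noise standard deviation (default 0.02).
#' @param replicates Number of replicate datasets (default 1); replicates are
#'   distinguished by a `_r<k>` suffix on `sample_id`.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param sample_id,mode Labels for the generated series.
#' @return A list with `data` (a validated tibble of sorption records) and
#'   `truth` (a tibble of the generating parameters, one row per temperature
#'   x parameter, plus the noise level).
#' @examples
#' sim <- simulate_sorption(sigma = 0, seed = 1)
#' sim$data
#' @export
simulate_sorption <- function(true_params = default_true_params(temperatures),
                              model = "gab",
                              temperatures = c(30, 40, 50),
                              aw = NULL, sigma = 0.02, replicates = 1,
                              seed = 1, sample_id = "synthetic",
                              mode = "desorption") {
  if (sigma < 0) abort("sigma must be >= 0", class = "sorptherm_config_error")
  f <- .model_fun(model)
  inf <- isotherm_model_info(model)
  if (is.null(aw)) aw <- .default_design(temperatures)
  if (!is.list(aw)) aw <- setNames(rep(list(aw), length(temperatures)),
                                   as.character(temperatures))
  for (tt in as.character(temperatures)) {
    p <- unlist(true_params[[tt]])
    if (is.null(p)) {
      abort(paste0("no true parameters for temperature ", tt),
            class = "sorptherm_config_error")
    }
    lo <- inf$lower[[1]]; up <- inf$upper[[1]]
    if (any(p < lo) || any(p > up)) {
      abort(paste0("true parameters violate ", model, " bounds at ", tt, " C"),
            class = "sorptherm_config_error")
    }
  }
  set.seed(seed)
  rows <- list()
  for (k in seq_len(replicates)) {
    sid <- if (replicates == 1) sample_id else paste0(sample_id, "_r", k)
    for (tt in as.character(temperatures)) {
      a <- aw[[tt]]
      mu <- f(a, unlist(true_params[[tt]]))
      eps <- pmin(pmax(rnorm(length(a), 0, sigma), -3 * sigma), 3 * sigma)
      x <- pmax(mu * (1 + eps), 0.1)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = sid, mode = mode, temperature_c = as.numeric(tt),
        aw = a, xeq_percent_db = x)
    }
  }
  truth <- list_rbind(map(as.character(temperatures), function(tt) {
    p <- unlist(true_params[[tt]])
    tibble(model = model, temperature_c = as.numeric(tt),
           param = names(p), value = unname(p))
  }))
  truth$sigma <- sigma
  list(data = validate_sorption_data(list_rbind(rows)), truth = truth)
}

#' Parameter and downstream-quantity recovery under noise
#'
#' Monte-Carlo assessment of the whole estimation chain: repeatedly generate
#' noisy datasets from a known ground truth, refit the model at each
#' temperature, and (optionally) push the fits through the thermodynamic
#' pipeline. Reports bias, RMSE and the median absolute relative error per
#' parameter and, with `downstream = TRUE`, for the net isosteric heat at
#' 18 percent moisture, the isokinetic temperature and the 30-degree surface
#' area.
#'
#' @inheritParams simulate_sorption
#' @param n_reps Number of Monte-Carlo replicates (default 200).
#' @param downstream Also evaluate derived thermodynamic quantities
#'   (default TRUE; slower).
#' @param qst_at Moisture level (percent dry basis) at which the isosteric
#'   heat is compared.
#' @return A tibble with one row per quantity: `quantity`, `temperature_c`
#'   (NA for pooled/downstream quantities), `truth`, `bias`, `rmse`,
#'   `median_abs_rel_err`, `n_reps`.
#' @export
recovery_report <- function(n_reps = 200, sigma = 0.02, seed = 1,
                            true_params = default_true_params(temperatures),
                            temperatures = c(30, 40, 50),
                            model = "gab", downstream = TRUE, qst_at = 18) {
  # ground truth for downstream quantities: the noiseless chain
  noiseless <- simulate_sorption(true_params, model, temperatures,
                                 sigma = 0, seed = seed)
  fits0 <- fit_isotherms(noiseless$data, models = model)
  truth_down <- NULL
  if (downstream) {
    th0 <- suppressWarnings(isosteric_heat(fits0))
    comp0 <- compensation_analysis(th0)
    s00 <- surface_properties(fits0)
    truth_down <- c(
      qst = th0$qst_kj_mol[th0$xeq == qst_at],
      t_beta = comp0$t_beta_k[1],
      s0 = s00$s0_m2_g[s00$temperature_c == temperatures[1]])
  }
  truth_par <- simulate_sorption(true_params, model, temperatures,
                                 sigma = 0, seed = seed)$truth
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  one_rep <- function(k) {
    sim <- simulate_sorption(true_params, model, temperatures,
                             sigma = sigma, seed = rep_seeds[k])
    fits <- fit_isotherms(sim$data, models = model)
    est <- fits |>
      mutate(par = map(.data$params, function(p) {
        tibble(param = names(p), estimate = unname(p))
      })) |>
      select(all_of(c("temperature_c", "par"))) |>
      tidyr::unnest("par")
    down <- NULL
    if (downstream) {
      th <- suppressWarnings(isosteric_heat(fits))
      comp <- compensation_analysis(th)
      s0 <- surface_properties(fits)
      down <- tibble(
        param = c("qst", "t_beta", "s0"), temperature_c = NA_real_,
        estimate = c(th$qst_kj_mol[th$xeq == qst_at],
                     comp$t_beta_k[1],
                     s0$s0_m2_g[s0$temperature_c == temperatures[1]]))
    }
    bind_rows(est, down) |> mutate(rep = k)
  }
  est <- list_rbind(map(seq_len(n_reps), one_rep))
  truth_tbl <- bind_rows(
    select(truth_par, all_of(c("temperature_c", "param", "value"))),
    if (downstream) tibble(temperature_c = NA_real_,
                           param = c("qst", "t_beta", "s0"),
                           value = unname(truth_down)))
  est |>
    left_join(truth_tbl, by = c("temperature_c", "param")) |>
    group_by(.data$param, .data$temperature_c) |>
    summarise(
      truth = .data$value[1],
      bias = mean(.data$estimate - .data$value),
      rmse = sqrt(mean((.data$estimate - .data$value)^2)),
      median_abs_rel_err = median(abs((.data$estimate - .data$value) /
                                        .data$value)),
      n_reps = n(), .groups = "drop") |>
    rename(quantity = "param")
}
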