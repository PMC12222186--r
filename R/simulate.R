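# Synthetic study-corpus generator.
#
# Emulates the statistical structure the meta-analysis assumes: per-setting
# monotone-decreasing dose-response of the relative value, multiplicative
# lognormal between-study noise, occasional gross outliers (targets for the
# Hampel filter), and setting-imbalanced study counts (greenhouse-heavy,
# mirroring the composition of published wheat salt-stress corpora,
# field:outdoor:greenhouse:chamber roughly 117:77:296:49, scaled down).

#' Per-setting dose-response parameters
#'
#' @param setting One of [setting_levels()].
#' @param c50 Stress-axis value (dS/m of relative EC) at which the mean
#'   relative response reaches 0.5.
#' @param shape Steepness of the response curve (> 0).
#' @param sigma_noise SD of the multiplicative lognormal noise (log scale).
#' @param contamination_rate Probability that an observation is replaced by
#'   a gross outlier (< 0.5).
#' @param contamination_scale Multiplicative factor (applied as x or 1/x,
#'   equiprobably) that turns an observation into an outlier.
#' @return A list of class `setting_response_params`.
#' @export
setting_response_params <- function(setting, c50, shape = 1.5,
                                    sigma_noise = 0.25,
                                    contamination_rate = 0.05,
                                    contamination_scale = 4) {
  stopifnot(setting %in% setting_levels(), c50 > 0, shape > 0,
            sigma_noise >= 0, contamination_rate >= 0, contamination_rate < 0.5,
            contamination_scale > 0)
  structure(list(setting = setting, c50 = c50, shape = shape,
                 sigma_noise = sigma_noise,
                 contamination_rate = contamination_rate,
                 contamination_scale = contamination_scale),
            class = "setting_response_params")
}

#' Mean dose-response curve
#'
#' Modified discount function r(x) = 1 / (1 + (x / c50)^shape): equal to 1
#' at zero stress, 0.5 at x = c50, and strictly decreasing in x. This is
#' the classical sigmoidal salt-tolerance response used for crop yield
#' decline with root-zone salinity; the generator exposes it as a plain
#' function so tests do not over-fit to the functional form.
#'
#' @param axis_value Non-negative stress-axis value(s).
#' @param c50 Axis value of half response.
#' @param shape Steepness (> 0).
#' @return Mean relative response in (0, 1].
#' @export
mean_response <- function(axis_value, c50, shape = 1.5) {
  if (any(axis_value < 0)) stop("axis_value must be non-negative", call. = FALSE)
  stopifnot(c50 > 0, shape > 0)
  1 / (1 + (axis_value / c50)^shape)
}

#' Default synthetic-corpus configuration
#'
#' Defaults encode the study conditions the generator emulates: four
#' settings with field plants least affected (largest c50) and
#' climate-chamber plants most affected, study counts imbalanced toward the
#' greenhouse in the proportions of the published corpus composition
#' (117:77:296:49, scaled by ~1/8), three stress levels per study with
#' relative EC uniform on 2-30 dS/m (the field-relevant range), stress
#' durations of 14-60 days, control salinities near zero (0-2 dS/m), 25%
#' multiplicative noise and 5% gross-outlier contamination.
#'
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @param params Named list of [setting_response_params()], one per setting
#'   to generate.
#' @param studies_per_setting Named integer vector of study counts.
#' @param variables Character vector of variable names, or a data frame
#'   with columns `variable` and `stage`. Plain growth-variable names get
#'   stage `"reproductive"`; use the data-frame form for vegetative-stage
#'   (stress-integral) variables.
#' @param levels_per_study Salinity levels per study.
#' @param ec_range Range (dS/m) of the relative EC of stress treatments.
#' @param control_ec_range Range (dS/m) of control-treatment salinity.
#' @param duration_range Range (days) of stress durations.
#' @param duration_c50_days Reference duration converting a c50 on the
#'   relative-EC scale to the stress-integral scale for vegetative-stage
#'   variables.
#' @param unit_mix Fraction of studies reporting salinity in molar or ppm
#'   units instead of EC (exercises unit conversion; values are
#'   equivalent).
#' @return A list of class `corpus_config`.
#' @export
default_corpus_config <- function(
    seed = 1,
    params = list(
      field           = setting_response_params("field", c50 = 30),
      outdoor_pots    = setting_response_params("outdoor_pots", c50 = 20),
      greenhouse      = setting_response_params("greenhouse", c50 = 12),
      climate_chamber = setting_response_params("climate_chamber", c50 = 10)),
    studies_per_setting = c(field = 15, outdoor_pots = 10,
                            greenhouse = 37, climate_chamber = 6),
    variables = c("grain_yield", "shoot_dw"),
    levels_per_study = 3,
    ec_range = c(2, 30),
    control_ec_range = c(0, 2),
    duration_range = c(14, 60),
    duration_c50_days = 30,
    unit_mix = 0.2) {
  if (is.character(variables)) {
    variables <- data.frame(
      variable = variables,
      stage = ifelse(variables %in% growth_variables(), "reproductive", "none"))
  }
  stopifnot(all(names(params) %in% setting_levels()),
            all(names(studies_per_setting) %in% names(params)),
            all(studies_per_setting >= 1),
            ec_range[1] > 0, ec_range[2] <= 60, ec_range[1] < ec_range[2],
            all(variables$variable %in% variable_levels()))
  structure(list(seed = seed, params = params,
                 studies_per_setting = studies_per_setting,
                 variables = variables, levels_per_study = levels_per_study,
                 ec_range = ec_range, control_ec_range = control_ec_range,
                 duration_range = duration_range,
                 duration_c50_days = duration_c50_days, unit_mix = unit_mix),
            class = "corpus_config")
}

#' Null (setting-exchangeable) corpus configuration
#'
#' All settings share the same dose-response parameters, so every pairwise
#' setting comparison tests a true null hypothesis. Used for type-I-error
#' calibration of the full pipeline.
#'
#' @param seed Integer seed.
#' @param c50,shape,sigma_noise,contamination_rate Shared parameters.
#' @param ... Passed on to [default_corpus_config()].
#' @return A `corpus_config`.
#' @export
null_corpus_config <- function(seed = 1, c50 = 15, shape = 1.5,
                               sigma_noise = 0.25, contamination_rate = 0.05,
                               ...) {
  params <- lapply(setting_levels(), function(s)
    setting_response_params(s, c50 = c50, shape = shape,
                            sigma_noise = sigma_noise,
                            contamination_rate = contamination_rate))
  names(params) <- setting_levels()
  default_corpus_config(seed = seed, params = params, ...)
}

# Express an EC value (dS/m) in another admissible unit, equivalently.
.ec_in_unit <- function(ec, unit) {
  switch(unit,
         dS_per_m = ec,
         mol_per_L_NaCl = ec / 98,
         ppm_NaCl = ec / (1.66 / 1000))
}

#' Generate a synthetic observation corpus
#'
#' Draws a full study corpus under the configured per-setting dose-response
#' model. For each study: a control salinity near zero, a per-variable
#' lognormal baseline (the control mean), and `levels_per_study` stress
#' levels with relative EC uniform over `ec_range` and a common stress
#' duration. Each stress mean is the control mean times the setting's mean
#' response at the observation's stress-axis value, times lognormal noise;
#' with probability `contamination_rate` it is multiplied or divided by
#' `contamination_scale` to create a gross outlier. A fraction of studies
#' report salinity in molar or ppm units (converted equivalently), so unit
#' normalization is exercised end to end. Identical configuration and seed
#' yield an identical corpus.
#'
#' @param config A `corpus_config` from [default_corpus_config()] or
#'   [null_corpus_config()].
#' @return Tibble of valid observation records (the [corpus_columns()]
#'   schema plus the `excluded_fresh_weight` flag).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  if (length(config$studies_per_setting) == 0) {
    stop("config covers no settings", call. = FALSE)
  }
  .with_seed(config$seed, {
    rows <- list()
    for (setting in names(config$studies_per_setting)) {
      pars <- config$params[[setting]]
      n_studies <- config$studies_per_setting[[setting]]
      for (st in seq_len(n_studies)) {
        study_id <- sprintf("S_%s_%02d", setting, st)
        unit <- if (stats::runif(1) < config$unit_mix)
          sample(c("mol_per_L_NaCl", "ppm_NaCl"), 1) else "dS_per_m"
        control_ec <- stats::runif(1, config$control_ec_range[1],
                                   config$control_ec_range[2])
        duration <- stats::runif(1, config$duration_range[1],
                                 config$duration_range[2])
        baselines <- stats::rlnorm(nrow(config$variables), meanlog = log(50),
                                   sdlog = 0.5)
        for (lv in seq_len(config$levels_per_study)) {
          rel_ec <- stats::runif(1, config$ec_range[1], config$ec_range[2])
          stress_ec <- control_ec + rel_ec
          for (vi in seq_len(nrow(config$variables))) {
            v <- config$variables$variable[vi]
            stage <- config$variables$stage[vi]
            vegetative <- v %in% growth_variables() && stage == "vegetative"
            axis <- if (vegetative) rel_ec * duration else rel_ec
            c50_eff <- pars$c50 * if (vegetative) config$duration_c50_days else 1
            r <- mean_response(axis, c50_eff, pars$shape) *
              stats::rlnorm(1, 0, pars$sigma_noise)
            if (stats::runif(1) < pars$contamination_rate) {
              r <- r * pars$contamination_scale^(sample(c(-1, 1), 1))
            }
            rows[[length(rows) + 1L]] <- data.frame(
              study_id = study_id, experiment_id = "E1", setting = setting,
              variable = v, stage = stage, method_tag = NA_character_,
              control_salinity_value = .ec_in_unit(control_ec, unit),
              control_salinity_unit = unit,
              stress_salinity_value = .ec_in_unit(stress_ec, unit),
              stress_salinity_unit = unit,
              control_value = baselines[vi],
              stress_value = baselines[vi] * r,
              stress_duration_days = duration,
              concentration_basis = if (v %in% metabolite_variables())
                "dry_weight" else NA_character_,
              n_genotypes = 1, year_label = NA_character_,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- tibble::as_tibble(do.call(rbind, rows))
    out$excluded_fresh_weight <- FALSE
    out
  })
}

#' Generate a long-format factorial experiment table
#'
#' Fixture source for the factorial analysis: a stress (control/salt) by
#' setting design with per-cell means
#' baseline x stress_effect x setting_effect x interaction and a chosen
#' noise law. `interaction` multiplies only the salt cells of the last
#' setting, so `interaction = 1` is an exactly multiplicative (additive on
#' the log scale) design.
#'
#' @param n_per_cell Observations per design cell.
#' @param settings Character vector of setting labels (>= 2).
#' @param baseline Grand baseline of the response.
#' @param stress_effect Multiplicative effect of the salt treatment.
#' @param setting_effects Named multiplicative effect per setting
#'   (default 1).
#' @param interaction Extra multiplicative term on salt x last setting.
#' @param noise `"gaussian"` (additive, sd = `sigma` x baseline),
#'   `"lognormal"` (multiplicative, sdlog = `sigma`) or `"t"` (additive,
#'   scaled t with `t_df` degrees of freedom).
#' @param sigma Noise scale.
#' @param t_df Degrees of freedom of the t noise.
#' @param seed Integer seed.
#' @return Tibble with columns `value`, `stress` (control/salt), `setting`.
#' @export
generate_factorial <- function(n_per_cell = 8,
                               settings = c("greenhouse", "climate_chamber"),
                               baseline = 100, stress_effect = 0.6,
                               setting_effects = NULL, interaction = 1,
                               noise = c("gaussian", "lognormal", "t"),
                               sigma = 0.1, t_df = 2, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(settings) >= 2, n_per_cell >= 1)
  if (is.null(setting_effects)) {
    setting_effects <- stats::setNames(rep(1, length(settings)), settings)
  }
  .with_seed(seed, {
    grid <- expand.grid(stress = c("control", "salt"), setting = settings,
                        rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
    mu <- baseline *
      ifelse(grid$stress == "salt", stress_effect, 1) *
      setting_effects[grid$setting] *
      ifelse(grid$stress == "salt" & grid$setting == settings[length(settings)],
             interaction, 1)
    eps <- switch(noise,
                  gaussian = stats::rnorm(nrow(grid), 0, sigma * baseline),
                  lognormal = NULL,
                  t = stats::rt(nrow(grid), df = t_df) * sigma * baseline)
    value <- if (noise == "lognormal")
      mu * stats::rlnorm(nrow(grid), 0, sigma) else mu + eps
    tibble::tibble(value = as.numeric(value), stress = grid$stress,
                   setting = grid$setting)
  })
}
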