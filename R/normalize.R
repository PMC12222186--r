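#' Average replicate rows across genotypes and years
#'
#' Study-level tables often report one row per genotype or per trial year
#' for the same (study, experiment, setting, variable, salinity level).
#' These replicates are collapsed by an unweighted arithmetic mean of the
#' control and stress values. Rows from distinct salinity levels, stages,
#' method tags or treatment combinations (encoded in `method_tag`) are never
#' merged, so treatments applied in combination with salt remain distinct.
#'
#' @param records Tibble of validated observation records.
#' @return Tibble with one row per aggregation group; `n_genotypes` holds
#'   the number of rows merged (or their recorded genotype counts summed).
#' @export
aggregate_replicates <- function(records) {
  if (nrow(records) == 0) return(records)
  ec_c <- ec_from_unit(records$control_salinity_value, records$control_salinity_unit)
  ec_s <- ec_from_unit(records$stress_salinity_value, records$stress_salinity_unit)
  key <- paste(records$study_id, records$experiment_id, records$setting,
               records$variable, records$stage, records$method_tag,
               records$concentration_basis,
               signif(ec_c, 12), signif(ec_s, 12),
               signif(records$stress_duration_days, 12),
               sep = "\r")
  groups <- split(seq_len(nrow(records)), key)

  rows <- lapply(groups, function(idx) {
    g <- records[idx, , drop = FALSE]
    units <- unique(c(g$control_salinity_unit, g$stress_salinity_unit))
    if (length(unique(g$control_salinity_unit)) > 1 ||
        length(unique(g$stress_salinity_unit)) > 1) {
      stop("inconsistent salinity units within aggregation group: ",
           g$study_id[1], " / ", g$variable[1],
           " (", paste(units, collapse = ", "), ")", call. = FALSE)
    }
    out <- g[1, , drop = FALSE]
    out$control_value <- mean(g$control_value)
    out$stress_value <- mean(g$stress_value)
    ng <- g$n_genotypes
    out$n_genotypes <- if (all(is.na(ng))) length(idx) else sum(ng, na.rm = TRUE)
    out$year_label <- if (length(unique(g$year_label)) == 1) g$year_label[1] else
      paste(sort(unique(g$year_label)), collapse = ";")
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$study_id, out$experiment_id, out$setting,
                   out$variable, out$stage), , drop = FALSE]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Derive relative-effect observations
#'
#' Converts each validated record into the effect scale the meta-analysis
#' operates on:
#' \describe{
#'   \item{relative_ec}{stress EC minus control EC (dS/m), which sets the
#'     control baseline to zero so studies reporting soil versus solution
#'     salinity become comparable.}
#'   \item{relative_response}{stress mean divided by control mean
#'     (dimensionless; 1 = no effect, < 1 = stress-induced decrease).}
#'   \item{stress_integral}{relative EC multiplied by stress duration
#'     (dS·day/m), present whenever the duration is known.}
#' }
#' The stress axis is `stress_integral` for vegetative-stage growth
#' variables — where the duration of exposure modulates the response — and
#' `relative_ec` for everything else. Fresh-weight metabolite rows (flagged
#' at ingest) are excluded here.
#'
#' @param records Tibble of validated (and typically aggregated) records.
#' @return Tibble of relative observations with columns `study_id`,
#'   `experiment_id`, `setting`, `variable`, `stage`, `method_tag`,
#'   `relative_ec`, `stress_integral`, `relative_response`, `stress_axis`
#'   and `axis_value`. Rows whose axis value cannot be formed (vegetative
#'   growth without a duration) are dropped with a warning.
#' @export
derive_relative <- function(records) {
  if ("excluded_fresh_weight" %in% names(records)) {
    records <- records[!records$excluded_fresh_weight, , drop = FALSE]
  }
  ec_c <- ec_from_unit(records$control_salinity_value, records$control_salinity_unit)
  ec_s <- ec_from_unit(records$stress_salinity_value, records$stress_salinity_unit)
  relative_ec <- ec_s - ec_c
  if (any(relative_ec <= 0)) {
    stop("relative EC must be positive for every stress row", call. = FALSE)
  }
  if (any(records$control_value <= 0)) {
    stop("control_value must be positive", call. = FALSE)
  }
  stress_integral <- relative_ec * records$stress_duration_days
  vegetative_growth <- records$variable %in% growth_variables() &
    records$stage == "vegetative"
  stress_axis <- ifelse(vegetative_growth, "stress_integral", "relative_ec")
  axis_value <- ifelse(stress_axis == "stress_integral", stress_integral, relative_ec)

  out <- tibble::tibble(
    study_id = records$study_id,
    experiment_id = records$experiment_id,
    setting = records$setting,
    variable = records$variable,
    stage = records$stage,
    method_tag = records$method_tag,
    relative_ec = relative_ec,
    stress_integral = stress_integral,
    relative_response = records$stress_value / records$control_value,
    stress_axis = stress_axis,
    axis_value = axis_value
  )
  no_axis <- is.na(out$axis_value)
  if (any(no_axis)) {
    warning(sum(no_axis), " vegetative-stage growth observation(s) dropped: ",
            "stress duration needed for the stress integral is missing",
            call. = FALSE)
    out <- out[!no_axis, , drop = FALSE]
  }
  out
}

#' Keep only salinity levels with an effective stress
#'
#' The meta-analysis only retains data where the salinity induced a decrease
#' in either shoot dry weight or grain yield. This gate operates per
#' (study, experiment, salinity level): if at least one anchor variable
#' (shoot_dw or grain_yield) is present and none of the present anchors
#' shows a response ratio below 1, every observation of that level is
#' dropped. Levels with neither anchor are handled by `policy`.
#'
#' @param observations Tibble of relative observations from
#'   [derive_relative()].
#' @param policy What to do with levels lacking both anchor variables:
#'   `"keep"` (default; warn once) or `"drop"`.
#' @return Tibble of retained observations; the dropped groups are attached
#'   as a tibble in the `"dropped_groups"` attribute.
#' @export
filter_effective_stress <- function(observations, policy = c("keep", "drop")) {
  policy <- match.arg(policy)
  if (nrow(observations) == 0) return(observations)
  key <- paste(observations$study_id, observations$experiment_id,
               signif(observations$relative_ec, 12), sep = "\r")
  anchor <- observations$variable %in% c("shoot_dw", "grain_yield")

  groups <- split(seq_len(nrow(observations)), key)
  keep <- rep(TRUE, nrow(observations))
  dropped <- list()
  n_no_anchor <- 0L
  for (idx in groups) {
    a <- idx[anchor[idx]]
    if (length(a) == 0) {
      n_no_anchor <- n_no_anchor + 1L
      if (policy == "drop") keep[idx] <- FALSE
      next
    }
    if (all(observations$relative_response[a] >= 1)) {
      keep[idx] <- FALSE
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        study_id = observations$study_id[idx[1]],
        experiment_id = observations$experiment_id[idx[1]],
        relative_ec = observations$relative_ec[idx[1]],
        n_observations = length(idx)
      )
    }
  }
  if (n_no_anchor > 0 && policy == "keep") {
    warning(n_no_anchor, " salinity level(s) lack both shoot_dw and ",
            "grain_yield; kept (policy = \"keep\")", call. = FALSE)
  }
  out <- observations[keep, , drop = FALSE]
  attr(out, "dropped_groups") <- if (length(dropped)) do.call(rbind, dropped) else
    tibble::tibble(study_id = character(), experiment_id = character(),
                   relative_ec = numeric(), n_observations = integer())
  out
}
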