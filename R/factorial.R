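# Factorial analysis of the experimental arm: a two-way ANOVA
# (stress x setting, with interaction) gated on residual normality, with the
# nonparametric Scheirer-Ray-Hare rank test as fallback.

.factorial_effects <- function(value, stress, setting) {
  stress <- factor(stress)
  setting <- factor(setting)
  if (nlevels(stress) < 2 || nlevels(setting) < 2) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  empty <- table(stress, setting) == 0
  if (any(empty)) {
    cells <- which(empty, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(levels(stress)[cells[, 1]], levels(setting)[cells[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }
  list(stress = stress, setting = setting)
}

.new_factorial_result <- function(method, effects, residual_normality_p,
                                  degenerate = FALSE) {
  structure(list(method = method, effects = effects,
                 residual_normality_p = residual_normality_p,
                 degenerate = degenerate),
            class = "factorial_result")
}

#' @export
print.factorial_result <- function(x, ...) {
  cat("Two-factor analysis:",
      if (x$method == "anova2") "two-way ANOVA" else "Scheirer-Ray-Hare", "\n")
  if (x$degenerate) cat("  (degenerate response: no variation)\n")
  print(as.data.frame(x$effects), row.names = FALSE)
  if (is.finite(x$residual_normality_p))
    cat("  residual Shapiro-Wilk p =", signif(x$residual_normality_p, 4), "\n")
  invisible(x)
}

#' Two-way ANOVA with interaction
#'
#' Fits `value ~ stress * setting` and reports type-II sums-of-squares F
#' tests for the stress main effect, the setting main effect and their
#' interaction, along with the Shapiro-Wilk p-value of the model residuals.
#' Type-II sums of squares are used so that unbalanced designs (e.g. lost
#' plants) are handled sensibly; on balanced designs they coincide with the
#' classical sequential decomposition.
#'
#' @param value Numeric response.
#' @param stress,setting Factors (or coercible) with >= 2 levels each and
#'   no empty cell.
#' @return A `factorial_result` with `method = "anova2"`, an `effects`
#'   tibble (effect, df, statistic, p_value, sum_sq) and
#'   `residual_normality_p`. A constant response yields a degenerate result
#'   with `NA` statistics.
#' @export
two_way_anova <- function(value, stress, setting) {
  f <- .factorial_effects(value, stress, setting)
  if (stats::var(value) == 0) {
    eff <- tibble::tibble(effect = c("stress", "setting", "interaction"),
                          df = NA_integer_, statistic = NA_real_,
                          p_value = NA_real_, sum_sq = 0)
    return(.new_factorial_result("anova2", eff, NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(value ~ f$stress * f$setting)
  tab <- car::Anova(fit, type = 2)
  ord <- c("f$stress", "f$setting", "f$stress:f$setting")
  eff <- tibble::tibble(
    effect = c("stress", "setting", "interaction"),
    df = tab[ord, "Df"],
    statistic = tab[ord, "F value"],
    p_value = tab[ord, "Pr(>F)"],
    sum_sq = tab[ord, "Sum Sq"]
  )
  resid_p <- .shapiro_p(stats::residuals(fit))
  res <- .new_factorial_result("anova2", eff, resid_p)
  res$sum_sq_residual <- tab["Residuals", "Sum Sq"]
  res$sum_sq_total <- sum((value - mean(value))^2)
  res
}

#' Scheirer-Ray-Hare rank test for a two-factor design
#'
#' Nonparametric two-factor extension of the Kruskal-Wallis test: the
#' response is replaced by its mid-ranks, a two-way ANOVA decomposition is
#' computed on the ranks, and each effect's H statistic is its rank sum of
#' squares divided by the total rank mean square MS_total =
#' SS_total / (N - 1). Mid-ranking ties deflates MS_total, which is exactly
#' the standard tie correction. H is referred to a chi-square distribution
#' with the effect's degrees of freedom. Because it only uses ranks, the
#' result is invariant under strictly increasing transforms of the
#' response.
#'
#' @inheritParams two_way_anova
#' @return A `factorial_result` with `method = "scheirer_ray_hare"`; all
#'   values tied yields a degenerate result.
#' @export
scheirer_ray_hare <- function(value, stress, setting) {
  f <- .factorial_effects(value, stress, setting)
  r <- rank(value)
  ss_total <- sum((r - mean(r))^2)
  if (ss_total == 0) {
    eff <- tibble::tibble(effect = c("stress", "setting", "interaction"),
                          df = NA_integer_, statistic = NA_real_,
                          p_value = NA_real_, sum_sq = 0)
    return(.new_factorial_result("scheirer_ray_hare", eff, NA_real_,
                                 degenerate = TRUE))
  }
  ms_total <- ss_total / (length(r) - 1)
  fit <- stats::lm(r ~ f$stress * f$setting)
  tab <- car::Anova(fit, type = 2)
  ord <- c("f$stress", "f$setting", "f$stress:f$setting")
  H <- tab[ord, "Sum Sq"] / ms_total
  df <- tab[ord, "Df"]
  eff <- tibble::tibble(
    effect = c("stress", "setting", "interaction"),
    df = df,
    statistic = H,
    p_value = stats::pchisq(H, df, lower.tail = FALSE),
    sum_sq = tab[ord, "Sum Sq"]
  )
  .new_factorial_result("scheirer_ray_hare", eff, NA_real_)
}

#' Residual-normality-gated factorial analysis
#'
#' Runs the two-way ANOVA; if a Shapiro-Wilk test finds the residuals not
#' normally distributed (p <= `alpha_gate`), the ANOVA is discarded and the
#' Scheirer-Ray-Hare rank test is reported instead. The result records
#' which path was taken (`method`) and the residual normality p-value of
#' the gate.
#'
#' @inheritParams two_way_anova
#' @param alpha_gate Gate level for the residual Shapiro-Wilk test.
#' @return A `factorial_result`.
#' @export
gated_factorial <- function(value, stress, setting, alpha_gate = 0.05) {
  if (length(value) < 3) {
    stop("need at least 3 observations for the residual normality gate",
         call. = FALSE)
  }
  an <- two_way_anova(value, stress, setting)
  gate_p <- an$residual_normality_p
  if (!is.na(gate_p) && gate_p > alpha_gate) return(an)
  srh <- scheirer_ray_hare(value, stress, setting)
  srh$residual_normality_p <- gate_p
  srh
}
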