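# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (set-builder / enumeration / textbook
# formulas) and never call the implementation they check.

# A small valid observation table (n rows, one setting, grain_yield).
make_valid_corpus <- function(n = 5, setting = "greenhouse",
                              variable = "grain_yield") {
  tibble::tibble(
    study_id = sprintf("S%02d", seq_len(n)),
    experiment_id = "E1",
    setting = setting,
    variable = variable,
    stage = "none",
    method_tag = NA_character_,
    control_salinity_value = 1,
    control_salinity_unit = "dS_per_m",
    stress_salinity_value = seq(5, 5 + 2 * (n - 1), by = 2),
    stress_salinity_unit = "dS_per_m",
    control_value = 100,
    stress_value = seq(90, 90 - 5 * (n - 1), by = -5),
    stress_duration_days = 30,
    concentration_basis = NA_character_,
    n_genotypes = 1,
    year_label = NA_character_
  )
}

# Brute-force Hampel filter straight from the set-builder definition.
oracle_hampel <- function(values, k = 3, scale = 1.4826) {
  med <- median(values)
  mad_raw <- median(abs(values - med))
  if (mad_raw == 0) return(list(retained = values, excluded = values[0]))
  out <- vapply(values, function(v) abs(v - med) > k * scale * mad_raw,
                logical(1))
  list(retained = values[!out], excluded = values[out])
}

# Exhaustive two-sided permutation p for the pooled-variance t statistic,
# computing each statistic with stats::t.test (independent code path).
oracle_perm_t_p <- function(a, b) {
  z <- c(a, b)
  n <- length(z); na <- length(a)
  tstat <- function(ia) {
    x <- z[ia]; y <- z[-ia]
    unname(t.test(x, y, var.equal = TRUE)$statistic)
  }
  t_obs <- tstat(seq_len(na))
  splits <- combn(n, na)
  ts <- apply(splits, 2, tstat)
  mean(abs(ts) >= abs(t_obs) - 1e-9)
}

# Exact two-sided Mann-Whitney p by enumerating all splits of the pooled
# values (tie-free inputs only).
oracle_mw_p <- function(a, b) {
  z <- c(a, b)
  n <- length(z); na <- length(a); nb <- n - na
  u_of <- function(x, y) sum(outer(x, y, ">"))
  mu <- na * nb / 2
  u_obs <- u_of(a, b)
  splits <- combn(n, na)
  us <- apply(splits, 2, function(ia) u_of(z[ia], z[-ia]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Scheirer-Ray-Hare H statistics from the classical group-total formula
# (balanced two-factor designs only).
oracle_srh <- function(value, A, B) {
  r <- rank(value)
  N <- length(r)
  nA <- table(A)[1]; nB <- table(B)[1]
  n_cell <- N / (length(unique(A)) * length(unique(B)))
  CF <- sum(r)^2 / N
  SS_tot <- sum(r^2) - CF
  SS_A <- sum(tapply(r, A, sum)^2 / (N / length(unique(A)))) - CF
  SS_B <- sum(tapply(r, B, sum)^2 / (N / length(unique(B)))) - CF
  SS_cells <- sum(tapply(r, paste(A, B), sum)^2 / n_cell) - CF
  SS_AB <- SS_cells - SS_A - SS_B
  MS_tot <- SS_tot / (N - 1)
  c(stress = SS_A, setting = SS_B, interaction = SS_AB) / MS_tot
}

# Balanced 2x2 (n = 3 per cell) integer fixture with distinct values;
# stress and setting totals chosen so the setting main effect vanishes.
factorial_fixture <- function() {
  list(value = c(12, 14, 13, 5, 6, 7, 11, 10, 15, 8, 9, 4),
       stress = rep(c("control", "salt", "control", "salt"), each = 3),
       setting = rep(c("greenhouse", "climate_chamber"), each = 6))
}
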