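# helpers to build relative-observation tibbles directly
make_rel_obs <- function(setting, axis, response = NULL) {
  n <- length(axis)
  tibble::tibble(
    study_id = sprintf("S%03d", seq_len(n)), experiment_id = "E1",
    setting = setting, variable = "grain_yield", stage = "none",
    method_tag = NA_character_, relative_ec = axis, stress_integral = NA_real_,
    relative_response = if (is.null(response)) rep(0.5, n) else response,
    stress_axis = "relative_ec", axis_value = axis)
}

test_that("hampel filter matches the worked example and its definition", {
  f <- hampel_filter(c(1, 2, 3, 4, 100), k = 3, scale = 1.4826)
  expect_equal(f$median, 3)
  expect_equal(f$mad, 1)
  expect_equal(f$threshold, 4.4478)
  expect_equal(f$retained, c(1, 2, 3, 4))
  expect_equal(f$excluded, 100)

  expect_equal(hampel_filter(rep(7, 6))$excluded, numeric(0))  # MAD = 0
  expect_equal(hampel_filter(5)$retained, 5)                   # singleton
  expect_error(hampel_filter(numeric(0)), "at least one")
})

test_that("hampel filter is order-invariant and affine-equivariant", {
  set.seed(99)
  for (i in 1:50) {
    v <- round(rnorm(sample(3:12, 1), sd = sample(c(1, 10), 1)), 2)
    f <- hampel_filter(v)
    o <- oracle_hampel(v)
    expect_equal(sort(f$retained), sort(o$retained))
    expect_equal(sort(f$excluded), sort(o$excluded))
    # order invariance
    p <- sample(seq_along(v))
    expect_equal(sort(hampel_filter(v[p])$excluded), sort(f$excluded))
    # affine equivariance: excluded points map to excluded points
    a <- runif(1, 0.5, 3) * sample(c(-1, 1), 1); b <- runif(1, -5, 5)
    g <- hampel_filter(a * v + b)
    expect_equal(sort(g$excluded), sort(a * f$excluded + b))
  }
})

test_that("bin scheme search finds feasible comparable schemes", {
  set.seed(7)
  obs <- rbind(make_rel_obs("field", runif(20, 0, 30)),
               make_rel_obs("greenhouse", runif(20, 0, 30)),
               make_rel_obs("outdoor_pots", runif(20, 0, 30)))
  sch <- build_bin_scheme(obs, min_count = 5)
  expect_s3_class(sch, "bin_scheme")
  expect_gte(length(sch$edges), 3)  # at least 2 bins
  assigned <- assign_bins(obs, sch)
  counts <- table(assigned$bin_index, assigned$setting)
  expect_true(all(counts >= 5))

  # a setting with 4 points can never be covered
  obs2 <- rbind(obs, make_rel_obs("climate_chamber", runif(4, 0, 30)))
  expect_warning(sch2 <- build_bin_scheme(obs2, min_count = 5),
                 "climate_chamber")
  expect_false("climate_chamber" %in% sch2$settings_covered)

  # fewer than two coverable settings is an error
  small <- rbind(make_rel_obs("field", runif(20, 0, 30)),
                 make_rel_obs("greenhouse", runif(3, 0, 30)))
  expect_error(suppressWarnings(build_bin_scheme(small, min_count = 5)),
               "fewer than 2 settings")

  # all points at one axis value: degenerate single-point bin
  degen <- rbind(make_rel_obs("field", rep(12, 6)),
                 make_rel_obs("greenhouse", rep(12, 6)))
  schd <- build_bin_scheme(degen, min_count = 5)
  expect_equal(schd$edges, c(12, 12))
  expect_equal(assign_bins(degen, schd)$bin_index, rep(1L, 12))
})

test_that("explicit edges override the search", {
  set.seed(8)
  obs <- rbind(make_rel_obs("field", runif(30, 0, 30)),
               make_rel_obs("greenhouse", runif(30, 0, 30)))
  sch <- build_bin_scheme(obs, min_count = 5, edges = c(0, 15, 30))
  expect_equal(sch$edges, c(0, 15, 30))
  # scheme serialization round-trips
  path <- withr::local_tempfile(fileext = ".yaml")
  write_bin_scheme(sch, path)
  back <- read_bin_scheme(path)
  expect_equal(back$edges, sch$edges)
  expect_equal(back$settings_covered, sch$settings_covered)
})

test_that("bin assignment follows the half-open convention and conserves points", {
  obs <- rbind(make_rel_obs("field", c(0, 5, 9.999, 10, 20, 25)),
               make_rel_obs("greenhouse", c(2, 31, -1, 15, 10, 20)))
  sch <- build_bin_scheme(obs, min_count = 1, edges = c(0, 10, 20))
  assigned <- assign_bins(obs, sch)
  got <- setNames(assigned$bin_index, assigned$axis_value)
  expect_equal(unname(got[names(got) %in% c("5", "9.999")]), c(1L, 1L))
  expect_equal(unname(got[names(got) == "10"]), c(2L, 2L))  # interior edge -> upper bin
  expect_equal(unname(got[names(got) == "20"]), c(2L, 2L))  # last edge -> last bin
  un <- attr(assigned, "unassigned")
  expect_setequal(un$axis_value, c(25, 31, -1))
  expect_equal(nrow(assigned) + nrow(un), nrow(obs))
  # partition: each in-range point in exactly one bin
  expect_false(any(is.na(assigned$bin_index)))

  # axis mismatch is an error
  veg <- make_rel_obs("field", 1:6)
  veg$stress_axis <- "stress_integral"
  expect_error(assign_bins(veg, sch), "axis mismatch")
})

test_that("per-cell filtering reconciles counts and summarizes retained values", {
  set.seed(21)
  axis <- runif(40, 0, 30)
  resp <- exp(rnorm(40, 0, 0.1)) * 0.6
  resp[1] <- 50  # gross outlier
  obs <- rbind(make_rel_obs("field", axis, resp),
               make_rel_obs("greenhouse", runif(40, 0, 30),
                            exp(rnorm(40, 0, 0.1)) * 0.6))
  sch <- build_bin_scheme(obs, min_count = 5)
  grp <- bin_groups(assign_bins(obs, sch), sch)
  expect_true(all(grp$n_total == grp$n_retained + grp$n_excluded))
  expect_gte(sum(grp$n_excluded), 1)
  expect_true(50 %in% unlist(grp$excluded))
  expect_false(50 %in% unlist(grp$values))
  tab <- bin_count_table(grp)
  expect_equal(sum(tab$field) + sum(tab$greenhouse), sum(grp$n_retained))
})

test_that("post-filter bin means decrease along a decreasing dose-response", {
  cfg <- default_corpus_config(
    seed = 314,
    params = list(greenhouse = setting_response_params(
      "greenhouse", c50 = 12, sigma_noise = 0.1, contamination_rate = 0),
      field = setting_response_params(
        "field", c50 = 12, sigma_noise = 0.1, contamination_rate = 0)),
    studies_per_setting = c(greenhouse = 60, field = 60),
    variables = "grain_yield")
  rel <- derive_relative(aggregate_replicates(generate_corpus(cfg)))
  sch <- build_bin_scheme(rel, min_count = 5)
  grp <- bin_groups(assign_bins(rel, sch), sch)
  for (s in sch$settings_covered) {
    m <- grp$mean_response[grp$setting == s][order(grp$bin_index[grp$setting == s])]
    expect_true(all(diff(m) < 0.05))  # non-increasing up to noise
  }
})
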