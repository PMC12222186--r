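test_that("the gate decision tree picks the documented branches", {
  set.seed(101)
  a <- rnorm(30, 10, 1); b <- rnorm(30, 10.5, 1)
  sel <- select_test(a, b)
  expect_equal(sel$test, "permutation_t")
  expect_equal(sel$transform, "raw")
  expect_equal(sel$gates$shapiro_raw_a, shapiro.test(a)$p.value)

  set.seed(102)
  a <- exp(rnorm(40, 0, 0.8)); b <- exp(rnorm(40, 0.3, 0.8))
  sel <- select_test(a, b)
  expect_equal(sel$test, "permutation_t")
  expect_equal(sel$transform, "log")
  expect_lte(min(sel$gates$shapiro_raw_a, sel$gates$shapiro_raw_b), 0.05)
  expect_gt(min(sel$gates$shapiro_log_a, sel$gates$shapiro_log_b), 0.05)

  set.seed(103)
  a <- rcauchy(40); b <- rcauchy(40)
  sel <- select_test(a, b)
  expect_equal(sel$test, "mann_whitney")

  # unequal variances on the candidate scale fail the homogeneity gate
  set.seed(104)
  a <- rnorm(40, 0, 1); b <- rnorm(40, 0, 6)
  sel <- select_test(a, b)
  expect_equal(sel$test, "mann_whitney")
  expect_lte(sel$gates$variance_p, 0.05)

  expect_warning(sel <- select_test(c(1, 2), c(3, 4, 5)), "too small")
  expect_equal(sel$test, "mann_whitney")
})

test_that("permutation t-test enumerates small problems exactly", {
  res <- permutation_t_test(c(1, 2), c(10, 11))
  expect_equal(res$p.value, 2 / 6)
  expect_equal(res$n_permutations, "exact")

  # identical samples: every relabeling ties the observed statistic
  expect_equal(permutation_t_test(c(3, 4, 5), c(3, 4, 5))$p.value, 1)

  # exhaustive agreement with an independent enumeration oracle
  set.seed(31)
  for (i in 1:10) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- round(rnorm(na, 0, 2), 3); b <- round(rnorm(nb, 1, 2), 3)
    expect_equal(permutation_t_test(a, b)$p.value, oracle_perm_t_p(a, b))
  }
})

test_that("sampled permutation p is reproducible and near the exact value", {
  set.seed(52)
  a <- rnorm(6); b <- rnorm(6, 1)
  p1 <- permutation_t_test(a, b, B = 499, seed = 7, enumeration_cap = 10)
  p2 <- permutation_t_test(a, b, B = 499, seed = 7, enumeration_cap = 10)
  expect_identical(p1$p.value, p2$p.value)
  expect_gte(p1$p.value, 1 / 500)

  p_exact <- permutation_t_test(a, b)$p.value
  ps <- permutation_t_test(a, b, B = 99999, seed = 8,
                           enumeration_cap = 10)$p.value
  mc_se <- sqrt(p_exact * (1 - p_exact) / 99999)
  expect_lt(abs(ps - p_exact), 3 * mc_se + 1e-4)
})

test_that("Mann-Whitney U handles exact, tied and approximate regimes", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1)

  # swap symmetry: U' = n_a n_b - U, identical p
  res2 <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res2$statistic, 9)
  expect_equal(res2$p.value, res$p.value)

  expect_equal(mann_whitney_u(1, 1)$statistic, 0.5)  # tie convention

  # exact p agrees with stats::wilcox.test on tie-free samples
  set.seed(61)
  for (i in 1:15) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.5)
    expect_equal(mann_whitney_u(a, b)$p.value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # tie-corrected normal approximation tracks the reference implementation
  set.seed(62)
  a <- round(rnorm(30), 1); b <- round(rnorm(30, 0.4), 1)
  got <- mann_whitney_u(a, b, enumeration_cap = 10)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("pairwise comparison pools overlapping bins and reports gaps", {
  set.seed(71)
  mk <- function(setting, lo, hi) {
    axis <- runif(30, lo, hi)
    tibble::tibble(study_id = "S", experiment_id = "E1", setting = setting,
                   variable = "grain_yield", stage = "none",
                   method_tag = NA_character_, relative_ec = axis,
                   stress_integral = NA_real_,
                   relative_response = exp(rnorm(30, 0, 0.2)) * 0.6,
                   stress_axis = "relative_ec", axis_value = axis)
  }
  obs <- rbind(mk("field", 0, 30), mk("greenhouse", 0, 30),
               mk("outdoor_pots", 0, 30))
  sch <- build_bin_scheme(obs, min_count = 5)
  grp <- bin_groups(assign_bins(obs, sch), sch)
  cmp <- compare_all_pairs(grp, seed = 5)
  expect_equal(nrow(cmp), 3)   # C(3, 2) pairs
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))

  # label-swap symmetry of the reported p-values
  a <- unlist(grp$values[grp$setting == "field"])
  b <- unlist(grp$values[grp$setting == "greenhouse"])
  expect_equal(mann_whitney_u(a, b)$p.value, mann_whitney_u(b, a)$p.value)
  expect_equal(permutation_t_test(a[1:5], b[1:5])$p.value,  # exhaustive
               permutation_t_test(b[1:5], a[1:5])$p.value)

  # a pair with disjoint bins is untestable, not an error
  grp2 <- grp[!(grp$setting == "outdoor_pots" & grp$bin_index > 1) &
                !(grp$setting == "field" & grp$bin_index == 1), ]
  attr(grp2, "scheme") <- sch
  cmp2 <- compare_all_pairs(grp2, seed = 5)
  row <- cmp2[cmp2$setting_a == "field" & cmp2$setting_b == "outdoor_pots", ]
  expect_equal(row$test_used, "untestable")
  expect_true(is.na(row$p_value))
})
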