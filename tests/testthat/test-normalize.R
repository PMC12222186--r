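test_that("replicate rows are averaged within their salinity level", {
  corp <- make_valid_corpus(1)[rep(1, 2), ]
  corp$control_value <- c(10, 20)
  corp$stress_value <- c(5, 15)
  agg <- aggregate_replicates(validate_corpus(corp)$records)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$control_value, 15)
  expect_equal(agg$stress_value, 10)

  # singleton groups pass through unchanged
  single <- validate_corpus(make_valid_corpus(3))$records
  expect_equal(aggregate_replicates(single)$control_value,
               single$control_value)

  # mixing units within one group is an error, not a silent conversion
  mixed <- make_valid_corpus(1)[rep(1, 2), ]
  mixed$stress_salinity_value <- c(9.8, 0.1)
  mixed$stress_salinity_unit <- c("dS_per_m", "mol_per_L_NaCl")
  expect_error(aggregate_replicates(validate_corpus(mixed)$records),
               "inconsistent salinity units")
})

test_that("relative observations implement the printed formulas", {
  corp <- make_valid_corpus(1)
  corp$control_salinity_value <- 2
  corp$stress_salinity_value <- 12
  corp$control_value <- 100
  corp$stress_value <- 50
  rel <- derive_relative(validate_corpus(corp)$records)
  expect_equal(rel$relative_ec, 10)
  expect_equal(rel$relative_response, 0.5)
  expect_equal(rel$stress_axis, "relative_ec")

  corp$stress_value <- 100
  expect_equal(derive_relative(validate_corpus(corp)$records)$relative_response, 1)

  # vegetative-stage growth: stress integral becomes the axis
  veg <- corp
  veg$variable <- "shoot_dw"; veg$stage <- "vegetative"
  veg$stress_duration_days <- 20
  rel <- derive_relative(validate_corpus(veg)$records)
  expect_equal(rel$stress_integral, 200)
  expect_equal(rel$stress_axis, "stress_integral")
  expect_equal(rel$axis_value, 200)
})

test_that("relative quantities respect scale and shift invariances", {
  set.seed(42)
  for (i in 1:20) {
    corp <- make_valid_corpus(1)
    corp$control_salinity_value <- runif(1, 0, 3)
    corp$stress_salinity_value <- corp$control_salinity_value + runif(1, 1, 25)
    corp$control_value <- runif(1, 10, 200)
    corp$stress_value <- corp$control_value * runif(1, 0.1, 1.5)
    base <- derive_relative(validate_corpus(corp)$records)

    k <- runif(1, 0.1, 10)
    scaled <- corp
    scaled$control_value <- corp$control_value * k
    scaled$stress_value <- corp$stress_value * k
    expect_equal(derive_relative(validate_corpus(scaled)$records)$relative_response,
                 base$relative_response)

    shift <- runif(1, 0, 5)
    shifted <- corp
    shifted$control_salinity_value <- corp$control_salinity_value + shift
    shifted$stress_salinity_value <- corp$stress_salinity_value + shift
    expect_equal(derive_relative(validate_corpus(shifted)$records)$relative_ec,
                 base$relative_ec)
    # stress_integral / relative_ec recovers the duration exactly
    expect_equal(base$stress_integral / base$relative_ec,
                 corp$stress_duration_days)
  }
})

test_that("levels without a decrease in shoot biomass or yield are dropped", {
  mk <- function(study, yield_ratio, shoot_ratio = NA) {
    vars <- c("grain_yield", if (!is.na(shoot_ratio)) "shoot_dw", "proline")
    corp <- make_valid_corpus(length(vars))
    corp$study_id <- study
    corp$variable <- vars
    corp$stage <- "none"
    corp$stress_salinity_value <- 10
    corp$control_value <- 100
    ratios <- c(yield_ratio, if (!is.na(shoot_ratio)) shoot_ratio, 0.7)
    corp$stress_value <- 100 * ratios
    corp
  }
  corp <- rbind(mk("A", 0.8),            # yield decrease: kept
                mk("B", 1.05, 1.02),     # no decrease in either: dropped
                mk("C", 1.05, 0.9))      # shoot decrease rescues the level
  rel <- derive_relative(validate_corpus(corp)$records)
  out <- filter_effective_stress(rel)
  expect_setequal(unique(out$study_id), c("A", "C"))
  expect_equal(attr(out, "dropped_groups")$study_id, "B")

  # a level lacking both anchors follows the policy
  orphan <- make_valid_corpus(1, variable = "proline")
  rel_o <- derive_relative(validate_corpus(orphan)$records)
  expect_warning(kept <- filter_effective_stress(rel_o), "lack both")
  expect_equal(nrow(kept), 1)
  expect_equal(nrow(filter_effective_stress(rel_o, policy = "drop")), 0)
})
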