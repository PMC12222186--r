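# End-to-end orchestration: aggregate -> derive -> effective-stress gate ->
# per-variable binning + Hampel filter -> pairwise setting comparisons,
# with a machine-readable run manifest.

#' Run the full meta-analysis pipeline on a corpus
#'
#' Applies, in order: replicate aggregation ([aggregate_replicates()]),
#' derivation of relative observations ([derive_relative()]), the
#' effective-stress gate ([filter_effective_stress()]), then for every
#' (variable, stage) with enough data: bin-scheme construction
#' ([build_bin_scheme()] unless explicit edges are supplied), bin
#' assignment, per-bin per-setting Hampel filtering ([bin_groups()]) and
#' all pairwise setting comparisons ([compare_all_pairs()]).
#'
#' @param records Tibble of validated observation records.
#' @param variables Optional character vector restricting the analysis.
#' @param min_count Minimum observations per setting per bin.
#' @param mad_k,mad_scale Hampel filter parameters.
#' @param alpha_gate Gate level for test selection.
#' @param B Permutation count for sampled permutation t-tests.
#' @param seed Integer seed; per-variable test seeds are derived from it so
#'   each stage is independently reproducible.
#' @param edges Optional named list (by variable) of explicit bin edges,
#'   overriding the scheme search.
#' @param effective_stress_policy Policy for levels lacking both anchor
#'   variables, see [filter_effective_stress()].
#' @return List of class `saltmeta_analysis` with elements `derived`
#'   (post-gate relative observations), `schemes`, `groups`, `counts`
#'   (per-variable retained-count tables), `comparisons` (one tibble, all
#'   variables), and `manifest` (parameters, input/row counts, per-variable
#'   filtering decisions).
#' @export
analyze_corpus <- function(records, variables = NULL, min_count = 5,
                           mad_k = 3, mad_scale = 1.4826, alpha_gate = 0.05,
                           B = 9999, seed = NULL, edges = NULL,
                           effective_stress_policy = "keep") {
  agg <- aggregate_replicates(records)
  rel <- derive_relative(agg)
  rel <- filter_effective_stress(rel, policy = effective_stress_policy)
  dropped <- attr(rel, "dropped_groups")
  if (!is.null(variables)) {
    rel <- rel[rel$variable %in% variables, , drop = FALSE]
  }
  if (nrow(rel) == 0) stop("no analyzable observations", call. = FALSE)

  keys <- unique(rel[c("variable", "stage", "stress_axis")])
  schemes <- list(); groups <- list(); counts <- list()
  comparisons <- list(); skipped <- character()
  for (i in seq_len(nrow(keys))) {
    v <- keys$variable[i]; stg <- keys$stage[i]
    label <- if (stg == "none") v else paste(v, stg, sep = "_")
    obs <- rel[rel$variable == v & rel$stage == stg, , drop = FALSE]
    scheme <- tryCatch(
      build_bin_scheme(obs, min_count = min_count,
                       edges = if (!is.null(edges)) edges[[label]] else NULL),
      error = function(e) e)
    if (inherits(scheme, "error")) {
      skipped <- c(skipped, stats::setNames(conditionMessage(scheme), label))
      next
    }
    assigned <- assign_bins(obs, scheme)
    grp <- bin_groups(assigned, scheme, k = mad_k, scale = mad_scale)
    cmp <- compare_all_pairs(grp, alpha_gate = alpha_gate, B = B,
                             seed = if (is.null(seed)) NULL else seed + 1000L * i)
    cmp$variable <- label
    schemes[[label]] <- scheme
    groups[[label]] <- grp
    counts[[label]] <- bin_count_table(grp)
    comparisons[[label]] <- cmp
  }
  if (length(comparisons) == 0) {
    stop("no variable could be binned with at least two covered settings",
         call. = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("saltmeta")),
    parameters = list(min_count = min_count, mad_k = mad_k,
                      mad_scale = mad_scale, alpha_gate = alpha_gate,
                      B = B, seed = seed,
                      effective_stress_policy = effective_stress_policy),
    n_input_records = nrow(records),
    n_aggregated = nrow(agg),
    n_levels_dropped_no_decrease = nrow(dropped),
    n_analyzed = nrow(rel),
    variables_skipped = as.list(skipped),
    per_variable = lapply(names(schemes), function(lab) list(
      edges = as.numeric(schemes[[lab]]$edges),
      settings_covered = schemes[[lab]]$settings_covered,
      n_outliers_excluded = sum(groups[[lab]]$n_excluded)))
  )
  names(manifest$per_variable) <- names(schemes)
  structure(list(derived = rel, schemes = schemes, groups = groups,
                 counts = counts,
                 comparisons = do.call(rbind, comparisons),
                 manifest = manifest),
            class = "saltmeta_analysis")
}

#' @export
print.saltmeta_analysis <- function(x, ...) {
  cat("Salt-stress meta-analysis:", length(x$schemes), "variable(s),",
      x$manifest$n_analyzed, "observations analyzed\n")
  print(x$comparisons[c("variable", "setting_a", "setting_b", "n_a", "n_b",
                        "transform", "test_used", "p_value")], n = 20)
  invisible(x)
}

#' Simulate a corpus and write it to disk
#'
#' @param out Output corpus path (CSV).
#' @param config A `corpus_config`; defaults to [default_corpus_config()].
#' @param seed Overrides `config$seed` when given.
#' @return The output path, invisibly.
#' @export
cmd_simulate <- function(out, config = default_corpus_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  corpus <- generate_corpus(config)
  write_corpus(corpus, out)
  message("wrote ", nrow(corpus), " observation(s) to ", out)
  invisible(out)
}

#' Analyze a corpus file and write result tables
#'
#' Reads a corpus, runs [analyze_corpus()], and writes into `outdir`:
#' the derived relative observations, the pairwise comparison table,
#' per-variable retained-count tables, bin-scheme YAMLs, and a JSON run
#' manifest recording inputs, parameters, seed and every filtering
#' decision count.
#'
#' @param corpus Path to a corpus CSV.
#' @param outdir Output directory (created if absent).
#' @param ... Passed to [analyze_corpus()].
#' @return The `saltmeta_analysis`, invisibly.
#' @export
cmd_analyze <- function(corpus, outdir, ...) {
  ingest <- read_corpus(corpus)
  if (nrow(ingest$rejections) > 0) {
    message(nrow(ingest$rejections), " malformed row(s) rejected")
  }
  res <- analyze_corpus(ingest$records, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$derived, file.path(outdir, "relative_observations.csv"),
                   progress = FALSE)
  readr::write_csv(res$comparisons, file.path(outdir, "comparisons.csv"),
                   progress = FALSE)
  for (lab in names(res$counts)) {
    readr::write_csv(res$counts[[lab]],
                     file.path(outdir, paste0("bin_counts_", lab, ".csv")),
                     progress = FALSE)
    write_bin_scheme(res$schemes[[lab]],
                     file.path(outdir, paste0("bin_scheme_", lab, ".yaml")))
  }
  if (nrow(ingest$rejections) > 0) {
    readr::write_csv(ingest$rejections, file.path(outdir, "rejections.csv"),
                     progress = FALSE)
  }
  res$manifest$input <- corpus
  res$manifest$n_rejected_rows <- nrow(ingest$rejections)
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Run the gated factorial analysis on a long-format table
#'
#' Reads a CSV with columns `value`, `stress` and `setting`, runs
#' [gated_factorial()], and writes the effect table plus a small JSON
#' manifest.
#'
#' @param table Path to the long-format CSV.
#' @param out Output CSV path for the effect table.
#' @param alpha_gate Residual-normality gate level.
#' @return The `factorial_result`, invisibly.
#' @export
cmd_factorial <- function(table, out, alpha_gate = 0.05) {
  df <- readr::read_csv(table, show_col_types = FALSE, progress = FALSE)
  need <- c("value", "stress", "setting")
  if (!all(need %in% names(df))) {
    stop("factorial table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  res <- gated_factorial(df$value, df$stress, df$setting,
                         alpha_gate = alpha_gate)
  tab <- res$effects
  tab$method <- res$method
  tab$residual_normality_p <- res$residual_normality_p
  readr::write_csv(tab, out, progress = FALSE)
  invisible(res)
}
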