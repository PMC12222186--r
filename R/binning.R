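# Adaptive binning of the stress axis and robust per-bin outlier filtering.
#
# Bins are half-open intervals [e_i, e_{i+1}) with the final bin closed, the
# standard histogram convention. A scheme is feasible when every covered
# setting contributes at least `min_count` points to every bin; among
# feasible candidates the scheme minimizing the worst-bin spread of
# per-setting mean axis values is chosen, so that bin averages are
# comparable across settings.

new_bin_scheme <- function(edges, variable, stress_axis, settings_covered,
                           min_count, J = NA_real_) {
  structure(
    list(edges = as.numeric(edges), variable = variable,
         stress_axis = stress_axis, settings_covered = settings_covered,
         min_count = as.integer(min_count), J = J),
    class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("Bin scheme for", x$variable, "on axis", x$stress_axis, "\n")
  cat("  edges:", paste(signif(x$edges, 5), collapse = ", "), "\n")
  cat("  settings:", paste(x$settings_covered, collapse = ", "),
      " (min ", x$min_count, " points per bin and setting)\n", sep = "")
  if (is.finite(x$J)) cat("  comparability objective J =", signif(x$J, 5), "\n")
  invisible(x)
}

.bin_index <- function(x, edges) {
  if (length(edges) == 2 && edges[1] == edges[2]) {
    # degenerate single-point scheme [v, v]
    return(ifelse(x == edges[1], 1L, NA_integer_))
  }
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i >= length(edges) | x > edges[length(edges)]] <- NA_integer_
  # findInterval with rightmost.closed puts x == max into the last bin and
  # returns length(edges) only for x > max, handled above.
  i[!is.na(i) & i == 0] <- NA_integer_
  as.integer(i)
}

.cell_counts <- function(bin, setting, n_bins, settings) {
  tab <- table(factor(bin, levels = seq_len(n_bins)),
               factor(setting, levels = settings))
  matrix(tab, nrow = n_bins, dimnames = list(NULL, settings))
}

.scheme_J <- function(x, setting, edges, settings) {
  bin <- .bin_index(x, edges)
  means <- tapply(x, list(factor(bin, levels = seq_len(length(edges) - 1)),
                          factor(setting, levels = settings)),
                  mean)
  spreads <- apply(means, 1, function(m) {
    m <- m[is.finite(m)]
    if (length(m) < 2) 0 else max(m) - min(m)
  })
  max(spreads, 0)
}

.feasible <- function(x, setting, edges, settings, min_count) {
  bin <- .bin_index(x, edges)
  cc <- .cell_counts(bin, setting, length(edges) - 1, settings)
  all(cc >= min_count)
}

# Greedily merge adjacent bins until every bin x setting cell reaches
# min_count; deterministic (worst cell first, ties to the lower bin; merge
# direction by lower post-merge J, ties to the left).
.repair_edges <- function(x, setting, edges, settings, min_count) {
  repeat {
    if (length(edges) <= 2) return(edges)
    bin <- .bin_index(x, edges)
    cc <- .cell_counts(bin, setting, length(edges) - 1, settings)
    worst <- min(cc)
    if (worst >= min_count) return(edges)
    b <- which(apply(cc, 1, min) == worst)[1]
    cand <- list()
    if (b > 1) cand$left <- edges[-b]
    if (b < nrow(cc)) cand$right <- edges[-(b + 1)]
    if (length(cand) == 1) {
      edges <- cand[[1]]
    } else {
      jl <- .scheme_J(x, setting, cand$left, settings)
      jr <- .scheme_J(x, setting, cand$right, settings)
      edges <- if (jl <= jr) cand$left else cand$right
    }
  }
}

#' Search for a feasible, comparable bin scheme
#'
#' Partitions the stress axis (relative EC or stress integral) of one
#' variable into bins such that every covered setting has at least
#' `min_count` observations in every bin, and the per-setting mean axis
#' values within each bin are as comparable as possible. Candidate edge
#' sequences are seeded from pooled quantiles at every bin count up to
#' `max_bins` and greedily merged to feasibility; the scheme minimizing the
#' comparability objective J (the worst-bin spread, across settings, of the
#' within-bin mean axis value) is returned, with ties broken toward fewer
#' bins and then toward lexicographically smaller edges. Settings with
#' fewer than `min_count` observations in total can never be covered and
#' are dropped with a warning.
#'
#' @param observations Tibble of relative observations of a single variable
#'   and stress axis (columns `setting`, `axis_value`, `stress_axis`).
#' @param min_count Minimum observations per setting per bin (default 5).
#' @param max_bins Largest candidate bin count seeded from quantiles.
#' @param edges Optional explicit edge vector; when supplied the search is
#'   skipped and the edges are used as given (settings that fail the count
#'   constraint under them are dropped from coverage with a warning).
#' @return A `bin_scheme` object.
#' @export
build_bin_scheme <- function(observations, min_count = 5, max_bins = 8,
                             edges = NULL) {
  stopifnot(nrow(observations) > 0)
  axis <- unique(observations$stress_axis)
  variable <- unique(paste(observations$variable,
                           ifelse(observations$stage == "none", "",
                                  observations$stage)))
  if (length(axis) != 1) {
    stop("observations mix stress axes; bin one axis at a time", call. = FALSE)
  }
  x_all <- observations$axis_value
  s_all <- observations$setting

  totals <- table(factor(s_all, levels = setting_levels()))
  covered <- names(totals)[totals >= min_count]
  dropped <- setdiff(names(totals)[totals > 0], covered)
  if (length(dropped)) {
    warning("setting(s) dropped from bin coverage (fewer than ", min_count,
            " observations): ", paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(covered) < 2) {
    stop("fewer than 2 settings can be covered at min_count = ", min_count,
         call. = FALSE)
  }
  keep <- s_all %in% covered
  x <- x_all[keep]; s <- s_all[keep]

  if (!is.null(edges)) {
    edges <- sort(as.numeric(edges))
    ok <- vapply(covered, function(st)
      all(.cell_counts(.bin_index(x[s == st], edges), s[s == st],
                       length(edges) - 1, st) >= min_count), logical(1))
    if (any(!ok)) {
      warning("explicit edges leave setting(s) under min_count: ",
              paste(covered[!ok], collapse = ", "), "; dropped from coverage",
              call. = FALSE)
      covered <- covered[ok]
      if (length(covered) < 2) stop("fewer than 2 settings covered", call. = FALSE)
      keep <- s_all %in% covered
      x <- x_all[keep]; s <- s_all[keep]
    }
    return(new_bin_scheme(edges, variable[1], axis, covered, min_count,
                          .scheme_J(x, s, edges, covered)))
  }

  rng <- range(x)
  if (rng[1] == rng[2]) {
    # all observations share one axis value: degenerate single bin [v, v]
    return(new_bin_scheme(c(rng[1], rng[2]), variable[1], axis, covered,
                          min_count, 0))
  }

  candidates <- list(c(rng[1], rng[2]))
  max_k <- max(2, min(max_bins, floor(min(totals[covered]) / min_count)))
  for (k in 2:max_k) {
    e <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1),
                                names = FALSE, type = 7))
    e[1] <- rng[1]; e[length(e)] <- rng[2]
    if (length(e) < 2) next
    e <- .repair_edges(x, s, e, covered, min_count)
    if (.feasible(x, s, e, covered, min_count)) {
      candidates[[length(candidates) + 1L]] <- e
    }
  }
  candidates <- unique(candidates)
  feas <- vapply(candidates, function(e) .feasible(x, s, e, covered, min_count),
                 logical(1))
  candidates <- candidates[feas]
  if (length(candidates) == 0) {
    stop("no feasible bin scheme at min_count = ", min_count, call. = FALSE)
  }
  J <- vapply(candidates, function(e) .scheme_J(x, s, e, covered), numeric(1))
  nb <- lengths(candidates)
  lex <- vapply(candidates, function(e)
    paste(formatC(e, format = "e", digits = 12), collapse = ","), character(1))
  ord <- order(J, nb, lex)
  best <- candidates[[ord[1]]]
  new_bin_scheme(best, variable[1], axis, covered, min_count, J[ord[1]])
}

#' Assign observations to bins
#'
#' Assigns each observation to the unique half-open bin containing its axis
#' value; a value equal to an interior edge belongs to the upper bin, and
#' the last edge belongs to the last bin. Out-of-range observations are
#' reported in the `"unassigned"` attribute, never silently dropped.
#'
#' @param observations Tibble of relative observations on the scheme's axis.
#' @param scheme A `bin_scheme`.
#' @return `observations` with a `bin_index` column (in-range rows only);
#'   out-of-range rows are attached as attribute `"unassigned"`.
#' @export
assign_bins <- function(observations, scheme) {
  if (!identical(unique(observations$stress_axis), scheme$stress_axis)) {
    stop("stress axis mismatch: scheme is on ", scheme$stress_axis, call. = FALSE)
  }
  idx <- .bin_index(observations$axis_value, scheme$edges)
  out <- observations
  out$bin_index <- idx
  unassigned <- out[is.na(idx), , drop = FALSE]
  out <- out[!is.na(idx), , drop = FALSE]
  attr(out, "unassigned") <- unassigned
  out
}

#' Single-pass Hampel outlier filter
#'
#' Excludes values lying farther than `k` (scaled) median absolute
#' deviations from the median of the input: a value v is excluded when
#' |v - median| > k * scale * MAD, with MAD the raw median of absolute
#' deviations from the median. The median and MAD are computed once on the
#' full input (single pass, not iterated). With `scale = 1.4826` (default)
#' MAD estimates the standard deviation of Gaussian data, the usual Hampel
#' convention; `scale = 1` gives the literal "k median absolute deviations"
#' reading. When the MAD is zero (at least half the values identical)
#' nothing is excluded — the conservative choice, since the literal rule
#' would then discard every non-median point.
#'
#' @param values Numeric vector (at least one value).
#' @param k Threshold in scaled MAD units (default 3).
#' @param scale MAD scale factor (default 1.4826).
#' @return List with `retained`, `excluded`, `median`, `mad` and
#'   `threshold` (the half-width of the acceptance window).
#' @export
hampel_filter <- function(values, k = 3, scale = 1.4826) {
  if (length(values) == 0) stop("hampel_filter needs at least one value", call. = FALSE)
  med <- stats::median(values)
  mad_raw <- stats::median(abs(values - med))
  thr <- k * scale * mad_raw
  out <- if (mad_raw == 0) rep(FALSE, length(values)) else abs(values - med) > thr
  list(retained = values[!out], excluded = values[out],
       median = med, mad = mad_raw, threshold = thr)
}

#' Group binned observations per setting and filter outliers
#'
#' Splits bin-assigned observations into (bin, setting) cells, applies the
#' Hampel filter to the relative responses of each cell, and summarizes the
#' retained values. The per-cell mean axis value and the mean +/- standard
#' error of the retained responses reproduce the quantities plotted in
#' binned dose-response figures.
#'
#' @param observations Output of [assign_bins()].
#' @param scheme The `bin_scheme` used for assignment.
#' @param k,scale Hampel filter parameters, see [hampel_filter()].
#' @return Tibble with one row per (bin_index, setting): `n_total`,
#'   `n_retained`, `n_excluded`, `mean_axis`, `mean_response`,
#'   `se_response`, and list columns `values` (retained) and `excluded`.
#' @export
bin_groups <- function(observations, scheme, k = 3, scale = 1.4826) {
  obs <- observations[observations$setting %in% scheme$settings_covered, ,
                      drop = FALSE]
  cells <- split(seq_len(nrow(obs)),
                 list(bin = factor(obs$bin_index,
                                   levels = seq_len(length(scheme$edges) - 1)),
                      setting = factor(obs$setting,
                                       levels = scheme$settings_covered)),
                 drop = TRUE)
  rows <- lapply(cells, function(idx) {
    g <- obs[idx, , drop = FALSE]
    f <- hampel_filter(g$relative_response, k = k, scale = scale)
    keep <- if (f$mad == 0) rep(TRUE, nrow(g)) else
      abs(g$relative_response - f$median) <= f$threshold
    tibble::tibble(
      bin_index = g$bin_index[1],
      setting = g$setting[1],
      n_total = nrow(g),
      n_retained = sum(keep),
      n_excluded = sum(!keep),
      mean_axis = mean(g$axis_value[keep]),
      mean_response = mean(g$relative_response[keep]),
      se_response = stats::sd(g$relative_response[keep]) / sqrt(sum(keep)),
      values = list(g$relative_response[keep]),
      excluded = list(g$relative_response[!keep])
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bin_index, out$setting), , drop = FALSE]
  attr(out, "scheme") <- scheme
  out
}

#' Per-bin retained-count table
#'
#' Cross-tabulates retained observation counts as bins x settings, the
#' companion table shown inside binned dose-response plots.
#'
#' @param groups Output of [bin_groups()].
#' @return Tibble with one row per bin and one column per setting.
#' @export
bin_count_table <- function(groups) {
  settings <- sort(unique(groups$setting))
  bins <- sort(unique(groups$bin_index))
  out <- tibble::tibble(bin_index = bins)
  for (s in settings) {
    out[[s]] <- vapply(bins, function(b) {
      i <- groups$bin_index == b & groups$setting == s
      if (any(i)) sum(groups$n_retained[i]) else 0L
    }, numeric(1))
  }
  out
}

#' Serialize or restore a bin scheme
#'
#' Bin schemes can be written to and read from a small YAML configuration
#' (variable, axis, edges, covered settings, min_count), so that a manually
#' chosen binning can be version-controlled and reused.
#'
#' @param scheme A `bin_scheme`.
#' @param path File path.
#' @return `read_bin_scheme()` returns a `bin_scheme`.
#' @export
write_bin_scheme <- function(scheme, path) {
  yaml::write_yaml(list(
    variable = scheme$variable, stress_axis = scheme$stress_axis,
    edges = as.numeric(scheme$edges),
    settings_covered = as.character(scheme$settings_covered),
    min_count = scheme$min_count), path)
  invisible(path)
}

#' @rdname write_bin_scheme
#' @export
read_bin_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  new_bin_scheme(cfg$edges, cfg$variable, cfg$stress_axis,
                 cfg$settings_covered, cfg$min_count)
}
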