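# Pairwise setting comparisons with a gated test-selection procedure.
#
# The decision tree follows standard meta-analytic practice for comparing
# two pooled samples of response ratios: Shapiro-Wilk normality on each
# group (raw scale, then log scale), Brown-Forsythe variance homogeneity on
# the candidate scale; if both gates pass, a permutation t-test on that
# scale, otherwise a Mann-Whitney U test on the raw data.

# Run an RNG-dependent expression under a local seed, restoring the global
# RNG state afterwards so callers' streams are unaffected.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.shapiro_p <- function(x) {
  if (length(x) < 3 || length(unique(x)) < 3) return(NA_real_)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

.brown_forsythe_p <- function(a, b) {
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  res <- tryCatch(car::leveneTest(c(a, b), g, center = stats::median),
                  error = function(e) NULL)
  if (is.null(res)) return(NA_real_)
  res[["Pr(>F)"]][1]
}

#' Select the two-sample test for a setting pair
#'
#' Implements the gated decision tree: (1) Shapiro-Wilk on each group of the
#' untransformed data; if both groups pass (p > `alpha_gate`) the candidate
#' scale is raw, otherwise Shapiro-Wilk is repeated on the log-transformed
#' data (possible only for strictly positive values) and, if both groups
#' pass, the candidate scale is log. (2) If a candidate scale exists,
#' Brown-Forsythe (median-centered Levene) variance homogeneity is tested on
#' that scale; if variances are homogeneous the permutation t-test on the
#' candidate scale is selected. Any failure — no normal scale, heterogeneous
#' variances, or groups too small for the normality test — falls through to
#' the Mann-Whitney U test on raw data.
#'
#' @param a,b Numeric samples.
#' @param alpha_gate Significance level of the gates (default 0.05).
#' @return List with `test` (`"permutation_t"` or `"mann_whitney"`),
#'   `transform` (`"raw"` or `"log"`), and `gates` (the gate p-values:
#'   `shapiro_raw_a/b`, `shapiro_log_a/b`, `variance_p`).
#' @export
select_test <- function(a, b, alpha_gate = 0.05) {
  gates <- list(shapiro_raw_a = NA_real_, shapiro_raw_b = NA_real_,
                shapiro_log_a = NA_real_, shapiro_log_b = NA_real_,
                variance_p = NA_real_)
  if (length(a) < 3 || length(b) < 3) {
    warning("samples too small for the normality gate; using Mann-Whitney",
            call. = FALSE)
    return(list(test = "mann_whitney", transform = "raw", gates = gates))
  }
  gates$shapiro_raw_a <- .shapiro_p(a)
  gates$shapiro_raw_b <- .shapiro_p(b)
  transform <- NULL
  if (isTRUE(gates$shapiro_raw_a > alpha_gate) &&
      isTRUE(gates$shapiro_raw_b > alpha_gate)) {
    transform <- "raw"
  } else if (all(a > 0) && all(b > 0)) {
    gates$shapiro_log_a <- .shapiro_p(log(a))
    gates$shapiro_log_b <- .shapiro_p(log(b))
    if (isTRUE(gates$shapiro_log_a > alpha_gate) &&
        isTRUE(gates$shapiro_log_b > alpha_gate)) {
      transform <- "log"
    }
  }
  if (is.null(transform)) {
    return(list(test = "mann_whitney", transform = "raw", gates = gates))
  }
  ta <- if (transform == "log") log(a) else a
  tb <- if (transform == "log") log(b) else b
  gates$variance_p <- .brown_forsythe_p(ta, tb)
  if (isTRUE(gates$variance_p > alpha_gate)) {
    list(test = "permutation_t", transform = transform, gates = gates)
  } else {
    list(test = "mann_whitney", transform = "raw", gates = gates)
  }
}

# Pooled-variance Student t statistic from group-a sums; zero pooled
# variance with equal means is defined as t = 0.
.t_from_sums <- function(sa, qa, na, S, Q, n) {
  nb <- n - na
  sb <- S - sa
  ssa <- qa - sa^2 / na
  ssb <- (Q - qa) - sb^2 / nb
  sp2 <- (ssa + ssb) / (n - 2)
  d <- sa / na - sb / nb
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  ifelse(se == 0, ifelse(d == 0, 0, Inf * sign(d)), d / se)
}

#' Two-sample permutation t-test
#'
#' Two-sided test of equal location using the pooled-variance Student t
#' statistic, with its null distribution obtained by permuting group labels.
#' When the number of distinct label assignments `choose(n, n_a)` is at most
#' `enumeration_cap` the null distribution is enumerated exhaustively and
#' the p-value is the exact fraction of assignments with |t*| >= |t_obs|
#' (the observed assignment is included, so p >= 1/choose(n, n_a));
#' otherwise `B` random permutations are drawn and the add-one estimate
#' p = (1 + #\{|t*| >= |t_obs|\}) / (1 + B) is reported, which can never be
#' zero. The pooled-variance statistic is the natural choice here because
#' permutation inference assumes exchangeability, i.e. equal spread, which
#' the variance gate has checked upstream.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param B Number of random permutations when not enumerating.
#' @param seed Optional integer seed for the random permutations; the
#'   global RNG state is restored afterwards.
#' @param enumeration_cap Largest number of label assignments enumerated
#'   exhaustively.
#' @return List with `statistic` (observed t), `p.value`,
#'   `n_permutations` (`"exact"` or `B`) and `method`.
#' @export
permutation_t_test <- function(a, b, B = 9999, seed = NULL,
                               enumeration_cap = 10000) {
  na <- length(a); nb <- length(b); n <- na + nb
  if (na < 2 || nb < 2) stop("each sample needs at least 2 values", call. = FALSE)
  z <- c(a, b)
  S <- sum(z); Q <- sum(z^2)
  t_obs <- .t_from_sums(sum(a), sum(a^2), na, S, Q, n)
  tol <- 1e-12 * max(1, abs(t_obs))

  if (choose(n, na) <= enumeration_cap) {
    idx <- utils::combn(n, na)
    ts <- apply(idx, 2, function(i) {
      zi <- z[i]
      .t_from_sums(sum(zi), sum(zi^2), na, S, Q, n)
    })
    p <- mean(abs(ts) >= abs(t_obs) - tol)
    return(list(statistic = t_obs, p.value = p, n_permutations = "exact",
                method = "permutation t-test (exhaustive)"))
  }
  count <- .with_seed(seed, {
    hits <- 0L
    for (i in seq_len(B)) {
      pi <- sample.int(n, na)
      zi <- z[pi]
      ti <- .t_from_sums(sum(zi), sum(zi^2), na, S, Q, n)
      if (abs(ti) >= abs(t_obs) - tol) hits <- hits + 1L
    }
    hits
  })
  list(statistic = t_obs, p.value = (1 + count) / (1 + B),
       n_permutations = B, method = "permutation t-test (sampled)")
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two samples with the U statistic
#' U = #\{(i, j): a_i > b_j\} + 0.5 * #\{ties\}. For tie-free data with at
#' most `enumeration_cap` rank splits the two-sided p-value is exact, by
#' enumerating all `choose(n, n_a)` assignments of ranks to group a and
#' counting those at least as far from the null mean n_a n_b / 2 as the
#' observed U (the null U distribution is symmetric). Otherwise the normal
#' approximation with mid-rank tie correction and continuity correction is
#' used.
#'
#' @param a,b Numeric samples (non-empty).
#' @param enumeration_cap Largest number of rank splits enumerated.
#' @return List with `statistic` (U for the first sample), `p.value` and
#'   `method`.
#' @export
mann_whitney_u <- function(a, b, enumeration_cap = 20000) {
  na <- length(a); nb <- length(b); n <- na + nb
  if (na < 1 || nb < 1) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- any(duplicated(c(a, b)))

  if (!ties && choose(n, na) <= enumeration_cap) {
    idx <- utils::combn(n, na)
    Us <- colSums(matrix(idx, nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(statistic = U, p.value = p, method = "Mann-Whitney U (exact)"))
  }
  tie_tab <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = U, p.value = 1,
                method = "Mann-Whitney U (degenerate)"))
  }
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(statistic = U, p.value = p,
       method = "Mann-Whitney U (normal approximation)")
}

#' Compare all setting pairs of a binned variable
#'
#' For every unordered pair of covered settings, pools the retained
#' (post-filter) relative responses across the bins where both settings
#' have data — the overlapping bins — selects the test with [select_test()]
#' and runs it. Pairs with no overlapping bin are reported as untestable.
#' No multiplicity correction is applied by default, matching common
#' reporting of such figure-level comparisons; `p_adjust = "holm"` adds a
#' Holm adjustment across the pairs of the variable.
#'
#' @param groups Output of [bin_groups()] for one variable.
#' @param alpha_gate Gate level for [select_test()].
#' @param B,seed,enumeration_cap Passed to [permutation_t_test()]; each
#'   pair uses a seed derived from `seed` so results do not depend on pair
#'   order.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Tibble with one row per pair: sample sizes, bins used, gate
#'   p-values, transform, test used, statistic and p-value.
#' @export
compare_all_pairs <- function(groups, alpha_gate = 0.05, B = 9999,
                              seed = NULL, enumeration_cap = 10000,
                              p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  scheme <- attr(groups, "scheme")
  settings <- sort(unique(groups$setting))
  if (length(settings) < 2) stop("need at least two settings", call. = FALSE)
  pairs <- utils::combn(settings, 2)

  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    s1 <- pairs[1, j]; s2 <- pairs[2, j]
    g1 <- groups[groups$setting == s1 & groups$n_retained > 0, , drop = FALSE]
    g2 <- groups[groups$setting == s2 & groups$n_retained > 0, , drop = FALSE]
    bins <- intersect(g1$bin_index, g2$bin_index)
    base <- tibble::tibble(
      variable = if (!is.null(scheme)) scheme$variable else NA_character_,
      setting_a = s1, setting_b = s2, n_bins = length(bins),
      n_a = NA_integer_, n_b = NA_integer_,
      shapiro_raw_p = NA_real_, shapiro_log_p = NA_real_,
      variance_p = NA_real_, transform = NA_character_,
      test_used = "untestable", statistic = NA_real_, p_value = NA_real_,
      n_permutations = NA_character_)
    if (length(bins) == 0) return(base)
    a <- unlist(g1$values[g1$bin_index %in% bins])
    b <- unlist(g2$values[g2$bin_index %in% bins])
    base$n_a <- length(a); base$n_b <- length(b)
    sel <- suppressWarnings(select_test(a, b, alpha_gate = alpha_gate))
    base$shapiro_raw_p <- min(sel$gates$shapiro_raw_a, sel$gates$shapiro_raw_b)
    base$shapiro_log_p <- min(sel$gates$shapiro_log_a, sel$gates$shapiro_log_b)
    base$variance_p <- sel$gates$variance_p
    base$transform <- sel$transform
    base$test_used <- sel$test
    if (sel$test == "permutation_t") {
      ta <- if (sel$transform == "log") log(a) else a
      tb <- if (sel$transform == "log") log(b) else b
      res <- permutation_t_test(ta, tb, B = B,
                                seed = if (is.null(seed)) NULL else seed + j,
                                enumeration_cap = enumeration_cap)
      base$n_permutations <- as.character(res$n_permutations)
    } else {
      res <- mann_whitney_u(a, b, enumeration_cap = enumeration_cap)
    }
    base$statistic <- res$statistic
    base$p_value <- res$p.value
    base
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") {
    testable <- !is.na(out$p_value)
    out$p_value[testable] <- stats::p.adjust(out$p_value[testable], "holm")
  }
  out
}
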