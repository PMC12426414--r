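#' Per-subject change table
#'
#' Derives change scores from a cohort table: for every metric with `_t0`
#' and `_t10` (and optionally `_t1m`) columns, the differences T10 - T0 and
#' T1M - T0, plus the UPDRS-III improvement rate (t0 - t10) / t0
#' (defined only when t0 > 0; improvement is a decrease).
#'
#' @param cohort Cohort tibble, e.g. from [simulate_cohort()]; metric
#'   columns follow the `<metric>_t0` / `_t10` / `_t1m` naming scheme.
#' @return A tibble with `id`, `group`, one `delta_<metric>_t10` (and
#'   `_t1m`) column per metric, `improvement_rate`, and any
#'   `delta_*` columns already present in the input (e.g. simulated P60
#'   changes).
#' @export
change_table <- function(cohort) {
  base_cols <- grep("_t0$", names(cohort), value = TRUE)
  out <- tibble(id = cohort$id, group = cohort$group)
  for (b in base_cols) {
    metric <- sub("_t0$", "", b)
    for (tp in c("t10", "t1m")) {
      col <- paste0(metric, "_", tp)
      if (col %in% names(cohort)) {
        out[[paste0("delta_", metric, "_", tp)]] <- cohort[[col]] - cohort[[b]]
      }
    }
  }
  if (all(c("updrs_t0", "updrs_t10") %in% names(cohort))) {
    out$improvement_rate <- ifelse(
      cohort$updrs_t0 > 0,
      (cohort$updrs_t0 - cohort$updrs_t10) / cohort$updrs_t0,
      NA_real_
    )
  }
  keep <- setdiff(grep("^delta_", names(cohort), value = TRUE), names(out))
  for (k in keep) out[[k]] <- cohort[[k]]
  out
}

degenerate <- function() {
  tibble(test = "degenerate", statistic = NA_real_, p = 1,
         note = "no variation; test degenerate")
}

#' Within-group paired change test
#'
#' Paired comparison of a metric at two time points: Shapiro-Wilk on the
#' paired differences gates a paired t-test versus a Wilcoxon signed-rank
#' test. The p-value is Bonferroni-adjusted for the stated family of
#' comparisons (`p_adj = min(1, p * family)`). All-zero differences yield
#' the degenerate result p = 1.
#'
#' @param values_t0,values_t1 Paired numeric vectors (n >= 3).
#' @param family Size of the comparison family for Bonferroni correction.
#' @return A one-row tibble: `test`, `statistic`, `p`, `p_adj`, `note`.
#' @export
paired_change_test <- function(values_t0, values_t1, family = 1L) {
  ok <- stats::complete.cases(values_t0, values_t1)
  x <- values_t0[ok]; y <- values_t1[ok]
  abort_if(length(x) < 3L, "need at least 3 complete pairs")
  d <- y - x
  if (all(d == 0)) {
    out <- degenerate()
  } else if (is_normalish(d)) {
    tt <- stats::t.test(x, y, paired = TRUE)
    out <- tibble(test = "paired-t", statistic = unname(tt$statistic),
                  p = tt$p.value, note = NA_character_)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE))
    out <- tibble(test = "wilcoxon-signed-rank",
                  statistic = unname(wt$statistic), p = wt$p.value,
                  note = NA_character_)
  }
  out$p_adj <- pmin(1, out$p * family)
  out[, c("test", "statistic", "p", "p_adj", "note")]
}

#' Change-change correlation
#'
#' Pearson correlation when both columns pass Shapiro-Wilk at alpha = 0.05,
#' Spearman otherwise; pairwise-complete observations.
#'
#' @param x,y Numeric vectors (>= 5 complete pairs).
#' @return A one-row tibble: `method`, `r`, `p`, `n`.
#' @export
correlate_changes <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  abort_if(length(x) < 5L, "need at least 5 complete pairs")
  abort_if(sd(x) == 0 || sd(y) == 0,
           "zero variance; correlation undefined",
           class = "tmsreact_undefined_ratio")
  method <- if (is_normalish(x) && is_normalish(y)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble(method = method, r = unname(ct$estimate), p = ct$p.value,
         n = length(x))
}

#' Between-group comparison of change scores
#'
#' Independent two-sample comparison of per-subject changes: Shapiro-Wilk on
#' each group gates an independent t-test versus a Mann-Whitney U test.
#'
#' @param delta_a,delta_b Numeric change scores for the two groups (>= 2
#'   each).
#' @return A one-row tibble: `test`, `statistic`, `p`, `note`.
#' @export
between_group_change <- function(delta_a, delta_b) {
  a <- delta_a[!is.na(delta_a)]; b <- delta_b[!is.na(delta_b)]
  abort_if(length(a) < 2L || length(b) < 2L, "need at least 2 per group")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(degenerate())
  }
  if (is_normalish(a) && is_normalish(b)) {
    tt <- stats::t.test(a, b)
    tibble(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
           note = NA_character_)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    tibble(test = "mann-whitney", statistic = unname(wt$statistic),
           p = wt$p.value, note = NA_character_)
  }
}
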