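#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample's own mean and SD. Because the reference parameters are estimated
#' from the same sample, the p-value is conservative (the Lilliefors caveat);
#' this is recorded in the result's `note` attribute.
#'
#' @param values Numeric vector, `n >= 3`, finite, non-degenerate.
#' @return The p-value, with attributes `statistic` and `note`.
#' @export
ks_normality <- function(values) {
  if (!is.numeric(values) || length(values) < 3)
    stop_("sample_size_error", "need at least 3 values")
  if (any(!is.finite(values))) stop_("data_error", "non-finite values")
  if (sd(values) == 0)
    stop_("degenerate_sample_error", "zero variance sample")
  res <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), sd(values)))
  structure(unname(res$p.value), statistic = unname(res$statistic),
            note = "reference N(mean, sd) estimated from the sample (Lilliefors caveat)")
}

#' Paired Student's t-test
#'
#' `t = mean(a - b) / (sd(a - b) / sqrt(n))` with `df = n - 1` and a
#' two-sided p-value.
#'
#' @param a,b Paired numeric vectors of equal length `n >= 2`.
#' @return A list with `t_stat`, `df`, `p_value`.
#' @export
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 3, 5))  # t = -4, df = 2
paired_t_test <- function(a, b) {
  if (length(a) != length(b))
    stop_("pairing_error", "a and b must have equal length")
  if (length(a) < 2) stop_("sample_size_error", "need at least 2 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_("data_error", "non-finite values")
  if (sd(a - b) == 0)
    stop_("degenerate_error", "zero variance of paired differences")
  res <- stats::t.test(a, b, paired = TRUE)
  list(t_stat = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Significance tier from a p-value
#'
#' `"**"` for `p < 0.01`, `"*"` for `p < 0.05`, otherwise `""`.
#'
#' @param p A p-value.
#' @return A string.
#' @export
significance_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

metric_column_ <- function(metric) {
  switch(metric, pe = "pe_nats", pme = "pme_nats",
         stop_("invalid_parameter", "metric must be 'pe' or 'pme'"))
}

# Per-(D, tau, state) paired subject values of one metric vs. baseline.
paired_values_ <- function(table, metric, D, tau, state, baseline) {
  col <- metric_column_(metric)
  sel <- table$D == D & table$tau == tau
  b <- table[sel & table$state == baseline, c("subject_id", col)]
  s <- table[sel & table$state == state, c("subject_id", col)]
  m <- merge(as.data.frame(s), as.data.frame(b), by = "subject_id",
             suffixes = c("_state", "_baseline"))
  m <- m[order(m$subject_id), ]
  ok <- stats::complete.cases(m)
  list(state = m[ok, paste0(col, "_state")],
       baseline = m[ok, paste0(col, "_baseline")],
       n_excluded = sum(!ok) +
         length(unique(c(setdiff(s$subject_id, b$subject_id),
                         setdiff(b$subject_id, s$subject_id)))))
}

#' Compare every non-baseline state against the baseline
#'
#' For each (metric, embedding dimension, delay, state) cell, pairs the
#' subjects' entropy values with their baseline-state values and runs a
#' two-sided paired Student's t-test. Group normality is checked per cell
#' with [ks_normality()]; when either group fails at the 0.05 level, a
#' Wilcoxon signed-rank p-value is reported alongside as a fallback column
#' (the parametric result remains the primary one). Subjects missing either
#' member of a pair are excluded pairwise and counted in `n_excluded`.
#'
#' @param table An entropy table as produced by [entropy_sweep()].
#' @param baseline Baseline state label (default `"neutral"`).
#' @param metrics Which metrics to compare, subset of `c("pe", "pme")`.
#' @return A tibble with one row per cell: `metric`, `D`, `tau`, `state`,
#'   `n_pairs`, `n_excluded`, `mean_state`, `sd_state`, `mean_neutral`,
#'   `sd_neutral`, `t_stat`, `df`, `p_value`, `significance`,
#'   `normality_p_state`, `normality_p_neutral`, `wilcoxon_p`.
#' @export
compare_states <- function(table, baseline = "neutral",
                           metrics = c("pe", "pme")) {
  table <- as.data.frame(table)
  if (!baseline %in% table$state)
    stop_("configuration_error", "baseline state '%s' absent from table",
          baseline)
  states <- setdiff(unique(table$state), baseline)
  cells <- unique(table[, c("D", "tau")])
  cells <- cells[order(cells$D, cells$tau), ]
  out <- list()
  for (metric in metrics) {
    for (r in seq_len(nrow(cells))) {
      for (st in states) {
        pv <- paired_values_(table, metric, cells$D[r], cells$tau[r], st,
                             baseline)
        if (length(pv$state) < 2)
          stop_("sample_size_error",
                "fewer than 2 complete pairs for %s, D=%d, tau=%d, state=%s",
                metric, cells$D[r], cells$tau[r], st)
        tt <- paired_t_test(pv$state, pv$baseline)
        np_s <- tryCatch(as.numeric(ks_normality(pv$state)),
                         error = function(e) NA_real_)
        np_b <- tryCatch(as.numeric(ks_normality(pv$baseline)),
                         error = function(e) NA_real_)
        wil <- NA_real_
        if (!is.na(np_s) && !is.na(np_b) && (np_s < 0.05 || np_b < 0.05)) {
          wil <- suppressWarnings(
            stats::wilcox.test(pv$state, pv$baseline, paired = TRUE)$p.value)
        }
        out[[length(out) + 1L]] <- data.frame(
          metric = metric, D = cells$D[r], tau = cells$tau[r], state = st,
          n_pairs = length(pv$state), n_excluded = pv$n_excluded,
          mean_state = mean(pv$state), sd_state = sd(pv$state),
          mean_neutral = mean(pv$baseline), sd_neutral = sd(pv$baseline),
          t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
          significance = significance_tier(tt$p_value),
          normality_p_state = np_s, normality_p_neutral = np_b,
          wilcoxon_p = wil)
      }
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Relative increment of entropy versus the baseline state
#'
#' The per-subject percentage change
#' `(E_state - E_baseline) / E_baseline * 100` summarised per (metric, D,
#' tau, state) by its mean and standard error across subjects
#' (`method = "per_subject"`, the default). `method = "group_means"` instead
#' forms the ratio of group means, with a delta-method standard error from
#' the paired differences.
#'
#' @inheritParams compare_states
#' @param method `"per_subject"` or `"group_means"`.
#' @return A tibble: `metric`, `D`, `tau`, `state`, `n`, `mean_percent`,
#'   `se_percent`, `method`.
#' @export
relative_increment <- function(table, baseline = "neutral",
                               metrics = c("pe", "pme"),
                               method = c("per_subject", "group_means")) {
  method <- match.arg(method)
  table <- as.data.frame(table)
  if (!baseline %in% table$state)
    stop_("configuration_error", "baseline state '%s' absent from table",
          baseline)
  states <- setdiff(unique(table$state), baseline)
  cells <- unique(table[, c("D", "tau")])
  cells <- cells[order(cells$D, cells$tau), ]
  out <- list()
  for (metric in metrics) {
    for (r in seq_len(nrow(cells))) {
      for (st in states) {
        pv <- paired_values_(table, metric, cells$D[r], cells$tau[r], st,
                             baseline)
        nz <- pv$baseline != 0
        if (any(!nz))
          warning(sprintf("%d zero-baseline subjects excluded (%s, state %s)",
                          sum(!nz), metric, st), call. = FALSE)
        s <- pv$state[nz]; b <- pv$baseline[nz]
        if (length(s) < 1)
          stop_("sample_size_error", "no valid pairs for %s, state %s",
                metric, st)
        if (method == "per_subject") {
          inc <- (s - b) / b * 100
          mean_pct <- mean(inc)
          se_pct <- if (length(inc) > 1) sd(inc) / sqrt(length(inc)) else 0
        } else {
          mean_pct <- (mean(s) - mean(b)) / mean(b) * 100
          se_pct <- if (length(s) > 1)
            100 * sd(s - b) / sqrt(length(s)) / mean(b) else 0
        }
        out[[length(out) + 1L]] <- data.frame(
          metric = metric, D = cells$D[r], tau = cells$tau[r], state = st,
          n = length(s), mean_percent = mean_pct, se_percent = se_pct,
          method = method)
      }
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Per-group state comparisons
#'
#' Runs [compare_states()] independently within each level of a grouping
#' column (gender by default). A group failing the comparison preconditions
#' (for example fewer than two complete pairs) is reported as insufficient
#' while the remaining groups are still computed.
#'
#' @inheritParams compare_states
#' @param group_field Name of the grouping column in `table`.
#' @return A named list of [compare_states()] tibbles, one per group;
#'   insufficient groups hold the condition message instead, and their names
#'   are listed in the `insufficient` attribute.
#' @export
subgroup_analysis <- function(table, group_field = "gender",
                              baseline = "neutral",
                              metrics = c("pe", "pme")) {
  table <- as.data.frame(table)
  if (!group_field %in% names(table))
    stop_("configuration_error", "no column '%s' in table", group_field)
  groups <- sort(unique(stats::na.omit(table[[group_field]])))
  if (length(groups) == 0)
    stop_("configuration_error", "grouping column '%s' has no labels",
          group_field)
  res <- lapply(groups, function(g) {
    tryCatch(compare_states(table[table[[group_field]] == g, , drop = FALSE],
                            baseline = baseline, metrics = metrics),
             error = function(e) conditionMessage(e))
  })
  names(res) <- groups
  insufficient <- groups[vapply(res, is.character, TRUE)]
  structure(res, insufficient = insufficient)
}

#' Plain-text comparison report
#'
#' Formats a [compare_states()] table in the conventional
#' "mean +/- SD, P" presentation, one line per cell.
#'
#' @param comparison A tibble from [compare_states()].
#' @return A character vector of report lines.
#' @export
format_comparison_report <- function(comparison) {
  apply(as.data.frame(comparison), 1L, function(r) {
    sprintf("%-3s D=%s tau=%-2s %-10s %.4f +/- %.2f vs %.4f +/- %.2f  P=%.3g %s",
            r[["metric"]], r[["D"]], r[["tau"]], r[["state"]],
            as.numeric(r[["mean_state"]]), as.numeric(r[["sd_state"]]),
            as.numeric(r[["mean_neutral"]]), as.numeric(r[["sd_neutral"]]),
            as.numeric(r[["p_value"]]), r[["significance"]])
  })
}
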