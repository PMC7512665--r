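test_that("paired t-test matches the closed-form hand computation", {
  res <- paired_t_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(res$t_stat, -4)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * stats::pt(-4, df = 2))
  # antisymmetry
  swapped <- paired_t_test(c(2, 3, 5), c(1, 2, 3))
  expect_equal(swapped$t_stat, 4)
  expect_equal(swapped$p_value, res$p_value)
  expect_error(paired_t_test(1:3, 1:3), class = "degenerate_error")
  expect_error(paired_t_test(1:3, 1:4), class = "pairing_error")
  expect_error(paired_t_test(1, 2), class = "sample_size_error")
})

test_that("KS normality flags gross non-normality and rejects degenerate input", {
  expect_error(ks_normality(c(1, 2)), class = "sample_size_error")
  expect_error(ks_normality(rep(5, 10)), class = "degenerate_sample_error")
  set.seed(31)
  two_point <- sample(c(0, 1), 500, replace = TRUE)
  expect_lt(as.numeric(ks_normality(two_point)), 0.01)
  expect_match(attr(ks_normality(rnorm(50)), "note"), "Lilliefors")
})

test_that("KS normality accepts normal samples in most replicates", {
  set.seed(32)
  hits <- sum(vapply(1:100, function(i) {
    as.numeric(ks_normality(rnorm(500))) > 0.05
  }, TRUE))
  expect_gte(hits, 85)
})

test_that("significance tiers follow the 0.05 / 0.01 convention", {
  expect_identical(significance_tier(0.03), "*")
  expect_identical(significance_tier(0.005), "**")
  expect_identical(significance_tier(0.10), "")
  expect_identical(significance_tier(0.05), "")
  expect_identical(significance_tier(0.01), "*")
})

# A hand-built entropy table: n subjects, one (D, tau) cell, chosen shifts.
toy_table <- function(n = 10, shift_pe = 0.05, shift_pme = 0.1, seed = 1,
                      states = c("neutral", "happiness"), gender = NULL) {
  set.seed(seed)
  base <- 1.70 + stats::rnorm(n, 0, 0.02)
  rows <- list()
  for (i in seq_len(n)) {
    for (s in states) {
      sh_pe <- if (s == "neutral") 0 else shift_pe
      sh_pme <- if (s == "neutral") 0 else shift_pme
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("subj%02d", i),
        state = s,
        gender = if (is.null(gender)) c("female", "male")[1 + i %% 2]
                 else gender,
        D = 3L, tau = 1L, n_windows = 348L,
        pe_nats = base[i] + sh_pe + stats::rnorm(1, 0, 0.005),
        pme_nats = base[i] - 0.4 + sh_pme + stats::rnorm(1, 0, 0.01))
    }
  }
  do.call(rbind, rows)
}

test_that("compare_states pairs subjects and annotates significance", {
  tab <- toy_table(n = 20, shift_pe = 0.05)
  cmp <- compare_states(tab)
  expect_identical(nrow(cmp), 2L)  # pe and pme, one state, one cell
  pe_row <- cmp[cmp$metric == "pe", ]
  expect_identical(pe_row$n_pairs, 20L)
  expect_identical(pe_row$df, 19)
  expect_gt(pe_row$t_stat, 0)
  expect_identical(pe_row$significance, "**")
  expect_lt(abs(pe_row$mean_state - pe_row$mean_neutral - 0.05), 0.01)
  # row order of the input is irrelevant
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(as.data.frame(compare_states(shuffled)), as.data.frame(cmp))
  expect_error(compare_states(tab, baseline = "serenity"),
               class = "configuration_error")
})

test_that("compare_states excludes incomplete subjects pairwise", {
  tab <- toy_table(n = 6)
  tab <- tab[!(tab$subject_id == "subj03" & tab$state == "happiness"), ]
  cmp <- compare_states(tab, metrics = "pe")
  expect_identical(cmp$n_pairs, 5L)
  expect_identical(cmp$n_excluded, 1L)
  tiny <- toy_table(n = 2)
  tiny <- tiny[!(tiny$subject_id == "subj01" & tiny$state == "happiness"), ]
  expect_error(compare_states(tiny, metrics = "pe"),
               class = "sample_size_error")
})

test_that("relative increments reproduce constant-ratio arithmetic", {
  tab <- toy_table(n = 8, shift_pe = 0, shift_pme = 0, seed = 3)
  sel0 <- tab$state == "happiness"
  tab$pe_nats[sel0] <- tab$pe_nats[tab$state == "neutral"][
    match(tab$subject_id[sel0], tab$subject_id[tab$state == "neutral"])]
  # identical states: zero increment, zero SE
  inc0 <- relative_increment(tab, metrics = "pe")
  expect_equal(inc0$mean_percent, 0)
  expect_equal(inc0$se_percent, 0)
  # constant ratio 1.1: exactly 10%, zero SE
  tab2 <- tab
  sel <- tab2$state == "happiness"
  tab2$pe_nats[sel] <- 1.1 *
    tab2$pe_nats[tab2$state == "neutral"][match(tab2$subject_id[sel],
      tab2$subject_id[tab2$state == "neutral"])]
  inc <- relative_increment(tab2, metrics = "pe")
  expect_equal(inc$mean_percent, 10, tolerance = 1e-9)
  expect_equal(inc$se_percent, 0, tolerance = 1e-9)
  # the group-mean ratio of the study's printed neutral/happiness PE means,
  # applied as a constant per-subject ratio
  tab3 <- tab
  ratio <- 1.7205 / 1.6834
  tab3$pe_nats[sel] <- ratio * tab3$pe_nats[tab3$state == "neutral"][
    match(tab3$subject_id[sel],
          tab3$subject_id[tab3$state == "neutral"])]
  inc3 <- relative_increment(tab3, metrics = "pe")
  expect_equal(inc3$mean_percent, 2.20, tolerance = 0.005)
  # both computation methods agree for a constant ratio
  inc3g <- relative_increment(tab3, metrics = "pe", method = "group_means")
  expect_equal(inc3g$mean_percent, inc3$mean_percent, tolerance = 0.05)
  # zero baselines are excluded with a warning
  tab4 <- toy_table(n = 4)
  tab4$pe_nats[tab4$subject_id == "subj01" & tab4$state == "neutral"] <- 0
  expect_warning(relative_increment(tab4, metrics = "pe"), "zero-baseline")
})

test_that("subgroup analysis splits by gender and flags thin groups", {
  tab <- toy_table(n = 12, shift_pe = 0.06)
  res <- subgroup_analysis(tab, metrics = "pe")
  expect_named(res, c("female", "male"))
  expect_identical(attr(res, "insufficient"), character(0))
  n_f <- res$female$n_pairs[1]
  n_m <- res$male$n_pairs[1]
  expect_identical(n_f + n_m, 12L)  # subgroup n sums to pooled n
  # single-gender table: the missing group simply isn't there; a group with
  # too few pairs is reported insufficient while others are computed
  one <- toy_table(n = 12, gender = "female")
  one$gender[one$subject_id == "subj01"] <- "male"
  res2 <- subgroup_analysis(one, metrics = "pe")
  expect_identical(attr(res2, "insufficient"), "male")
  expect_s3_class(res2$female, "tbl_df")
  expect_type(res2$male, "character")
  expect_error(subgroup_analysis(tab, group_field = "site"),
               class = "configuration_error")
})

test_that("comparison report lines carry the mean +/- SD and tier", {
  cmp <- compare_states(toy_table(n = 10, shift_pe = 0.05), metrics = "pe")
  lines <- format_comparison_report(cmp)
  expect_length(lines, 1L)
  expect_match(lines, "happiness")
  expect_match(lines, "\\+/-")
})
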