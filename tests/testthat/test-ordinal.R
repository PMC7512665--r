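test_that("single-window symbolization follows the time-position convention", {
  expect_identical(ordinal_pattern(c(3, 5, 2)), "312")
  expect_identical(ordinal_pattern(c(1, 4, 8)), "123")
  expect_identical(ordinal_pattern(c(5, 2, 1)), "321")
  expect_identical(ordinal_pattern(c(4, 8, 5)), "132")
  expect_error(ordinal_pattern(c(1, NA, 2)), class = "data_error")
  expect_error(ordinal_pattern(3), class = "shape_error")
})

test_that("tie policies resolve equal values as documented", {
  # stable-rank: earlier time position ranks lower
  expect_identical(ordinal_pattern(c(7, 7, 9), stable_policy), "123")
  expect_identical(ordinal_pattern(c(9, 7, 7), stable_policy), "231")
  # noise: deterministic under a fixed seed, one of the two tie orders
  p1 <- ordinal_pattern(c(7, 7, 9), tie_policy("noise", seed = 11))
  p2 <- ordinal_pattern(c(7, 7, 9), tie_policy("noise", seed = 11))
  expect_identical(p1, p2)
  expect_true(p1 %in% c("123", "213"))
  expect_error(tie_policy("noise", noise_amplitude = 0),
               class = "invalid_parameter")
})

test_that("pattern labels and rank-vector codec are inverse permutations", {
  expect_identical(pattern_labels(3),
                   c("123", "132", "213", "231", "312", "321"))
  expect_length(pattern_labels(4), 24)
  expect_identical(pattern_to_ranks("312"), c(2L, 3L, 1L))
  expect_identical(ranks_to_pattern(c(2, 3, 1)), "312")
  for (D in 3:4) {
    for (lab in pattern_labels(D)) {
      expect_identical(ranks_to_pattern(pattern_to_ranks(lab)), lab)
    }
  }
  expect_error(pattern_to_ranks("311"), class = "invalid_parameter")
})

test_that("distribution bookkeeping: window count, alphabet, preconditions", {
  set.seed(101)
  for (i in 1:25) {
    D <- sample(3:4, 1)
    tau <- sample(1:3, 1)
    N <- as.integer(sample((D - 1L) * tau + 1:150, 1))
    d <- suppressWarnings(pattern_distribution(rnorm(N), D, tau))
    expect_identical(d$n_windows, N - (D - 1L) * tau)
    expect_identical(sum(d$counts), d$n_windows)
    expect_length(d$counts, factorial(D))
  }
  expect_error(pattern_distribution(rnorm(4), D = 3, tau = 2),
               class = "length_error")
  expect_warning(pattern_distribution(rnorm(20), D = 3, tau = 1),
                 "short relative")
  expect_error(pattern_distribution(c(rnorm(50), Inf), 3, 1),
               class = "data_error")
})

test_that("entropy closed forms: uniform, degenerate, partial distributions", {
  # monotone series: a single pattern, zero entropy
  d1 <- suppressWarnings(pattern_distribution(1:10, 3, 1))
  expect_identical(unname(d1$counts["123"]), 8L)
  expect_equal(permutation_entropy(d1), 0)
  expect_equal(permutation_min_entropy(d1), 0)
  # periodic ramp (60 windows): three patterns at exactly 1/3 each
  d3 <- pattern_distribution(rep_len(c(1, 2, 3), 62), 3, 1, stable_policy)
  expect_equal(permutation_entropy(d3), log(3), tolerance = 1e-12)
  expect_equal(permutation_min_entropy(d3), log(3), tolerance = 1e-12)
  # direct evaluation on constructed counts: two patterns at 1/2
  d2 <- structure(list(D = 3L, tau = 1L,
                       counts = c("123" = 5L, "132" = 0L, "213" = 0L,
                                  "231" = 0L, "312" = 0L, "321" = 5L),
                       n_windows = 10L),
                  class = "ordinal_distribution")
  expect_equal(permutation_entropy(d2), log(2), tolerance = 1e-12)
  expect_equal(permutation_min_entropy(d2), log(2), tolerance = 1e-12)
  # max p = 3/4 but several patterns: PME strictly below PE bound story
  d4 <- structure(list(D = 3L, tau = 1L,
                       counts = c("123" = 6L, "132" = 1L, "213" = 1L,
                                  "231" = 0L, "312" = 0L, "321" = 0L),
                       n_windows = 8L),
                  class = "ordinal_distribution")
  expect_equal(permutation_min_entropy(d4), -log(6 / 8), tolerance = 1e-12)
  expect_lt(permutation_min_entropy(d4), permutation_entropy(d4))
  d_empty <- structure(list(D = 3L, tau = 1L, counts = integer(6),
                            n_windows = 0L), class = "ordinal_distribution")
  expect_error(permutation_entropy(d_empty), class = "domain_error")
  expect_error(permutation_min_entropy(d_empty), class = "domain_error")
})

test_that("PE and PME are invariant under monotone transforms and reversal", {
  set.seed(202)
  for (i in 1:30) {
    x <- rnorm(100)
    D <- sample(3:4, 1)
    tau <- sample(1:2, 1)
    d0 <- suppressWarnings(pattern_distribution(x, D, tau, stable_policy))
    for (f in list(function(z) exp(z), function(z) 3 * z + 7,
                   function(z) z^3)) {
      df <- suppressWarnings(pattern_distribution(f(x), D, tau, stable_policy))
      expect_identical(df$counts, d0$counts)
    }
    dr <- suppressWarnings(pattern_distribution(rev(x), D, tau, stable_policy))
    expect_identical(sort(unname(dr$counts)), sort(unname(d0$counts)))
    expect_equal(permutation_entropy(dr), permutation_entropy(d0))
    expect_equal(permutation_min_entropy(dr), permutation_min_entropy(d0))
  }
  # noise policy with tiny amplitude also leaves tie-free data invariant
  x <- rnorm(200)
  pol <- tie_policy("noise", seed = 3)
  expect_identical(pattern_distribution(x, 3, 1, pol)$counts,
                   pattern_distribution(x, 3, 1, stable_policy)$counts)
})

test_that("a deterministic logistic-map orbit shows forbidden patterns", {
  x <- numeric(500)
  x[1] <- 0.3
  for (i in 2:500) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  d <- pattern_distribution(x, D = 4, tau = 1, stable_policy)
  expect_lt(sum(d$counts > 0), 24)
})

test_that("iid series use mirrored pattern pairs with similar frequency", {
  set.seed(303)
  reps <- 300
  freq <- matrix(0, reps, 6,
                 dimnames = list(NULL, pattern_labels(3)))
  for (r in seq_len(reps)) {
    d <- pattern_distribution(rnorm(400), 3, 1, stable_policy)
    freq[r, ] <- d$counts / d$n_windows
  }
  m <- colMeans(freq)
  for (pair in list(c("123", "321"), c("132", "213"), c("231", "312"))) {
    expect_lt(abs(m[pair[1]] - m[pair[2]]), 0.01)
  }
})

test_that("entropy_sweep emits the full grid and matches direct calls", {
  s <- generate_rri(state_model("neutral", phi = 0.5), n = 350, seed = 4,
                    subject_id = "subj01")
  tab <- entropy_sweep(list(s), dimensions = c(3, 4), delays = 1:10)
  expect_identical(nrow(tab), 20L)
  expect_identical(unique(tab$subject_id), "subj01")
  d <- pattern_distribution(as.numeric(s), 3, 1)
  row <- tab[tab$D == 3 & tab$tau == 1, ]
  expect_equal(row$pe_nats, permutation_entropy(d))
  expect_equal(row$pme_nats, permutation_min_entropy(d))
  expect_true(all(tab$pme_nats <= tab$pe_nats + 1e-12))
  # too-short cells are flagged rows, not dropped
  short <- suppressWarnings(
    entropy_sweep(list(rnorm(6)), dimensions = 4, delays = c(1, 2)))
  expect_identical(nrow(short), 2L)
  expect_identical(short$n_windows[2], 0L)
  expect_true(is.na(short$pe_nats[2]))
  expect_false(is.na(short$pe_nats[1]))
  expect_error(entropy_sweep(list()), class = "input_error")
})

test_that("pattern counts agree with the sorting comparator on random data", {
  set.seed(404)
  for (i in 1:100) {
    x <- rnorm(50)
    D <- sample(3:4, 1)
    tau <- sample(1:3, 1)
    d <- suppressWarnings(pattern_distribution(x, D, tau, stable_policy))
    expect_identical(unname(d$counts), bf_pattern_counts(x, D, tau))
  }
})
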