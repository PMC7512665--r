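# Independent oracles used across the suite.

# Brute-force ordinal-pattern counts: sorts every window independently with
# order() (stable, so ties rank earlier-first) -- no sharing with the
# package's Lehmer-code path.
bf_pattern_counts <- function(x, D, tau) {
  m <- length(x) - (D - 1) * tau
  labs <- vapply(seq_len(m), function(t) {
    paste0(order(x[t + (0:(D - 1)) * tau]), collapse = "")
  }, "")
  counts <- table(factor(labs, levels = pattern_labels(D)))
  as.integer(counts)
}

# Shannon entropy of counts, direct evaluation.
bf_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Greedy peak matching within +/- tol samples; returns confusion counts.
match_peaks <- function(detected, truth, tol) {
  used <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    cand <- which(!used & abs(detected - t) <= tol)
    if (length(cand)) {
      used[cand[which.min(abs(detected[cand] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = sum(!used), fn = length(truth) - tp)
}

f1_score <- function(tp, fp, fn) {
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Band power below f_hi (Hz) from the periodogram, excluding DC.
band_power <- function(x, fs, f_hi) {
  P <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) * fs / length(x)
  sum(P[fr > 0 & fr < f_hi])
}

stable_policy <- tie_policy("stable-rank")

# Small AR(1) cohort config helper for simulation tests.
two_state_config <- function(phi_neutral, phi_state, n_subjects = 60,
                             seed = 1, state = "happiness", ...) {
  cohort_config(
    n_subjects = n_subjects,
    gender_split = c(female = ceiling(n_subjects / 2),
                     male = floor(n_subjects / 2)),
    states = list(state_model("neutral", phi = phi_neutral),
                  state_model(state, phi = phi_state)),
    seed = seed, ...)
}
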