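# Periodized orthogonal discrete wavelet transform with the symlet-8 basis.
#
# Analysis rows are the even circular shifts of the scaling/wavelet filters;
# because sym8 is orthogonal the synthesis is the exact adjoint, giving
# perfect reconstruction (unit-tested). FFT-based circular correlation keeps
# each level O(N log N). Constraint: the signal length at every level must be
# even and at least the filter length (16), so callers pad to a multiple of
# 2^levels with 16 * 2^levels as a floor.

# Symlet-8 scaling (low-pass) filter, 16 taps (Daubechies' least-asymmetric
# family, 8 vanishing moments).
sym8_dec_lo <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.0316950878114929800,
   0.0076074873249176050, -0.1432942383508097000, -0.0612733590676585240,
   0.4813596512583722000,  0.7771857517005235000, 0.3644418948353314000,
  -0.0519458381077090400, -0.0272190299170560030, 0.0491371796736075060,
   0.0038087520138906150, -0.0149522583370482300, -0.0003029205147213668,
   0.0018899503327594609)

# Quadrature-mirror high-pass: g[n] = (-1)^n h[L - 1 - n].
sym8_dec_hi <- rev(sym8_dec_lo) * (-1)^seq_along(sym8_dec_lo)

circ_xcorr_ <- function(s, h) {
  hp <- c(h, numeric(length(s) - length(h)))
  Re(stats::fft(stats::fft(s) * Conj(stats::fft(hp)), inverse = TRUE)) /
    length(s)
}

circ_conv_ <- function(s, h) {
  hp <- c(h, numeric(length(s) - length(h)))
  Re(stats::fft(stats::fft(s) * stats::fft(hp), inverse = TRUE)) / length(s)
}

dwt_step_ <- function(s) {
  even <- seq(1L, length(s), 2L)
  list(a = circ_xcorr_(s, sym8_dec_lo)[even],
       d = circ_xcorr_(s, sym8_dec_hi)[even])
}

idwt_step_ <- function(a, d) {
  N <- 2L * length(a)
  ua <- numeric(N); ua[seq(1L, N, 2L)] <- a
  ud <- numeric(N); ud[seq(1L, N, 2L)] <- d
  circ_conv_(ua, sym8_dec_lo) + circ_conv_(ud, sym8_dec_hi)
}

# Multi-level decomposition: returns approximation `a` at the deepest level
# and details d[[1]] (finest) .. d[[levels]] (coarsest).
dwt_sym8_ <- function(x, levels) {
  if (length(x) %% 2^levels != 0)
    stop_("length_error", "signal length must be a multiple of 2^levels")
  if (length(x) / 2^levels < length(sym8_dec_lo))
    stop_("length_error",
          "signal too short for %d levels (needs >= %d samples)",
          levels, length(sym8_dec_lo) * 2^levels)
  d <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step_(a)
    d[[l]] <- s$d
    a <- s$a
  }
  list(a = a, d = d)
}

idwt_sym8_ <- function(w) {
  a <- w$a
  for (l in rev(seq_along(w$d))) a <- idwt_step_(a, w$d[[l]])
  a
}

# Symmetric (whole-point reflection) extension of x to length m, tiling
# x, rev(x), x, ... as needed.
reflect_pad_ <- function(x, m) {
  n <- length(x)
  if (m <= n) return(x[seq_len(m)])
  tile <- c(x, rev(x))
  rep_len(tile, m)
}
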