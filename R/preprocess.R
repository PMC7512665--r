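#' Wavelet denoising of an ECG record
#'
#' Removes high-frequency interference and baseline drift with a symlet-8
#' discrete wavelet transform: the approximation band at the deepest level is
#' zeroed (at 1000 Hz with 8 levels this band covers roughly 0-2 Hz, where
#' baseline wander lives), and the finest detail bands are soft-thresholded
#' with the universal threshold \eqn{\sigma \sqrt{2 \log N}}, where
#' \eqn{\sigma} is the median-absolute-deviation estimate from the finest
#' band. The signal is padded by symmetric reflection to a transform-friendly
#' length and trimmed back, so output length equals input length.
#'
#' @param ecg An [ecg_record()].
#' @param levels Decomposition depth; the zeroed approximation band spans
#'   `[0, fs / 2^(levels + 1)]` Hz.
#' @param detail_levels How many of the finest detail bands to
#'   soft-threshold.
#' @return An [ecg_record()] with denoised samples; metadata (including any
#'   ground-truth peaks) is preserved.
#' @export
denoise_ecg <- function(ecg, levels = 8L, detail_levels = 2L) {
  if (!inherits(ecg, "ecg_record"))
    stop_("invalid_parameter", "ecg must be an ecg_record")
  x <- ecg$samples
  n <- length(x)
  if (n < 2^levels)
    stop_("length_error", "record of %d samples is shorter than 2^%d",
          n, levels)
  block <- 2^levels
  m <- max(ceiling(n / block) * block, length(sym8_dec_lo) * block)
  xp <- reflect_pad_(x, m)
  w <- dwt_sym8_(xp, levels)
  w$a <- numeric(length(w$a))
  sigma <- stats::mad(w$d[[1]])
  thr <- sigma * sqrt(2 * log(n))
  for (l in seq_len(min(detail_levels, levels))) {
    dl <- w$d[[l]]
    w$d[[l]] <- sign(dl) * pmax(abs(dl) - thr, 0)
  }
  y <- idwt_sym8_(w)[seq_len(n)]
  ecg_record(y, ecg$sampling_rate, subject_id = ecg$subject_id,
             state = ecg$state, true_peaks = ecg$true_peaks)
}

# Trailing-window running maximum, window w, expanding at the start.
# Classic two-pass block algorithm (prefix/suffix cummax with block size w).
running_max_ <- function(x, w) {
  n <- length(x)
  if (w >= n) return(cummax(x))
  nb <- ceiling(n / w)
  pad <- nb * w - n
  xp <- c(x, rep(-Inf, pad))
  P <- numeric(nb * w); S <- numeric(nb * w)
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * w + 1L):(b * w)
    P[idx] <- cummax(xp[idx])
    S[idx] <- rev(cummax(rev(xp[idx])))
  }
  i <- seq_len(n)
  j <- i - w + 1L
  out <- P[i]
  ok <- j >= 1L
  out[ok] <- pmax(out[ok], S[j[ok]])
  out
}

#' Difference-threshold R-peak detection
#'
#' Detects R peaks on a (denoised) ECG by thresholding the first difference
#' of the trace: the adaptive threshold is `threshold_frac` times the running
#' maximum of the absolute difference over a trailing `window_s`-second
#' window, floored at 30% of the record-wide maximal absolute difference
#' (so quiescent stretches before the first beat cannot fire on noise).
#' Each threshold crossing opens a candidate beat; the peak is
#' refined to the local signal maximum within `refine_ms` of the crossing,
#' and candidates within `refractory_ms` of the previous accepted peak are
#' discarded. The first and last `edge_s` seconds are ignored.
#'
#' @param ecg An [ecg_record()] (denoise first for noisy data).
#' @param threshold_frac Fraction of the running difference maximum.
#' @param window_s Trailing window (s) for the running maximum.
#' @param refractory_ms Minimum peak separation (ms).
#' @param refine_ms Half-width (ms) of the local-maximum refinement window.
#' @param edge_s Edge margin (s) excluded from detection.
#' @return Strictly increasing integer sample indices of detected R peaks;
#'   empty when no threshold crossing exists (for example a flat record).
#' @export
detect_r_peaks <- function(ecg, threshold_frac = 0.6, window_s = 2,
                           refractory_ms = 200, refine_ms = 50,
                           edge_s = 0.5) {
  if (!inherits(ecg, "ecg_record"))
    stop_("invalid_parameter", "ecg must be an ecg_record")
  x <- ecg$samples
  if (any(!is.finite(x))) stop_("data_error", "non-finite samples")
  fs <- ecg$sampling_rate
  n <- length(x)
  d <- diff(x)
  a <- abs(d)
  thr <- threshold_frac * running_max_(a, max(2L, round(window_s * fs)))
  # absolute gate: before the first beat the trailing maximum reflects noise
  # only, so the adaptive threshold alone would fire on it; real upstrokes
  # reach a fixed fraction of the record's steepest slope
  thr <- pmax(thr, 0.3 * max(a))
  above <- d > thr & thr > 0
  # rising edges of the above-threshold mask
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  edge <- round(edge_s * fs)
  crossings <- crossings[crossings > edge & crossings <= n - edge]
  if (length(crossings) == 0) return(integer(0))

  half <- round(refine_ms * fs / 1000)
  refract <- refractory_ms * fs / 1000
  peaks <- integer(0)
  last <- -Inf
  for (cr in crossings) {
    if (cr - last < refract) next
    lo <- max(1L, cr - half)
    hi <- min(n, cr + half)
    p <- lo + which.max(x[lo:hi]) - 1L
    if (length(peaks) && p - last < refract) next
    if (length(peaks) == 0 || p > last) {
      peaks <- c(peaks, p)
      last <- p
    }
  }
  peaks
}

#' Extract RR intervals from R-peak indices
#'
#' `intervals[i] = (peaks[i + 1] - peaks[i]) / sampling_rate * 1000` ms.
#'
#' @param peaks Strictly increasing integer sample indices, length >= 2.
#' @param sampling_rate Sampling rate (Hz).
#' @param subject_id,state,gender Labels forwarded to the result.
#' @return An [rri_series()] of length `length(peaks) - 1`.
#' @export
#' @examples
#' extract_rri(c(0, 1000, 2000), 1000)  # 1000 ms, 1000 ms
extract_rri <- function(peaks, sampling_rate, subject_id = NA_character_,
                        state = NA_character_, gender = NA_character_) {
  if (length(peaks) < 2)
    stop_("length_error", "need at least 2 peaks to form an interval")
  if (any(diff(peaks) <= 0))
    stop_("ordering_error", "peak indices must be strictly increasing")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_("invalid_parameter", "sampling_rate must be > 0")
  rri_series(diff(peaks) / sampling_rate * 1000,
             subject_id = subject_id, state = state, gender = gender)
}

#' Artifact-rejection rules for RR-interval series
#'
#' An automated surrogate for manual error-beat editing: intervals outside
#' physiological bounds, or deviating from the local running median by more
#' than a relative jump, are flagged.
#'
#' @param min_ms,max_ms Physiological bounds (ms), `0 < min_ms < max_ms`.
#' @param max_rel_jump Maximal allowed relative deviation from the running
#'   median (window 11), as a fraction.
#' @param action `"drop"` removes flagged intervals; `"merge"` adds each
#'   flagged interval to its successor (predecessor for the last interval),
#'   the usual repair for split beats.
#' @return An object of class `clean_rules`.
#' @export
clean_rules <- function(min_ms = 250, max_ms = 2000, max_rel_jump = 0.3,
                        action = c("drop", "merge")) {
  action <- match.arg(action)
  if (!(min_ms > 0 && min_ms < max_ms))
    stop_("invalid_parameter", "need 0 < min_ms < max_ms")
  if (max_rel_jump <= 0) stop_("invalid_parameter", "max_rel_jump must be > 0")
  structure(list(min_ms = min_ms, max_ms = max_ms,
                 max_rel_jump = max_rel_jump, action = action),
            class = "clean_rules")
}

#' Clean an RR-interval series
#'
#' Applies [clean_rules()]: an interval is flagged when it falls outside
#' `[min_ms, max_ms]` or differs from the running median (window 11, median
#' end-rule) by more than `max_rel_jump` relatively. Flagged intervals are
#' dropped or merged according to the rules; every decision is listed in the
#' rejection report so the automated step can be audited.
#'
#' @param rri An [rri_series()] or positive numeric vector (ms).
#' @param rules A [clean_rules()].
#' @return A list: `rri` (the cleaned [rri_series()]) and `report` (tibble
#'   with columns `index`, `value_ms`, `rule`; empty when nothing fired).
#' @export
clean_rri <- function(rri, rules = clean_rules()) {
  if (!inherits(rules, "clean_rules"))
    stop_("invalid_parameter", "rules must be a clean_rules object")
  x <- as.numeric(rri)
  if (length(x) == 0) stop_("length_error", "empty series")
  med <- if (length(x) >= 3) {
    k <- min(11L, if (length(x) %% 2L) length(x) else length(x) - 1L)
    stats::runmed(x, k = k, endrule = "median")
  } else rep(stats::median(x), length(x))
  out_of_bounds <- x < rules$min_ms | x > rules$max_ms
  jump <- abs(x - med) / med > rules$max_rel_jump
  flagged <- which(out_of_bounds | jump)
  rule <- paste0(ifelse(out_of_bounds[flagged], "bounds", ""),
                 ifelse(out_of_bounds[flagged] & jump[flagged], ",", ""),
                 ifelse(jump[flagged], "rel_jump", ""))
  report <- tibble::tibble(index = as.integer(flagged),
                           value_ms = x[flagged], rule = rule)
  if (length(flagged) == length(x))
    stop_("empty_output_error", "all %d intervals were rejected", length(x))
  if (length(flagged) == 0) {
    cleaned <- x
  } else if (rules$action == "drop") {
    cleaned <- x[-flagged]
  } else {
    cleaned <- x
    for (i in rev(flagged)) {       # merge into successor (predecessor if last)
      if (i < length(cleaned)) {
        cleaned[i + 1L] <- cleaned[i + 1L] + cleaned[i]
      } else {
        cleaned[i - 1L] <- cleaned[i - 1L] + cleaned[i]
      }
      cleaned <- cleaned[-i]
    }
  }
  list(rri = rri_series(cleaned,
                        subject_id = attr(rri, "subject_id") %||% NA_character_,
                        state = attr(rri, "state") %||% NA_character_,
                        gender = attr(rri, "gender") %||% NA_character_),
       report = report)
}

#' End-to-end ECG to clean RR intervals
#'
#' Convenience chain: [denoise_ecg()], [detect_r_peaks()], [extract_rri()],
#' [clean_rri()].
#'
#' @param ecg An [ecg_record()].
#' @param rules A [clean_rules()].
#' @param ... Passed to [detect_r_peaks()].
#' @return As [clean_rri()]: list with `rri` and `report`.
#' @export
preprocess_ecg <- function(ecg, rules = clean_rules(), ...) {
  den <- denoise_ecg(ecg)
  peaks <- detect_r_peaks(den, ...)
  rri <- extract_rri(peaks, ecg$sampling_rate, subject_id = ecg$subject_id,
                     state = ecg$state)
  clean_rri(rri, rules)
}
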