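#' Tie-breaking policy for ordinal symbolization
#'
#' Equal values in a window have no unique rank order. Two resolutions are
#' supported: `"noise"` adds an infinitesimal random perturbation (amplitude
#' expressed as a fraction of the series SD) before ranking, which is the usual
#' recommendation for discretized data such as integer-millisecond RR
#' intervals; `"stable-rank"` ranks tied values by time position (earlier
#' position ranks lower), which is deterministic and bit-exact.
#'
#' @param mode `"noise"` or `"stable-rank"`.
#' @param noise_amplitude Perturbation SD as a fraction of the series SD
#'   (ignored for `"stable-rank"`). Must be positive in noise mode.
#' @param seed Integer seed for the perturbation, so noise mode is
#'   reproducible.
#' @return An object of class `tie_policy`.
#' @export
#' @examples
#' tie_policy("stable-rank")
tie_policy <- function(mode = c("noise", "stable-rank"),
                       noise_amplitude = 1e-6, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "noise") {
    if (!is.numeric(noise_amplitude) || length(noise_amplitude) != 1 ||
        !is.finite(noise_amplitude) || noise_amplitude <= 0)
      stop_("invalid_parameter", "noise_amplitude must be a positive number")
  }
  structure(list(mode = mode, noise_amplitude = noise_amplitude,
                 seed = as.integer(seed)),
            class = "tie_policy")
}

#' @export
print.tie_policy <- function(x, ...) {
  cat("<tie_policy> mode:", x$mode,
      if (x$mode == "noise")
        sprintf("(amplitude %g x series SD, seed %d)", x$noise_amplitude, x$seed),
      "\n")
  invisible(x)
}

# Apply a tie policy to a numeric vector. Returns a vector whose strict
# ordering encodes the policy's resolution of ties.
resolve_ties_ <- function(x, policy) {
  if (policy$mode == "stable-rank") return(x)
  s <- sd(x)
  scale <- if (is.finite(s) && s > 0) s else 1
  x + with_seed_(policy$seed, rnorm(length(x), 0, policy$noise_amplitude * scale))
}

# All permutations of 1..D in lexicographic order, one per row.
perms_ <- function(D) {
  if (D == 1L) return(matrix(1L, 1L, 1L))
  p <- perms_(D - 1L)
  do.call(rbind, lapply(seq_len(D), function(k) {
    cbind(rep(k, nrow(p)), p + (p >= k))
  }))
}

#' Ordinal pattern labels for an embedding dimension
#'
#' Labels follow the time-position convention: the label lists the 1-based
#' time positions of the window elements in ascending value order, so `"312"`
#' means the third element is smallest, then the first, then the second.
#'
#' @param D Embedding dimension (number of values per window), `D >= 2`.
#' @return Character vector of the `factorial(D)` labels in lexicographic
#'   order.
#' @export
#' @examples
#' pattern_labels(3)
pattern_labels <- function(D) {
  D <- check_dimension_(D)
  apply(perms_(D), 1L, paste0, collapse = "")
}

check_dimension_ <- function(D) {
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D < 2 || D != round(D))
    stop_("invalid_parameter", "D must be a single integer >= 2")
  as.integer(D)
}

# Cache of {labels, lehmer -> lexicographic index} per dimension.
pattern_tables_ <- local({
  cache <- list()
  function(D) {
    key <- as.character(D)
    if (!is.null(cache[[key]])) return(cache[[key]])
    P <- perms_(D)
    labels <- apply(P, 1L, paste0, collapse = "")
    fact <- rev(cumprod(c(1, seq_len(D - 1))))  # (D-1)!, ..., 1!, 0!
    lehmer <- integer(nrow(P))
    for (r in seq_len(nrow(P))) {
      o <- P[r, ]
      w <- integer(D)
      w[o] <- seq_len(D)             # representative window with this pattern
      cj <- vapply(seq_len(D), function(j) sum(w[-seq_len(j)] < w[j]), 0L)
      lehmer[r] <- sum(cj * fact) + 1L
    }
    map <- integer(length(labels))
    map[lehmer] <- seq_along(labels) # lehmer index -> lexicographic index
    tab <- list(labels = labels, lehmer_to_lex = map, fact = fact)
    cache[[key]] <<- tab
    tab
  }
})

# Vectorized window coder: rows of `W` (n x D) are embedding windows; returns
# the lexicographic pattern index of each row via its Lehmer code
# c_j = #{k > j : x_k < x_j}. Ties resolve to the stable (earlier-is-lower)
# order; callers wanting noise resolution perturb the series first.
ordinal_codes_ <- function(W) {
  D <- ncol(W)
  tab <- pattern_tables_(D)
  code <- rep.int(0, nrow(W))
  for (j in seq_len(D - 1L)) {
    cj <- rep.int(0L, nrow(W))
    for (k in (j + 1L):D) cj <- cj + (W[, k] < W[, j])
    code <- code + cj * tab$fact[j]
  }
  tab$lehmer_to_lex[code + 1L]
}

embed_windows_ <- function(x, D, tau) {
  m <- length(x) - (D - 1L) * tau
  W <- matrix(0, nrow = m, ncol = D)
  for (j in seq_len(D)) W[, j] <- x[seq_len(m) + (j - 1L) * tau]
  W
}

#' Symbolize a single embedding window
#'
#' Maps `D` values to their ordinal pattern: the permutation of time positions
#' `1..D` at which the values appear in ascending order.
#'
#' @param window Numeric vector of length `D >= 2`; all values finite.
#' @param policy A [tie_policy()].
#' @return The pattern label, e.g. `"312"` for a window whose third value is
#'   the smallest.
#' @export
#' @examples
#' ordinal_pattern(c(3, 5, 2))  # "312"
#' ordinal_pattern(c(1, 4, 8))  # "123"
ordinal_pattern <- function(window, policy = tie_policy()) {
  if (!is.numeric(window) || length(window) < 2)
    stop_("shape_error", "window must be a numeric vector of length D >= 2")
  if (any(!is.finite(window)))
    stop_("data_error", "window contains non-finite values")
  stopifnot(inherits(policy, "tie_policy"))
  w <- resolve_ties_(window, policy)
  paste0(order(w), collapse = "")
}

#' Ordinal-pattern distribution of a time series
#'
#' Slides a window of `D` values at index spacing `tau` along the series and
#' counts each of the `factorial(D)` ordinal patterns. The number of windows
#' is `N - (D - 1) * tau`.
#'
#' @param series Numeric vector, length `N > (D - 1) * tau`; all values
#'   finite. A reliable frequency estimate requires `N >> factorial(D)`; a
#'   warning is emitted when `N < 5 * factorial(D)`.
#' @param D Embedding dimension.
#' @param tau Embedding delay (index units), `tau >= 1`.
#' @param policy A [tie_policy()].
#' @return An object of class `ordinal_distribution` with elements `D`, `tau`,
#'   `counts` (named integer vector over all pattern labels), `n_windows`.
#' @export
#' @examples
#' d <- pattern_distribution(c(3, 5, 2, 1, 4, 8, 5, 6), D = 3, tau = 1)
#' d$counts                    # each of the six patterns observed once
#' permutation_entropy(d)      # log(6) = 1.7918
pattern_distribution <- function(series, D = 3L, tau = 1L,
                                 policy = tie_policy()) {
  D <- check_dimension_(D)
  if (!is.numeric(tau) || length(tau) != 1 || tau < 1 || tau != round(tau))
    stop_("invalid_parameter", "tau must be a single integer >= 1")
  tau <- as.integer(tau)
  if (!is.numeric(series)) stop_("data_error", "series must be numeric")
  if (any(!is.finite(series)))
    stop_("data_error", "series contains non-finite values")
  N <- length(series)
  if (N <= (D - 1L) * tau)
    stop_("length_error",
          "series of length %d admits no window with D = %d, tau = %d",
          N, D, tau)
  if (N < 5L * factorial(D))
    warning(sprintf(paste0("series length %d is short relative to the %d-",
                           "pattern alphabet; frequencies will be noisy"),
                    N, factorial(D)), call. = FALSE)
  x <- resolve_ties_(as.numeric(series), policy)
  idx <- ordinal_codes_(embed_windows_(x, D, tau))
  tab <- pattern_tables_(D)
  counts <- tabulate(idx, nbins = length(tab$labels))
  names(counts) <- tab$labels
  structure(list(D = D, tau = tau, counts = counts,
                 n_windows = N - (D - 1L) * tau),
            class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("<ordinal_distribution> D = %d, tau = %d, %d windows\n",
              x$D, x$tau, x$n_windows))
  nz <- x$counts[x$counts > 0]
  cat(sprintf("  %d of %d patterns observed; PE = %.4f, PME = %.4f nats\n",
              length(nz), length(x$counts),
              permutation_entropy(x), permutation_min_entropy(x)))
  invisible(x)
}

check_dist_ <- function(dist) {
  if (!inherits(dist, "ordinal_distribution"))
    stop_("invalid_parameter", "expected an ordinal_distribution")
  if (dist$n_windows <= 0 || sum(dist$counts) <= 0)
    stop_("domain_error", "empty ordinal distribution")
}

#' Permutation entropy (nats)
#'
#' Shannon entropy \eqn{-\sum_\pi p(\pi) \log p(\pi)} of the ordinal-pattern
#' relative frequencies, with the convention \eqn{0 \log 0 = 0}. Bounded by
#' `[0, log(factorial(D))]`; maximal for uniform pattern usage (white noise).
#'
#' @param dist An `ordinal_distribution` from [pattern_distribution()].
#' @return Entropy in nats.
#' @export
permutation_entropy <- function(dist) {
  check_dist_(dist)
  p <- dist$counts / sum(dist$counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Permutation min-entropy (nats)
#'
#' The order-infinity Renyi entropy of the ordinal-pattern distribution,
#' \eqn{-\log \max_\pi p(\pi)}. Depends only on the most probable pattern and
#' never exceeds the permutation entropy; bounded by
#' `[0, log(factorial(D))]`.
#'
#' @inheritParams permutation_entropy
#' @return Min-entropy in nats.
#' @export
permutation_min_entropy <- function(dist) {
  check_dist_(dist)
  -log(max(dist$counts) / sum(dist$counts))
}

#' Convert a pattern label to its rank vector (and back)
#'
#' The package's canonical label lists time positions in ascending value
#' order (`"312"`: value at position 3 is smallest). Other libraries encode
#' the same pattern as a rank vector `r`, where `r[i]` is the ascending rank
#' of the value at time position `i`. The two are inverse permutations.
#'
#' @param label Pattern label, a permutation of the digits `1..D` (`D <= 9`).
#' @return `pattern_to_ranks()`: integer rank vector. `ranks_to_pattern()`:
#'   the label.
#' @export
#' @examples
#' pattern_to_ranks("312")        # c(2, 3, 1)
#' ranks_to_pattern(c(2, 3, 1))   # "312"
pattern_to_ranks <- function(label) {
  o <- as.integer(strsplit(label, "")[[1]])
  if (!setequal(o, seq_along(o)))
    stop_("invalid_parameter", "label must be a permutation of 1..D")
  r <- integer(length(o))
  r[o] <- seq_along(o)
  r
}

#' @param ranks Integer rank vector, a permutation of `1..D`.
#' @rdname pattern_to_ranks
#' @export
ranks_to_pattern <- function(ranks) {
  ranks <- as.integer(ranks)
  if (!setequal(ranks, seq_along(ranks)))
    stop_("invalid_parameter", "ranks must be a permutation of 1..D")
  paste0(order(ranks), collapse = "")
}

#' Entropy sweep over embedding dimensions and delays
#'
#' Computes permutation entropy and permutation min-entropy for every series
#' in a collection over a grid of embedding dimensions and delays. The grid
#' default (`D` in {3, 4}, `tau` in 1..10) suits RR-interval series of a few
#' hundred beats.
#'
#' @param series_collection An `rri_cohort`, a list of [rri_series()], or a
#'   single numeric series.
#' @param dimensions Integer vector of embedding dimensions.
#' @param delays Integer vector of embedding delays.
#' @param policy A [tie_policy()].
#' @return A tibble with one row per (series, D, tau): columns `subject_id`,
#'   `state`, `gender`, `D`, `tau`, `n_windows`, `pe_nats`, `pme_nats`.
#'   Series too short for a cell are kept as rows with `n_windows = 0` and
#'   `NA` entropies rather than dropped.
#' @export
#' @examples
#' s <- generate_rri(state_model("neutral", phi = 0.5), n = 350, seed = 1)
#' entropy_sweep(list(s), dimensions = 3, delays = 1:2)
entropy_sweep <- function(series_collection, dimensions = c(3L, 4L),
                          delays = 1:10, policy = tie_policy()) {
  if (inherits(series_collection, "rri_cohort"))
    series_collection <- series_collection$series
  if (is.numeric(series_collection))
    series_collection <- list(series_collection)
  if (!is.list(series_collection) || length(series_collection) == 0)
    stop_("input_error", "series_collection must be a non-empty list of series")
  if (length(dimensions) == 0 || length(delays) == 0)
    stop_("input_error", "dimensions and delays must be non-empty")
  dimensions <- vapply(dimensions, check_dimension_, 0L)
  delays <- as.integer(delays)
  if (any(delays < 1)) stop_("invalid_parameter", "delays must be >= 1")

  grid <- expand.grid(tau = delays, D = dimensions,
                      s = seq_along(series_collection))
  n <- nrow(grid)
  subject_id <- state <- gender <- character(n)
  n_windows <- integer(n)
  pe <- pme <- numeric(n)
  for (i in seq_len(n)) {
    D <- grid$D[i]; tau <- grid$tau[i]
    ser <- series_collection[[grid$s[i]]]
    x <- as.numeric(ser)
    subject_id[i] <- attr(ser, "subject_id") %||% NA_character_
    state[i] <- attr(ser, "state") %||% NA_character_
    gender[i] <- attr(ser, "gender") %||% NA_character_
    if (length(x) <= (D - 1L) * tau) {
      n_windows[i] <- 0L
      pe[i] <- pme[i] <- NA_real_
    } else {
      d <- pattern_distribution(x, D, tau, policy)
      n_windows[i] <- d$n_windows
      pe[i] <- permutation_entropy(d)
      pme[i] <- permutation_min_entropy(d)
    }
  }
  tibble::tibble(subject_id = subject_id, state = state, gender = gender,
                 D = as.integer(grid$D), tau = as.integer(grid$tau),
                 n_windows = n_windows, pe_nats = pe, pme_nats = pme)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
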