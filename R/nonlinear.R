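#' Ordinal pattern distribution of a time series
#'
#' Delay-embeds the series into vectors of length `m` with delay `tau`,
#' replaces each vector by the permutation of its indices under ascending
#' sort, and returns the relative frequency of each observed permutation.
#' Ties are broken stably: among equal values the earlier index sorts first,
#' so a constant run counts as the ascending pattern. With `n` samples there
#' are `M = n - (m - 1) * tau` embedded vectors and at most `m!` patterns.
#'
#' @param x Numeric vector, length at least `(m - 1) * tau + 1`.
#' @param m Embedding dimension (integer >= 2, default 3).
#' @param tau Delay (integer >= 1, default 1).
#' @return Named numeric vector of probabilities (summing to 1); names are the
#'   1-based index orders of the sorted vector, joined by `-` (for `m = 2`,
#'   `"1-2"` is ascending and `"2-1"` descending).
#' @examples
#' ordinal_pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), m = 2)
#' @export
ordinal_pattern_distribution <- function(x, m = 3, tau = 1) {
  x <- as.numeric(x)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2L) stop("m must be >= 2")
  if (tau < 1L) stop("tau must be >= 1")
  n <- length(x)
  M <- n - (m - 1L) * tau
  if (M < 1L) stop(sprintf("series too short: need at least %d samples for m=%d, tau=%d",
                           (m - 1L) * tau + 1L, m, tau))
  E <- vapply(seq_len(m), function(k) x[seq_len(M) + (k - 1L) * tau],
              numeric(M))
  if (M == 1L) E <- matrix(E, nrow = 1L)
  # rank of column k = #(strictly smaller) + #(equal with smaller index)
  ranks <- matrix(0L, nrow = M, ncol = m)
  for (k in seq_len(m)) {
    for (l in seq_len(m)) {
      if (l == k) next
      if (l < k) ranks[, k] <- ranks[, k] + (E[, l] <= E[, k])
      else       ranks[, k] <- ranks[, k] + (E[, l] <  E[, k])
    }
  }
  code <- as.vector(ranks %*% m^(seq_len(m) - 1L))
  tab <- table(code)
  probs <- as.numeric(tab) / M
  names(probs) <- vapply(as.integer(names(tab)), function(cd) {
    r <- integer(m)
    for (k in seq_len(m)) { r[k] <- cd %% m; cd <- cd %/% m }
    ord <- integer(m)
    ord[r + 1L] <- seq_len(m)    # element k occupies sorted position r[k]+1
    paste(ord, collapse = "-")
  }, character(1))
  probs
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the ordinal pattern distribution:
#' `H = -sum(p * ln p)` with `0 * ln 0 := 0`. Ranges from 0 for a strictly
#' monotone series to `ln(m!)` when all patterns are equally likely;
#' `normalized = TRUE` divides by `ln(m!)`. Low values indicate regular,
#' predictable dynamics; epileptic discharges typically lower the value
#' relative to background EEG.
#'
#' @inheritParams ordinal_pattern_distribution
#' @param normalized Divide by `ln(m!)` so the result lies in `[0, 1]`
#'   (default FALSE; the raw value in nats is emitted).
#' @return Permutation entropy in nats (or normalized, dimensionless).
#' @examples
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), m = 2)  # ~0.6365
#' @export
permutation_entropy <- function(x, m = 3, tau = 1, normalized = FALSE) {
  p <- ordinal_pattern_distribution(x, m, tau)
  p <- p[p > 0]
  h <- -sum(p * log(p)) + 0   # + 0 avoids signed zero for one-pattern series
  if (isTRUE(normalized)) h <- h / log(factorial(m))
  h
}

#' Normalized curve length of one decimated subsequence
#'
#' For scale `k` and offset `m_start` in `1..k`, the subsequence
#' `x(m), x(m + k), x(m + 2k), ...` has normalized length
#' `L_m(k) = (1/k) * sum(|successive differences|) * (N - 1) / (floor((N - m)/k) * k)`
#' (1-based indexing). Subsequences with fewer than two points are excluded
#' from averaging (returns `NA`).
#'
#' @param x Numeric vector of length `N`.
#' @param k Scale factor (integer >= 1).
#' @param m_start Offset, `1 <= m_start <= k`.
#' @return The normalized length, or `NA_real_` when the subsequence has
#'   fewer than two points.
#' @export
curve_length_at_scale <- function(x, k, m_start) {
  x <- as.numeric(x)
  N <- length(x)
  k <- as.integer(k); m_start <- as.integer(m_start)
  if (k < 1L) stop("k must be >= 1")
  if (m_start < 1L || m_start > k) stop("m_start must be in 1..k")
  nseg <- (N - m_start) %/% k
  if (nseg < 1L) return(NA_real_)
  idx <- m_start + (0:nseg) * k
  sum(abs(diff(x[idx]))) * (N - 1) / (nseg * k) / k
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a time series from the scaling of mean
#' normalized curve length with scale: `ln<L(k)>` is regressed on `ln k` by
#' unweighted ordinary least squares over `k = 1..k_max`, and the estimate is
#' the negated slope. Roughly 1 for smooth curves and 2 for white noise; lower
#' values indicate reduced signal complexity, as during ictal synchronous
#' discharges.
#'
#' @param x Numeric vector with `length(x) >= 2 * k_max`.
#' @param k_max Maximum scale factor (integer >= 2, default 10).
#' @return The dimension estimate. A constant signal (all curve lengths zero)
#'   returns 0 with a warning rather than erroring.
#' @examples
#' higuchi_fd(seq_len(1024))  # ~1 for a straight line
#' @export
higuchi_fd <- function(x, k_max = 10) {
  x <- as.numeric(x)
  k_max <- as.integer(k_max)
  if (k_max < 2L) stop("k_max must be >= 2")
  if (length(x) < 2L * k_max) stop("need length(x) >= 2 * k_max")
  Lk <- vapply(seq_len(k_max), function(k) {
    lm_vals <- vapply(seq_len(k), function(m) curve_length_at_scale(x, k, m),
                      numeric(1))
    mean(lm_vals, na.rm = TRUE)
  }, numeric(1))
  if (any(Lk <= 0)) {
    warning("zero curve length (constant signal); returning 0")
    return(0)
  }
  fit <- stats::lm.fit(cbind(1, log(seq_len(k_max))), log(Lk))
  -unname(fit$coefficients[2])
}
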