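#' Min-max normalize a vector with clipping
#'
#' Maps values to `[0, 1]` by `(v - min) / (max - min)` using externally
#' supplied bounds (typically fitted on training-fold windows only, so test
#' values can fall outside and are clipped to `[0, 1]`). Degenerate bounds
#' (`max <= min`) map everything to 0.
#'
#' @param v Numeric vector.
#' @param bounds Length-2 numeric `(min, max)`.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_sequence <- function(v, bounds) {
  stopifnot(length(bounds) == 2L)
  lo <- bounds[1]; hi <- bounds[2]
  if (!(hi > lo)) return(rep(0, length(v)))
  pmin(pmax((v - lo) / (hi - lo), 0), 1)
}

#' Dynamic feature increment of a normalized feature sequence
#'
#' For a temporally ordered matrix of normalized features from a single
#' recording, the dynamic feature increment at window `t >= 2` is the sum
#' over features of the absolute first difference,
#' `DFI_t = sum_f |norm_f(t) - norm_f(t-1)|` (convention `"sum_abs"`), which
#' captures how sharply the feature profile moves between adjacent windows;
#' the first window of each recording has no predecessor and gets 0. The
#' alternative reading `"abs_sum"` (`|sum_f delta_f|`) is available behind the
#' `convention` switch. With four features each in `[0, 1]`, the value lies
#' in `[0, 4]`.
#'
#' @param norm_features Numeric matrix (rows = windows in temporal order,
#'   columns = normalized features in `[0, 1]`).
#' @param convention `"sum_abs"` (default: per-feature absolute difference,
#'   then sum) or `"abs_sum"` (sum the signed differences, then absolute).
#' @return Numeric vector of per-window DFI values (first element 0).
#' @examples
#' m <- cbind(c(0, 0.5, 0.5), c(1, 1, 0.2))
#' dfi(m)  # 0, 0.5, 0.8
#' @export
dfi <- function(norm_features, convention = c("sum_abs", "abs_sum")) {
  convention <- match.arg(convention)
  norm_features <- as.matrix(norm_features)
  n <- nrow(norm_features)
  if (n < 1L) stop("need at least one window")
  if (n == 1L) return(0)
  d <- diff(norm_features)
  inc <- if (convention == "sum_abs") rowSums(abs(d)) else abs(rowSums(d))
  c(0, inc)
}
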