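#' Extract the four base features for every window of one or more recordings
#'
#' Segments each recording into overlapping windows and computes, per window,
#' the spike-wave energy (`SpikeE`), sharp-wave energy (`SharpE`), Higuchi
#' fractal dimension (`HFD`) and permutation entropy (`PE`). The fifth
#' feature, the dynamic feature increment (`DFI`), depends on normalization
#' bounds and is added separately by [add_dfi()] (inside cross-validation the
#' bounds must come from the training fold; see [run_task()]).
#'
#' @param recordings A single [recording()], a list of them, or a
#'   `synth_eeg` dataset from [generate_dataset()].
#' @param window_len,overlap Segmentation parameters passed to [segment()].
#' @param criteria Wave criteria from [wave_criteria()].
#' @param m,tau Permutation-entropy embedding dimension and delay.
#' @param k_max Higuchi maximum scale factor.
#' @param detect_negative Also detect downward transients (default FALSE).
#' @param pe_normalized Emit normalized permutation entropy (default FALSE).
#' @return data.frame with one row per window: `recording_id`, `window_index`,
#'   `start_sample`, `label`, `SpikeE`, `SharpE`, `HFD`, `PE`, `spike_count`,
#'   `sharp_count`.
#' @export
extract_features <- function(recordings, window_len = 256, overlap = 0.5,
                             criteria = wave_criteria(), m = 3, tau = 1,
                             k_max = 10, detect_negative = FALSE,
                             pe_normalized = FALSE) {
  if (inherits(recordings, "synth_eeg")) recordings <- recordings$recordings
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(rec) {
    w <- segment(rec, window_len = window_len, overlap = overlap)
    nw <- nrow(w$samples)
    if (nw == 0L) return(NULL)
    feats <- t(vapply(seq_len(nw), function(i) {
      xi <- w$samples[i, ]
      en <- wave_energy(xi, rec$fs, criteria, detect_negative)
      hfd <- suppressWarnings(higuchi_fd(xi, k_max = k_max))
      pe <- permutation_entropy(xi, m = m, tau = tau, normalized = pe_normalized)
      c(SpikeE = en$spike_energy, SharpE = en$sharp_energy,
        HFD = hfd, PE = pe,
        spike_count = en$spike_count, sharp_count = en$sharp_count)
    }, numeric(6)))
    cbind(w$meta, as.data.frame(feats))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Base feature column names
#' @return `c("SpikeE", "SharpE", "HFD", "PE")`
#' @export
base_feature_names <- function() c("SpikeE", "SharpE", "HFD", "PE")

#' Append the dynamic feature increment to a feature table
#'
#' Normalizes the four base features with the supplied (or self-fitted)
#' min-max bounds, then computes the per-window DFI within each recording in
#' `window_index` order. Differencing never crosses recording boundaries.
#'
#' @param features Feature table from [extract_features()].
#' @param bounds Named list of `(min, max)` pairs per base feature, e.g. from
#'   [fit_fold_scaler()]. `NULL` fits the bounds on `features` itself (do NOT
#'   do this on test-fold rows; use the training-fold scaler instead).
#' @param convention DFI convention, see [dfi()].
#' @return `features` with a `DFI` column appended.
#' @export
add_dfi <- function(features, bounds = NULL, convention = c("sum_abs", "abs_sum")) {
  convention <- match.arg(convention)
  fn <- base_feature_names()
  stopifnot(all(fn %in% names(features)))
  if (is.null(bounds)) {
    bounds <- lapply(features[fn], range)
    names(bounds) <- fn
  }
  norm <- vapply(fn, function(f) normalize_sequence(features[[f]], bounds[[f]]),
                 numeric(nrow(features)))
  if (nrow(features) == 1L) norm <- matrix(norm, nrow = 1L, dimnames = list(NULL, fn))
  features$DFI <- NA_real_
  for (rid in unique(features$recording_id)) {
    sel <- which(features$recording_id == rid)
    sel <- sel[order(features$window_index[sel])]
    features$DFI[sel] <- dfi(norm[sel, , drop = FALSE], convention = convention)
  }
  features
}

#' Per-class box-plot summary of the extracted features
#'
#' For each state label and feature, the quantities a box-and-whisker plot
#' displays: minimum, lower quartile, median, mean, upper quartile, maximum.
#' Useful for a priori checks of feature validity, e.g. that ictal windows
#' show higher wave energy and lower complexity than interictal ones.
#'
#' @param features Feature table from [extract_features()] (optionally with
#'   `DFI` added).
#' @param feature_cols Columns to summarize (default the base features plus
#'   `DFI` when present).
#' @return data.frame with columns `label`, `feature`, `min`, `q1`, `median`,
#'   `mean`, `q3`, `max`.
#' @export
feature_summary <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(c(base_feature_names(), "DFI"), names(features))
  }
  out <- expand.grid(label = unique(features$label), feature = feature_cols,
                     stringsAsFactors = FALSE)
  stats_m <- t(mapply(function(lab, f) {
    v <- features[[f]][features$label == lab]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    c(min = q[1], q1 = q[2], median = q[3], mean = mean(v), q3 = q[4], max = q[5])
  }, out$label, out$feature))
  cbind(out, as.data.frame(stats_m))
}
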