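#' Recording-stratified fold plan
#'
#' Assigns whole recordings to folds so that every window of a recording
#' shares its fold (no within-recording leakage) and each fold receives a
#' near-equal number of recordings of every class. Deterministic given the
#' seed.
#'
#' @param recordings One of: a data.frame with `recording_id` and `label`
#'   columns (duplicate rows, e.g. a window-level feature table, are
#'   deduplicated), a list of [recording()] objects, or a `synth_eeg` dataset.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the within-class shuffle.
#' @return An object of class `fold_plan`: data.frame with `recording_id`,
#'   `label`, `fold` plus attributes `n_folds` and `seed`.
#' @export
build_fold_plan <- function(recordings, n_folds = 10, seed = 1L) {
  if (inherits(recordings, "synth_eeg")) recordings <- recordings$recordings
  if (is.list(recordings) && !is.data.frame(recordings) &&
      all(vapply(recordings, inherits, logical(1), "eeg_recording"))) {
    recordings <- data.frame(
      recording_id = vapply(recordings, `[[`, character(1), "recording_id"),
      label = vapply(recordings, `[[`, character(1), "label"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(recordings),
            all(c("recording_id", "label") %in% names(recordings)))
  recs <- unique(recordings[, c("recording_id", "label")])
  if (anyDuplicated(recs$recording_id))
    stop("a recording_id appears with more than one label")
  n_folds <- as.integer(n_folds)
  counts <- table(recs$label)
  if (any(counts < n_folds))
    stop("every class needs at least n_folds recordings; short: ",
         paste(names(counts)[counts < n_folds], collapse = ", "))
  set.seed(seed)
  recs$fold <- NA_integer_
  for (lab in sort(unique(recs$label))) {
    sel <- which(recs$label == lab)
    sel <- sel[sample.int(length(sel))]
    recs$fold[sel] <- rep(seq_len(n_folds), length.out = length(sel))
  }
  structure(recs[order(recs$recording_id), ], n_folds = n_folds, seed = seed,
            class = c("fold_plan", "data.frame"))
}

#' Fit a min-max scaler on training-fold features
#'
#' Per-feature minimum and maximum computed from training rows only; applying
#' the scaler to held-out rows clips to `[0, 1]`, so no statistic of the test
#' fold ever enters the normalization. A zero-variance feature maps to all
#' zeros with a warning.
#'
#' @param train_features data.frame containing the feature columns.
#' @param feature_cols Columns to scale (default the four base features).
#' @return An object of class `fold_scaler`: named list of `(min, max)` pairs.
#' @export
fit_fold_scaler <- function(train_features, feature_cols = base_feature_names()) {
  stopifnot(nrow(train_features) > 0, all(feature_cols %in% names(train_features)))
  bounds <- lapply(train_features[feature_cols], range)
  degenerate <- vapply(bounds, function(b) !(b[2] > b[1]), logical(1))
  if (any(degenerate))
    warning("zero-variance feature(s) map to 0: ",
            paste(feature_cols[degenerate], collapse = ", "))
  structure(bounds, class = "fold_scaler")
}

#' Apply a fitted scaler to a feature table
#'
#' @param scaler A `fold_scaler` from [fit_fold_scaler()].
#' @param features data.frame with the scaler's feature columns.
#' @return Numeric matrix of normalized (clipped) features.
#' @export
apply_scaler <- function(scaler, features) {
  fn <- names(scaler)
  out <- vapply(fn, function(f) normalize_sequence(features[[f]], scaler[[f]]),
                numeric(nrow(features)))
  if (nrow(features) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, fn))
  out
}

.ratio0 <- function(num, den) {
  if (den == 0) { warning("0/0 metric ratio defined as 0"); return(0) }
  num / den
}

.binary_metrics <- function(tp, tn, fp, fn) {
  pre <- .ratio0(tp, tp + fp)
  sen <- .ratio0(tp, tp + fn)
  list(acc = .ratio0(tp + tn, tp + tn + fp + fn),
       spe = .ratio0(tn, tn + fp),
       sen = sen,
       pre = pre,
       f1 = if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen))
}

.default_positive <- function(lv) {
  hit <- lv[tolower(lv) %in% c("ictal", "seizure", "epileptic", "e")]
  if (length(hit) == 1L) hit else lv[length(lv)]
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, specificity, sensitivity, precision and F1 (harmonic mean of
#' precision and sensitivity). Binary tasks use the four cells directly with
#' the seizure/ictal class as positive; multiclass tasks are macro-averaged:
#' each metric is computed per class one-vs-rest and averaged with equal
#' class weight. Undefined 0/0 ratios are set to 0 with a warning.
#'
#' @param cm Square confusion matrix, rows = true classes, columns =
#'   predicted classes (same ordered names).
#' @param averaging `"auto"` (binary when two classes, else macro),
#'   `"binary"`, or `"macro"`.
#' @param positive Positive class for binary averaging; default picks the
#'   class named ictal/seizure/epileptic/E (case-insensitive), else the last.
#' @return Named list `acc`, `spe`, `sen`, `pre`, `f1`, `averaging`,
#'   `positive` of class `metric_set`.
#' @examples
#' cm <- matrix(c(90, 20, 10, 80), 2, dimnames = list(c("ictal", "other"),
#'                                                    c("ictal", "other")))
#' compute_metrics(cm)$acc  # 0.85
#' @export
compute_metrics <- function(cm, averaging = c("auto", "binary", "macro"),
                            positive = NULL) {
  averaging <- match.arg(averaging)
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), !is.null(rownames(cm)),
            identical(rownames(cm), colnames(cm)))
  lv <- rownames(cm)
  if (averaging == "auto") averaging <- if (length(lv) == 2L) "binary" else "macro"
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  if (averaging == "binary") {
    if (length(lv) != 2L) stop("binary averaging needs a 2x2 matrix")
    if (is.null(positive)) positive <- .default_positive(lv)
    neg <- setdiff(lv, positive)
    m <- .binary_metrics(tp = cm[positive, positive], tn = cm[neg, neg],
                         fp = cm[neg, positive], fn = cm[positive, neg])
  } else {
    per_class <- lapply(lv, function(cl) {
      tp <- cm[cl, cl]
      fn <- sum(cm[cl, ]) - tp
      fp <- sum(cm[, cl]) - tp
      tn <- total - tp - fn - fp
      .binary_metrics(tp, tn, fp, fn)
    })
    m <- lapply(c("acc", "spe", "sen", "pre", "f1"),
                function(k) mean(vapply(per_class, `[[`, numeric(1), k)))
    names(m) <- c("acc", "spe", "sen", "pre", "f1")
    positive <- NA_character_
  }
  structure(c(m, list(averaging = averaging, positive = positive)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("acc %.4f  pre %.4f  sen %.4f  f1 %.4f  spe %.4f  (%s)\n",
              x$acc, x$pre, x$sen, x$f1, x$spe, x$averaging))
  invisible(x)
}

# resolve "plf+ndf+dfi" / "all" to feature column names
resolve_subset <- function(subset) {
  if (identical(tolower(subset), "all")) subset <- "plf+ndf+dfi"
  fams <- strsplit(tolower(subset), "+", fixed = TRUE)[[1]]
  cols <- unlist(lapply(fams, function(f) switch(f,
    plf = c("SpikeE", "SharpE"),
    ndf = c("HFD", "PE"),
    dfi = "DFI",
    stop("unknown feature family '", f, "' (use plf, ndf, dfi)"))))
  if (length(cols) == 0L) stop("empty feature subset")
  unique(cols)
}

# normalized design matrices + DFI for one train/test split, leakage-safe
.prepare_split <- function(train, test, convention) {
  scaler <- suppressWarnings(fit_fold_scaler(train))
  prep <- function(df) {
    norm <- apply_scaler(scaler, df)
    df2 <- add_dfi(cbind(df[c("recording_id", "window_index", "label")],
                         as.data.frame(norm)),
                   bounds = lapply(names(scaler), function(f) c(0, 1)) |>
                     stats::setNames(names(scaler)),
                   convention = convention)
    # note: norm columns are already in [0,1]; identity bounds keep them as-is
    x <- cbind(norm, DFI = df2$DFI)
    x
  }
  list(train_x = prep(train), test_x = prep(test), scaler = scaler)
}

#' Run a classification task under recording-stratified cross-validation
#'
#' The full leakage-safe evaluation protocol: for each fold, a min-max scaler
#' is fitted on training-fold windows only and applied (with clipping) to the
#' test fold; the dynamic feature increment is computed from those normalized
#' features within each recording; the requested classifiers are trained on
#' each requested feature subset; metrics are the mean over the test folds
#' and confusion matrices are summed over folds.
#'
#' @param features Feature table from [extract_features()] (base features
#'   only; DFI is computed fold-locally inside this function).
#' @param plan A `fold_plan` from [build_fold_plan()].
#' @param classifiers Character vector among `"xgb"`, `"rf"`, `"svm"`,
#'   `"knn"`, `"dt"`.
#' @param subsets Character vector of feature subsets, each a `+`-joined
#'   combination of the families `plf` (SpikeE, SharpE), `ndf` (HFD, PE) and
#'   `dfi`, e.g. `c("plf", "ndf", "plf+ndf", "plf+ndf+dfi")`; `"all"` is
#'   shorthand for `"plf+ndf+dfi"`.
#' @param task Optional named character vector mapping recording labels to
#'   task classes (e.g. `c(A = "non-seizure", E = "seizure")`); unmapped
#'   labels are dropped. `NULL` uses the labels as classes.
#' @param positive Positive class for binary metrics (default: the
#'   ictal/seizure class).
#' @param seed Master seed; per-fold classifier seeds are derived from it.
#' @param convention DFI convention, see [dfi()].
#' @return Object of class `eeg_eval`: `results` (one row per subset x
#'   classifier with fold-mean `acc`, `pre`, `sen`, `f1`, `spe`),
#'   `confusion` (summed confusion matrix per row), `per_fold` metrics, and
#'   the run configuration.
#' @export
run_task <- function(features, plan, classifiers = "xgb",
                     subsets = "plf+ndf+dfi", task = NULL, positive = NULL,
                     seed = 1L, convention = c("sum_abs", "abs_sum")) {
  convention <- match.arg(convention)
  stopifnot(inherits(plan, "fold_plan"))
  if (!is.null(task)) {
    features <- features[features$label %in% names(task), , drop = FALSE]
    features$label <- unname(task[features$label])
  }
  lv <- sort(unique(features$label))
  if (is.null(positive) && length(lv) == 2L) positive <- .default_positive(lv)
  fold_of <- stats::setNames(plan$fold, plan$recording_id)
  features <- features[features$recording_id %in% plan$recording_id, , drop = FALSE]
  n_folds <- attr(plan, "n_folds")
  grid <- expand.grid(subset = subsets, classifier = classifiers,
                      stringsAsFactors = FALSE)
  confusion <- vector("list", nrow(grid))
  per_fold <- list()
  for (f in seq_len(n_folds)) {
    test_ids <- plan$recording_id[plan$fold == f]
    train <- features[!fold_of[features$recording_id] %in% f, , drop = FALSE]
    test <- features[fold_of[features$recording_id] %in% f, , drop = FALSE]
    if (nrow(test) == 0L || length(unique(train$label)) < 2L) next
    sp <- .prepare_split(train, test, convention)
    y_train <- factor(train$label, levels = lv)
    y_test <- factor(test$label, levels = lv)
    for (g in seq_len(nrow(grid))) {
      cols <- resolve_subset(grid$subset[g])
      clf <- fit_classifier(sp$train_x[, cols, drop = FALSE], y_train,
                            classifier = grid$classifier[g],
                            seed = seed + 1000L * f)
      pred <- predict(clf, sp$test_x[, cols, drop = FALSE], type = "class")
      cm <- table(true = y_test, pred = factor(pred, levels = lv))
      cm <- unclass(cm); dimnames(cm) <- list(lv, lv)
      mets <- suppressWarnings(compute_metrics(cm, positive = positive))
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        fold = f, subset = grid$subset[g], classifier = grid$classifier[g],
        acc = mets$acc, pre = mets$pre, sen = mets$sen, f1 = mets$f1,
        spe = mets$spe, stringsAsFactors = FALSE)
      confusion[[g]] <- if (is.null(confusion[[g]])) cm else confusion[[g]] + cm
    }
  }
  per_fold <- do.call(rbind, per_fold)
  agg <- stats::aggregate(per_fold[c("acc", "pre", "sen", "f1", "spe")],
                          by = per_fold[c("subset", "classifier")], FUN = mean)
  # keep the requested row order
  key <- paste(agg$subset, agg$classifier)
  agg <- agg[match(paste(grid$subset, grid$classifier), key), ]
  rownames(agg) <- NULL
  names(confusion) <- paste(grid$subset, grid$classifier, sep = " / ")
  structure(list(results = agg, confusion = confusion, per_fold = per_fold,
                 n_folds = n_folds, seed = seed, positive = positive,
                 classes = lv),
            class = "eeg_eval")
}

#' @export
print.eeg_eval <- function(x, digits = 4, ...) {
  cat(sprintf("<eeg_eval> %d-fold recording-stratified CV, classes: %s\n",
              x$n_folds, paste(x$classes, collapse = ", ")))
  r <- x$results
  r[c("acc", "pre", "sen", "f1", "spe")] <-
    round(r[c("acc", "pre", "sen", "f1", "spe")], digits)
  print(r, row.names = FALSE)
  invisible(x)
}

#' Train on one feature table, test on another
#'
#' Single train/test pass (no cross-validation) for cross-dataset transfer:
#' the scaler and DFI normalization bounds come from the training table only.
#'
#' @param train_features,test_features Feature tables from
#'   [extract_features()] sharing the base feature schema.
#' @param classifier One classifier name.
#' @param subset One feature subset string (see [run_task()]).
#' @param task Optional label mapping applied to both tables.
#' @param positive Positive class for binary metrics.
#' @param seed Classifier seed.
#' @param convention DFI convention.
#' @return List with `metrics` (a `metric_set`) and `confusion`.
#' @export
cross_dataset_eval <- function(train_features, test_features,
                               classifier = "xgb", subset = "plf+ndf+dfi",
                               task = NULL, positive = NULL, seed = 1L,
                               convention = c("sum_abs", "abs_sum")) {
  convention <- match.arg(convention)
  stopifnot(all(base_feature_names() %in% names(train_features)),
            all(base_feature_names() %in% names(test_features)))
  if (!is.null(task)) {
    for (nm in c("train_features", "test_features")) {
      df <- get(nm)
      df <- df[df$label %in% names(task), , drop = FALSE]
      df$label <- unname(task[df$label])
      assign(nm, df)
    }
  }
  lv <- sort(unique(c(train_features$label, test_features$label)))
  if (is.null(positive) && length(lv) == 2L) positive <- .default_positive(lv)
  sp <- .prepare_split(train_features, test_features, convention)
  cols <- resolve_subset(subset)
  clf <- fit_classifier(sp$train_x[, cols, drop = FALSE],
                        factor(train_features$label, levels = lv),
                        classifier = classifier, seed = seed)
  pred <- predict(clf, sp$test_x[, cols, drop = FALSE], type = "class")
  cm <- table(true = factor(test_features$label, levels = lv),
              pred = factor(pred, levels = lv))
  cm <- unclass(cm); dimnames(cm) <- list(lv, lv)
  list(metrics = suppressWarnings(compute_metrics(cm, positive = positive)),
       confusion = cm)
}
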