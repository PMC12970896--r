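# small window-level feature table with controllable class separation
make_feature_table <- function(n_rec_per_class, n_win = 4, classes = c("a", "b"),
                               shift = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (ci in seq_along(classes)) {
    for (r in seq_len(n_rec_per_class)) {
      id <- sprintf("%s_%02d", classes[ci], r)
      rows[[id]] <- data.frame(
        recording_id = id, window_index = seq_len(n_win) - 1L,
        label = classes[ci],
        SpikeE = if (is.na(shift)) rep((ci - 1) * 10, n_win) else
          rnorm(n_win, mean = (ci - 1) * shift),
        SharpE = if (is.na(shift)) rep((ci - 1) * 8, n_win) else
          rnorm(n_win, mean = (ci - 1) * shift),
        HFD = rnorm(n_win, mean = 1.5 + (ci - 1) * 0.05, sd = 0.02),
        PE = rnorm(n_win, mean = 1.7, sd = 0.02))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

test_that("fold plans stratify whole recordings by class, deterministically", {
  recs <- data.frame(recording_id = sprintf("r%03d", 1:100),
                     label = rep(c("a", "b"), each = 50))
  plan <- build_fold_plan(recs, n_folds = 10, seed = 3)
  per_fold <- table(plan$fold, plan$label)
  expect_true(all(per_fold == 5))
  plan2 <- build_fold_plan(recs, n_folds = 10, seed = 3)
  expect_identical(plan, plan2)
  plan3 <- build_fold_plan(recs, n_folds = 10, seed = 4)
  expect_false(identical(plan$fold, plan3$fold))
  expect_error(build_fold_plan(recs[1:5, ], n_folds = 10, seed = 1),
               "at least n_folds")
})

test_that("fold scaler is fitted on training rows only and clips test rows", {
  train <- data.frame(SpikeE = c(0, 10), SharpE = c(1, 2),
                      HFD = c(1, 2), PE = c(0, 1))
  sc <- fit_fold_scaler(train)
  test <- data.frame(SpikeE = c(5, 12, -1), SharpE = c(1.5, 1.5, 1.5),
                     HFD = c(1.5, 1.5, 1.5), PE = c(0.5, 0.5, 0.5))
  norm <- apply_scaler(sc, test)
  expect_equal(norm[, "SpikeE"], c(0.5, 1, 0))
  # zero-variance feature maps to zero with a warning
  train$PE <- 1
  expect_warning(sc0 <- fit_fold_scaler(train), "zero-variance")
  expect_equal(apply_scaler(sc0, test)[, "PE"], rep(0, 3))
})

test_that("metric formulas reproduce direct substitution", {
  cm <- matrix(c(90, 20, 10, 80), 2, 2,
               dimnames = list(c("seizure", "non"), c("seizure", "non")))
  m <- compute_metrics(cm, positive = "seizure")
  expect_equal(m$acc, 0.85)
  expect_equal(m$sen, 0.90)
  expect_equal(m$spe, 0.80)
  expect_equal(m$pre, 90 / 110)
  expect_equal(m$f1, 2 * (90 / 110) * 0.9 / (90 / 110 + 0.9))
  # perfect diagonal: everything 1
  d2 <- diag(c(30, 70)); dimnames(d2) <- list(c("x", "y"), c("x", "y"))
  m2 <- compute_metrics(d2, positive = "x")
  expect_equal(unlist(m2[c("acc", "spe", "sen", "pre", "f1")]),
               c(acc = 1, spe = 1, sen = 1, pre = 1, f1 = 1))
  d3 <- diag(c(30, 30, 40)); dimnames(d3) <- list(letters[1:3], letters[1:3])
  m3 <- compute_metrics(d3)
  expect_equal(m3$averaging, "macro")
  expect_equal(unlist(m3[c("acc", "spe", "sen", "pre", "f1")]),
               c(acc = 1, spe = 1, sen = 1, pre = 1, f1 = 1))
})

test_that("macro metrics are invariant under relabeling of a symmetric matrix", {
  cm <- matrix(c(40, 5, 3, 5, 40, 3, 3, 3, 44), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m1 <- compute_metrics(cm)
  perm <- c(3, 1, 2)
  cm2 <- cm[perm, perm]
  m2 <- compute_metrics(cm2)
  expect_equal(unlist(m1[c("acc", "spe", "sen", "pre", "f1")]),
               unlist(m2[c("acc", "spe", "sen", "pre", "f1")]))
})

test_that("degenerate 0/0 ratios become 0 with a warning", {
  cm <- matrix(c(0, 0, 10, 90), 2, 2,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  expect_warning(m <- compute_metrics(cm, positive = "pos"), "0/0")
  expect_equal(m$pre, 0)
  expect_equal(m$f1, 0)
})

test_that("all five classifiers separate a perfectly separable task", {
  # class-constant energy features: held-out values coincide with training
  # values, so separability is exact for every classifier family
  feats <- make_feature_table(12, shift = NA)
  plan <- build_fold_plan(feats, n_folds = 10, seed = 2)
  ev <- run_task(feats, plan, classifiers = c("xgb", "rf", "svm", "knn", "dt"),
                 subsets = "plf+ndf", seed = 2)
  expect_true(all(ev$results$acc == 1))
  expect_true(all(ev$results$f1 == 1))
})

test_that("evaluation is reproducible and respects label mapping", {
  feats <- make_feature_table(12, shift = 2, seed = 6)
  plan <- build_fold_plan(feats, n_folds = 10, seed = 6)
  ev1 <- run_task(feats, plan, classifiers = "xgb", subsets = "all", seed = 6)
  ev2 <- run_task(feats, plan, classifiers = "xgb", subsets = "all", seed = 6)
  expect_identical(ev1$results, ev2$results)
  mapped <- run_task(feats, plan, classifiers = "xgb", subsets = "all",
                     task = c(a = "non-seizure", b = "seizure"), seed = 6)
  expect_equal(mapped$classes, c("non-seizure", "seizure"))
  expect_equal(mapped$positive, "seizure")
  expect_equal(sum(mapped$confusion[[1]]), nrow(feats))
})

test_that("subset resolution maps feature families to columns", {
  expect_equal(resolve_subset("plf"), c("SpikeE", "SharpE"))
  expect_equal(resolve_subset("ndf"), c("HFD", "PE"))
  expect_equal(resolve_subset("all"), c("SpikeE", "SharpE", "HFD", "PE", "DFI"))
  expect_error(resolve_subset("plf+bogus"), "unknown feature family")
})

test_that("cross-dataset transfer degrades monotonically with target shift", {
  train <- make_feature_table(15, n_win = 6, shift = 4, seed = 9)
  accs <- vapply(c(0, 2, 6), function(delta) {
    test <- make_feature_table(10, n_win = 6, shift = 4, seed = 10)
    sel <- test$label == "b"
    test$SpikeE[sel] <- test$SpikeE[sel] - delta
    test$SharpE[sel] <- test$SharpE[sel] - delta
    cross_dataset_eval(train, test, classifier = "svm", subset = "plf")$metrics$acc
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_gt(accs[1], 0.9)
  # self-transfer equals resubstitution
  r <- cross_dataset_eval(train, train, classifier = "dt", subset = "plf+ndf")
  expect_equal(sum(diag(r$confusion)) / sum(r$confusion), r$metrics$acc)
})
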