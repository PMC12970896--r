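#' Interventional value function for a feature subset
#'
#' The coalition value `g(S)` used by the exact Shapley computation:
#' the mean model output over background rows in which the features in `S`
#' are replaced by the instance's values and the remaining features keep the
#' background row's values (interventional marginalization). `g(empty set)`
#' is the mean model output over the background (the base value) and
#' `g(full set)` is the model output at the instance.
#'
#' @param predfun Function mapping a numeric feature matrix to a numeric
#'   vector of model outputs (e.g. the probability of one class).
#' @param instance Named numeric vector of feature values.
#' @param S Character vector (or logical/integer index) of features in the
#'   coalition; may be empty.
#' @param background Numeric matrix/data.frame of background rows with the
#'   instance's feature columns.
#' @return The coalition value, a single number.
#' @export
shap_value_function <- function(predfun, instance, S, background) {
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background must be nonempty")
  X <- background[, names(instance), drop = FALSE]
  if (length(S) > 0) X[, S] <- matrix(instance[S], nrow(X), length(S), byrow = TRUE)
  mean(predfun(X))
}

# all coalition values in one batched prediction
.coalition_values <- function(predfun, instance, background) {
  M <- length(instance)
  nb <- nrow(background)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), M)))
  colnames(subsets) <- names(instance)
  big <- background[rep(seq_len(nb), times = nrow(subsets)), , drop = FALSE]
  for (j in seq_len(M)) {
    rows <- rep(subsets[, j], each = nb)
    big[rows, j] <- instance[j]
  }
  out <- predfun(big)
  g <- vapply(seq_len(nrow(subsets)), function(s)
    mean(out[((s - 1L) * nb + 1L):(s * nb)]), numeric(1))
  list(subsets = subsets, g = g)
}

#' Exact Shapley attribution by full subset enumeration
#'
#' Computes, for every feature `j`, the Shapley value
#' `phi_j = sum over S not containing j of |S|! (M - |S| - 1)! / M! *
#' (g(S + j) - g(S))` with the interventional value function of
#' [shap_value_function()], enumerating all `2^M` coalitions. With the five
#' features used here this is exact — no sampling, identical across runs —
#' and the local-accuracy identity `base_value + sum(phi) = model output`
#' holds to floating-point precision by construction.
#'
#' @param model Either an `eeg_classifier` (its predicted probability of
#'   `target_class` is explained) or a function mapping a feature matrix to a
#'   numeric output vector.
#' @param instance Named numeric vector (one row of features).
#' @param background Numeric matrix/data.frame of background rows (e.g. the
#'   training fold, subsampled to a few hundred rows).
#' @param target_class For `eeg_classifier` models: the class whose
#'   probability is explained; default the model's predicted class for the
#'   instance.
#' @param max_features Enumeration guard (default 12): more features than
#'   this is refused.
#' @param instance_id Optional identifier stored in the result.
#' @return Object of class `shap_explanation`: `base_value`, `phi` (named),
#'   `model_output`, `target_class`, `instance`, `instance_id`, `n_background`.
#' @examples
#' f <- function(X) 2 * X[, 1] + 3 * X[, 2]
#' bg <- matrix(0, 10, 2, dimnames = list(NULL, c("a", "b")))
#' ex <- exact_shapley(f, c(a = 1, b = 1), bg)
#' ex$phi  # (2, 3)
#' @export
exact_shapley <- function(model, instance, background, target_class = NULL,
                          max_features = 12L, instance_id = NA) {
  instance <- unlist(instance)
  M <- length(instance)
  if (is.null(names(instance))) names(instance) <- paste0("x", seq_len(M))
  if (M > max_features)
    stop("exact enumeration limited to ", max_features, " features")
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background must be nonempty")
  background <- background[, names(instance), drop = FALSE]
  if (inherits(model, "eeg_classifier")) {
    clf <- model
    if (is.null(target_class)) {
      target_class <- as.character(predict(clf, matrix(instance, nrow = 1L),
                                           type = "class"))
    }
    predfun <- function(X) predict(clf, X, type = "prob")[, target_class]
  } else {
    predfun <- match.fun(model)
    if (is.null(target_class)) target_class <- NA_character_
  }
  cv <- .coalition_values(predfun, instance, background)
  sizes <- rowSums(cv$subsets)
  w <- factorial(0:(M - 1)) * factorial(M - 1 - (0:(M - 1))) / factorial(M)
  # index coalitions by bitmask for O(1) lookup of S + j
  bit <- 2^(seq_len(M) - 1L)
  mask <- as.integer(cv$subsets %*% bit)
  g_of <- numeric(2^M); g_of[mask + 1L] <- cv$g
  phi <- numeric(M)
  for (j in seq_len(M)) {
    without_j <- !cv$subsets[, j]
    s <- mask[without_j]
    phi[j] <- sum(w[sizes[without_j] + 1L] * (g_of[s + bit[j] + 1L] - g_of[s + 1L]))
  }
  names(phi) <- names(instance)
  structure(list(base_value = g_of[1L],
                 phi = phi,
                 model_output = g_of[2^M],
                 target_class = target_class,
                 instance = instance,
                 instance_id = instance_id,
                 n_background = nrow(background)),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation>%s base %.6f -> output %.6f%s\n",
              if (is.na(x$instance_id)) "" else paste0(" [", x$instance_id, "]"),
              x$base_value, x$model_output,
              if (is.na(x$target_class)) "" else paste0(" (class ", x$target_class, ")")))
  print(round(x$phi, 6))
  invisible(x)
}

#' Global feature importance from a set of explanations
#'
#' Ranks features by the mean absolute attribution across explanations
#' (ties broken alphabetically). When explanations target several classes, a
#' per-class breakdown is included.
#'
#' @param explanations List of `shap_explanation` objects sharing a feature
#'   schema.
#' @return data.frame with `feature`, `mean_abs_phi`, `rank`; attribute
#'   `"per_class"` holds the per-target-class breakdown when applicable.
#' @export
global_importance <- function(explanations) {
  stopifnot(length(explanations) > 0)
  phis <- t(vapply(explanations, function(e) e$phi,
                   numeric(length(explanations[[1]]$phi))))
  fn <- names(explanations[[1]]$phi)
  colnames(phis) <- fn
  imp <- colMeans(abs(phis))
  ord <- order(-imp, fn)
  out <- data.frame(feature = fn[ord], mean_abs_phi = unname(imp[ord]),
                    rank = seq_along(fn), stringsAsFactors = FALSE)
  classes <- vapply(explanations, function(e) as.character(e$target_class),
                    character(1))
  if (length(unique(classes[!is.na(classes)])) > 1L) {
    per_class <- do.call(rbind, lapply(unique(classes), function(cl) {
      sel <- classes == cl
      data.frame(target_class = cl, feature = fn,
                 mean_abs_phi = colMeans(abs(phis[sel, , drop = FALSE])),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    attr(out, "per_class") <- per_class
  }
  out
}

#' Bar plot of global feature importance
#'
#' @param height data.frame from [global_importance()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_importance <- function(height, ...) {
  graphics::barplot(rev(height$mean_abs_phi), names.arg = rev(height$feature),
                    horiz = TRUE, las = 1, xlab = "mean |SHAP value|", ...)
}
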