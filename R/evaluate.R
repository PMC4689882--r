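# Evaluation harness: recall / precision / F over stratified k-fold
# cross-validation, with pooled (micro) counts as the headline numbers and
# per-fold (macro) values alongside.

#' Recall, precision and F-value from counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F = 2 R P / (R + P)`. A zero denominator yields 0 with
#' `degenerate = TRUE`.
#'
#' @param tp,fp,fn Non-negative counts (true positives, false positives,
#'   false negatives).
#' @return Tibble with `recall`, `precision`, `f_value`, `degenerate`.
#' @export
prf <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative",
                                   call. = FALSE)
  degenerate <- FALSE
  recall <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  precision <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  f <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else { degenerate <- TRUE; 0 }
  tibble::tibble(recall = recall, precision = precision, f_value = f,
                 degenerate = degenerate)
}

.count_confusion <- function(pred, gold) {
  c(tp = sum(pred == "positive" & gold == "positive"),
    fp = sum(pred == "positive" & gold == "negative"),
    fn = sum(pred == "negative" & gold == "positive"),
    tn = sum(pred == "negative" & gold == "negative"))
}

#' Cross-validated evaluation of one method
#'
#' Outer stratified k-fold cross-validation: per fold the model (including
#' any DK refinement, which runs entirely inside the training side) is fit
#' on the complement and evaluated on the held-out fold. Headline metrics
#' pool the counts over folds (micro average); per-fold metrics are kept
#' for inspection and macro averaging.
#'
#' @param features Labeled feature tibble.
#' @param method Method variant (see [ppi_fit()]).
#' @param config A [ppi_config()]; `config$cv_folds` and `config$seed`
#'   control the outer folds.
#' @param learner Optional [ppi_learner()].
#' @param folds Optional pre-computed integer fold assignment (used by
#'   [ppi_compare_methods()] to share folds across methods).
#' @return A `ppi_eval` object.
#' @export
ppi_cross_validate <- function(features, method = "dk-fs-mc",
                               config = ppi_config(), learner = NULL,
                               folds = NULL) {
  k <- config$cv_folds
  if (k > nrow(features)) stop("more folds than instances", call. = FALSE)
  if (is.null(folds)) {
    folds <- .stratified_folds(as.character(features$label), k,
                               config$seed + 104729L)
  }
  per_fold <- list()
  counts <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  predictions <- list()
  for (j in sort(unique(folds))) {
    train <- features[folds != j, , drop = FALSE]
    test <- features[folds == j, , drop = FALSE]
    fit <- ppi_fit(train, method, config, learner)
    # leakage guard: refinement must never have touched the test fold
    if (!is.null(fit$dk_state) &&
        length(intersect(fit$dk_state$instance_id, test$instance_id)) > 0) {
      stop("internal error: DK refinement saw outer-test instances",
           call. = FALSE)
    }
    pr <- stats::predict(fit, test)
    cc <- .count_confusion(pr$.pred, test$label)
    counts <- counts + cc
    per_fold[[j]] <- dplyr::bind_cols(
      tibble::tibble(fold = j, n = nrow(test), tp = cc[["tp"]],
                     fp = cc[["fp"]], fn = cc[["fn"]], tn = cc[["tn"]]),
      prf(cc[["tp"]], cc[["fp"]], cc[["fn"]]))
    predictions[[j]] <- dplyr::mutate(pr, fold = j)
  }
  micro <- prf(counts[["tp"]], counts[["fp"]], counts[["fn"]])
  per_fold <- dplyr::bind_rows(per_fold)
  structure(list(
    method = method,
    counts = counts,
    micro = micro,
    macro = tibble::tibble(recall = mean(per_fold$recall),
                           precision = mean(per_fold$precision),
                           f_value = mean(per_fold$f_value)),
    per_fold = per_fold,
    predictions = dplyr::bind_rows(predictions),
    config = config
  ), class = "ppi_eval")
}

#' Compare method variants on identical folds
#'
#' Runs [ppi_cross_validate()] for each requested method with one shared
#' stratified fold assignment, and tabulates recall, precision and F.
#'
#' @param features Labeled feature tibble.
#' @param methods Character vector of method variants.
#' @param config A [ppi_config()].
#' @param learner Optional [ppi_learner()].
#' @return A `ppi_comparison`: tibble of per-method metrics with the
#'   individual `ppi_eval` objects in `attr(, "evals")`.
#' @export
ppi_compare_methods <- function(features,
                                methods = c("sc", "mc", "dk-mc", "fs-mc",
                                            "dk-fs-mc"),
                                config = ppi_config(), learner = NULL) {
  folds <- .stratified_folds(as.character(features$label), config$cv_folds,
                             config$seed + 104729L)
  evals <- lapply(methods, function(m) {
    ppi_cross_validate(features, m, config, learner, folds = folds)
  })
  names(evals) <- methods
  tab <- dplyr::bind_rows(lapply(evals, glance))
  structure(tab, evals = evals, class = c("ppi_comparison", class(tab)))
}

#' @export
print.ppi_eval <- function(x, ...) {
  cat("<ppi_eval>", toupper(x$method), "—",
      sprintf("R %.3f  P %.3f  F %.3f (micro, %d folds)\n",
              x$micro$recall, x$micro$precision, x$micro$f_value,
              nrow(x$per_fold)))
  invisible(x)
}

#' Tidy per-fold evaluation results
#'
#' @param x A `ppi_eval`.
#' @param ... Unused.
#' @method tidy ppi_eval
#' @export
tidy.ppi_eval <- function(x, ...) {
  out <- x$per_fold
  out$method <- x$method
  dplyr::relocate(out, "method")
}

#' @rdname tidy.ppi_eval
#' @method glance ppi_eval
#' @export
glance.ppi_eval <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    tp = x$counts[["tp"]], fp = x$counts[["fp"]],
    fn = x$counts[["fn"]], tn = x$counts[["tn"]],
    recall = x$micro$recall, precision = x$micro$precision,
    f_value = x$micro$f_value,
    recall_macro = x$macro$recall, precision_macro = x$macro$precision,
    f_value_macro = x$macro$f_value
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a method comparison
#'
#' Bar chart of micro recall / precision / F per method variant.
#'
#' @param object A `ppi_comparison` from [ppi_compare_methods()].
#' @param ... Unused.
#' @method autoplot ppi_comparison
#' @export
autoplot.ppi_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("method", "recall", "precision", "f_value")],
    -"method", names_to = "metric", values_to = "value")
  long$method <- factor(toupper(long$method),
                        levels = toupper(.method_levels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_brewer(palette = "Dark2",
                               labels = c(f_value = "F", precision = "P",
                                          recall = "R")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "PPI extraction: method comparison") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold evaluation spread
#'
#' @param object A `ppi_eval`.
#' @param ... Unused.
#' @method autoplot ppi_eval
#' @export
autoplot.ppi_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_fold[, c("fold", "recall", "precision", "f_value")],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Per-fold metrics:", toupper(object$method))) +
    ggplot2::theme_minimal()
}
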