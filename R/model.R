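# Four-way training-set partition and the five method variants.
#
# Subsets cross the DK flag with the keyword position: II (dominant,
# infix), IP (dominant, prefix/postfix), NI (no dominant keyword, infix),
# NP (otherwise). Feature selection (FS variants) removes four pattern
# features per subset; keyword-less instances route to NP.

.method_levels <- c("sc", "mc", "dk-mc", "fs-mc", "dk-fs-mc")

#' Assign instances to the II/IP/NI/NP subsets
#'
#' @param dk Integer vector of DK values (0/1).
#' @param position Character vector in
#'   `c("infix", "prefix", "postfix", "none")`.
#' @return Character vector of subset ids.
#' @export
assign_subset <- function(dk, position) {
  out <- rep("NP", length(dk))
  infix <- position == "infix"
  prepost <- position %in% c("prefix", "postfix")
  out[dk == 1L & infix] <- "II"
  out[dk == 1L & prepost] <- "IP"
  out[dk == 0L & infix] <- "NI"
  out
}

#' Per-subset removed features
#'
#' The manual feature-selection masks: infix subsets (II, NI) drop the
#' phrase patterns 7, 8, 9 and 13; prefix/postfix subsets (IP, NP) drop
#' the S-V-O patterns 1, 2, 10 and 12.
#'
#' @param subset One of `"II"`, `"IP"`, `"NI"`, `"NP"`.
#' @return Character vector of four removed feature names.
#' @export
feature_mask <- function(subset) {
  subset <- match.arg(subset, c("II", "IP", "NI", "NP"))
  if (subset %in% c("II", "NI")) paste0("pattern", c(7, 8, 9, 13))
  else paste0("pattern", c(1, 2, 10, 12))
}

.position_of <- function(features) {
  dplyr::case_when(features$pos_infix ~ "infix",
                   features$pos_prefix ~ "prefix",
                   features$pos_postfix ~ "postfix",
                   TRUE ~ "none")
}

.drop_cols <- function(features, cols) {
  features[, setdiff(names(features), cols), drop = FALSE]
}

#' Fit a PPI extraction model
#'
#' Trains one of the five method variants on a labeled feature table:
#' \describe{
#'   \item{`sc`}{a single classifier on all features;}
#'   \item{`mc`}{DK by unbalance degree only, four subset classifiers;}
#'   \item{`dk-mc`}{iterative DK refinement plus a DK-classifier for
#'     routing unlabeled instances, four subset classifiers on the
#'     refinement survivors;}
#'   \item{`fs-mc`, `dk-fs-mc`}{as `mc`/`dk-mc` with the per-subset
#'     feature masks applied before fitting.}
#' }
#'
#' @param features Labeled feature tibble from [extract_features()].
#' @param method One of `"sc"`, `"mc"`, `"dk-mc"`, `"fs-mc"`,
#'   `"dk-fs-mc"`.
#' @param config A [ppi_config()].
#' @param learner A [ppi_learner()]; default [learner_ranger()].
#' @return A fitted `ppi_model`.
#' @export
ppi_fit <- function(features, method = "dk-fs-mc", config = ppi_config(),
                    learner = NULL) {
  method <- match.arg(tolower(method), .method_levels)
  if (is.null(learner)) learner <- learner_ranger(config$num_trees)
  if (anyNA(features$label)) stop("training features must be labeled",
                                  call. = FALSE)
  y_all <- factor(as.character(features$label),
                  levels = c("negative", "positive"))

  if (method == "sc") {
    return(structure(list(
      method = method, config = config, learner = learner,
      classifier = learner$fit(features, y_all, config$seed),
      subset_classifiers = NULL, dk_model = NULL, dominant = NULL,
      masks = NULL, dk_state = NULL,
      subset_sizes = tibble::tibble(subset = "ALL", n = nrow(features),
                                    n_positive = sum(y_all == "positive"),
                                    stub = FALSE)
    ), class = "ppi_model"))
  }

  use_refinement <- method %in% c("dk-mc", "dk-fs-mc")
  use_masks <- method %in% c("fs-mc", "dk-fs-mc")

  if (use_refinement) {
    state <- refine_dk(features, config, learner)
    dk_model <- train_dk_classifier(features, state, learner,
                                    seed = config$seed + 3L)
    dom <- NULL
  } else {
    state <- initial_dk(features, config)
    dk_model <- NULL
    dom <- dominant_stems(features, config$threshold_T)
  }

  surv_ids <- state$instance_id[!state$removed]
  train <- features[features$instance_id %in% surv_ids, , drop = FALSE]
  dk <- state$dk[match(train$instance_id, state$instance_id)]
  subset <- assign_subset(dk, .position_of(train))

  masks <- if (use_masks) {
    stats::setNames(lapply(c("II", "IP", "NI", "NP"), feature_mask),
                    c("II", "IP", "NI", "NP"))
  } else NULL

  classifiers <- list()
  sizes <- list()
  for (s in c("II", "IP", "NI", "NP")) {
    f <- train[subset == s, , drop = FALSE]
    y <- factor(as.character(f$label), levels = c("negative", "positive"))
    if (use_masks) f <- .drop_cols(f, masks[[s]])
    if (nrow(f) == 0 || length(unique(as.character(y))) < 2) {
      classifiers[[s]] <- .majority_stub(y_all)
      stub <- TRUE
    } else {
      classifiers[[s]] <- learner$fit(f, y, config$seed + match(s, c("II", "IP", "NI", "NP")))
      stub <- FALSE
    }
    sizes[[s]] <- tibble::tibble(subset = s, n = nrow(f),
                                 n_positive = sum(y == "positive"),
                                 stub = stub)
  }

  structure(list(
    method = method, config = config, learner = learner,
    classifier = NULL, subset_classifiers = classifiers,
    dk_model = dk_model, dominant = dom, masks = masks, dk_state = state,
    subset_sizes = dplyr::bind_rows(sizes)
  ), class = "ppi_model")
}

#' Predict interaction labels
#'
#' Routes unlabeled instances exactly as the fitted method prescribes:
#' `sc` predicts directly; `mc`/`fs-mc` set `dk = 1` when the instance's
#' selected keyword stem belongs to the training-derived dominant set;
#' `dk-mc`/`dk-fs-mc` obtain `dk` from the DK-classifier. Instances are
#' then dispatched to their subset classifier (with the subset's feature
#' mask for FS variants).
#'
#' @param object A fitted `ppi_model`.
#' @param new_features Feature tibble for prediction-time instances.
#' @param ... Unused.
#' @return Tibble with `instance_id`, `.pred`
#'   (factor `negative`/`positive`), `.dk` and `.subset`.
#' @export
predict.ppi_model <- function(object, new_features, ...) {
  if (object$method == "sc") {
    p <- object$learner$predict(object$classifier, new_features)
    return(tibble::tibble(instance_id = new_features$instance_id, .pred = p,
                          .dk = NA_integer_, .subset = "ALL"))
  }
  dk <- if (object$method %in% c("mc", "fs-mc")) {
    as.integer(new_features$keyword %in% object$dominant)
  } else {
    predict_dk(object$dk_model, new_features)
  }
  subset <- assign_subset(dk, .position_of(new_features))
  pred <- factor(rep(NA_character_, nrow(new_features)),
                 levels = c("negative", "positive"))
  for (s in unique(subset)) {
    rows <- subset == s
    f <- new_features[rows, , drop = FALSE]
    if (!is.null(object$masks)) f <- .drop_cols(f, object$masks[[s]])
    pred[rows] <- .predict_model(object$subset_classifiers[[s]],
                                 object$learner, f)
  }
  tibble::tibble(instance_id = new_features$instance_id, .pred = pred,
                 .dk = dk, .subset = subset)
}

#' @export
print.ppi_model <- function(x, ...) {
  cat("<ppi_model> method:", toupper(x$method), "| learner:", x$learner$name,
      "\n")
  print(x$subset_sizes)
  if (!is.null(x$dk_state)) {
    cat("DK survivors:", sum(!x$dk_state$removed), "of",
        nrow(x$dk_state), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted PPI model
#'
#' One row per training subset with its size, positive count and whether
#' it degraded to a majority stub.
#'
#' @param x A `ppi_model`.
#' @param ... Unused.
#' @method tidy ppi_model
#' @export
tidy.ppi_model <- function(x, ...) {
  out <- x$subset_sizes
  out$method <- x$method
  dplyr::relocate(out, "method")
}

#' @rdname tidy.ppi_model
#' @method glance ppi_model
#' @export
glance.ppi_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_train = sum(x$subset_sizes$n),
    n_removed = if (is.null(x$dk_state)) 0L else sum(x$dk_state$removed),
    n_dk1 = if (is.null(x$dk_state)) NA_integer_ else
      sum(x$dk_state$dk[!x$dk_state$removed] == 1L),
    threshold_T = x$config$threshold_T,
    learner = x$learner$name
  )
}
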