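# Dominant-keyword (DK) machinery: the unbalance degree, the initial DK
# assumption, the iterative cross-validation refinement with its three
# update cases, and the DK-classifier that transfers DK values to unlabeled
# instances.

#' Method configuration
#'
#' Collects the tunable parameters of the pipeline. Defaults are the
#' reference conditions of the method: unbalance threshold `T = 0.15`,
#' refinement with `k = 10` folds, `m = 5` iterations and mutation rate
#' `alpha = 0.05`.
#'
#' @param threshold_T Unbalance threshold in (0, 0.5]; a keyword `K` is
#'   initially dominant when `min(U(K), 1 - U(K)) < T` (strict).
#' @param folds_k Folds of the inner refinement cross-validation.
#' @param iterations_m Refinement iterations.
#' @param mutation_alpha Probability of flipping the DK value of a
#'   true-negative instance in Case 2.
#' @param seed Integer seed; all fold draws, mutation draws and forest
#'   seeds derive from it.
#' @param cv_folds Folds of the outer evaluation cross-validation.
#' @param num_trees Trees for the default random-forest learner.
#' @param repartition Re-draw the inner CV partition at every iteration
#'   (`TRUE`, the default) or reuse the first partition.
#' @param wildcard_max Pattern wildcard span bound.
#' @return A `ppi_config` list.
#' @export
ppi_config <- function(threshold_T = 0.15, folds_k = 10L, iterations_m = 5L,
                       mutation_alpha = 0.05, seed = 1L, cv_folds = 10L,
                       num_trees = 100L, repartition = TRUE,
                       wildcard_max = 5L) {
  stopifnot(threshold_T > 0, threshold_T <= 0.5, folds_k >= 2,
            iterations_m >= 0, mutation_alpha >= 0, mutation_alpha <= 1)
  structure(list(threshold_T = threshold_T, folds_k = as.integer(folds_k),
                 iterations_m = as.integer(iterations_m),
                 mutation_alpha = mutation_alpha, seed = as.integer(seed),
                 cv_folds = as.integer(cv_folds),
                 num_trees = as.integer(num_trees),
                 repartition = isTRUE(repartition),
                 wildcard_max = as.integer(wildcard_max)),
            class = "ppi_config")
}

# small counter-based RNG stream: isolated from the global RNG so toggling
# the mutation rate does not shift fold randomness
.rng_stream <- function(seed) {
  state <- NULL
  function(n = 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    u <- stats::runif(n)
    state <<- get(".Random.seed", globalenv())
    u
  }
}

# stratified fold assignment (by y) with a local seed
.stratified_folds <- function(y, k, seed) {
  n <- length(y)
  k <- min(k, n)
  fold <- integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (lev in unique(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Unbalance degree of a keyword
#'
#' `U(K)` is the fraction of positive instances among the instances whose
#' *selected* keyword is `K`. `U = 0.5` means `K` is completely balanced;
#' `U = 0` or `U = 1`, completely unbalanced.
#'
#' @param keyword_stem A keyword stem.
#' @param features Labeled feature tibble (needs `keyword` and `label`).
#' @return A number in \[0, 1\].
#' @export
unbalance_degree <- function(keyword_stem, features) {
  hit <- features$keyword == keyword_stem
  if (!any(hit)) {
    stop("no instance has selected keyword '", keyword_stem, "'",
         call. = FALSE)
  }
  mean(features$label[hit] == "positive")
}

#' Unbalance table and dominant stems
#'
#' `unbalance_table()` computes `U(K)` for every selected keyword;
#' `dominant_stems()` returns the stems initially regarded as dominant,
#' i.e. those with `min(U, 1 - U) < T` (strict inequality).
#'
#' @param features Labeled feature tibble.
#' @param threshold_T Unbalance threshold.
#' @return `unbalance_table()`: tibble with `keyword`, `n`, `U`;
#'   `dominant_stems()`: character vector of stems.
#' @export
unbalance_table <- function(features) {
  features |>
    dplyr::filter(.data$keyword != "none") |>
    dplyr::group_by(.data$keyword) |>
    dplyr::summarise(n = dplyr::n(),
                     U = mean(.data$label == "positive"), .groups = "drop")
}

#' @rdname unbalance_table
#' @export
dominant_stems <- function(features, threshold_T = 0.15) {
  tab <- unbalance_table(features)
  tab$keyword[pmin(tab$U, 1 - tab$U) < threshold_T]
}

#' Initial DK assignment
#'
#' Instances whose selected keyword is initially dominant get `dk = 1`;
#' all others (including keyword-less instances) get `dk = 0`.
#'
#' @param features Labeled feature tibble.
#' @param config A [ppi_config()].
#' @return A `dk_state` tibble: `instance_id`, `dk`, `removed`.
#' @export
initial_dk <- function(features, config = ppi_config()) {
  dom <- dominant_stems(features, config$threshold_T)
  structure(tibble::tibble(
    instance_id = features$instance_id,
    dk = as.integer(features$keyword %in% dom),
    removed = FALSE
  ), class = c("dk_state", "tbl_df", "tbl", "data.frame"),
  history = tibble::tibble(iteration = integer(), case1 = integer(),
                           mutations = integer(), removed = integer()))
}

#' Train the DK pair of classifiers
#'
#' `C0` is fit on the surviving training instances with `dk = 0`, `C1` on
#' those with `dk = 1`, each on all 44 features. An empty or single-class
#' side degrades to a stub predicting the majority label of the whole
#' training side (recorded in the result).
#'
#' @param features Labeled training features.
#' @param dk Integer vector of current DK values aligned with `features`.
#' @param learner A [ppi_learner()].
#' @param seed Integer seed forwarded to the learner.
#' @return List with fitted `C0`, `C1`, and `degraded` flags.
#' @export
train_c0_c1 <- function(features, dk, learner, seed = 1L) {
  fit_side <- function(side) {
    f <- features[dk == side, , drop = FALSE]
    y <- droplevels(f$label)
    if (nrow(f) == 0 || nlevels(y) < 2) {
      return(list(model = .majority_stub(features$label), stub = TRUE))
    }
    list(model = learner$fit(f, factor(as.character(f$label),
                                       levels = c("negative", "positive")),
                             seed + side),
         stub = FALSE)
  }
  c0 <- fit_side(0L); c1 <- fit_side(1L)
  list(C0 = c0$model, C1 = c1$model,
       degraded = c(C0 = c0$stub, C1 = c1$stub))
}

.predict_model <- function(model, learner, features) {
  if (inherits(model, "dkppi_stub")) .stub_predict(model, features)
  else learner$predict(model, features)
}

#' Update DK values for one fold
#'
#' Applies the three update cases to each fold instance given the
#' predictions of `C0` and `C1` and the gold labels:
#' Case 1 (predictions differ): the correct classifier's side wins —
#' `dk = 1` if only `C1` is right, `dk = 0` if only `C0` is right.
#' Case 2 (both correct): a true-negative instance has its `dk` flipped
#' with probability `alpha` (mutation).
#' Case 3 (both wrong): a gold-negative instance is removed; positives are
#' never removed.
#'
#' @param fold_features Features of the held-out fold (gold labels known).
#' @param fit A classifier pair from [train_c0_c1()].
#' @param state A `dk_state` tibble.
#' @param config A [ppi_config()].
#' @param learner The [ppi_learner()] used to fit the pair.
#' @param mutate_draw Function returning uniform draws (the dedicated
#'   mutation stream); defaults to a fresh stream from `config$seed`.
#' @return Updated `dk_state` plus an attribute `changes` (named counts).
#' @export
update_dk_fold <- function(fold_features, fit, state, config, learner,
                           mutate_draw = NULL) {
  if (is.null(mutate_draw)) mutate_draw <- .rng_stream(config$seed + 7919L)
  p0 <- .predict_model(fit$C0, learner, fold_features)
  p1 <- .predict_model(fit$C1, learner, fold_features)
  gold <- fold_features$label
  idx <- match(fold_features$instance_id, state$instance_id)

  case1 <- 0L; muts <- 0L; rem <- 0L
  for (i in seq_along(idx)) {
    si <- idx[i]
    ok0 <- p0[i] == gold[i]; ok1 <- p1[i] == gold[i]
    if (ok0 != ok1) {
      new <- as.integer(ok1)
      if (state$dk[si] != new) case1 <- case1 + 1L
      state$dk[si] <- new
    } else if (ok0 && ok1) {
      if (gold[i] == "negative" && mutate_draw(1L) < config$mutation_alpha) {
        state$dk[si] <- 1L - state$dk[si]
        muts <- muts + 1L
      }
    } else {
      if (gold[i] == "negative") {
        state$removed[si] <- TRUE
        rem <- rem + 1L
      }
    }
  }
  attr(state, "changes") <- c(case1 = case1, mutations = muts, removed = rem)
  state
}

#' Refine DK values by iterated cross-validation
#'
#' Starting from [initial_dk()], repeats `m` times: partition the surviving
#' instances into `k` label-stratified folds, and for each fold train
#' `(C0, C1)` on the complement (with current DK values) and update the
#' fold's DK values with [update_dk_fold()]. Removals take effect
#' immediately. Mutation draws come from a dedicated seeded stream, so the
#' fold partition is identical whether or not mutation is enabled.
#'
#' @param features Labeled training features.
#' @param config A [ppi_config()].
#' @param learner A [ppi_learner()]; default [learner_ranger()] with
#'   `config$num_trees` trees.
#' @param state Optional starting `dk_state` (defaults to [initial_dk()]).
#' @return The final `dk_state`, with a per-iteration `history` attribute.
#' @export
refine_dk <- function(features, config = ppi_config(), learner = NULL,
                      state = NULL) {
  if (is.null(learner)) learner <- learner_ranger(config$num_trees)
  if (is.null(state)) state <- initial_dk(features, config)
  mutate_draw <- .rng_stream(config$seed + 7919L)
  history <- attr(state, "history")

  for (it in seq_len(config$iterations_m)) {
    surv_ids <- state$instance_id[!state$removed]
    surv <- features[features$instance_id %in% surv_ids, , drop = FALSE]
    part_seed <- config$seed + if (config$repartition) it else 1L
    fold <- .stratified_folds(as.character(surv$label),
                              min(config$folds_k, nrow(surv)), part_seed)
    it_changes <- c(case1 = 0L, mutations = 0L, removed = 0L)
    for (j in sort(unique(fold))) {
      fold_ids <- surv$instance_id[fold == j]
      # removals earlier in this iteration take effect immediately
      alive <- !state$removed
      train_ids <- setdiff(state$instance_id[alive], fold_ids)
      tr <- features[features$instance_id %in% train_ids, , drop = FALSE]
      dk_tr <- state$dk[match(tr$instance_id, state$instance_id)]
      fit <- train_c0_c1(tr, dk_tr, learner,
                         seed = config$seed + 131L * it + 2L * j)
      fold_feats <- surv[fold == j & !state$removed[match(surv$instance_id,
                                                          state$instance_id)], ,
                         drop = FALSE]
      state <- update_dk_fold(fold_feats, fit, state, config, learner,
                              mutate_draw)
      it_changes <- it_changes + attr(state, "changes")
    }
    history <- dplyr::bind_rows(history,
      tibble::tibble(iteration = it, case1 = it_changes[["case1"]],
                     mutations = it_changes[["mutations"]],
                     removed = it_changes[["removed"]]))
  }
  attr(state, "history") <- history
  attr(state, "changes") <- NULL
  state
}

#' Train the DK-classifier and predict DK values
#'
#' The DK-classifier is trained on the surviving instances' feature
#' vectors with their refined DK value as the class label, and assigns DK
#' values to unlabeled instances. If all survivors share one DK value the
#' classifier degrades to a constant predictor.
#'
#' @param features Training features (survivors are selected via `state`).
#' @param state A refined `dk_state`.
#' @param learner A [ppi_learner()].
#' @param seed Integer seed.
#' @return A `dk_classifier` object.
#' @export
train_dk_classifier <- function(features, state, learner, seed = 1L) {
  surv_ids <- state$instance_id[!state$removed]
  f <- features[features$instance_id %in% surv_ids, , drop = FALSE]
  dk <- state$dk[match(f$instance_id, state$instance_id)]
  y <- factor(dk, levels = c(0L, 1L))
  if (length(unique(dk)) < 2) {
    model <- structure(list(level = as.character(dk[1] %||% 0L),
                            levels = c("0", "1")), class = "dkppi_stub")
    return(structure(list(model = model, learner = learner, constant = TRUE),
                     class = "dk_classifier"))
  }
  structure(list(model = learner$fit(f, y, seed), learner = learner,
                 constant = FALSE),
            class = "dk_classifier")
}

#' @rdname train_dk_classifier
#' @param object A `dk_classifier`.
#' @param new_features Feature tibble for unlabeled instances.
#' @return `predict_dk()`: integer vector of 0/1 DK values.
#' @export
predict_dk <- function(object, new_features) {
  p <- .predict_model(object$model, object$learner, new_features)
  as.integer(as.character(p))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
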