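# Pluggable binary-classifier contract.
#
# A ppi_learner is a pair of closures: fit(features, y, seed) -> model and
# predict(model, features) -> factor with the levels of y. Learners receive
# the full feature tibble (including instance_id) and are responsible for
# restricting themselves to the registered feature columns they use; the
# shipped ranger learner does so, while the oracle/constant learners used
# in tests look only at instance ids.

#' Define a learner
#'
#' @param fit `function(features, y, seed)` returning a fitted model; `y`
#'   is a factor, `seed` an integer controlling any internal randomness.
#' @param predict `function(model, features)` returning a factor with the
#'   training levels.
#' @param name Display name.
#' @return A `ppi_learner` object.
#' @export
ppi_learner <- function(fit, predict, name = "custom") {
  structure(list(fit = fit, predict = predict, name = name),
            class = "ppi_learner")
}

#' @export
print.ppi_learner <- function(x, ...) {
  cat("<ppi_learner>", x$name, "\n"); invisible(x)
}

#' Random-forest learner (ranger backend)
#'
#' The default classifier. Nominal feature columns become factors whose
#' level sets are fixed at fit time (with a `"none"` catch-all); values
#' unseen in training map to `"none"` at prediction. Runs single-threaded
#' so results do not depend on scheduling.
#'
#' @param num_trees Number of trees (default 100; see the methods vignette
#'   for the choice).
#' @param mtry Variables tried per split; default one third of the
#'   feature count. With 44 features of which only a few are decisive for
#'   any one subset, the usual `sqrt(p)` starves the splits of the
#'   relevant variables.
#' @return A [ppi_learner()].
#' @export
learner_ranger <- function(num_trees = 100L, mtry = NULL) {
  prepare <- function(features, levels_map = NULL) {
    cols <- intersect(ppi_feature_names(), names(features))
    x <- as.data.frame(features[, cols], stringsAsFactors = FALSE)
    if (is.null(levels_map)) {
      levels_map <- list()
      for (cl in cols) {
        if (is.character(x[[cl]])) {
          levels_map[[cl]] <- unique(c(x[[cl]], "none"))
        }
      }
    }
    for (cl in names(levels_map)) {
      v <- x[[cl]]
      v[!v %in% levels_map[[cl]]] <- "none"
      x[[cl]] <- factor(v, levels = levels_map[[cl]])
    }
    list(x = x, levels_map = levels_map)
  }
  ppi_learner(
    fit = function(features, y, seed = 1L) {
      p <- prepare(features)
      rf <- ranger::ranger(
        x = p$x, y = y, num.trees = num_trees,
        mtry = if (is.null(mtry)) max(floor(ncol(p$x) / 3), 1L) else mtry,
        num.threads = 1L, seed = seed,
        respect.unordered.factors = "order")
      structure(list(rf = rf, levels_map = p$levels_map,
                     y_levels = levels(y)),
                class = "dkppi_ranger_fit")
    },
    predict = function(model, features) {
      p <- prepare(features, model$levels_map)
      pr <- stats::predict(model$rf, data = p$x, num.threads = 1L)
      factor(as.character(pr$predictions), levels = model$y_levels)
    },
    name = sprintf("ranger(%d trees)", num_trees)
  )
}

#' Constant-prediction learner
#'
#' Predicts one fixed level regardless of input; used for degraded subsets
#' and in tests.
#'
#' @param level The level to predict.
#' @param levels All class levels.
#' @return A [ppi_learner()].
#' @export
learner_constant <- function(level, levels = c("negative", "positive")) {
  ppi_learner(
    fit = function(features, y, seed = 1L) list(level = level,
                                                levels = levels(y)),
    predict = function(model, features) {
      factor(rep(model$level, nrow(features)), levels = model$levels)
    },
    name = paste0("constant(", level, ")")
  )
}

#' Oracle learner
#'
#' Looks the answer up in a gold table by `instance_id` (fit is a no-op).
#' Useful for fixed-point and leakage tests where perfect prediction is
#' required by construction.
#'
#' @param truth Tibble with `instance_id` and `label` columns.
#' @return A [ppi_learner()].
#' @export
learner_oracle <- function(truth) {
  ppi_learner(
    fit = function(features, y, seed = 1L) list(truth = truth,
                                                levels = levels(y)),
    predict = function(model, features) {
      lab <- model$truth$label[match(features$instance_id,
                                     model$truth$instance_id)]
      factor(as.character(lab), levels = model$levels)
    },
    name = "oracle"
  )
}

# majority-label stub honouring the degraded-classifier contract
.majority_stub <- function(y) {
  tab <- table(y)
  lev <- names(tab)[which.max(tab)]
  structure(list(level = lev, levels = levels(y)), class = "dkppi_stub")
}

.stub_predict <- function(model, features) {
  factor(rep(model$level, nrow(features)), levels = model$levels)
}
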