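# Subset assignment, feature masks, the five method variants, and routing.

test_that("subset assignment crosses DK with keyword position", {
  expect_equal(assign_subset(1L, "infix"), "II")
  expect_equal(assign_subset(1L, "prefix"), "IP")
  expect_equal(assign_subset(1L, "postfix"), "IP")
  expect_equal(assign_subset(0L, "infix"), "NI")
  expect_equal(assign_subset(0L, "postfix"), "NP")
  expect_equal(assign_subset(0L, "none"), "NP")
  expect_equal(assign_subset(1L, "none"), "NP")
  expect_equal(assign_subset(c(1L, 0L), c("infix", "prefix")), c("II", "NP"))
})

test_that("feature masks remove exactly the published pattern features", {
  expect_setequal(feature_mask("II"), paste0("pattern", c(7, 8, 9, 13)))
  expect_setequal(feature_mask("NI"), paste0("pattern", c(7, 8, 9, 13)))
  expect_setequal(feature_mask("IP"), paste0("pattern", c(1, 2, 10, 12)))
  expect_setequal(feature_mask("NP"), paste0("pattern", c(1, 2, 10, 12)))
  expect_length(setdiff(ppi_feature_names(), feature_mask("II")), 40L)
  expect_error(feature_mask("XX"))
})

fx <- small_synth_features(n = 120, seed = 17)

test_that("each method variant assembles the right model parts", {
  cfg <- fast_config(seed = 17)
  m_sc <- ppi_fit(fx$features, "sc", cfg)
  expect_null(m_sc$subset_classifiers)
  expect_null(m_sc$dk_model)
  expect_false(is.null(m_sc$classifier))

  m_mc <- ppi_fit(fx$features, "mc", cfg)
  expect_length(m_mc$subset_classifiers, 4L)
  expect_null(m_mc$dk_model)
  expect_true("interact" %in% m_mc$dominant)
  expect_null(m_mc$masks)

  m_full <- ppi_fit(fx$features, "dk-fs-mc", cfg)
  expect_length(m_full$subset_classifiers, 4L)
  expect_s3_class(m_full$dk_model, "dk_classifier")
  expect_length(m_full$masks, 4L)
  expect_null(m_full$dominant)

  m_fs <- ppi_fit(fx$features, "fs-mc", cfg)
  expect_length(m_fs$masks, 4L)
  expect_null(m_fs$dk_model)

  expect_error(ppi_fit(dplyr::mutate(fx$features, label = NA), "sc", cfg),
               "labeled")
})

test_that("the four subsets partition the surviving training set", {
  cfg <- fast_config(seed = 17)
  m <- ppi_fit(fx$features, "dk-fs-mc", cfg)
  st <- m$dk_state
  surv <- st[!st$removed, ]
  expect_equal(sum(m$subset_sizes$n), nrow(surv))
  f_surv <- fx$features[match(surv$instance_id, fx$features$instance_id), ]
  sub <- assign_subset(surv$dk, dkppi:::.position_of(f_surv))
  expect_equal(sort(unique(sub)), sort(m$subset_sizes$subset[m$subset_sizes$n > 0]))
  counts <- table(factor(sub, levels = c("II", "IP", "NI", "NP")))
  expect_equal(as.integer(counts[m$subset_sizes$subset]), m$subset_sizes$n)
})

test_that("routing follows dominance and position; keyword-less goes to NP", {
  cfg <- fast_config(seed = 17)
  m_mc <- ppi_fit(fx$features, "mc", cfg)
  pr <- predict(m_mc, fx$features)
  f <- fx$features
  expect_equal(pr$.dk, as.integer(f$keyword %in% m_mc$dominant))
  expect_true(all(pr$.subset[f$keyword %in% m_mc$dominant & f$pos_infix] ==
                    "II"))
  nokw <- f$keyword == "none"
  expect_true(any(nokw))
  expect_true(all(pr$.subset[nokw] == "NP"))
  # SC bypasses routing entirely
  pr_sc <- predict(ppi_fit(f, "sc", cfg), f)
  expect_true(all(pr_sc$.subset == "ALL"))
  # DK variants route via the DK-classifier
  m_dk <- ppi_fit(f, "dk-mc", cfg)
  pr_dk <- predict(m_dk, f)
  expect_equal(pr_dk$.dk, predict_dk(m_dk$dk_model, f))
})

test_that("masked classifiers never see a removed feature", {
  cfg <- fast_config(seed = 17)
  spy_env <- new.env(parent = emptyenv())
  spy_env$fit_cols <- list(); spy_env$pred_cols <- list()
  spy <- ppi_learner(
    fit = function(features, y, seed = 1L) {
      spy_env$fit_cols[[length(spy_env$fit_cols) + 1]] <-
        intersect(ppi_feature_names(), names(features))
      list(maj = names(which.max(table(y))), lev = levels(y))
    },
    predict = function(model, features) {
      spy_env$pred_cols[[length(spy_env$pred_cols) + 1]] <-
        intersect(ppi_feature_names(), names(features))
      factor(rep(model$maj, nrow(features)), levels = model$lev)
    }, name = "spy")
  m <- ppi_fit(fx$features, "fs-mc", cfg, learner = spy)
  invisible(predict(m, fx$features))
  masks <- list(feature_mask("II"), feature_mask("IP"))
  seen <- c(spy_env$fit_cols, spy_env$pred_cols)
  expect_true(length(seen) >= 4)
  for (cols in seen) {
    expect_length(cols, 40L)
    # the 4 absent features are exactly one of the two mask sets
    absent <- setdiff(ppi_feature_names(), cols)
    expect_true(setequal(absent, masks[[1]]) || setequal(absent, masks[[2]]))
  }
})

test_that("fits and predictions are reproducible under a fixed seed", {
  cfg <- fast_config(seed = 4)
  p1 <- predict(ppi_fit(fx$features, "dk-fs-mc", cfg), fx$features)
  p2 <- predict(ppi_fit(fx$features, "dk-fs-mc", cfg), fx$features)
  expect_identical(p1, p2)
})

test_that("tidy and glance summarise fitted models", {
  cfg <- fast_config(seed = 17)
  m <- ppi_fit(fx$features, "dk-fs-mc", cfg)
  td <- tidy(m)
  expect_equal(nrow(td), 4L)
  expect_true(all(c("method", "subset", "n", "n_positive", "stub") %in%
                    names(td)))
  gl <- glance(m)
  expect_equal(gl$method, "dk-fs-mc")
  expect_equal(gl$n_train, sum(td$n))
  expect_equal(gl$threshold_T, 0.15)
})
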