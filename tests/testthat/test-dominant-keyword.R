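# Unbalance degree, initial DK assumption, refinement cases, DK-classifier.

test_that("unbalance degree is the positive fraction per selected keyword", {
  f <- kw_features(rep("bind", 4), c("positive", "positive", "positive",
                                     "negative"))
  expect_equal(unbalance_degree("bind", f), 0.75)
  expect_equal(unbalance_degree("bind",
                                kw_features(rep("bind", 3),
                                            rep("positive", 3))), 1.0)
  expect_equal(unbalance_degree("bind",
                                kw_features(rep("bind", 3),
                                            rep("negative", 3))), 0.0)
  f2 <- kw_features(rep("bind", 4), c("positive", "positive", "negative",
                                      "negative"))
  expect_equal(unbalance_degree("bind", f2), 0.5)
  expect_error(unbalance_degree("ghost", f), "no instance")
  tab <- unbalance_table(dplyr::bind_rows(f, kw_features("none", "positive")))
  expect_false("none" %in% tab$keyword)
  expect_true(all(tab$U >= 0 & tab$U <= 1))
})

test_that("initial DK uses a strict threshold and zeroes keyword-less rows", {
  # U = 0.9: 1 - U = 0.1 < 0.15 -> dominant
  f <- dplyr::bind_rows(
    kw_features(rep("interact", 10),
                c(rep("positive", 9), "negative")),
    kw_features(rep("bind", 20), c(rep("positive", 17), rep("negative", 3))),
    kw_features(rep("associ", 4), c("positive", "positive", "negative",
                                    "negative")),
    kw_features("none", "positive"))
  f$instance_id <- paste0("i", seq_len(nrow(f)))
  st <- initial_dk(f, ppi_config(threshold_T = 0.15))
  dk_of <- function(kw) unique(st$dk[f$keyword == kw])
  expect_equal(dk_of("interact"), 1L)
  # U = 0.85 exactly: min(U, 1-U) = 0.15 is NOT < 0.15
  expect_equal(dk_of("bind"), 0L)
  expect_equal(dk_of("associ"), 0L)
  expect_equal(dk_of("none"), 0L)
  expect_false(any(st$removed))
})

test_that("C0/C1 training degrades to majority stubs when a side collapses", {
  fx <- small_synth_features(n = 30, seed = 3)
  f <- fx$features
  lr <- learner_ranger(25)
  fit <- train_c0_c1(f, rep(0L, nrow(f)), lr, seed = 1)
  expect_true(fit$degraded[["C1"]])
  expect_false(fit$degraded[["C0"]])
  p <- dkppi:::.predict_model(fit$C1, lr, f)
  expect_equal(length(unique(as.character(p))), 1L)
  # both sides populated -> two real classifiers, reproducible predictions
  dk <- as.integer(f$keyword == "interact")
  fit2 <- train_c0_c1(f, dk, lr, seed = 1)
  fit3 <- train_c0_c1(f, dk, lr, seed = 1)
  expect_identical(as.character(lr$predict(fit2$C0, f)),
                   as.character(lr$predict(fit3$C0, f)))
})

test_that("the three update cases rewrite DK values as specified", {
  f <- tibble::tibble(
    instance_id = paste0("i", 1:6),
    keyword = "bind",
    label = factor(c("positive", "positive", "negative", "negative",
                     "negative", "positive"),
                   levels = c("negative", "positive")))
  state <- initial_dk(f, ppi_config())
  state$dk <- c(0L, 1L, 1L, 0L, 1L, 1L)
  pred <- function(...) {
    stats::setNames(factor(c(...), levels = c("negative", "positive")),
                    f$instance_id)
  }
  # C0 and C1 predictions chosen to exercise every case:
  # i1: only C1 right -> dk 1; i2: only C0 right -> dk 0
  # i3: both right (TN) -> mutation candidate; i4: both right (TN)
  # i5: both wrong (gold-negative) -> removed
  # i6: both wrong (gold-positive) -> untouched, never removed
  fit <- list(
    C0 = table_model(pred("negative", "positive", "negative", "negative",
                          "positive", "negative")),
    C1 = table_model(pred("positive", "negative", "negative", "negative",
                          "positive", "negative")))
  cfg1 <- ppi_config(mutation_alpha = 1)
  st1 <- update_dk_fold(f, fit, state, cfg1, table_learner,
                        mutate_draw = function(n) rep(0, n))
  expect_equal(st1$dk[1:2], c(1L, 0L))
  expect_equal(st1$dk[3:4], 1L - state$dk[3:4])  # alpha = 1 flips both TNs
  expect_true(st1$removed[5])
  expect_false(st1$removed[6])
  expect_equal(st1$dk[6], state$dk[6])
  # alpha = 0: no mutations at all
  st0 <- update_dk_fold(f, fit, state, ppi_config(mutation_alpha = 0),
                        table_learner, mutate_draw = function(n) rep(1, n))
  expect_equal(st0$dk[3:4], state$dk[3:4])
  # only gold-negative instances are ever removed
  expect_true(all(f$label[st1$removed] == "negative"))
})

test_that("refinement is the identity at m = 0 and a fixed point under an oracle", {
  fx <- small_synth_features(n = 60, seed = 8)
  f <- fx$features
  cfg0 <- ppi_config(iterations_m = 0)
  expect_equal(
    as.data.frame(refine_dk(f, cfg0, table_learner)),
    as.data.frame(initial_dk(f, cfg0)))
  # oracle learner, alpha = 0: both classifiers always correct -> Case 2
  # only, and with no mutation nothing ever changes
  oracle <- learner_oracle(f[, c("instance_id", "label")])
  cfg <- ppi_config(iterations_m = 3, folds_k = 5, mutation_alpha = 0)
  st <- refine_dk(f, cfg, oracle)
  expect_equal(st$dk, initial_dk(f, cfg)$dk)
  expect_false(any(st$removed))
  hist <- attr(st, "history")
  expect_equal(sum(hist$case1), 0L)
  expect_equal(sum(hist$removed), 0L)
})

test_that("refinement invariants hold under a real learner", {
  fx <- small_synth_features(n = 100, seed = 21)
  f <- fx$features
  st <- refine_dk(f, fast_config(seed = 21))
  expect_true(all(st$dk %in% 0:1))
  # removal is restricted to gold negatives
  removed_labels <- f$label[match(st$instance_id[st$removed], f$instance_id)]
  expect_true(all(removed_labels == "negative"))
  # deterministic given the seed
  st2 <- refine_dk(f, fast_config(seed = 21))
  expect_equal(as.data.frame(st), as.data.frame(st2))
})

test_that("the DK-classifier transfers DK values and degrades to constants", {
  fx <- small_synth_features(n = 80, seed = 31)
  f <- fx$features
  lr <- learner_ranger(25)
  # all-one-class DK -> constant predictor
  st <- initial_dk(f, ppi_config())
  st$dk <- rep(0L, nrow(st))
  dkc <- train_dk_classifier(f, st, lr)
  expect_true(dkc$constant)
  expect_equal(unique(predict_dk(dkc, f)), 0L)
  # interpolating learner reproduces training DK on training instances
  st$dk <- as.integer(f$keyword == "interact")
  oracle_dk <- learner_oracle(tibble::tibble(instance_id = f$instance_id,
                                             label = st$dk))
  dkc2 <- train_dk_classifier(f, st, oracle_dk)
  expect_equal(predict_dk(dkc2, f), st$dk)
})
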