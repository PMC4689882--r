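# Lexical (sentence-level) features.

test_that("the worked example sentence reproduces all printed values", {
  f <- extract_features(driven_corpus())
  expect_equal(f$keyword, "driven")
  expect_equal(c(f$dist_type1, f$dist_type2, f$dist_type3), c(1L, 1L, 3L))
  expect_true(f$pos_infix)
  expect_false(f$pos_prefix || f$pos_postfix)
  expect_equal(c(f$position1, f$position2), c(1L, 5L))
  expect_equal(f$comma, "nn")
  expect_equal(f$preposition, "by")
  expect_false(f$multiple_keywords)
  expect_false(f$negative)
})

test_that("negation and conjunction flags follow their printed scopes", {
  f <- features_of("P1 is not driven by P2", c("P1", "P2"))
  expect_true(f$negative)
  expect_false(f$conjunctive)
  f2 <- features_of("GerE binds CotX although pH falls", c("GerE", "CotX"))
  expect_true(f2$conjunctive)
  # negation outside every anchor gap does not fire the between-scoped flag
  f3 <- features_of("Not surprisingly GerE binds CotX", c("GerE", "CotX"))
  expect_false(f3$negative)
  f4 <- features_of("GerE binds CotX if heated", c("GerE", "CotX"))
  expect_false(f4$condition)
  f5 <- features_of("whether GerE binds CotX", c("GerE", "CotX"))
  expect_false(f5$condition)  # before the keyword and both proteins
  f6 <- features_of("GerE binds when whether CotX", c("GerE", "CotX"))
  expect_true(f6$condition)
  expect_true(f6$conjunctive)
})

test_that("keyword selection minimises the pair distance, ties leftmost", {
  f <- features_of("P1 binds and interacts with P2", c("P1", "P2"))
  expect_equal(f$keyword, "bind")
  expect_true(f$multiple_keywords)
  expect_true(f$second_interact)
  expect_false(f$second_bind)  # "bind" is the selected keyword itself
  # no lexicon hit -> absent keyword, sentinel values
  f2 <- features_of("P1 near P2", c("P1", "P2"))
  expect_equal(f2$keyword, "none")
  expect_equal(c(f2$dist_type1, f2$dist_type2), c(-1L, -1L))
  expect_equal(f2$dist_type3, 1L)
  expect_equal(f2$comma, "none")
  expect_equal(f2$preposition, "none")
  expect_false(f2$pos_infix || f2$pos_prefix || f2$pos_postfix)
  expect_false(f2$multiple_keywords)
  expect_false(any(unlist(f2[paste0("second_",
                                    c("bind", "interact", "regulate",
                                      "induce", "stimulate", "associate",
                                      "known"))])))
})

test_that("distances, positions and keyword order cover all three layouts", {
  f <- features_of("GerE binds CotX", c("GerE", "CotX"))
  expect_equal(c(f$dist_type1, f$dist_type2, f$dist_type3), c(0L, 0L, 1L))
  expect_true(f$pos_infix)

  f2 <- features_of("binds GerE to CotX", c("GerE", "CotX"))
  expect_equal(c(f2$dist_type1, f2$dist_type2, f2$dist_type3), c(0L, 1L, 1L))
  expect_true(f2$pos_prefix)

  f3 <- features_of("Interaction of GerE with CotX", c("GerE", "CotX"))
  expect_true(f3$pos_prefix)
  f4 <- features_of("GerE and CotX interact", c("GerE", "CotX"))
  expect_true(f4$pos_postfix)

  f5 <- features_of("aa bb cc GerE dd CotX", c("GerE", "CotX"))
  expect_equal(c(f5$position1, f5$position2), c(4L, 6L))
})

test_that("comma configurations inspect the two anchor gaps in order", {
  f <- features_of("binds GerE, CotX", c("GerE", "CotX"))
  expect_equal(f$comma, "ny")
  f2 <- features_of("GerE, which binds, drives CotX", c("GerE", "CotX"))
  expect_equal(f2$comma, "yy")
  expect_true(f2$which)
  f3 <- features_of("GerE, but not CotX, interacts", c("GerE", "CotX"))
  expect_true(f3$but)
})

test_that("the keyword preposition respects the distance-3 window", {
  f <- features_of("GerE is driven by CotX", c("GerE", "CotX"))
  expect_equal(f$preposition, "by")
  expect_equal(features_of("GerE binds CotX", c("GerE", "CotX"))$preposition,
               "none")
  # four words between keyword and preposition: out of window
  f2 <- features_of("binds aa bb cc dd with GerE near CotX",
                    c("GerE", "CotX"))
  expect_equal(f2$preposition, "none")
  # nearest qualifying preposition wins
  f3 <- features_of("GerE binds aa to CotX with SpoB",
                    c("GerE", "CotX"))
  expect_equal(f3$preposition, "to")
})

test_that("parallel expression accepts only the listed separators", {
  expect_true(features_of("Protein binds P1 or P2", c("P1", "P2"))$parallel)
  expect_false(features_of("P1 is driven by P2", c("P1", "P2"))$parallel)
  expect_true(features_of("binds P1 ( P2", c("P1", "P2"))$parallel)
  expect_true(features_of("binds P1 and P2", c("P1", "P2"))$parallel)
  expect_true(features_of("binds P1 / P2", c("P1", "P2"))$parallel)
})

test_that("the registry is total: 44 features, no missing values", {
  expect_length(ppi_feature_names(), 44L)
  fx <- small_synth_features(n = 40, seed = 11)
  f <- fx$features
  expect_true(all(ppi_feature_names() %in% names(f)))
  expect_false(anyNA(f[, ppi_feature_names()]))
  # deterministic: extraction twice gives identical tables
  expect_identical(f, extract_features(fx$corpus))
})

test_that("infix geometry identity holds: type1 + type2 + 1 == type3", {
  f <- small_synth_features(n = 80, seed = 5)$features
  infix <- f[f$pos_infix, ]
  expect_gt(nrow(infix), 0)
  expect_true(all(infix$dist_type1 + infix$dist_type2 + 1L ==
                    infix$dist_type3))
  expect_true(all(f$dist_type3 >= 0))
  expect_true(all(f$dist_type1 >= -1 & f$dist_type2 >= -1))
  # exactly one position indicator fires whenever a keyword is present
  has_kw <- f$keyword != "none"
  expect_true(all(rowSums(cbind(f$pos_infix, f$pos_prefix,
                                f$pos_postfix))[has_kw] == 1L))
  expect_true(all(rowSums(cbind(f$pos_infix, f$pos_prefix,
                                f$pos_postfix))[!has_kw] == 0L))
})
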