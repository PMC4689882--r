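# Corpus reading, tokenisation, instance enumeration, blinding and
# round-trips.

test_that("tokenisation counts word tokens and sidelines punctuation", {
  tk <- ppi_tokenize("P1 is driven by P2")$tokens
  expect_equal(sum(tk$is_word), 5L)
  expect_equal(tk$index[tk$is_word], 0:4)

  tk2 <- ppi_tokenize("P1, however, binds P2")$tokens
  expect_equal(tk2$surface[tk2$is_word], c("P1", "however", "binds", "P2"))
  expect_equal(sum(!tk2$is_word), 2L)
  expect_true(all(tk2$surface[!tk2$is_word] == ","))
  expect_true(all(is.na(tk2$index[!tk2$is_word])))

  expect_equal(nrow(ppi_tokenize("")$tokens), 0L)
})

test_that("multi-word mentions collapse to one token; bad offsets error", {
  m <- tibble::tibble(mention_id = "e1", char_start = 0L, char_end = 12L)
  tk <- ppi_tokenize("GerE protein binds CotX", m)
  expect_equal(sum(tk$tokens$is_word), 3L)
  expect_equal(tk$tokens$surface[1], "GerE protein")
  expect_equal(tk$tokens$n_words[1], 2L)
  expect_equal(tk$mentions$token_id, 1L)

  bad <- tibble::tibble(mention_id = "e1", char_start = 1L, char_end = 4L)
  expect_error(ppi_tokenize("GerE binds CotX", bad), "token boundary")
  out <- tibble::tibble(mention_id = "e1", char_start = 0L, char_end = 99L)
  expect_error(ppi_tokenize("GerE binds CotX", out), "outside")
})

test_that("unified XML reading yields labeled instances per schema", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<corpus source="t"><document id="d1">',
    '<sentence id="d1.s0" text="GerE binds CotX">',
    '<entity id="d1.s0.e0" charOffset="0-3" text="GerE" type="protein"/>',
    '<entity id="d1.s0.e1" charOffset="11-14" text="CotX" type="protein"/>',
    '<pair id="d1.s0.p0" e1="d1.s0.e0" e2="d1.s0.e1" interaction="True"/>',
    '</sentence>',
    '<sentence id="d1.s1" text="GerA binds GerB and GerC">',
    '<entity id="d1.s1.e0" charOffset="0-3" text="GerA" type="protein"/>',
    '<entity id="d1.s1.e1" charOffset="11-14" text="GerB" type="protein"/>',
    '<entity id="d1.s1.e2" charOffset="20-23" text="GerC" type="protein"/>',
    '<pair id="d1.s1.p0" e1="d1.s1.e0" e2="d1.s1.e1" interaction="True"/>',
    '</sentence>',
    '</document></corpus>'), path)
  co <- read_ppi_corpus(path)
  expect_equal(nrow(co$sentences), 2L)
  i0 <- co$instances[co$instances$sentence_id == "d1.s0", ]
  expect_equal(nrow(i0), 1L)
  expect_equal(as.character(i0$label), "positive")
  # 3 entities, 1 annotated pair -> 3 instances: 1 positive, 2 negative
  i1 <- co$instances[co$instances$sentence_id == "d1.s1", ]
  expect_equal(nrow(i1), 3L)
  expect_equal(sum(i1$label == "positive"), 1L)
  expect_equal(sum(i1$label == "negative"), 2L)
})

test_that("empty corpora parse and schema violations are reported", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<corpus source="t"></corpus>', path)
  co <- read_ppi_corpus(path)
  expect_equal(nrow(co$sentences), 0L)
  expect_equal(nrow(co$instances), 0L)

  writeLines('<corpus><sentence id="s" text="A b C">', path)
  expect_error(read_ppi_corpus(path), "malformed XML")

  writeLines(c('<corpus><sentence id="s" text="GerE binds CotX">',
               '<entity id="e0" charOffset="0-3" text="GerE"/>',
               '<pair e1="e0" e2="missing" interaction="True"/>',
               '</sentence></corpus>'), path)
  expect_error(read_ppi_corpus(path), "unknown entity")
})

test_that("instance enumeration is C(n,2) and counts occurrences separately", {
  co <- toy_corpus("Aa binds Bb and Cc near Dd",
                   list(c("Aa", "Bb", "Cc", "Dd")))
  expect_equal(nrow(co$instances), choose(4, 2))
  # duplicate surface at two positions: two distinct mentions, pairs per
  # occurrence
  co2 <- toy_corpus("GerE binds GerE and CotX", list(c("GerE", "GerE", "CotX")))
  expect_equal(nrow(co2$instances), 3L)
  # <2 mentions yields none; self-pairs never enumerated
  co3 <- toy_corpus("GerE is phosphorylated", list("GerE"))
  expect_equal(nrow(co3$instances), 0L)
})

test_that("blinding maps the pair to PROT1/PROT2 and bystanders to PROT", {
  co <- toy_corpus("GerE binds CotX or SpoA", list(c("GerE", "CotX", "SpoA")))
  id12 <- co$instances$instance_id[co$instances$p1 == "s1.e1" &
                                     co$instances$p2 == "s1.e2"]
  tk <- blind_tokens(co, id12)
  expect_equal(tk$surface[tk$is_word], c("PROT1", "binds", "PROT2", "or", "PROT"))
  expect_equal(tk$stem[tk$is_word][c(1, 3, 5)], c("prot1", "prot2", "prot"))
  # idempotent: re-blinding blinded tokens changes nothing
  men <- co$mentions
  tk2 <- dkppi:::.blind(tk, men$token_id[1], men$token_id[2], men$token_id)
  expect_identical(tk, tk2)
  # labels are untouched by blinding (it only rewrites token surfaces)
  expect_identical(co$instances$label,
                   toy_corpus("GerE binds CotX or SpoA",
                              list(c("GerE", "CotX", "SpoA")))$instances$label)
})

test_that("parse-tree files validate and key by sentence id", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\t(S (NP (NN P1)) (VP (VBZ is)))"), path)
  tr <- read_parse_trees(path)
  expect_equal(tr$sentence_id, "s1")
  expect_equal(nrow(tree_leaf_paths(tr$tree[1])), 2L)
  writeLines("s1\t(S (NP (NN P1)", path)
  expect_error(read_parse_trees(path), "line 1")
})

test_that("feature matrices round-trip losslessly", {
  fx <- small_synth_features(n = 15, seed = 7)
  f <- fx$features
  f$dk <- sample(0:1, nrow(f), replace = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(f, path)
  back <- read_feature_matrix(path)
  reg <- ppi_feature_names()
  expect_identical(as.data.frame(back[, reg]), as.data.frame(f[, reg]))
  expect_identical(back$label, f$label)
  expect_identical(back$dk, as.integer(f$dk))
  expect_error(write_feature_matrix(f[, 1:5], path), "missing registered")
})
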