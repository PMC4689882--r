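# Shared fixture builders; everything is constructed in code.

# Corpus from one or more sentences; mentions given as the protein surface
# strings to locate (first occurrence each, in order).
toy_corpus <- function(texts, mention_surfaces, positive_pairs = NULL,
                       trees = NULL) {
  sent <- tibble::tibble(
    sentence_id = paste0("s", seq_along(texts)), text = texts,
    tree = if (is.null(trees)) NA_character_ else trees)
  men_rows <- list()
  for (i in seq_along(texts)) {
    offset <- 0L
    for (j in seq_along(mention_surfaces[[i]])) {
      surf <- mention_surfaces[[i]][j]
      at <- regexpr(surf, substr(texts[i], offset + 1L, nchar(texts[i])),
                    fixed = TRUE)
      stopifnot(at > 0)
      start <- offset + as.integer(at) - 1L
      men_rows[[length(men_rows) + 1L]] <- list(
        sentence_id = paste0("s", i), mention_id = paste0("s", i, ".e", j),
        char_start = start, char_end = start + nchar(surf))
      offset <- start + nchar(surf)
    }
  }
  pairs <- NULL
  if (!is.null(positive_pairs)) {
    pairs <- dplyr::bind_rows(lapply(seq_along(positive_pairs), function(i) {
      pp <- positive_pairs[[i]]
      if (is.null(pp)) return(NULL)
      tibble::tibble(sentence_id = paste0("s", i),
                     e1 = paste0("s", i, ".e", pp[1]),
                     e2 = paste0("s", i, ".e", pp[2]),
                     interaction = TRUE)
    }))
  } else {
    pairs <- tibble::tibble(sentence_id = character(), e1 = character(),
                            e2 = character(), interaction = logical())
  }
  ppi_corpus(sent, dplyr::bind_rows(men_rows), pairs)
}

# The Table worked-example sentence with its constituent tree.
driven_tree <-
  "(S (NP (NN P1)) (VP (VBZ is) (VP (VBN driven) (PP (IN by) (NP (NN P2))))))"

driven_corpus <- function(with_tree = TRUE) {
  toy_corpus("P1 is driven by P2", list(c("P1", "P2")),
             positive_pairs = list(c(1, 2)),
             trees = if (with_tree) driven_tree else NULL)
}

features_of <- function(text, mentions, tree = NULL, positive = NULL,
                        lexicon = default_lexicon()) {
  co <- toy_corpus(text, list(mentions),
                   positive_pairs = if (is.null(positive)) NULL else
                     list(positive),
                   trees = tree)
  extract_features(co, lexicon)
}

# ---- independent exhaustive pattern-matching oracle -----------------------
# Enumerates every wildcard span assignment (0..wmax each) at every start
# position; element matching is re-derived here, not shared with the
# package's DP matcher.
oracle_match <- function(spec, stems, lexicon, wmax = 5L) {
  els <- spec$elements
  types <- vapply(els, `[[`, character(1), "type")
  n <- length(stems)
  if (n == 0) return(FALSE)
  el_ok <- function(el, s) {
    switch(el$type,
           p1 = s == "prot1", p2 = s == "prot2",
           iverb = s %in% lexicon$iverb, inoun = s %in% lexicon$inoun,
           lit = s == el$value, alt = s %in% el$value)
  }
  wild_idx <- which(types == "wild")
  fixed_idx <- which(types != "wild")
  combos <- if (length(wild_idx) == 0) matrix(0L, 1, 0) else
    as.matrix(expand.grid(rep(list(0:wmax), length(wild_idx))))
  n_fixed_before <- cumsum(types != "wild") -
    as.integer(types != "wild")  # fixed elements strictly before each slot
  wilds_before <- lapply(seq_along(els), function(j) {
    which(wild_idx < j)
  })
  mv <- vector("list", length(els))
  for (j in fixed_idx) mv[[j]] <- vapply(stems, el_ok, logical(1), el = els[[j]])
  first <- fixed_idx[1]
  starts <- which(mv[[first]])  # element 1 is never a wildcard in the 13 set
  if (types[1] == "wild") starts <- seq_len(n)
  for (start in starts) {
    ok <- rep(TRUE, nrow(combos))
    for (j in fixed_idx) {
      pos <- rep.int(start + n_fixed_before[j], nrow(combos)) +
        (if (length(wilds_before[[j]]) == 0) 0 else
           rowSums(combos[, wilds_before[[j]], drop = FALSE]))
      inb <- pos >= 1 & pos <= n
      ok <- ok & inb
      ok[ok] <- mv[[j]][pos[ok]]
      if (!any(ok)) break
    }
    if (any(ok)) return(TRUE)
  }
  FALSE
}

# random stem sequences for pattern tests (tokens are already stems)
random_pattern_sentence <- function(rng_n = 15) {
  vocab <- c("bind", "interact", "complex", "between", "and", "of", "by",
             "with", "to", "on", "through", "form", "depend", "interaction",
             "the", "a", "cell", "xx", "yy", "prot")
  n <- sample(4:rng_n, 1)
  s <- sample(vocab, n, replace = TRUE)
  i <- sort(sample(n, 2))
  s[i[1]] <- "prot1"; s[i[2]] <- "prot2"
  s
}

# lookup-table learner for forcing classifier behaviour in DK update tests
table_model <- function(pred) {
  structure(list(pred = pred), class = "toy_table_model")
}

table_learner <- ppi_learner(
  fit = function(features, y, seed = 1L) stop("table models are hand-built"),
  predict = function(model, features) {
    factor(unname(model$pred[features$instance_id]),
           levels = c("negative", "positive"))
  },
  name = "table"
)

# small labeled feature tibble with a single keyword column of interest
kw_features <- function(keyword, labels) {
  tibble::tibble(
    instance_id = paste0("i", seq_along(labels)),
    keyword = keyword,
    label = factor(labels, levels = c("negative", "positive"))
  )
}

small_synth_features <- function(n = 120, seed = 42, dominance = 1.0) {
  co <- synth_generate(synth_config(n_sentences = n, dominance = dominance,
                                    seed = seed))
  list(corpus = co, features = extract_features(co))
}

fast_config <- function(...) {
  ppi_config(folds_k = 3L, iterations_m = 2L, cv_folds = 3L,
             num_trees = 25L, ...)
}
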