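# Synthetic corpus generator.
#
# Emulates the statistical structure the dominant-keyword method assumes:
# sentences with two (optionally three) blinded protein mentions, one
# binary label per pair, a designated keyword under which instances are
# positive with probability `dominance` (planted_dk = 1), context-driven
# labels otherwise (planted_dk = 0) with visible negative-class cues, a
# controllable infix/prefix/postfix mix, and a fixed bracketed parse tree
# per template. The generator targets the method's assumptions, not fluent
# biomedical prose.

#' Synthetic corpus configuration
#'
#' @param n_sentences Number of sentences.
#' @param positive_rate Positive-class probability for context-driven
#'   (non-dominant) instances.
#' @param dominance Positive-class probability for instances whose
#'   sentence uses the designated dominant keyword; those instances carry
#'   `planted_dk = 1`. At 1 the keyword's presence forces the positive
#'   label; at `positive_rate` no keyword is dominant.
#' @param position_mix Probabilities of the infix / prefix / postfix
#'   template families; must sum to 1.
#' @param n_distractor_keywords Number of non-dominant keyword families
#'   (max 7).
#' @param p_dominant Probability that a keyword-bearing sentence uses the
#'   positively dominant keyword.
#' @param p_dominant_negative Probability that a keyword-bearing sentence
#'   uses the negatively dominant keyword ("colocalize"), whose instances
#'   are negative with a strength mirroring `dominance`:
#'   `P(positive) = positive_rate * (1 - dominance) / (1 - positive_rate)`,
#'   so `dominance = 1` pins `U` at 0 and `dominance = positive_rate`
#'   recovers the balanced background. Together with `positive_rate` these
#'   defaults keep the corpus negative-biased, as PPI corpora are.
#' @param p_no_keyword Probability of a keyword-less sentence.
#' @param extra_mention_rate Probability that a sentence carries a third
#'   protein mention; its extra pairs are negative with `planted_dk = 0`
#'   while still selecting the sentence keyword, so they dilute the
#'   dominant keyword's unbalance degree below its nominal `dominance`
#'   level. Off by default to keep `U` at its nominal value; raise it to
#'   stress instance enumeration and keyword ambiguity.
#' @param cue_strength Probability that a context-driven negative carries
#'   a visible class cue (a negation word or a comma between the anchors);
#'   below 1 the residual negatives are label noise.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sentences = 600L, positive_rate = 0.3,
                         dominance = 0.9,
                         position_mix = c(infix = 0.6, prefix = 0.2,
                                          postfix = 0.2),
                         n_distractor_keywords = 5L, p_dominant = 0.25,
                         p_dominant_negative = 0.15,
                         p_no_keyword = 0.05, extra_mention_rate = 0,
                         cue_strength = 1.0, seed = 1L) {
  stopifnot(n_sentences >= 1, positive_rate >= 0, positive_rate <= 1,
            dominance >= 0, dominance <= 1,
            p_dominant + p_dominant_negative <= 1,
            n_distractor_keywords >= 1, n_distractor_keywords <= 7)
  if (abs(sum(position_mix) - 1) > 1e-9) {
    stop("position_mix must sum to 1", call. = FALSE)
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 positive_rate = positive_rate, dominance = dominance,
                 position_mix = position_mix,
                 n_distractor_keywords = as.integer(n_distractor_keywords),
                 p_dominant = p_dominant,
                 p_dominant_negative = p_dominant_negative,
                 p_no_keyword = p_no_keyword,
                 extra_mention_rate = extra_mention_rate,
                 cue_strength = cue_strength, seed = as.integer(seed)),
            class = "synth_config")
}

# keyword families: 3rd-person verb and event noun sharing a Porter stem
.synth_families <- list(
  dominant = list(stem = "interact", verb = "interacts", noun = "interaction"),
  dominant_negative = list(stem = "colocal", verb = "colocalizes",
                           noun = "colocalization"),
  distractors = list(
    list(stem = "bind",     verb = "binds",      noun = "binding"),
    list(stem = "associ",   verb = "associates", noun = "association"),
    list(stem = "regul",    verb = "regulates",  noun = "regulation"),
    list(stem = "activ",    verb = "activates",  noun = "activation"),
    list(stem = "inhibit",  verb = "inhibits",   noun = "inhibition"),
    list(stem = "suppress", verb = "suppresses", noun = "suppression"),
    list(stem = "stimul",   verb = "stimulates", noun = "stimulation")
  )
)

.synth_neutral_mods <- c("previously", "recently", "reportedly", "apparently",
                         "partially")
# visible negative-class cues: a negation word (negation flag) or a comma
# between the anchors (comma feature) — both live in the feature encoding
.synth_neg_mods <- c("not", ",")
.synth_noise <- c("novel", "putative", "recombinant", "endogenous", "nuclear",
                  "cytoplasmic", "bacterial", "yeast", "human", "murine",
                  "purified", "truncated", "native", "mutant", "tagged")

.synth_protein_pool <- function() {
  paste0(rep(c("Spo", "Ger", "Cot", "Sig", "Rpo", "Che", "Fli", "Mot", "Deg",
               "Com", "Kin", "Phr", "Rap", "Tag", "Lyt", "Wal", "Res", "Pho",
               "Yfh", "Cwl"), each = 4), c("A", "B", "C", "D"))
}

# templates: token vector with {P1} {P2} {P3} {K} {MOD} {N1} {N2} slots and
# a matching tree whose leaves are exactly the word tokens
.synth_templates <- list(
  list(pos = "infix", kind = "verb", extra = FALSE,
       tokens = c("{P1}", "{MOD}", "{K}", "with", "{P2}"),
       tree = "(S (NP (NN {P1})) (ADVP (RB {MOD})) (VP (VBZ {K}) (PP (IN with) (NP (NN {P2})))))"),
  list(pos = "infix", kind = "verb", extra = FALSE,
       tokens = c("The", "{N1}", "{P1}", "{MOD}", "{K}", "{P2}"),
       tree = "(S (NP (DT The) (JJ {N1}) (NN {P1})) (ADVP (RB {MOD})) (VP (VBZ {K}) (NP (NN {P2}))))"),
  list(pos = "infix", kind = "verb", extra = FALSE,
       tokens = c("{P1}", "{MOD}", "{K}", "the", "{N1}", "{P2}", "in", "{N2}", "cells"),
       tree = "(S (NP (NN {P1})) (ADVP (RB {MOD})) (VP (VBZ {K}) (NP (DT the) (JJ {N1}) (NN {P2})) (PP (IN in) (NP (JJ {N2}) (NNS cells)))))"),
  list(pos = "infix", kind = "verb", extra = FALSE,
       tokens = c("Results", "show", "that", "{P1}", "{MOD}", "{K}", "{P2}"),
       tree = "(S (NP (NNS Results)) (VP (VBP show) (SBAR (IN that) (S (NP (NN {P1})) (ADVP (RB {MOD})) (VP (VBZ {K}) (NP (NN {P2})))))))"),
  list(pos = "infix", kind = "verb", extra = TRUE,
       tokens = c("{P1}", "{MOD}", "{K}", "{P2}", "and", "{P3}"),
       tree = "(S (NP (NN {P1})) (ADVP (RB {MOD})) (VP (VBZ {K}) (NP (NP (NN {P2})) (CC and) (NP (NN {P3})))))"),
  list(pos = "prefix", kind = "noun", extra = FALSE,
       tokens = c("The", "{K}", "of", "{P1}", "{MOD}", "with", "{P2}"),
       tree = "(NP (NP (DT The) (NN {K})) (PP (IN of) (NP (NN {P1}))) (ADVP (RB {MOD})) (PP (IN with) (NP (NN {P2}))))"),
  list(pos = "prefix", kind = "noun", extra = FALSE,
       tokens = c("{K}", "between", "{P1}", "{MOD}", "and", "{P2}", "was", "observed"),
       tree = "(S (NP (NP (NN {K})) (PP (IN between) (NP (NP (NN {P1})) (ADVP (RB {MOD})) (CC and) (NP (NN {P2}))))) (VP (VBD was) (VP (VBN observed))))"),
  list(pos = "prefix", kind = "noun", extra = FALSE,
       tokens = c("{N1}", "analysis", "revealed", "the", "{K}", "of", "{P1}", "{MOD}", "and", "{P2}"),
       tree = "(S (NP (JJ {N1}) (NN analysis)) (VP (VBD revealed) (NP (NP (DT the) (NN {K})) (PP (IN of) (NP (NP (NN {P1})) (ADVP (RB {MOD})) (CC and) (NP (NN {P2})))))))"),
  list(pos = "postfix", kind = "verb", extra = FALSE,
       tokens = c("{P1}", "and", "{P2}", "{MOD}", "{K}"),
       tree = "(S (NP (NP (NN {P1})) (CC and) (NP (NN {P2}))) (ADVP (RB {MOD})) (VP (VBP {K})))"),
  list(pos = "postfix", kind = "verb", extra = FALSE,
       tokens = c("{P1}", "or", "{P2}", "{MOD}", "{K}", "in", "{N1}", "cells"),
       tree = "(S (NP (NP (NN {P1})) (CC or) (NP (NN {P2}))) (ADVP (RB {MOD})) (VP (VBP {K}) (PP (IN in) (NP (JJ {N1}) (NNS cells)))))"),
  list(pos = "postfix", kind = "verb", extra = TRUE,
       tokens = c("{P1}", ",", "{P2}", "and", "{P3}", "{MOD}", "{K}"),
       tree = "(S (NP (NP (NN {P1})) (NP (NN {P2})) (CC and) (NP (NN {P3}))) (ADVP (RB {MOD})) (VP (VBP {K})))"),
  list(pos = "none", kind = "none", extra = FALSE,
       tokens = c("{P1}", "is", "{MOD}", "present", "in", "{P2}", "cultures"),
       tree = "(S (NP (NN {P1})) (VP (VBZ is) (ADVP (RB {MOD})) (ADJP (JJ present)) (PP (IN in) (NP (NN {P2}) (NNS cultures)))))"),
  list(pos = "none", kind = "none", extra = FALSE,
       tokens = c("The", "{N1}", "level", "of", "{P1}", "{MOD}", "and", "{P2}", "was", "unchanged"),
       tree = "(S (NP (NP (DT The) (JJ {N1}) (NN level)) (PP (IN of) (NP (NP (NN {P1})) (ADVP (RB {MOD})) (CC and) (NP (NN {P2}))))) (VP (VBD was) (ADJP (JJ unchanged))))")
)

#' Generate a synthetic PPI corpus with planted DK ground truth
#'
#' Every sentence instantiates a template family drawn from
#' `position_mix`; the designated protein pair's label follows the
#' generative rule — `Bernoulli(dominance)` when the dominant keyword is
#' present (`planted_dk = 1`), otherwise `Bernoulli(positive_rate)`
#' (`planted_dk = 0`); negatives carry visible class cues. Extra mention
#' pairs are negative. Sentences carry template-fixed bracketed parse
#' trees.
#'
#' @param config A [synth_config()].
#' @return A `ppi_synth` corpus (a [ppi_corpus()] with a `planted` tibble
#'   of per-instance `planted_dk` ground truth and the config attached).
#' @export
synth_generate <- function(config = synth_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  distractors <- .synth_families$distractors[
    seq_len(config$n_distractor_keywords)]
  # mirror of `dominance` on the negative side: 0 at dominance = 1, the
  # balanced background at dominance = positive_rate
  p_pos_negdom <- min(1, config$positive_rate * (1 - config$dominance) /
                        max(1 - config$positive_rate, 1e-12))
  pool <- .synth_protein_pool()
  tmpl_pos <- vapply(.synth_templates, `[[`, character(1), "pos")
  tmpl_extra <- vapply(.synth_templates, `[[`, logical(1), "extra")

  sent_rows <- list(); men_rows <- list(); pair_rows <- list()
  planted_rows <- list()

  for (i in seq_len(config$n_sentences)) {
    sid <- sprintf("s%04d", i)
    no_kw <- stats::runif(1) < config$p_no_keyword
    if (no_kw) {
      cand <- which(tmpl_pos == "none")
    } else {
      poscls <- sample(names(config$position_mix), 1,
                       prob = config$position_mix)
      extra <- stats::runif(1) < config$extra_mention_rate
      cand <- which(tmpl_pos == poscls & tmpl_extra == extra)
      if (length(cand) == 0) cand <- which(tmpl_pos == poscls)
    }
    tm <- .synth_templates[[sample(rep(cand, 2), 1)]]

    # keyword + designated-pair label
    kw_kind <- "none"; planted <- 0L
    if (!no_kw) {
      u <- stats::runif(1)
      if (u < config$p_dominant) {
        kw_kind <- "dominant"; fam <- .synth_families$dominant
      } else if (u < config$p_dominant + config$p_dominant_negative) {
        kw_kind <- "dominant_negative"
        fam <- .synth_families$dominant_negative
      } else {
        kw_kind <- "distractor"
        fam <- distractors[[sample(length(distractors), 1)]]
      }
      kw_surface <- if (tm$kind == "noun") fam$noun else fam$verb
    } else kw_surface <- NULL
    if (kw_kind == "dominant") {
      label <- stats::runif(1) < config$dominance
      planted <- 1L
    } else if (kw_kind == "dominant_negative") {
      label <- stats::runif(1) < p_pos_negdom
      planted <- 1L
    } else {
      label <- stats::runif(1) < config$positive_rate
    }
    # context-driven negatives carry a visible cue; dominant-keyword
    # instances never do — there the keyword is the evidence
    if (!label && planted == 0L && stats::runif(1) < config$cue_strength) {
      # keyword-less sentences take the negation word: the comma feature
      # is anchored on the keyword and cannot see a comma cue without one
      mod <- if (no_kw) "not" else
        sample(rep(.synth_neg_mods, 2), 1, prob = c(.6, .4, .6, .4))
    } else {
      mod <- sample(.synth_neutral_mods, 1)
    }

    prots <- sample(pool, 3)
    fills <- c("{P1}" = prots[1], "{P2}" = prots[2], "{P3}" = prots[3],
               "{MOD}" = mod,
               "{N1}" = sample(.synth_noise, 1),
               "{N2}" = sample(.synth_noise, 1))
    if (!is.null(kw_surface)) fills["{K}"] <- kw_surface

    toks <- tm$tokens
    for (sl in names(fills)) toks[toks == sl] <- fills[[sl]]
    tree <- tm$tree
    for (sl in names(fills)) tree <- gsub(sl, fills[[sl]], tree, fixed = TRUE)

    # assemble text + mention offsets; commas attach to the previous token
    text <- ""
    starts <- integer(length(toks))
    for (t in seq_along(toks)) {
      if (toks[t] == ",") { text <- paste0(text, ","); starts[t] <- NA
      } else {
        if (nzchar(text)) text <- paste0(text, " ")
        starts[t] <- nchar(text)
        text <- paste0(text, toks[t])
      }
    }
    text <- paste0(text, ".")

    n_m <- if (tm$extra) 3L else 2L
    slots <- c("{P1}", "{P2}", "{P3}")[seq_len(n_m)]
    for (j in seq_len(n_m)) {
      pos_tok <- which(tm$tokens == slots[j])
      men_rows[[length(men_rows) + 1L]] <- list(
        sentence_id = sid, mention_id = paste0(sid, ".e", j),
        char_start = starts[pos_tok],
        char_end = starts[pos_tok] + nchar(fills[[slots[j]]]))
    }
    pair_rows[[length(pair_rows) + 1L]] <- list(
      sentence_id = sid, e1 = paste0(sid, ".e1"), e2 = paste0(sid, ".e2"),
      interaction = label)
    sent_rows[[length(sent_rows) + 1L]] <- list(sentence_id = sid,
                                                text = text, tree = tree)
    planted_rows[[length(planted_rows) + 1L]] <- list(
      sentence_id = sid, pair = paste0(sid, ".e1|", sid, ".e2"),
      planted_dk = planted)
  }

  corpus <- ppi_corpus(dplyr::bind_rows(sent_rows), dplyr::bind_rows(men_rows),
                       dplyr::bind_rows(pair_rows))
  planted_map <- dplyr::bind_rows(planted_rows)
  planted <- tibble::tibble(
    instance_id = corpus$instances$instance_id,
    planted_dk = 0L
  )
  key <- paste0(corpus$instances$sentence_id, "|",
                corpus$instances$p1, "|", corpus$instances$p2)
  hit <- match(key, paste0(planted_map$sentence_id, "|", planted_map$pair))
  planted$planted_dk[!is.na(hit)] <-
    planted_map$planted_dk[hit[!is.na(hit)]]
  corpus$planted <- planted
  attr(corpus, "synth_config") <- config
  class(corpus) <- c("ppi_synth", class(corpus))
  corpus
}

#' Export a synthetic corpus
#'
#' Writes the unified XML file, the bracketed-tree file, and the planted
#' DK ground truth (CSV) into a directory; the XML/tree pair round-trips
#' through [read_ppi_corpus()].
#'
#' @param corpus A `ppi_synth` corpus.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synth_export <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ppi_corpus(corpus, file.path(dir, "corpus.xml"),
                   trees_path = file.path(dir, "trees.tsv"))
  readr::write_csv(corpus$planted, file.path(dir, "planted_dk.csv"))
  invisible(dir)
}
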