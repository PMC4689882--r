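# Corpus container and unified-XML I/O.
#
# A ppi_corpus keeps four aligned tibbles: sentences, tokens, mentions and
# instances. Instances enumerate every unordered protein-mention pair of a
# sentence (the pair appearing first in token order is P1); pairs without a
# positive annotation are negative, the convention under which the five
# benchmark corpora are distributed.

#' Construct a PPI corpus from tabular parts
#'
#' Tokenizes every sentence around its mentions, enumerates all
#' protein-pair instances and attaches gold labels. This is the common
#' constructor behind [read_ppi_corpus()] and the synthetic generator.
#'
#' @param sentences Tibble with `sentence_id`, `text`, optional `tree`
#'   (bracketed string or `NA`).
#' @param mentions Tibble with `sentence_id`, `mention_id`, `char_start`,
#'   `char_end` (0-based half-open).
#' @param pairs Optional tibble with `sentence_id`, `e1`, `e2` (mention
#'   ids), `interaction` (logical); pairs absent from this table are
#'   negative instances.
#' @return A `ppi_corpus` object.
#' @export
ppi_corpus <- function(sentences, mentions, pairs = NULL) {
  sentences <- tibble::as_tibble(sentences)
  if (!"tree" %in% names(sentences)) sentences$tree <- NA_character_
  mentions <- tibble::as_tibble(mentions)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    unknown <- !(pairs$e1 %in% mentions$mention_id &
                 pairs$e2 %in% mentions$mention_id)
    if (any(unknown)) {
      stop("pair references unknown entity id: ",
           paste(unique(c(pairs$e1, pairs$e2)[c(unknown, unknown)]),
                 collapse = ", "), call. = FALSE)
    }
  }

  tok_list <- vector("list", nrow(sentences))
  men_list <- vector("list", nrow(sentences))
  for (i in seq_len(nrow(sentences))) {
    sid <- sentences$sentence_id[i]
    m <- mentions[mentions$sentence_id == sid, , drop = FALSE]
    tk <- ppi_tokenize(sentences$text[i], m)
    tk$tokens$sentence_id <- sid
    tk$mentions$sentence_id <- if (nrow(tk$mentions)) sid else character()
    tok_list[[i]] <- tk$tokens
    men_list[[i]] <- tk$mentions
  }
  empty_tokens <- tibble::tibble(
    sentence_id = character(), token_id = integer(), surface = character(),
    stem = character(), index = integer(), is_word = logical(),
    n_words = integer(), mention_id = character())
  empty_mentions <- tibble::tibble(
    sentence_id = character(), mention_id = character(),
    char_start = integer(), char_end = integer(), token_id = integer())
  tokens <- dplyr::bind_rows(c(list(empty_tokens), tok_list))
  mentions2 <- dplyr::bind_rows(c(list(empty_mentions), men_list))

  instances <- enumerate_instances(sentences, tokens, mentions2, pairs)

  structure(list(sentences = sentences,
                 tokens = tokens[, c("sentence_id", "token_id", "surface",
                                     "stem", "index", "is_word", "n_words",
                                     "mention_id")],
                 mentions = mentions2,
                 instances = instances),
            class = "ppi_corpus")
}

#' Enumerate protein-pair instances
#'
#' One instance per unordered mention pair within each sentence; sentences
#' with fewer than two mentions yield none, self-pairs are never formed, and
#' repeated occurrences of the same surface pair count separately. P1 is the
#' mention whose collapsed token comes first in token order.
#'
#' @param sentences,tokens,mentions Corpus part tibbles (see [ppi_corpus()]).
#' @param pairs Optional gold-pair tibble (`sentence_id`, `e1`, `e2`,
#'   `interaction`).
#' @return Tibble with `instance_id`, `sentence_id`, `p1`, `p2` (mention
#'   ids, P1 first in token order) and `label`
#'   (factor `negative`/`positive`, `NA` when no pair table is given).
#' @export
enumerate_instances <- function(sentences, tokens, mentions, pairs = NULL) {
  rows <- list()
  for (sid in sentences$sentence_id) {
    m <- mentions[mentions$sentence_id == sid, , drop = FALSE]
    if (nrow(m) < 2) next
    tk <- tokens[tokens$sentence_id == sid, , drop = FALSE]
    m$tok_index <- tk$index[match(m$token_id, tk$token_id)]
    ord <- order(m$tok_index, m$char_start, m$mention_id)
    m <- m[ord, , drop = FALSE]
    cmb <- utils::combn(nrow(m), 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      rows[[length(rows) + 1L]] <- list(
        sentence_id = sid, p1 = m$mention_id[a], p2 = m$mention_id[b])
    }
  }
  inst <- dplyr::bind_rows(rows)
  if (nrow(inst) == 0) {
    return(tibble::tibble(instance_id = character(), sentence_id = character(),
                          p1 = character(), p2 = character(),
                          label = factor(character(),
                                         levels = c("negative", "positive"))))
  }
  inst$instance_id <- paste(inst$sentence_id, inst$p1, inst$p2, sep = "|")
  lab <- rep(NA_character_, nrow(inst))
  if (!is.null(pairs)) {
    lab <- rep("negative", nrow(inst))
    if (nrow(pairs) > 0) {
      key <- function(s, a, b) {
        paste(s, pmin(a, b), pmax(a, b), sep = "\r")
      }
      pos <- pairs[as.logical(pairs$interaction), , drop = FALSE]
      lab[key(inst$sentence_id, inst$p1, inst$p2) %in%
            key(pos$sentence_id, pos$e1, pos$e2)] <- "positive"
    }
  }
  inst$label <- factor(lab, levels = c("negative", "positive"))
  tibble::as_tibble(inst[, c("instance_id", "sentence_id", "p1", "p2", "label")])
}

#' Read a unified PPI XML corpus
#'
#' Parses the corpus/document/sentence/entity/pair interchange schema used
#' by the LLL, HPRD50, IEPA, AImed and BioInfer distributions. Entity
#' `charOffset` attributes are inclusive ranges (`"0-3"` covers characters
#' 0..3) and are converted to the package's 0-based half-open convention;
#' multi-span offsets use the first span. Pairs with `interaction="True"`
#' are positive; all other mention pairs are negative.
#'
#' @param path Path to the XML file.
#' @param trees Optional path to a bracketed-tree file
#'   (see [read_parse_trees()]); trees are attached to sentences by id.
#' @return A [ppi_corpus()] object.
#' @export
read_ppi_corpus <- function(path, trees = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  sent_nodes <- xml2::xml_find_all(doc, ".//sentence")
  sent_rows <- list(); men_rows <- list(); pair_rows <- list()
  for (sn in sent_nodes) {
    sid <- xml2::xml_attr(sn, "id")
    text <- xml2::xml_attr(sn, "text")
    if (is.na(sid) || is.na(text)) {
      stop("sentence element missing id or text attribute", call. = FALSE)
    }
    sent_rows[[length(sent_rows) + 1L]] <- list(sentence_id = sid, text = text)
    for (en in xml2::xml_find_all(sn, "./entity")) {
      off <- xml2::xml_attr(en, "charOffset")
      if (is.na(off)) stop("entity without charOffset in sentence ", sid,
                           call. = FALSE)
      first <- strsplit(off, ",", fixed = TRUE)[[1]][1]
      se <- as.integer(strsplit(first, "-", fixed = TRUE)[[1]])
      men_rows[[length(men_rows) + 1L]] <- list(
        sentence_id = sid, mention_id = xml2::xml_attr(en, "id"),
        char_start = se[1], char_end = se[2] + 1L)
    }
    for (pn in xml2::xml_find_all(sn, "./pair")) {
      pair_rows[[length(pair_rows) + 1L]] <- list(
        sentence_id = sid,
        e1 = xml2::xml_attr(pn, "e1"), e2 = xml2::xml_attr(pn, "e2"),
        interaction = tolower(xml2::xml_attr(pn, "interaction")) == "true")
    }
  }
  sentences <- if (length(sent_rows)) dplyr::bind_rows(sent_rows) else
    tibble::tibble(sentence_id = character(), text = character())
  mentions <- if (length(men_rows)) dplyr::bind_rows(men_rows) else
    tibble::tibble(sentence_id = character(), mention_id = character(),
                   char_start = integer(), char_end = integer())
  pairs <- if (length(pair_rows)) dplyr::bind_rows(pair_rows) else
    tibble::tibble(sentence_id = character(), e1 = character(),
                   e2 = character(), interaction = logical())

  if (!is.null(trees)) {
    tr <- read_parse_trees(trees)
    sentences$tree <- tr$tree[match(sentences$sentence_id, tr$sentence_id)]
  }
  ppi_corpus(sentences, mentions, pairs)
}

#' Write a corpus to unified PPI XML
#'
#' Inverse of [read_ppi_corpus()]: entities are written with inclusive
#' `charOffset` ranges and every instance becomes a `pair` element carrying
#' its label. If sentences have trees, a companion tree file is written.
#'
#' @param corpus A [ppi_corpus()].
#' @param path Output XML path.
#' @param trees_path Optional output path for the bracketed-tree file.
#' @return `path`, invisibly.
#' @export
write_ppi_corpus <- function(corpus, path, trees_path = NULL) {
  root <- xml2::xml_new_root("corpus", source = "dkppi")
  docn <- xml2::xml_add_child(root, "document", id = "d1")
  for (i in seq_len(nrow(corpus$sentences))) {
    sid <- corpus$sentences$sentence_id[i]
    sn <- xml2::xml_add_child(docn, "sentence", id = sid,
                              text = corpus$sentences$text[i])
    m <- corpus$mentions[corpus$mentions$sentence_id == sid, , drop = FALSE]
    for (j in seq_len(nrow(m))) {
      xml2::xml_add_child(sn, "entity", id = m$mention_id[j],
                          charOffset = paste0(m$char_start[j], "-",
                                              m$char_end[j] - 1L),
                          text = substr(corpus$sentences$text[i],
                                        m$char_start[j] + 1L, m$char_end[j]),
                          type = "protein")
    }
    inst <- corpus$instances[corpus$instances$sentence_id == sid, , drop = FALSE]
    for (j in seq_len(nrow(inst))) {
      xml2::xml_add_child(sn, "pair",
                          id = inst$instance_id[j],
                          e1 = inst$p1[j], e2 = inst$p2[j],
                          interaction = ifelse(inst$label[j] == "positive",
                                               "True", "False"))
    }
  }
  xml2::write_xml(root, path)
  if (!is.null(trees_path)) {
    has <- !is.na(corpus$sentences$tree)
    writeLines(paste(corpus$sentences$sentence_id[has],
                     corpus$sentences$tree[has], sep = "\t"), trees_path)
  }
  invisible(path)
}

#' Blind protein names in a sentence's tokens
#'
#' Returns the token table of an instance's sentence with the pair's
#' mentions replaced by `PROT1`/`PROT2` and every other protein mention by
#' `PROT` (stems updated accordingly), so classifiers never see protein
#' surface forms. Blinding is idempotent.
#'
#' @param corpus A [ppi_corpus()].
#' @param instance_id Id of an instance in `corpus$instances`.
#' @return The sentence's token tibble with blinded `surface` and `stem`.
#' @export
blind_tokens <- function(corpus, instance_id) {
  inst <- corpus$instances[corpus$instances$instance_id == instance_id, ,
                           drop = FALSE]
  if (nrow(inst) != 1) stop("unknown instance id: ", instance_id, call. = FALSE)
  tk <- corpus$tokens[corpus$tokens$sentence_id == inst$sentence_id, ,
                      drop = FALSE]
  m <- corpus$mentions[corpus$mentions$sentence_id == inst$sentence_id, ,
                       drop = FALSE]
  .blind(tk, m$token_id[match(inst$p1, m$mention_id)],
         m$token_id[match(inst$p2, m$mention_id)], m$token_id)
}

.blind <- function(tokens, p1_tok, p2_tok, mention_toks) {
  other <- setdiff(mention_toks, c(p1_tok, p2_tok))
  set <- function(tokens, ids, surf) {
    hit <- tokens$token_id %in% ids
    tokens$surface[hit] <- surf
    tokens$stem[hit] <- tolower(surf)
    tokens
  }
  tokens <- set(tokens, p1_tok, "PROT1")
  tokens <- set(tokens, p2_tok, "PROT2")
  set(tokens, other, "PROT")
}

#' @export
print.ppi_corpus <- function(x, ...) {
  lab <- table(x$instances$label)
  cat("<ppi_corpus> ", nrow(x$sentences), " sentences, ",
      nrow(x$mentions), " mentions, ", nrow(x$instances), " instances (",
      lab[["positive"]], " positive / ", lab[["negative"]], " negative), ",
      sum(!is.na(x$sentences$tree)), " parse trees\n", sep = "")
  invisible(x)
}
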