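# Instance feature extraction: the 44-dimensional encoding.
#
# 25 lexical features (keyword identity, three word distances, the keyword
# position expanded to three indicators, the two protein positions, the
# comma configuration, five boolean cue flags, the keyword's preposition,
# the multiple-keyword flag, seven second-keyword flags and the
# parallel-expression flag), 6 parse features (three heights, three
# root-path POS strings) and 13 pattern features. Sentinels: -1 for
# undefined distances/heights, "none" for undefined nominals, FALSE for
# undefined booleans.

.second_words <- c("bind", "interact", "regulate", "induce", "stimulate",
                   "associate", "known")

.parallel_seps <- c("—", "-", "/", "and", "or", "(")

#' The registered feature names
#'
#' @param types If `TRUE`, return a tibble with `name` and `type`
#'   (`nominal`, `integer` or `boolean`) instead of a character vector.
#' @return Character vector of the 44 feature names (or a two-column
#'   tibble).
#' @export
ppi_feature_names <- function(types = FALSE) {
  reg <- tibble::tibble(
    name = c("keyword", "dist_type1", "dist_type2", "dist_type3",
             "pos_infix", "pos_prefix", "pos_postfix",
             "position1", "position2", "comma",
             "negative", "conjunctive", "which", "but", "condition",
             "preposition", "multiple_keywords",
             paste0("second_", .second_words), "parallel",
             "height_p1", "height_p2", "height_k",
             "pos_path_p1", "pos_path_p2", "pos_path_k",
             paste0("pattern", 1:13)),
    type = c("nominal", "integer", "integer", "integer",
             "boolean", "boolean", "boolean",
             "integer", "integer", "nominal",
             rep("boolean", 5),
             "nominal", "boolean",
             rep("boolean", 7), "boolean",
             rep("integer", 3), rep("nominal", 3),
             rep("boolean", 13))
  )
  if (types) reg else reg$name
}

# word distance between two anchors: word tokens strictly between them,
# not counting the instance's own protein tokens
.between_count <- function(a, b, prot = integer()) {
  lo <- min(a, b); hi <- max(a, b)
  max(hi - lo - 1L - sum(prot > lo & prot < hi), 0L)
}

# keyword selection: among non-protein word tokens whose stem is a lexicon
# keyword, minimise distance(P1,K) + distance(P2,K); ties go to the
# leftmost candidate. Returns the word index or NA.
.select_keyword <- function(wt, i1, i2, lexicon) {
  cand <- which(wt$stem %in% lexicon$keywords & is.na(wt$mention_id) &
                  !wt$surface %in% c("PROT1", "PROT2", "PROT"))
  if (length(cand) == 0) return(NA_integer_)
  ik <- wt$index[cand]
  score <- vapply(ik, function(i) {
    .between_count(i, i1, c(i1, i2)) + .between_count(i, i2, c(i1, i2))
  }, integer(1))
  cand <- cand[order(score, ik)]
  wt$index[cand[1]]
}

.keyword_position <- function(ik, i1, i2) {
  if (is.na(ik)) return("none")
  if (i1 < ik && ik < i2) "infix"
  else if (ik < i1) "prefix"
  else "postfix"
}

# comma configuration: order the three anchors by position as A < B < C;
# first letter: comma in gap (A,B), second: comma in gap (B,C)
.comma_feature <- function(tokens, anchors_tid) {
  if (anyNA(anchors_tid)) return("none")
  s <- sort(anchors_tid)
  gap_has_comma <- function(a, b) {
    any(tokens$surface[tokens$token_id > a & tokens$token_id < b] == ",")
  }
  paste0(ifelse(gap_has_comma(s[1], s[2]), "y", "n"),
         ifelse(gap_has_comma(s[2], s[3]), "y", "n"))
}

# cue between the protein names or between the keyword and either protein
.between_flag <- function(wt, stems_set, ik, i1, i2) {
  hit <- wt$index[wt$stem %in% stems_set & !is.na(wt$index)]
  if (length(hit) == 0) return(FALSE)
  spans <- list(sort(c(i1, i2)))
  if (!is.na(ik)) spans <- c(spans, list(sort(c(ik, i1))), list(sort(c(ik, i2))))
  any(vapply(spans, function(sp) any(hit > sp[1] & hit < sp[2]), logical(1)))
}

.extract_one <- function(tokens, p1_tok, p2_tok, mention_toks, tree_paths,
                         lexicon, specs, wildcard_max) {
  tk <- .blind(tokens, p1_tok, p2_tok, mention_toks)
  wt <- tk[tk$is_word, , drop = FALSE]
  i1 <- wt$index[wt$token_id == p1_tok]
  i2 <- wt$index[wt$token_id == p2_tok]

  ik <- .select_keyword(wt, i1, i2, lexicon)
  kw_tid <- if (is.na(ik)) NA_integer_ else wt$token_id[match(ik, wt$index)]
  kw_stem <- if (is.na(ik)) "none" else wt$stem[match(ik, wt$index)]

  pos <- .keyword_position(ik, i1, i2)

  feats <- list(
    keyword = kw_stem,
    dist_type1 = if (is.na(ik)) -1L else .between_count(ik, i1, c(i1, i2)),
    dist_type2 = if (is.na(ik)) -1L else .between_count(ik, i2, c(i1, i2)),
    dist_type3 = .between_count(i1, i2),
    pos_infix = pos == "infix",
    pos_prefix = pos == "prefix",
    pos_postfix = pos == "postfix",
    position1 = i1 + 1L,
    position2 = i2 + 1L,
    comma = .comma_feature(tk, c(kw_tid, p1_tok, p2_tok)),
    negative = .between_flag(wt, lexicon$negative, ik, i1, i2),
    conjunctive = any(wt$stem %in% lexicon$conjunctive),
    which = any(wt$stem == "which"),
    but = any(wt$stem == "but"),
    condition = .between_flag(wt, lexicon$condition, ik, i1, i2)
  )

  # preposition following the keyword within a between-word distance of 3
  prep <- "none"
  if (!is.na(ik)) {
    after <- wt[!is.na(wt$index) & wt$index > ik &
                  (wt$index - ik - 1L) <= 3L & wt$stem %in% lexicon$prepositions, ,
                drop = FALSE]
    if (nrow(after) > 0) prep <- after$stem[which.min(after$index)]
  }
  feats$preposition <- prep

  kw_tokens <- wt$stem %in% lexicon$keywords & is.na(wt$mention_id) &
    !wt$surface %in% c("PROT1", "PROT2", "PROT")
  feats$multiple_keywords <- sum(kw_tokens) >= 2L

  second_stems <- porter_stem(.second_words)
  lo <- min(i1, i2); hi <- max(i1, i2)
  between_stems <- wt$stem[!is.na(wt$index) & wt$index > lo & wt$index < hi]
  for (j in seq_along(.second_words)) {
    feats[[paste0("second_", .second_words[j])]] <-
      second_stems[j] %in% between_stems && second_stems[j] != kw_stem
  }

  sep <- tk[tk$token_id > min(p1_tok, p2_tok) & tk$token_id < max(p1_tok, p2_tok), ,
            drop = FALSE]
  feats$parallel <- nrow(sep) == 0 ||
    all(tolower(sep$surface) %in% .parallel_seps)

  # parse features
  if (is.null(tree_paths)) {
    feats$height_p1 <- -1L; feats$height_p2 <- -1L; feats$height_k <- -1L
    feats$pos_path_p1 <- "none"; feats$pos_path_p2 <- "none"
    feats$pos_path_k <- "none"
  } else {
    leaf_of <- attr(tree_paths, "leaf_of_index")
    pick <- function(i) {
      if (is.na(i)) return(list(h = -1L, p = "none"))
      l <- leaf_of[i + 1L]
      if (is.na(l)) return(list(h = -1L, p = "none"))
      list(h = tree_paths$height[l], p = tree_paths$path[l])
    }
    a <- pick(i1); b <- pick(i2); k <- pick(ik)
    feats$height_p1 <- a$h; feats$height_p2 <- b$h; feats$height_k <- k$h
    feats$pos_path_p1 <- a$p; feats$pos_path_p2 <- b$p; feats$pos_path_k <- k$p
  }

  pv <- pattern_vector(wt$stem, specs, lexicon, wildcard_max)
  feats[names(pv)] <- as.list(pv)
  feats
}

# Align a sentence's tree leaves with its word tokens: punctuation-only
# leaves are skipped; a collapsed multi-word mention absorbs as many leaves
# as its surface has words and takes the last (head) leaf. Returns the
# leaf-path tibble with attribute `leaf_of_index` (word index + 1 -> leaf
# row), or NULL when alignment fails (features degrade to sentinels).
.align_tree <- function(tree_string, wt) {
  paths <- tryCatch(tree_leaf_paths(tree_string), error = function(e) NULL)
  if (is.null(paths)) return(NULL)
  keep <- !grepl("^[[:punct:]]+$", paths$word)
  paths <- paths[keep, , drop = FALSE]
  if (sum(wt$n_words) != nrow(paths)) return(NULL)
  leaf_of <- integer(nrow(wt))
  l <- 0L
  for (r in seq_len(nrow(wt))) {
    l <- l + wt$n_words[r]
    leaf_of[r] <- l
  }
  attr(paths, "leaf_of_index") <- leaf_of[order(wt$index)]
  paths
}

#' Extract the 44-feature encoding for every instance of a corpus
#'
#' Blinds each instance's protein names, selects its keyword, and computes
#' the lexical, parse-tree and pattern features. Instances whose sentence
#' has no (alignable) parse tree receive sentinel values for the six parse
#' features.
#'
#' @param corpus A [ppi_corpus()].
#' @param lexicon A [ppi_lexicon()]; defaults to the shipped lexicon.
#' @param wildcard_max Wildcard span bound for pattern matching.
#' @return A tibble with `instance_id`, `sentence_id`, `label` and the 44
#'   registered feature columns, one row per instance.
#' @export
extract_features <- function(corpus, lexicon = default_lexicon(),
                             wildcard_max = 5L) {
  specs <- ppi_patterns(lexicon)
  inst <- corpus$instances
  tok_split <- split(corpus$tokens, corpus$tokens$sentence_id)
  men_split <- split(corpus$mentions, corpus$mentions$sentence_id)
  tree_of <- stats::setNames(corpus$sentences$tree, corpus$sentences$sentence_id)

  tree_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(inst))
  for (i in seq_len(nrow(inst))) {
    sid <- inst$sentence_id[i]
    tk <- tok_split[[sid]]
    m <- men_split[[sid]]
    p1_tok <- m$token_id[match(inst$p1[i], m$mention_id)]
    p2_tok <- m$token_id[match(inst$p2[i], m$mention_id)]

    tp <- NULL
    tr <- tree_of[[sid]]
    if (!is.na(tr)) {
      if (!is.null(tree_cache[[sid]])) {
        tp <- tree_cache[[sid]]
        if (identical(tp, FALSE)) tp <- NULL
      } else {
        tp <- .align_tree(tr, tk[tk$is_word, , drop = FALSE])
        tree_cache[[sid]] <- if (is.null(tp)) FALSE else tp
      }
    }

    rows[[i]] <- c(list(instance_id = inst$instance_id[i], sentence_id = sid),
                   .extract_one(tk, p1_tok, p2_tok, m$token_id, tp,
                                lexicon, specs, wildcard_max))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    reg <- ppi_feature_names(types = TRUE)
    out <- tibble::tibble(instance_id = character(), sentence_id = character())
    for (i in seq_len(nrow(reg))) {
      out[[reg$name[i]]] <- switch(reg$type[i], nominal = character(),
                                   integer = integer(), boolean = logical())
    }
  }
  out$label <- inst$label[match(out$instance_id, inst$instance_id)]
  dplyr::relocate(out, "instance_id", "sentence_id", "label")
}

#' Write / read a feature matrix as CSV
#'
#' The CSV carries `instance_id`, `label`, `dk` and the 44 registered
#' feature columns; the round trip is lossless on names and values.
#'
#' @param features A feature tibble from [extract_features()], optionally
#'   with a `dk` column.
#' @param path CSV path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the feature tibble.
#' @export
write_feature_matrix <- function(features, path) {
  reg <- ppi_feature_names()
  missing <- setdiff(reg, names(features))
  if (length(missing) > 0) {
    stop("feature matrix is missing registered features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- features
  if (!"dk" %in% names(out)) out$dk <- NA_integer_
  out$label <- as.character(out$label)
  readr::write_csv(out[, c("instance_id", "label", "dk", reg)], path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  reg <- ppi_feature_names(types = TRUE)
  cols <- c(list(instance_id = readr::col_character(),
                 label = readr::col_character(),
                 dk = readr::col_integer()),
            stats::setNames(lapply(reg$type, function(t) {
              switch(t, nominal = readr::col_character(),
                     integer = readr::col_integer(),
                     boolean = readr::col_logical())
            }), reg$name))
  out <- readr::read_csv(path, col_types = do.call(readr::cols, cols))
  out$label <- factor(out$label, levels = c("negative", "positive"))
  out
}
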