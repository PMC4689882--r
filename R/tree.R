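# Bracketed (Penn-Treebank-style) constituent trees.
#
# The parse features need, per leaf, the label path from the root down to
# the preterminal (POS tag): the root label itself is excluded, the
# preterminal included, the terminal word excluded. A leaf's height is the
# length of that path.

#' Parse a bracketed constituent tree
#'
#' @param s A bracketed tree string, e.g.
#'   `"(S (NP (NN P1)) (VP (VBZ is)))"`.
#' @return A nested list: internal nodes are `list(label, children)`, leaves
#'   are `list(label, word)` where `label` is the preterminal POS tag.
#' @export
parse_bracketed_tree <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  n <- length(toks)
  parse_node <- function() {
    if (pos > n || toks[pos] != "(") stop("expected '('", call. = FALSE)
    pos <<- pos + 1L
    if (pos > n) stop("unbalanced brackets", call. = FALSE)
    label <- toks[pos]; pos <<- pos + 1L
    children <- list()
    word <- NULL
    while (pos <= n && toks[pos] != ")") {
      if (toks[pos] == "(") {
        children[[length(children) + 1L]] <- parse_node()
      } else {
        word <- toks[pos]; pos <<- pos + 1L
      }
    }
    if (pos > n) stop("unbalanced brackets", call. = FALSE)
    pos <<- pos + 1L  # consume ')'
    if (length(children) > 0) list(label = label, children = children)
    else list(label = label, word = if (is.null(word)) "" else word)
  }
  node <- parse_node()
  if (pos <= n) stop("unbalanced brackets: trailing input", call. = FALSE)
  node
}

#' Root-to-preterminal label paths for every leaf
#'
#' Walks a parsed tree and returns one row per terminal, with the label path
#' from the child of the root down to (and including) the preterminal. The
#' height of a leaf is the number of labels on that path, so
#' `height == lengths of path` holds by construction.
#'
#' @param tree A tree from [parse_bracketed_tree()] (or a bracketed string).
#' @return A tibble with columns `leaf` (1-based leaf order), `word`,
#'   `path` (comma-joined labels) and `height`.
#' @export
tree_leaf_paths <- function(tree) {
  if (is.character(tree)) tree <- parse_bracketed_tree(tree)
  rows <- list()
  walk <- function(node, path) {
    if (!is.null(node$word)) {
      rows[[length(rows) + 1L]] <<- list(word = node$word,
                                         path = c(path, node$label))
      return(invisible())
    }
    for (ch in node$children) walk(ch, c(path, node$label))
  }
  # root label excluded: start children walks below the root
  if (!is.null(tree$word)) {
    rows[[1L]] <- list(word = tree$word, path = tree$label)
  } else {
    for (ch in tree$children) walk(ch, character())
  }
  tibble::tibble(
    leaf = seq_along(rows),
    word = vapply(rows, function(r) r$word, character(1)),
    path = vapply(rows, function(r) paste(r$path, collapse = ","), character(1)),
    height = vapply(rows, function(r) length(r$path), integer(1))
  )
}

#' Attach parse trees produced by an external parser
#'
#' Adapter hook for corpora without tree files: applies a callable with
#' the contract *sentence string -> bracketed tree string* to every
#' sentence lacking a tree, validating each result.
#'
#' @param corpus A `ppi_corpus`.
#' @param parser `function(text)` returning a bracketed tree string.
#' @return The corpus with its `tree` column filled in.
#' @export
add_parse_trees <- function(corpus, parser) {
  miss <- which(is.na(corpus$sentences$tree))
  for (i in miss) {
    tr <- parser(corpus$sentences$text[i])
    parse_bracketed_tree(tr)  # validate
    corpus$sentences$tree[i] <- tr
  }
  corpus
}

#' Read a file of bracketed parse trees
#'
#' One tree per line in the format `<sentence-id>\t<bracketed tree>`.
#' Malformed trees raise an error naming the offending line.
#'
#' @param path Path to a tree file.
#' @return A tibble with columns `sentence_id` and `tree` (the bracketed
#'   string, validated by parsing).
#' @export
read_parse_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(length(lines)); trees <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      stop("line ", i, ": expected '<sentence-id>\\t<tree>'", call. = FALSE)
    }
    ids[i] <- parts[1]
    trees[i] <- paste(parts[-1], collapse = "\t")
    tryCatch(parse_bracketed_tree(trees[i]),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  }
  tibble::tibble(sentence_id = ids, tree = trees)
}
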