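# Sentence tokenisation with mention protection.
#
# Word-distance features count *word* tokens only: standalone punctuation
# (commas, semicolons, parentheses, brackets, slashes, dashes) is emitted as
# is_word = FALSE tokens so it can still be inspected (comma feature,
# parallel-expression separators) without entering any distance. Each
# protein mention is collapsed to a single word token regardless of how many
# words its surface form spans.

.punct_keep <- c(",", ";", "(", ")", "[", "]", "{", "}", "/", "—")
.punct_drop <- c(".", "!", "?", ":", "\"", "'", "’", "“", "”")

.split_chunk <- function(chunk) {
  items <- strsplit(chunk, "\\s+")[[1]]
  items <- items[nzchar(items)]
  out <- list()
  for (it in items) {
    pre <- character(); post <- character()
    repeat {
      ch <- substr(it, 1L, 1L)
      if (nchar(it) > 1L && ch %in% c(.punct_keep, .punct_drop)) {
        pre <- c(pre, ch); it <- substr(it, 2L, nchar(it))
      } else break
    }
    repeat {
      n <- nchar(it)
      ch <- substr(it, n, n)
      if (n > 1L && ch %in% c(.punct_keep, .punct_drop)) {
        post <- c(ch, post); it <- substr(it, 1L, n - 1L)
      } else break
    }
    emit <- function(ch) {
      if (ch %in% .punct_keep) list(surface = ch, is_word = FALSE) else NULL
    }
    for (ch in pre) out <- c(out, list(emit(ch)))
    if (nchar(it) == 1L && it %in% c(.punct_keep, .punct_drop)) {
      out <- c(out, list(emit(it)))
    } else if (nzchar(it)) {
      # split embedded slash / em-dash, keeping separators as punctuation
      parts <- strsplit(it, "(?=[/—])|(?<=[/—])", perl = TRUE)[[1]]
      for (p in parts) {
        if (p %in% c("/", "—")) {
          out <- c(out, list(list(surface = p, is_word = FALSE)))
        } else if (nzchar(p)) {
          out <- c(out, list(list(surface = p, is_word = TRUE)))
        }
      }
    }
    for (ch in post) out <- c(out, list(emit(ch)))
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Tokenize a sentence around annotated protein mentions
#'
#' Splits a raw sentence into word and punctuation tokens while collapsing
#' every protein mention (given as 0-based half-open character offsets) to a
#' single word token. Word tokens receive consecutive 0-based indices
#' (`index`); punctuation tokens carry `index = NA` and never contribute to
#' word distances. Stems come from [porter_stem()].
#'
#' @param text Sentence string.
#' @param mentions Data frame with columns `mention_id`, `char_start`,
#'   `char_end` (0-based half-open offsets into `text`). May be empty.
#' @return A list with `tokens` (tibble: `token_id`, `surface`, `stem`,
#'   `index`, `is_word`, `n_words`, `mention_id`) and `mentions` (the input
#'   plus a `token_id` column locating each mention's collapsed token).
#' @export
ppi_tokenize <- function(text, mentions = NULL) {
  if (is.null(mentions)) {
    mentions <- tibble::tibble(mention_id = character(),
                               char_start = integer(), char_end = integer())
  }
  nt <- nchar(text)
  if (nrow(mentions) > 0) {
    bad <- mentions$char_start < 0 | mentions$char_end > nt |
      mentions$char_start >= mentions$char_end
    if (any(bad)) {
      stop("mention offsets outside sentence text: ",
           paste(mentions$mention_id[bad], collapse = ", "), call. = FALSE)
    }
  }

  # Greedy left-to-right protection of non-overlapping spans; a mention fully
  # nested in an accepted span shares its token, partial overlap is an error.
  m <- mentions[order(mentions$char_start, -(mentions$char_end)), , drop = FALSE]
  spans <- list()
  owner <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    s <- m$char_start[i]; e <- m$char_end[i]
    placed <- FALSE
    for (j in seq_along(spans)) {
      sp <- spans[[j]]
      if (s >= sp[1] && e <= sp[2]) { owner[i] <- j; placed <- TRUE; break }
      if (s < sp[2] && e > sp[1]) {
        stop("mention ", m$mention_id[i],
             " partially overlaps another mention", call. = FALSE)
      }
    }
    if (!placed) {
      spans[[length(spans) + 1L]] <- c(s, e)
      owner[i] <- length(spans)
    }
  }
  # mention boundaries must not cut through an alphanumeric run
  is_alnum <- function(pos) {
    pos >= 0 && pos < nt && grepl("[[:alnum:]]", substr(text, pos + 1L, pos + 1L))
  }
  for (sp in spans) {
    if (is_alnum(sp[1] - 1L) || is_alnum(sp[2])) {
      stop("mention offsets cross a token boundary at chars ",
           sp[1], "-", sp[2], call. = FALSE)
    }
  }

  ord <- order(vapply(spans, `[`, numeric(1), 1L))
  spans <- spans[ord]
  owner <- match(owner, ord)

  toks <- list()
  span_token <- integer(length(spans))
  cursor <- 0L
  add_chunk <- function(from, to) {
    if (to > from) {
      chunk <- substr(text, from + 1L, to)
      for (t in .split_chunk(chunk)) toks[[length(toks) + 1L]] <<- t
    }
  }
  for (j in seq_along(spans)) {
    sp <- spans[[j]]
    add_chunk(cursor, sp[1])
    surf <- substr(text, sp[1] + 1L, sp[2])
    toks[[length(toks) + 1L]] <- list(
      surface = surf, is_word = TRUE,
      n_words = length(strsplit(trimws(surf), "\\s+")[[1]]), span = j)
    span_token[j] <- length(toks)
    cursor <- sp[2]
  }
  add_chunk(cursor, nt)

  n <- length(toks)
  tokens <- tibble::tibble(
    token_id = seq_len(n),
    surface  = vapply(toks, function(t) t$surface, character(1)),
    is_word  = vapply(toks, function(t) isTRUE(t$is_word), logical(1)),
    n_words  = vapply(toks, function(t) if (is.null(t$n_words)) 1L else t$n_words,
                      integer(1))
  )
  tokens$stem <- ifelse(tokens$is_word, porter_stem(tokens$surface), tokens$surface)
  tokens$index <- NA_integer_
  tokens$index[tokens$is_word] <- seq_len(sum(tokens$is_word)) - 1L
  tokens$mention_id <- NA_character_

  men_token <- integer(nrow(m))
  if (nrow(m) > 0) {
    men_token <- span_token[owner]
    # first (outermost) mention of a span names the token
    for (j in seq_along(spans)) {
      first <- which(owner == j)[1]
      tokens$mention_id[span_token[j]] <- m$mention_id[first]
    }
  }
  mentions_out <- m
  mentions_out$token_id <- men_token
  mentions_out <- mentions_out[match(mentions$mention_id, mentions_out$mention_id), ,
                               drop = FALSE]
  list(tokens = tokens[, c("token_id", "surface", "stem", "index", "is_word",
                           "n_words", "mention_id")],
       mentions = tibble::as_tibble(mentions_out))
}
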