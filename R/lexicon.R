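#' Keyword lexicon for PPI feature extraction
#'
#' A `ppi_lexicon` bundles the stem sets that drive feature extraction: the
#' keyword set (candidate interaction triggers), the interaction verb and
#' noun subsets used by the structure patterns, the seven second keywords,
#' negation cues, the sixteen conjunctive words, condition cues, and a
#' closed preposition set. All sets are stored as Porter stems; membership
#' tests against sentence tokens therefore go through [porter_stem()] on
#' both sides.
#'
#' @param keywords,iverb,inoun,second,negative,conjunctive,condition,prepositions
#'   Character vectors of words; each is lowercased and stemmed. `iverb`,
#'   `inoun` and `second` are folded into `keywords` so the invariant
#'   `second` ⊆ `keywords` and `iverb` ∪ `inoun` ⊆ `keywords` always holds.
#' @return An object of class `ppi_lexicon`: a named list of stem sets.
#' @seealso [default_lexicon()], [read_lexicon()]
#' @export
ppi_lexicon <- function(keywords, iverb = character(), inoun = character(),
                        second = character(), negative = character(),
                        conjunctive = character(), condition = character(),
                        prepositions = character()) {
  st <- function(x) unique(porter_stem(x))
  iverb <- st(iverb); inoun <- st(inoun); second <- st(second)
  lex <- structure(list(
    keywords     = unique(c(st(keywords), iverb, inoun, second)),
    iverb        = iverb,
    inoun        = inoun,
    second       = second,
    negative     = st(negative),
    conjunctive  = st(conjunctive),
    condition    = st(condition),
    prepositions = st(prepositions)
  ), class = "ppi_lexicon")
  lex
}

#' Read a lexicon file
#'
#' Parses the plain-text sectioned lexicon format: one entry per line,
#' section headers `[keywords] [iverb] [inoun] [second] [negative]
#' [conjunctive] [condition] [prepositions]`, `#` comments and blank lines
#' ignored. Entries are stemmed at load time.
#'
#' @param path Path to a lexicon file.
#' @return A [ppi_lexicon()] object.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  secs <- c("keywords", "iverb", "inoun", "second", "negative",
            "conjunctive", "condition", "prepositions")
  out <- stats::setNames(vector("list", length(secs)), secs)
  out[] <- list(character())
  cur <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      cur <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!cur %in% secs) {
        stop("unknown lexicon section [", cur, "] in ", path, call. = FALSE)
      }
    } else {
      if (is.null(cur)) stop("lexicon entry before any section header: ", ln,
                             call. = FALSE)
      out[[cur]] <- c(out[[cur]], tolower(ln))
    }
  }
  do.call(ppi_lexicon, out)
}

#' The shipped default lexicon
#'
#' Loads the interaction verb/noun lexicon distributed with the package
#' (`inst/extdata/lexicon_default.txt`), a curated list assembled from the
#' interaction-trigger vocabulary of the PPI extraction literature. The
#' result is cached for the session.
#'
#' @return A [ppi_lexicon()] object.
#' @export
default_lexicon <- function() {
  cached <- .dkppi_env$default_lexicon
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "lexicon_default.txt", package = "dkppi")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "lexicon_default.txt")
  lex <- read_lexicon(path)
  .dkppi_env$default_lexicon <- lex
  lex
}

.dkppi_env <- new.env(parent = emptyenv())

#' @export
print.ppi_lexicon <- function(x, ...) {
  cat("<ppi_lexicon>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %d stems\n", nm, length(x[[nm]])))
  invisible(x)
}
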