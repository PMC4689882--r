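# The thirteen structure patterns.
#
# Each pattern is an ordered element list over {P1, P2, iVerb, iNoun,
# literal, alternative literals, wildcard}. A wildcard spans 0-5 word
# tokens; literals, iVerb and iNoun members match by Porter stem; P1/P2
# match the blinded placeholders. A pattern matches an instance when its
# element sequence matches some contiguous run of the blinded word tokens.

.pat_el <- function(type, value = NULL) list(type = type, value = value)
.P1 <- .pat_el("p1"); .P2 <- .pat_el("p2")
.IV <- .pat_el("iverb"); .IN <- .pat_el("inoun"); .W <- .pat_el("wild")
.L <- function(w) .pat_el("lit", porter_stem(w))
.A <- function(...) .pat_el("alt", porter_stem(c(...)))

#' Compile the thirteen PPI structure patterns
#'
#' Builds the built-in pattern set. Bracketed alternatives
#' (`[by|through]`, `[with|to|on]`) become alternative-literal elements;
#' the interaction-verb and -noun elements take their stem sets from the
#' lexicon.
#'
#' @param lexicon A [ppi_lexicon()] (only `iverb`/`inoun` are consulted, at
#'   match time).
#' @return A list of 13 pattern specs (`id`, `elements`).
#' @export
ppi_patterns <- function(lexicon = default_lexicon()) {
  specs <- list(
    list(.P1, .W, .IV, .W, .P2),
    list(.P1, .W, .IV, .W, .L("by"), .W, .P2),
    list(.IV, .L("of"), .W, .P1, .W, .L("by"), .W, .P2),
    list(.IV, .L("of"), .W, .P1, .W, .L("to"), .W, .P2),
    list(.IN, .L("of"), .W, .P1, .W, .A("by", "through"), .W, .P2),
    list(.IN, .L("of"), .W, .P1, .W, .A("with", "to", "on"), .W, .P2),
    list(.IN, .L("between"), .W, .P1, .W, .L("and"), .W, .P2),
    list(.L("complex"), .L("between"), .W, .P1, .W, .L("and"), .W, .P2),
    list(.L("complex"), .L("of"), .W, .P1, .W, .L("and"), .W, .P2),
    list(.P1, .W, .L("form"), .W, .L("complex"), .L("with"), .W, .IV, .W, .P2),
    list(.P1, .W, .P2, .W, .IN),
    list(.P1, .L("depend"), .L("of"), .P2),
    list(.L("between"), .P1, .L("and"), .P2)
  )
  lapply(seq_along(specs), function(i) list(id = i, elements = specs[[i]]))
}

#' Read patterns from a file
#'
#' One pattern per line: whitespace-separated elements where `P1`/`P2`
#' match the blinded pair, `IVERB`/`INOUN` the lexicon stem sets, `*` a
#' bounded wildcard, `[a|b]` alternative literals, and anything else a
#' stem-matched literal. Blank lines and `#` comments are ignored.
#' Patterns are numbered in file order.
#'
#' @param path Path to a pattern file.
#' @return A pattern list as from [ppi_patterns()].
#' @export
read_patterns <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\\s+")[[1]]
    els <- lapply(parts, function(p) {
      if (p == "P1") .P1
      else if (p == "P2") .P2
      else if (p == "IVERB") .IV
      else if (p == "INOUN") .IN
      else if (p == "*") .W
      else if (grepl("^\\[.+\\]$", p)) {
        do.call(.A, as.list(strsplit(sub("^\\[(.+)\\]$", "\\1", p),
                                     "|", fixed = TRUE)[[1]]))
      } else .L(p)
    })
    list(id = i, elements = els)
  })
}

.element_match_vec <- function(el, stems, lexicon) {
  switch(el$type,
    p1    = stems == "prot1",
    p2    = stems == "prot2",
    iverb = stems %in% lexicon$iverb,
    inoun = stems %in% lexicon$inoun,
    lit   = stems == el$value,
    alt   = stems %in% el$value,
    stop("wildcard has no single-token match", call. = FALSE)
  )
}

#' Match one pattern against blinded word-token stems
#'
#' Dynamic-programming matcher: `reach[e, t]` holds when elements `e..E`
#' can match starting at token `t`; wildcards try spans `0..wildcard_max`.
#' A match may start and end anywhere in the token sequence.
#'
#' @param spec One pattern from [ppi_patterns()].
#' @param stems Character vector of blinded word-token stems (with `prot1`,
#'   `prot2`, `prot` placeholders).
#' @param lexicon A [ppi_lexicon()] supplying the iVerb/iNoun stem sets.
#' @param wildcard_max Maximum number of words a wildcard may absorb
#'   (default 5).
#' @return Logical scalar.
#' @export
match_ppi_pattern <- function(spec, stems, lexicon = default_lexicon(),
                              wildcard_max = 5L) {
  els <- spec$elements
  E <- length(els); n <- length(stems)
  if (n == 0) return(FALSE)
  # reach[e, t]: elements e..E match starting at position t (t in 1..n+1)
  reach <- matrix(FALSE, nrow = E + 1L, ncol = n + 2L)
  reach[E + 1L, ] <- TRUE  # all elements consumed; trailing tokens allowed
  for (e in E:1) {
    el <- els[[e]]
    if (el$type == "wild") {
      for (t in 1:(n + 1L)) {
        hi <- min(wildcard_max, n + 1L - t)
        reach[e, t] <- any(reach[e + 1L, t + 0:hi])
      }
    } else {
      mv <- .element_match_vec(el, stems, lexicon)
      reach[e, 1:n] <- mv & reach[e + 1L, 2:(n + 1L)]
    }
  }
  any(reach[1L, 1:n])
}

#' Pattern feature vector for an instance
#'
#' @param stems Blinded word-token stems of the instance's sentence.
#' @param specs Pattern list from [ppi_patterns()].
#' @param lexicon A [ppi_lexicon()].
#' @param wildcard_max Wildcard span bound.
#' @return Named logical vector `pattern1`..`pattern13` (in pattern order).
#' @export
pattern_vector <- function(stems, specs = ppi_patterns(),
                           lexicon = default_lexicon(), wildcard_max = 5L) {
  v <- vapply(specs, match_ppi_pattern, logical(1), stems = stems,
              lexicon = lexicon, wildcard_max = wildcard_max)
  names(v) <- paste0("pattern", vapply(specs, `[[`, integer(1), "id"))
  v
}
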