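# Porter suffix-stripping stemmer (the classic 1980 five-step algorithm).
# Keyword, pattern-literal, and preposition membership are all defined over
# stems, so the stemmer is a first-class, tested primitive here.

# A letter is a consonant unless it is a/e/i/o/u, or a 'y' preceded by a
# consonant (word-initial 'y' is a consonant).
.porter_cv <- function(chars) {
  n <- length(chars)
  cv <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    cv[i] <- if (ch %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (ch == "y") {
      if (i == 1L) TRUE else cv[i - 1L]  # cons iff previous is vowel
    } else {
      TRUE
    }
  }
  cv
}

# m = number of VC sequences in the [C](VC)^m[V] decomposition of `stem`
.porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cv <- .porter_cv(strsplit(stem, "", fixed = TRUE)[[1]])
  r <- rle(cv)$values
  if (length(r) < 2L) return(0L)
  sum(!r[-length(r)] & r[-1L])
}

.porter_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.porter_cv(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  cv <- .porter_cv(strsplit(word, "", fixed = TRUE)[[1]])
  cv[n]
}

# *o: stem ends consonant-vowel-consonant where the final consonant is not
# w, x or y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cv <- .porter_cv(strsplit(word, "", fixed = TRUE)[[1]])
  cv[n - 2L] && !cv[n - 1L] && cv[n] && !substr(word, n, n) %in% c("w", "x", "y")
}

.ends <- function(word, suffix) {
  nw <- nchar(word); ns <- nchar(suffix)
  nw > ns && substr(word, nw - ns + 1L, nw) == suffix
}

.chop <- function(word, n) substr(word, 1L, nchar(word) - n)

# Apply the longest matching (suffix -> replacement) rule whose measure
# condition holds on the remaining stem; within a Porter step only the
# longest matching suffix is ever considered.
.porter_rule_step <- function(word, rules, min_m) {
  ns <- nchar(names(rules))
  for (i in order(ns, decreasing = TRUE)) {
    suf <- names(rules)[i]
    if (.ends(word, suf)) {
      stem <- .chop(word, nchar(suf))
      if (.porter_m(stem) > min_m) {
        return(paste0(stem, rules[[i]]))
      }
      return(word)
    }
  }
  word
}

.porter1 <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # Step 1a
  if (.ends(word, "sses")) {
    word <- .chop(word, 2L)
  } else if (.ends(word, "ies")) {
    word <- paste0(.chop(word, 3L), "i")
  } else if (!.ends(word, "ss") && .ends(word, "s")) {
    word <- .chop(word, 1L)
  }

  # Step 1b
  fired <- FALSE
  if (.ends(word, "eed")) {
    if (.porter_m(.chop(word, 3L)) > 0L) word <- .chop(word, 1L)
  } else if (.ends(word, "ed") && .porter_has_vowel(.chop(word, 2L))) {
    word <- .chop(word, 2L); fired <- TRUE
  } else if (.ends(word, "ing") && .porter_has_vowel(.chop(word, 3L))) {
    word <- .chop(word, 3L); fired <- TRUE
  }
  if (fired) {
    if (.ends(word, "at") || .ends(word, "bl") || .ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_double_cons(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- .chop(word, 1L)
    } else if (.porter_m(word) == 1L && .porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c
  if (.ends(word, "y") && .porter_has_vowel(.chop(word, 1L))) {
    word <- paste0(.chop(word, 1L), "i")
  }

  # Step 2 (m > 0)
  word <- .porter_rule_step(word, c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble", logi = "log"
  ), 0L)

  # Step 3 (m > 0)
  word <- .porter_rule_step(word, c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  ), 0L)

  # Step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  suf4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  for (suf in suf4[order(nchar(suf4), decreasing = TRUE)]) {
    if (.ends(word, suf)) {
      stem <- .chop(word, nchar(suf))
      ok <- .porter_m(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (.ends(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) word <- stem
  }

  # Step 5b
  if (.porter_m(word) > 1L && .porter_double_cons(word) &&
      .ends(word, "l")) {
    word <- .chop(word, 1L)
  }

  word
}

#' Stem words with the Porter algorithm
#'
#' Lowercases and stems a character vector with the classic five-step Porter
#' suffix stripper. All lexicon membership tests in the package (keywords,
#' interaction verbs/nouns, pattern literals, prepositions) operate on these
#' stems, so the same normalisation is applied to lexicon entries and to
#' sentence tokens.
#'
#' @param words Character vector of words.
#' @return Character vector of lowercase stems, same length as `words`.
#' @examples
#' porter_stem(c("interacts", "binding", "regulation", "driven"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), .porter1, character(1), USE.NAMES = FALSE)
}
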