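# Porter stemmer (original 1980 definition), implemented here because the
# text stage needs a deterministic English suffix stripper and the
# algorithm is short enough to state exactly. A letter is a consonant
# unless it is a/e/i/o/u or a 'y' preceded by a consonant; the measure m
# counts vowel-consonant sequences in [C](VC)^m[V].

.porter_is_cons <- function(chars) {
  n <- length(chars)
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  if (n > 1) {
    for (i in 2:n) {
      if (chars[i] == "y" && !cons[i - 1]) cons[i] <- TRUE # y after vowel
      if (chars[i] == "y" && cons[i - 1]) cons[i] <- FALSE # y after consonant
    }
  }
  cons
}

.porter_measure <- function(stem) {
  if (!nchar(stem)) return(0L)
  cons <- .porter_is_cons(strsplit(stem, "")[[1]])
  rle_v <- rle(cons)$values
  sum(rle_v == FALSE & c(rle_v[-1], NA) == TRUE, na.rm = TRUE)
}

.porter_has_vowel <- function(stem) {
  if (!nchar(stem)) return(FALSE)
  any(!.porter_is_cons(strsplit(stem, "")[[1]]))
}

.porter_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2) return(FALSE)
  a <- substr(stem, n - 1, n - 1)
  b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  cons <- .porter_is_cons(strsplit(stem, "")[[1]])
  cons[n]
}

# *o: ends consonant-vowel-consonant where the final consonant is not w/x/y
.porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3) return(FALSE)
  cons <- .porter_is_cons(strsplit(stem, "")[[1]])
  last <- substr(stem, n, n)
  cons[n - 2] && !cons[n - 1] && cons[n] && !(last %in% c("w", "x", "y"))
}

.porter_ends <- function(word, suffix) {
  nw <- nchar(word); ns <- nchar(suffix)
  nw > ns && substr(word, nw - ns + 1, nw) == suffix
}

# apply the first (longest) matching rule of a step-2/3/4 style block:
# list of c(suffix, replacement), condition on the measure of the stem
.porter_rule_block <- function(word, rules, min_m, extra = NULL) {
  for (r in rules) {
    suf <- r[[1]]
    if (.porter_ends(word, suf)) {
      stem <- substr(word, 1, nchar(word) - nchar(suf))
      ok <- .porter_measure(stem) > min_m
      if (ok && !is.null(extra)) ok <- extra(stem)
      if (ok) word <- paste0(stem, r[[2]])
      return(word) # longest match consumed the step either way
    }
  }
  word
}

.porter_step4 <- function(word) {
  sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  for (suf in sufs) {
    if (.porter_ends(word, suf)) {
      stem <- substr(word, 1, nchar(word) - nchar(suf))
      ok <- .porter_measure(stem) > 1
      if (suf == "ion") {
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      }
      if (ok) word <- stem
      return(word)
    }
  }
  word
}

.porter_one <- function(word) {
  if (nchar(word) <= 2) return(word)

  # step 1a
  if (.porter_ends(word, "sses")) {
    word <- substr(word, 1, nchar(word) - 2)
  } else if (.porter_ends(word, "ies")) {
    word <- substr(word, 1, nchar(word) - 2)
  } else if (!.porter_ends(word, "ss") && .porter_ends(word, "s")) {
    word <- substr(word, 1, nchar(word) - 1)
  }

  # step 1b
  fired <- FALSE
  if (.porter_ends(word, "eed")) {
    stem <- substr(word, 1, nchar(word) - 3)
    if (.porter_measure(stem) > 0) word <- substr(word, 1, nchar(word) - 1)
  } else if (.porter_ends(word, "ed")) {
    stem <- substr(word, 1, nchar(word) - 2)
    if (.porter_has_vowel(stem)) { word <- stem; fired <- TRUE }
  } else if (.porter_ends(word, "ing")) {
    stem <- substr(word, 1, nchar(word) - 3)
    if (.porter_has_vowel(stem)) { word <- stem; fired <- TRUE }
  }
  if (fired) {
    if (.porter_ends(word, "at") || .porter_ends(word, "bl") ||
        .porter_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_double_cons(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- substr(word, 1, nchar(word) - 1)
    } else if (.porter_measure(word) == 1 && .porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (.porter_ends(word, "y") &&
      .porter_has_vowel(substr(word, 1, nchar(word) - 1))) {
    word <- paste0(substr(word, 1, nchar(word) - 1), "i")
  }

  # step 2 (m > 0)
  word <- .porter_rule_block(word, list(
    list("ational", "ate"), list("tional", "tion"),
    list("enci", "ence"), list("anci", "ance"), list("izer", "ize"),
    list("abli", "able"), list("alli", "al"), list("entli", "ent"),
    list("eli", "e"), list("ousli", "ous"), list("ization", "ize"),
    list("ation", "ate"), list("ator", "ate"), list("alism", "al"),
    list("iveness", "ive"), list("fulness", "ful"), list("ousness", "ous"),
    list("aliti", "al"), list("iviti", "ive"), list("biliti", "ble")
  ), 0)

  # step 3 (m > 0)
  word <- .porter_rule_block(word, list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ful", ""),
    list("ness", "")
  ), 0)

  # step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  word <- .porter_step4(word)

  # step 5a
  if (.porter_ends(word, "e")) {
    stem <- substr(word, 1, nchar(word) - 1)
    m <- .porter_measure(stem)
    if (m > 1 || (m == 1 && !.porter_cvc(stem))) word <- stem
  }
  # step 5b
  if (.porter_measure(word) > 1 && .porter_double_cons(word) &&
      substr(word, nchar(word), nchar(word)) == "l") {
    word <- substr(word, 1, nchar(word) - 1)
  }
  word
}

#' Porter stem a vector of words
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems.
#' @examples
#' porter_stem(c("relational", "caresses", "hopping")) # relat caress hop
#' @export
porter_stem <- function(words) {
  if (!length(words)) return(character(0))
  uw <- unique(words)
  stems <- vapply(uw, .porter_one, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}
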