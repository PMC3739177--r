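#' Porter stemming algorithm
#'
#' The classic suffix-stripping stemmer (Porter 1980), implemented in full:
#' steps 1a/1b/1c strip plurals and -ed/-ing, steps 2-4 strip derivational
#' suffixes gated on the measure m (the number of vowel-consonant sequences
#' in the stem), and step 5 tidies a trailing -e and double consonants.
#' Operates on lower-case alphabetic tokens; words of length <= 2 are
#' returned unchanged, as in the original.
#'
#' @param words character vector of tokens
#' @return character vector of stems
#' @examples
#' porter_stem(c("termites", "hindguts", "relational", "hopping"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), .porter_one, "", USE.NAMES = FALSE)
}

# y is a consonant at position 1 or after a vowel, else a vowel
.is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") return(if (i == 1L) TRUE else !.is_cons(chars, i - 1L))
  TRUE
}

.cv_pattern <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  vapply(seq_along(chars), function(i) .is_cons(chars, i), TRUE)
}

# measure m: number of VC sequences in the (possibly truncated) word
.measure <- function(word) {
  if (!nzchar(word)) return(0L)
  cons <- .cv_pattern(word)
  # collapse runs, count V->C transitions
  runs <- rle(cons)$values
  sum(runs[-1] == TRUE & runs[-length(runs)] == FALSE)
}

.has_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(!.cv_pattern(word))
}

.ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L); b <- substr(word, n, n)
  a == b && .is_cons(strsplit(word, "", fixed = TRUE)[[1]], n)
}

# *o condition: stem ends cvc where the final c is not w, x or y
.ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- .cv_pattern(word)
  if (!(cons[n] && !cons[n - 1L] && cons[n - 2L])) return(FALSE)
  !substr(word, n, n) %in% c("w", "x", "y")
}

.ends_with <- function(word, suf) {
  n <- nchar(word); k <- nchar(suf)
  n >= k && substr(word, n - k + 1L, n) == suf
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

.porter_one <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (.ends_with(w, "sses")) w <- .chop(w, 2L)
  else if (.ends_with(w, "ies")) w <- .chop(w, 2L)
  else if (.ends_with(w, "ss")) w <- w
  else if (.ends_with(w, "s")) w <- .chop(w, 1L)

  # step 1b
  step1b_fix <- FALSE
  if (.ends_with(w, "eed")) {
    if (.measure(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else if (.ends_with(w, "ed") && .has_vowel(.chop(w, 2L))) {
    w <- .chop(w, 2L); step1b_fix <- TRUE
  } else if (.ends_with(w, "ing") && .has_vowel(.chop(w, 3L))) {
    w <- .chop(w, 3L); step1b_fix <- TRUE
  }
  if (step1b_fix) {
    if (.ends_with(w, "at") || .ends_with(w, "bl") || .ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.ends_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- .chop(w, 1L)
    } else if (.measure(w) == 1L && .ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (.ends_with(w, "y") && .has_vowel(.chop(w, 1L)))
    w <- paste0(.chop(w, 1L), "i")

  # steps 2-4: (suffix, replacement, minimum measure of the stem)
  apply_rules <- function(w, rules, m_min = 0L) {
    for (r in rules) {
      if (.ends_with(w, r[[1]])) {
        stem <- .chop(w, nchar(r[[1]]))
        if (.measure(stem) > m_min) return(paste0(stem, r[[2]]))
        return(w) # longest matching suffix decides, even if condition fails
      }
    }
    w
  }

  w <- apply_rules(w, list(
    list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
    list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
    list("alli", "al"), list("entli", "ent"), list("eli", "e"),
    list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
    list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
    list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
    list("iviti", "ive"), list("biliti", "ble")))

  w <- apply_rules(w, list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ful", ""),
    list("ness", "")))

  # step 4 requires m > 1
  step4 <- list(
    list("al", ""), list("ance", ""), list("ence", ""), list("er", ""),
    list("ic", ""), list("able", ""), list("ible", ""), list("ant", ""),
    list("ement", ""), list("ment", ""), list("ent", ""), list("ou", ""),
    list("ism", ""), list("ate", ""), list("iti", ""), list("ous", ""),
    list("ive", ""), list("ize", ""))
  # -ion only when the stem ends in s or t
  matched <- FALSE
  for (r in step4) {
    if (.ends_with(w, r[[1]])) {
      stem <- .chop(w, nchar(r[[1]]))
      if (.measure(stem) > 1L) w <- stem
      matched <- TRUE
      break
    }
  }
  if (!matched && .ends_with(w, "ion")) {
    stem <- .chop(w, 3L)
    if (.measure(stem) > 1L &&
        substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))
      w <- stem
  }

  # step 5a
  if (.ends_with(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) w <- stem
  }
  # step 5b
  if (.measure(w) > 1L && .ends_double_cons(w) && .ends_with(w, "l"))
    w <- .chop(w, 1L)
  w
}
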