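#' Porter stemmer
#'
#' Reduces an English word to its stem using the Porter (1980) suffix
#' stripping algorithm. The same stemmer is applied to mention text,
#' ontology aliases, and knowledge-base explanation text, so that surface
#' variants such as "arteries"/"artery" or "extremities"/"extremity"
#' collapse to one indexed form.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("caresses", "ponies", "relational", "extremities"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# -- single-word implementation ---------------------------------------------
# Works on a character vector of single letters; words of length <= 2 are
# returned unchanged, per the algorithm.

porter_stem1 <- function(word) {
  if (is.na(word) || nchar(word) < 3) return(word)
  w <- strsplit(word, "", fixed = TRUE)[[1]]
  w <- p_step1a(w)
  w <- p_step1b(w)
  w <- p_step1c(w)
  w <- p_step2(w)
  w <- p_step3(w)
  w <- p_step4(w)
  w <- p_step5(w)
  paste(w, collapse = "")
}

p_is_cons <- function(w, i) {
  ch <- w[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!p_is_cons(w, i - 1L))
  }
  TRUE
}

# measure m: number of vowel->consonant transitions in [C](VC)^m[V]
p_measure <- function(w) {
  if (length(w) == 0L) return(0L)
  types <- vapply(seq_along(w), function(i) p_is_cons(w, i), logical(1))
  m <- 0L
  for (i in seq_along(types)[-1]) {
    if (types[i] && !types[i - 1L]) m <- m + 1L
  }
  m
}

p_has_vowel <- function(w) {
  any(!vapply(seq_along(w), function(i) p_is_cons(w, i), logical(1)))
}

p_ends_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[n] == w[n - 1L] && p_is_cons(w, n)
}

# *o: stem ends cvc where the final consonant is not w, x or y
p_ends_cvc <- function(w) {
  n <- length(w)
  n >= 3L &&
    p_is_cons(w, n) && !p_is_cons(w, n - 1L) && p_is_cons(w, n - 2L) &&
    !(w[n] %in% c("w", "x", "y"))
}

p_ends_with <- function(w, suffix) {
  s <- strsplit(suffix, "", fixed = TRUE)[[1]]
  n <- length(w); k <- length(s)
  n >= k && all(w[(n - k + 1L):n] == s)
}

p_drop <- function(w, k) if (k >= length(w)) character(0) else w[seq_len(length(w) - k)]

p_replace <- function(w, suffix, replacement) {
  stem <- p_drop(w, nchar(suffix))
  c(stem, strsplit(replacement, "", fixed = TRUE)[[1]])
}

p_step1a <- function(w) {
  if (p_ends_with(w, "sses")) return(p_replace(w, "sses", "ss"))
  if (p_ends_with(w, "ies"))  return(p_replace(w, "ies", "i"))
  if (p_ends_with(w, "ss"))   return(w)
  if (p_ends_with(w, "s"))    return(p_drop(w, 1L))
  w
}

p_step1b <- function(w) {
  if (p_ends_with(w, "eed")) {
    if (p_measure(p_drop(w, 3L)) > 0L) return(p_drop(w, 1L))
    return(w)
  }
  fired <- FALSE
  if (p_ends_with(w, "ed") && p_has_vowel(p_drop(w, 2L))) {
    w <- p_drop(w, 2L); fired <- TRUE
  } else if (p_ends_with(w, "ing") && p_has_vowel(p_drop(w, 3L))) {
    w <- p_drop(w, 3L); fired <- TRUE
  }
  if (fired) {
    if (p_ends_with(w, "at")) return(p_replace(w, "at", "ate"))
    if (p_ends_with(w, "bl")) return(p_replace(w, "bl", "ble"))
    if (p_ends_with(w, "iz")) return(p_replace(w, "iz", "ize"))
    if (p_ends_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      return(p_drop(w, 1L))
    }
    if (p_measure(w) == 1L && p_ends_cvc(w)) return(c(w, "e"))
  }
  w
}

p_step1c <- function(w) {
  if (p_ends_with(w, "y") && p_has_vowel(p_drop(w, 1L))) {
    return(p_replace(w, "y", "i"))
  }
  w
}

# step 2/3 tables: suffix -> replacement, applied on longest match with m(stem) > 0
p_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("bli", "ble"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble"),
  c("logi", "log")
)

p_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

p_apply_table <- function(w, rules) {
  ord <- order(vapply(rules, function(r) nchar(r[1]), integer(1)),
               decreasing = TRUE)
  for (r in rules[ord]) {
    if (p_ends_with(w, r[1])) {
      stem <- p_drop(w, nchar(r[1]))
      if (p_measure(stem) > 0L) return(p_replace(w, r[1], r[2]))
      return(w)
    }
  }
  w
}

p_step2 <- function(w) p_apply_table(w, p_step2_rules)
p_step3 <- function(w) p_apply_table(w, p_step3_rules)

p_step4_suffixes <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                      "ent", "ion", "ism", "ate", "iti", "ous", "ive", "ize",
                      "al", "er", "ic", "ou")

p_step4 <- function(w) {
  for (s in p_step4_suffixes[order(nchar(p_step4_suffixes), decreasing = TRUE)]) {
    if (p_ends_with(w, s)) {
      stem <- p_drop(w, nchar(s))
      if (p_measure(stem) > 1L) {
        if (s == "ion" && !(length(stem) > 0L && stem[length(stem)] %in% c("s", "t"))) {
          return(w)
        }
        return(stem)
      }
      return(w)
    }
  }
  w
}

p_step5 <- function(w) {
  # 5a
  if (p_ends_with(w, "e")) {
    stem <- p_drop(w, 1L)
    m <- p_measure(stem)
    if (m > 1L || (m == 1L && !p_ends_cvc(stem))) w <- stem
  }
  # 5b
  if (p_ends_with(w, "ll") && p_measure(w) > 1L) w <- p_drop(w, 1L)
  w
}

#' Tokenize text on non-alphanumeric boundaries
#'
#' Lowercases and splits on any run of characters that is neither a letter
#' nor a digit. Empty tokens are dropped. This is the single tokenizer used
#' for mentions, ontology aliases, and explanation text.
#'
#' @param text character vector (each element tokenized independently).
#' @return for a single input string, a character vector of tokens; for a
#'   vector input, a list of such vectors.
#' @export
tokenize <- function(text) {
  out <- lapply(strsplit(tolower(text), "[^a-z0-9]+"), function(x) x[nzchar(x)])
  if (length(out) == 1L) out[[1]] else out
}
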