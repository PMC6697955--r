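# Irregular plurals that Porter suffix stripping cannot singularize.
# (s-final singulars such as "pancreas" are listed too: suffix stripping
# alone cannot reunite them with their "-es" plurals)
.irregular_singulars <- c(
  feet = "foot", teeth = "tooth", men = "man", women = "woman",
  children = "child", vertebrae = "vertebra", bronchi = "bronchus",
  alveoli = "alveolus", ganglia = "ganglion",
  pancreases = "pancreas", uteruses = "uterus", uteri = "uterus",
  pelvises = "pelvis", pelves = "pelvis",
  esophagi = "esophagus", esophaguses = "esophagus"
)

#' Packaged stopword list
#'
#' A small fixed clinical-English stopword list shipped with the package;
#' replaceable by passing your own character vector to the functions that
#' take a `stopwords` argument.
#'
#' @return character vector of stopwords.
#' @export
thbp_stopwords <- function() {
  if (is.null(.thbp_cache$stopwords)) {
    .thbp_cache$stopwords <-
      readLines(thbp_file("resources", "stopwords.txt"), warn = FALSE)
  }
  .thbp_cache$stopwords
}

#' Load normalization resources from a directory
#'
#' Reads `stopwords.txt` (one word per line), `positional.tsv` (columns
#' `surface`, `canonical`), `abbreviations.tsv` (columns `key`,
#' `full_forms` pipe-separated) and, if present, `coref_chains.tsv`
#' (columns `chain_id`, `doc_id`, `member_text`).
#'
#' @param dir resource directory.
#' @return list with elements `stopwords`, `positional` (named character
#'   vector, stemmed surface -> canonical form), `abbrev` (named list,
#'   stemmed key -> character vector of full forms), `chains` (data frame,
#'   possibly empty).
#' @export
load_resources <- function(dir) {
  if (!dir.exists(dir)) {
    stop("resource directory does not exist: ", dir, call. = FALSE)
  }
  stopwords <- readLines(file.path(dir, "stopwords.txt"), warn = FALSE)

  pos <- utils::read.delim(file.path(dir, "positional.tsv"),
                           colClasses = "character")
  pos_keys <- vapply(pos$surface, function(s) alias_key(s, stopwords),
                     character(1), USE.NAMES = FALSE)
  positional <- stats::setNames(pos$canonical, pos_keys)
  positional <- positional[!duplicated(names(positional))]

  ab <- utils::read.delim(file.path(dir, "abbreviations.tsv"),
                          colClasses = "character")
  abbrev <- stats::setNames(
    lapply(ab$full_forms, function(f) strsplit(f, "|", fixed = TRUE)[[1]]),
    vapply(ab$key, function(k) alias_key(k, stopwords), character(1),
           USE.NAMES = FALSE))

  chain_path <- file.path(dir, "coref_chains.tsv")
  chains <- if (file.exists(chain_path)) {
    utils::read.delim(chain_path, colClasses = "character")
  } else {
    data.frame(chain_id = character(0), doc_id = character(0),
               member_text = character(0))
  }
  list(stopwords = stopwords, positional = positional, abbrev = abbrev,
       chains = chains)
}

#' Packaged normalization resources
#'
#' @return the resource list shipped with the package (see
#'   [load_resources()]), cached after the first call.
#' @export
thbp_resources <- function() {
  if (is.null(.thbp_cache$resources)) {
    .thbp_cache$resources <- load_resources(thbp_file("resources"))
  }
  .thbp_cache$resources
}

#' Normalize raw text to a stemmed token sequence
#'
#' Lowercases, tokenizes on non-alphanumeric boundaries, removes
#' stopwords, singularizes irregular plurals (regular plurals collapse
#' under stemming), and Porter-stems each token. This single pipeline is
#' applied to mentions, ontology aliases and explanation text, so all
#' three meet in the same token space.
#'
#' @param text a character string.
#' @param stopwords stopword list (raw lowercase tokens to drop).
#' @return character vector of stemmed tokens (possibly empty).
#' @examples
#' stem_and_clean("left extremities")  # "left" "extrem"
#' stem_and_clean("the heart")         # "heart"
#' @export
stem_and_clean <- function(text, stopwords = thbp_stopwords()) {
  if (length(text) != 1L || is.na(text)) {
    stop("stem_and_clean() expects a single string", call. = FALSE)
  }
  toks <- tokenize(text)
  toks <- toks[!toks %in% stopwords]
  hit <- toks %in% names(.irregular_singulars)
  toks[hit] <- .irregular_singulars[toks[hit]]
  porter_stem(toks)
}

#' Split positional modifiers from a token sequence
#'
#' Removes tokens found in the positional vocabulary (left, right,
#' bilateral, upper, lower, ...) and returns their canonical forms in
#' original order together with the residual core. Spans of the sequence
#' that match an ontology alias are protected, so positional words that
#' are part of a body-part name survive: in "right lower extremity" the
#' span "lower extremity" is an alias and only "right" is stripped, and a
#' sequence that entirely equals an alias is never altered.
#'
#' @param tokens stemmed token sequence (output of [stem_and_clean()]).
#' @param vocab positional vocabulary: named character vector, stemmed
#'   surface -> canonical form (see [load_resources()]).
#' @param ontology optional `thbp_ontology` used for alias-span
#'   protection; with `NULL`, every positional token is stripped.
#' @return list with `positionals` (canonical forms, original order) and
#'   `core` (residual token sequence).
#' @examples
#' r <- thbp_resources()
#' strip_positional(stem_and_clean("legs bilaterally"), r$positional)
#' @export
strip_positional <- function(tokens, vocab = thbp_resources()$positional,
                             ontology = NULL) {
  n <- length(tokens)
  if (n == 0L) return(list(positionals = character(0), core = tokens))
  protected <- rep(FALSE, n)
  if (!is.null(ontology)) {
    i <- 1L
    while (i <= n) {
      matched_len <- 0L
      for (len in seq(min(ontology$max_alias_tokens, n - i + 1L), 1L)) {
        key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
        if (!is.null(index_get(ontology$alias_index, key))) {
          matched_len <- len
          break
        }
      }
      if (matched_len > 0L) {
        protected[i:(i + matched_len - 1L)] <- TRUE
        i <- i + matched_len
      } else {
        i <- i + 1L
      }
    }
  }
  is_pos <- tokens %in% names(vocab) & !protected
  list(
    positionals = unname(vocab[tokens[is_pos]]),
    core = tokens[!is_pos]
  )
}

#' Expand an abbreviation to full forms
#'
#' Looks up full forms for a (stemmed) core token sequence. Document-local
#' evidence beats the global table: the mention's coreference chain is
#' consulted first, then the abbreviation dictionary. A chain member
#' counts as a full form when the abbreviation's letters are the member's
#' word initials in order, or the abbreviation is a prefix of the member.
#' Dictionary entries may map one key to several full forms (multi-part
#' abbreviations such as HEENT).
#'
#' @param core stemmed core token sequence.
#' @param abbrev abbreviation dictionary (named list, stemmed key ->
#'   character vector of full forms).
#' @param chains coreference chain data frame (`chain_id`, `doc_id`,
#'   `member_text`), possibly empty.
#' @param doc_id,chain_id identifiers selecting the mention's chain; may
#'   be `NULL`/empty.
#' @param stopwords stopword list for normalizing the full forms.
#' @return list of full-form token sequences (each the [stem_and_clean()]
#'   of one full form); empty when neither source applies. The attribute
#'   `"source"` is `"coreference"` or `"dictionary"` when non-empty.
#' @export
expand_abbreviation <- function(core, abbrev = thbp_resources()$abbrev,
                                chains = NULL, doc_id = NULL,
                                chain_id = NULL,
                                stopwords = thbp_stopwords()) {
  if (length(core) == 0L) return(list())
  abbr_str <- paste(core, collapse = "")

  # (1) coreference chain of this mention
  if (!is.null(chains) && nrow(chains) > 0L &&
      !is.null(chain_id) && length(chain_id) == 1L && nzchar(chain_id)) {
    rows <- chains$chain_id == chain_id
    if (!is.null(doc_id) && length(doc_id) == 1L && nzchar(doc_id)) {
      rows <- rows & chains$doc_id == doc_id
    }
    members <- chains$member_text[rows]
    full <- list()
    for (m in members) {
      words <- tokenize(m)
      if (length(words) == 0L) next
      joined <- paste(words, collapse = "")
      if (joined == abbr_str) next  # the abbreviation itself
      initials <- paste(substr(words, 1L, 1L), collapse = "")
      if (identical(initials, abbr_str) ||
          (nchar(joined) > nchar(abbr_str) && startsWith(joined, abbr_str))) {
        full <- c(full, list(stem_and_clean(m, stopwords)))
      }
    }
    full <- unique(full)
    if (length(full) > 0L) {
      attr(full, "source") <- "coreference"
      return(full)
    }
  }

  # (2) global abbreviation dictionary
  key <- paste(core, collapse = " ")
  forms <- abbrev[[key]] %||% NULL
  if (!is.null(forms)) {
    full <- lapply(forms, stem_and_clean, stopwords = stopwords)
    attr(full, "source") <- "dictionary"
    return(full)
  }
  list()
}

#' Normalize a mention
#'
#' Composes [stem_and_clean()], [strip_positional()] and
#' [expand_abbreviation()]: the raw surface becomes a stemmed,
#' stopword-free core with positional modifiers split off, plus any
#' full-form expansions found via the mention's coreference chain or the
#' abbreviation dictionary. Idempotent on its own rendered output.
#'
#' @param m a mention: list or one-row data frame with at least `surface`;
#'   optional `doc_id`, `mention_id`, `coref_chain_id`.
#' @param resources resource list (see [load_resources()]).
#' @param ontology optional ontology for positional-span protection.
#' @return object of class `thbp_normalized`: list with `core_tokens`,
#'   `positionals`, `expansions` (list of token sequences) and
#'   `provenance` (`"plain"`, `"dictionary"` or `"coreference"`).
#' @examples
#' normalize_mention(list(surface = "legs bilaterally"),
#'                   thbp_resources(), thbp_ontology())
#' @export
normalize_mention <- function(m, resources = thbp_resources(),
                              ontology = NULL) {
  surface <- as.character(m$surface %||% "")
  if (length(surface) != 1L || is.na(surface) || !nzchar(trimws(surface))) {
    stop("invalid mention: empty surface", call. = FALSE)
  }
  tokens <- stem_and_clean(surface, resources$stopwords)
  sp <- strip_positional(tokens, resources$positional, ontology)
  expansions <- expand_abbreviation(
    sp$core, resources$abbrev, resources$chains,
    doc_id = as.character(m$doc_id %||% ""),
    chain_id = as.character(m$coref_chain_id %||% ""),
    stopwords = resources$stopwords
  )
  provenance <- attr(expansions, "source") %||% "plain"
  attr(expansions, "source") <- NULL
  structure(
    list(core_tokens = sp$core, positionals = sp$positionals,
         expansions = expansions, provenance = provenance),
    class = "thbp_normalized"
  )
}

#' Re-attach positional modifiers to a final body-part label
#'
#' Prefixes the canonical positional words (in their original order,
#' space-separated) to the mapped part's formal name, e.g. "bilateral" +
#' "lower extremity" -> "bilateral lower extremity".
#'
#' @param positionals character vector of canonical positional words.
#' @param part_label a formal name from the ontology.
#' @return the final label string.
#' @export
reattach_positional <- function(positionals, part_label) {
  stopifnot(is.character(part_label), length(part_label) == 1L)
  paste(c(positionals, part_label), collapse = " ")
}

#' @export
print.thbp_normalized <- function(x, ...) {
  cat("<thbp_normalized> core: [", paste(x$core_tokens, collapse = " "),
      "]", sep = "")
  if (length(x$positionals)) {
    cat("  positionals: [", paste(x$positionals, collapse = " "), "]",
        sep = "")
  }
  if (length(x$expansions)) {
    cat("  expansions: ",
        paste(vapply(x$expansions, paste, character(1), collapse = " "),
              collapse = "; "), sep = "")
  }
  cat("  (", x$provenance, ")\n", sep = "")
  invisible(x)
}
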