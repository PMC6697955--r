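#' Fixture knowledge source
#'
#' A knowledge source backed by a local directory of UTF-8 `.txt` files,
#' one explanation per term. File names are lowercase slugs (spaces and
#' punctuation collapsed to underscores) with extension `.txt`; an
#' optional `index.tsv` (columns `term`, `filename`) overrides the slug
#' convention for terms with non-filename-safe characters.
#'
#' @param path directory of explanation files.
#' @return object of class `thbp_kb` with `mode = "fixture"`.
#' @export
kb_fixture <- function(path) {
  if (!dir.exists(path)) {
    stop("knowledge-base configuration error: fixture directory does not ",
         "exist: ", path, call. = FALSE)
  }
  index <- NULL
  idx_path <- file.path(path, "index.tsv")
  if (file.exists(idx_path)) {
    index <- utils::read.delim(idx_path, colClasses = "character")
  }
  structure(
    list(mode = "fixture", path = path, index = index,
         cache = new.env(parent = emptyenv())),
    class = "thbp_kb"
  )
}

#' Live encyclopedia knowledge source
#'
#' A knowledge source that queries a Wikipedia-style REST summary endpoint
#' for the lead extract of an article. Disambiguation pages are treated as
#' a miss. Network failures signal a condition of class
#' `thbp_kb_transport_error`, distinct from an ordinary miss (`NULL`).
#' This source requires network access; all packaged tests and benchmarks
#' run against [kb_fixture()] sources instead.
#'
#' @param endpoint base URL; the URL-encoded term is appended.
#' @param timeout_seconds request timeout.
#' @param scope `"lead"` (the summary extract) — full-page retrieval is
#'   not implemented for the live source.
#' @return object of class `thbp_kb` with `mode = "live"`.
#' @export
kb_live <- function(endpoint = "https://en.wikipedia.org/api/rest_v1/page/summary/",
                    timeout_seconds = 10, scope = "lead") {
  scope <- match.arg(scope, "lead")
  structure(
    list(mode = "live", endpoint = endpoint,
         timeout_seconds = timeout_seconds, scope = scope,
         cache = new.env(parent = emptyenv())),
    class = "thbp_kb"
  )
}

kb_slug <- function(term) {
  s <- gsub("[^a-z0-9]+", "_", tolower(trimws(term)))
  gsub("^_+|_+$", "", s)
}

#' Fetch the explanation text for a term
#'
#' Looks the term up in the configured knowledge source and returns its
#' explanation preprocessed into the token stream scored by
#' [rank_candidates()]. Lookups are cached per source object, so repeated
#' queries for the same term in one run hit the source once.
#'
#' @param source a `thbp_kb` (see [kb_fixture()], [kb_live()]).
#' @param term the term to look up (matched case-insensitively).
#' @param stopwords stopword list for preprocessing.
#' @return object of class `thbp_explanation` (list with `term`,
#'   `raw_text`, `tokens`, `source`), or `NULL` on a miss.
#' @export
fetch_explanation <- function(source, term, stopwords = thbp_stopwords()) {
  stopifnot(inherits(source, "thbp_kb"))
  key <- tolower(trimws(term))
  if (!nzchar(key)) return(NULL)
  if (!is.null(source$cache[[key]])) {
    hit <- source$cache[[key]]
    return(if (identical(hit, "miss")) NULL else hit)
  }
  raw <- switch(source$mode,
    fixture = kb_fetch_fixture(source, key),
    live = kb_fetch_live(source, key)
  )
  if (is.null(raw)) {
    source$cache[[key]] <- "miss"
    return(NULL)
  }
  expl <- structure(
    list(term = term, raw_text = raw,
         tokens = preprocess_explanation(raw, stopwords),
         source = source$mode),
    class = "thbp_explanation"
  )
  source$cache[[key]] <- expl
  expl
}

kb_fetch_fixture <- function(source, key) {
  filename <- NULL
  if (!is.null(source$index)) {
    hit <- which(tolower(source$index$term) == key)
    if (length(hit) > 0L) filename <- source$index$filename[hit[1]]
  }
  if (is.null(filename)) filename <- paste0(kb_slug(key), ".txt")
  path <- file.path(source$path, filename)
  if (!file.exists(path)) return(NULL)
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

kb_fetch_live <- function(source, key) {
  url <- paste0(source$endpoint, utils::URLencode(key, reserved = TRUE))
  res <- tryCatch(
    jsonlite::fromJSON(url),
    error = function(e) {
      cond <- simpleError(paste0("knowledge-base transport error for '",
                                 key, "': ", conditionMessage(e)))
      class(cond) <- c("thbp_kb_transport_error", class(cond))
      stop(cond)
    }
  )
  if (is.null(res$extract) || identical(res$type, "disambiguation")) {
    return(NULL)
  }
  res$extract
}

#' Preprocess explanation prose into the scored token stream
#'
#' Applies the identical tokenization / stopword-removal / stemming
#' pipeline as [stem_and_clean()] to explanation prose. Token offsets used
#' by the scoring stage are 0-based positions in this filtered stream.
#'
#' @param raw_text explanation prose.
#' @param stopwords stopword list.
#' @return character vector of stemmed tokens.
#' @export
preprocess_explanation <- function(raw_text, stopwords = thbp_stopwords()) {
  stem_and_clean(raw_text, stopwords)
}

#' Packaged fixture knowledge base
#'
#' @return a [kb_fixture()] over the explanation texts shipped with the
#'   package (electrocardiography, sigmoidoscopy, colonoscopy,
#'   myocarditis).
#' @export
thbp_kb <- function() {
  kb_fixture(thbp_file("kb"))
}
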