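# Shared string matcher: exact stemmed-token resolution against the alias
# index; failing that, containment — ontology terms occurring inside the
# mention, either as whole tokens ("left eye" includes "eye") or as a
# character substring of a token ("colonoscopy" includes "colon";
# substring candidates need >= 4 characters to avoid degenerate hits).
# The candidate with the longest matched alias wins, then the deeper
# node, then the lexicographically first name. Returns a body-part
# record or NULL.
string_match <- function(ontology, tokens) {
  node <- resolve_term(ontology, tokens)
  if (!is.null(node)) return(node)
  if (length(tokens) == 0L) return(NULL)

  cand_ids <- character(0)
  cand_len <- integer(0)
  n <- length(tokens)
  i <- 1L
  while (i <= n) {
    adv <- 1L
    for (len in seq(min(ontology$max_alias_tokens, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      id <- index_get(ontology$alias_index, key)
      if (!is.null(id)) {
        cand_ids <- c(cand_ids, id)
        cand_len <- c(cand_len, nchar(key))
        adv <- len
        break
      }
    }
    i <- i + adv
  }
  joined <- paste(tokens, collapse = " ")
  keys <- names(ontology$alias_index)
  keys <- keys[nchar(keys) >= 4L]
  hit <- keys[vapply(keys, function(k) grepl(k, joined, fixed = TRUE),
                     logical(1))]
  cand_ids <- c(cand_ids, unname(ontology$alias_index[hit]))
  cand_len <- c(cand_len, nchar(hit))
  if (length(cand_ids) == 0L) return(NULL)

  depth <- vapply(cand_ids, function(id) ontology$nodes[[id]]$depth,
                  integer(1))
  formal <- vapply(cand_ids, function(id) ontology$nodes[[id]]$formal_name,
                   character(1))
  best <- order(-cand_len, -depth, formal)[1]
  ontology$nodes[[cand_ids[best]]]
}

#' Baseline string-matching mapper
#'
#' The baseline system: Porter-stemmed string matching of the raw surface
#' against the ontology, with no normalization stage and no knowledge-base
#' fallback. An entity whose stemmed form equals — or contains — an
#' ontology term is mapped to that term's node ("left eye" is included in
#' "eye"); otherwise it comes out as not matched.
#'
#' @param ontology a `thbp_ontology`.
#' @param surface raw mention text.
#' @param stopwords stopword list.
#' @return the matched body-part record, or `NULL`.
#' @export
baseline_map <- function(ontology, surface, stopwords = thbp_stopwords()) {
  string_match(ontology, stem_and_clean(surface, stopwords))
}

#' Map one mention to body parts through the full cascade
#'
#' Runs the mapping cascade: (1) normalize the mention (stemming, stopword
#' removal, positional splitting, abbreviation expansion); (2) try string
#' matching of the core and of each expansion against the ontology — every
#' hit contributes a part, so multi-part abbreviations like HEENT yield
#' several; (3) on failure, fall back to the knowledge base: fetch an
#' explanation for the core (then for the raw surface), find all ontology
#' terms occurring in it, score them by occurrence distance and frequency,
#' and take the top-ranked candidate; (4) re-attach positional modifiers
#' to each mapped part's formal name. When the core itself resolves
#' directly, that wins over any expansions.
#'
#' @param m mention: list or one-row data frame with `surface` and
#'   optionally `mention_id`, `doc_id`, `coref_chain_id`.
#' @param ontology a `thbp_ontology`.
#' @param resources normalization resources (see [load_resources()]).
#' @param kb_source a `thbp_kb`, or `NULL` to disable the fallback.
#' @param params a [scoring_params()] object.
#' @return object of class `thbp_mapping`: list with `mention_id`, `stage`
#'   (`"direct"`, `"kb"` or `"unmatched"`), `parts` (data frame with
#'   `part_id`, `label`), `best_score` (combined score when `stage ==
#'   "kb"`, else `NA`) and `provenance`.
#' @examples
#' map_mention(list(surface = "HEENT"), thbp_ontology(), thbp_resources())
#' @export
map_mention <- function(m, ontology, resources = thbp_resources(),
                        kb_source = NULL, params = scoring_params()) {
  if (is.null(resources$stopwords) || is.null(resources$positional) ||
      is.null(resources$abbrev)) {
    stop("configuration error: resources must carry stopwords, positional ",
         "vocabulary and abbreviation dictionary", call. = FALSE)
  }
  nm <- normalize_mention(m, resources, ontology)
  mention_id <- as.character(m$mention_id %||% NA_character_)
  parts <- list()  # list of node records
  stage <- "unmatched"
  best_score <- NA_real_
  labels_override <- NULL

  # (2) direct string match: core first, then expansions
  if (length(nm$core_tokens) > 0L) {
    node <- string_match(ontology, nm$core_tokens)
    if (!is.null(node)) {
      parts <- list(node)
      stage <- "direct"
    }
  }
  if (stage == "unmatched" && length(nm$expansions) > 0L) {
    labels <- character(0)
    for (ex in nm$expansions) {
      sp <- strip_positional(ex, resources$positional, ontology)
      node <- string_match(ontology, sp$core)
      if (!is.null(node) && !node$id %in% vapply(parts, `[[`, "", "id")) {
        parts <- c(parts, list(node))
        # positionals carried by the expansion itself (e.g. RLE ->
        # "right lower extremity") are kept in its label
        labels <- c(labels, reattach_positional(
          c(nm$positionals, sp$positionals), node$formal_name))
      }
    }
    if (length(parts) > 0L) {
      stage <- "direct"
      labels_override <- labels
    }
  }

  # (3) knowledge-base fallback
  if (stage == "unmatched" && !is.null(kb_source) &&
      length(nm$core_tokens) > 0L) {
    queries <- unique(c(paste(nm$core_tokens, collapse = " "),
                        as.character(m$surface)))
    for (q in queries) {
      expl <- fetch_explanation(kb_source, q, resources$stopwords)
      if (is.null(expl)) next
      ranked <- rank_candidates(find_matches_in_text(ontology, expl$tokens),
                                ontology, params)
      if (nrow(ranked) > 0L) {
        parts <- list(ontology$nodes[[ranked$part_id[1]]])
        best_score <- ranked$score[1]
        stage <- "kb"
        break
      }
    }
  }

  labels <- if (!is.null(labels_override)) labels_override else {
    vapply(parts, function(p) reattach_positional(nm$positionals,
                                                  p$formal_name),
           character(1))
  }
  structure(
    list(mention_id = mention_id, stage = stage,
         parts = data.frame(
           part_id = vapply(parts, `[[`, "", "id"),
           label = labels, stringsAsFactors = FALSE),
         best_score = best_score, provenance = nm$provenance),
    class = "thbp_mapping"
  )
}

#' @export
print.thbp_mapping <- function(x, ...) {
  cat("<thbp_mapping> ", if (!is.na(x$mention_id)) x$mention_id else "",
      " stage: ", x$stage, sep = "")
  if (nrow(x$parts) > 0L) {
    cat("  parts: ", paste(x$parts$label, collapse = "; "), sep = "")
  }
  if (!is.na(x$best_score)) cat("  score: ", format(x$best_score), sep = "")
  cat("\n")
  invisible(x)
}

#' Read a mention TSV
#'
#' Columns: `doc_id`, `mention_id`, `start`, `end`, `surface`, and
#' optionally `coref_chain_id` (empty allowed).
#'
#' @param path TSV file path.
#' @return data frame of mentions.
#' @export
read_mentions <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("doc_id", "mention_id", "start", "end", "surface")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("mention file ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"coref_chain_id" %in% names(df)) df$coref_chain_id <- ""
  df
}

#' Map a whole mention corpus
#'
#' Applies the mapping cascade to each mention in input order and collects
#' the results in the tabular result format. Per-term knowledge-base
#' fetches are cached inside the source object. `method` selects the
#' system variant: `"full"` is the complete cascade, `"normalize"` runs
#' normalization plus string matching with the knowledge base disabled,
#' and `"baseline"` is raw string matching only ([baseline_map()]).
#'
#' @param mentions data frame of mentions or path to a mention TSV.
#' @param ontology a `thbp_ontology`.
#' @param resources normalization resources.
#' @param kb_source a `thbp_kb` or `NULL`.
#' @param params a [scoring_params()] object.
#' @param method `"full"`, `"normalize"`, or `"baseline"`.
#' @param quiet suppress the per-stage count message.
#' @return data frame with columns `mention_id`, `stage`, `parts`
#'   (semicolon-separated final labels), `part_ids` (semicolon-separated)
#'   and `best_score` (empty unless `stage == "kb"`).
#' @export
map_corpus <- function(mentions, ontology, resources = thbp_resources(),
                       kb_source = NULL, params = scoring_params(),
                       method = c("full", "normalize", "baseline"),
                       quiet = FALSE) {
  method <- match.arg(method)
  if (is.character(mentions) && length(mentions) == 1L) {
    mentions <- read_mentions(mentions)
  }
  dup <- which(duplicated(mentions$mention_id))
  if (length(dup) > 0L) {
    stop("input error: duplicate mention_id '",
         mentions$mention_id[dup[1]], "' at row ", dup[1], call. = FALSE)
  }
  n <- nrow(mentions)
  out <- data.frame(mention_id = character(n), stage = character(n),
                    parts = character(n), part_ids = character(n),
                    best_score = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    m <- mentions[i, , drop = FALSE]
    if (method == "baseline") {
      node <- baseline_map(ontology, m$surface, resources$stopwords)
      res <- list(
        mention_id = m$mention_id,
        stage = if (is.null(node)) "unmatched" else "direct",
        parts = if (is.null(node)) {
          data.frame(part_id = character(0), label = character(0))
        } else {
          data.frame(part_id = node$id, label = node$formal_name,
                     stringsAsFactors = FALSE)
        },
        best_score = NA_real_
      )
    } else {
      res <- map_mention(m, ontology, resources,
                         kb_source = if (method == "full") kb_source,
                         params = params)
    }
    out$mention_id[i] <- m$mention_id
    out$stage[i] <- res$stage
    out$parts[i] <- paste(res$parts$label, collapse = ";")
    out$part_ids[i] <- paste(res$parts$part_id, collapse = ";")
    out$best_score[i] <- if (is.na(res$best_score)) "" else
      format(res$best_score, digits = 10)
  }
  if (!quiet) {
    counts <- table(factor(out$stage,
                           levels = c("direct", "kb", "unmatched")))
    message("mapped ", n, " mentions (", method, "): ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  out
}

#' Write a result TSV
#'
#' @param results result data frame from [map_corpus()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
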