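# Package-local cache for lazily loaded packaged resources.
.thbp_cache <- new.env(parent = emptyenv())

#' Path to a file shipped with the package
#'
#' @param ... path components below `inst/extdata`.
#' @return absolute path to the installed file.
#' @export
thbp_file <- function(...) {
  system.file("extdata", ..., package = "thbpmap", mustWork = TRUE)
}

# Stemmed index key for an alias or term: tokenized, stopword-free,
# singularized, Porter-stemmed, space-joined.
alias_key <- function(text, stopwords = thbp_stopwords()) {
  paste(stem_and_clean(text, stopwords), collapse = " ")
}

#' Load a Tree of Human Body Parts ontology from JSON
#'
#' The ontology file is a JSON array of records with keys `id` (string),
#' `formal_name` (string), `aliases` (array of strings, possibly empty) and
#' `parent` (string or null). Formal names and aliases are stemmed and
#' lowercased before indexing, so that surface variants in text
#' ("arteries", "artery") resolve to the same node. The packaged ontology
#' organizes human body parts by anatomical position into nine top-level
#' regions (head, neck, chest, abdomen, pelvis, back, hip, extremity,
#' trunk), each with organ/tissue sublayers; tissues distributed across the
#' whole body (nerve, blood, bone, ...) sit under trunk.
#'
#' @param path path to the ontology JSON file.
#' @param validate if `TRUE` (default), stop with a validation error when
#'   any structural invariant is violated (cycles, duplicate formal names,
#'   alias collisions, unreachable nodes).
#' @return an object of class `thbp_ontology`: a list with `nodes` (named
#'   list of body-part records carrying `id`, `formal_name`, `aliases`,
#'   `parent`, `depth`, `alias_keys`), `roots` (ids of top-level parts),
#'   `alias_index` (named character vector, stemmed alias key -> node id)
#'   and `max_alias_tokens`.
#' @seealso [validate_ontology()], [resolve_term()], [find_matches_in_text()]
#' @export
load_ontology <- function(path, validate = TRUE) {
  records <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("ontology format error: cannot parse '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (!is.list(records) || length(records) == 0L) {
    stop("ontology format error: expected a non-empty JSON array of records",
         call. = FALSE)
  }
  for (i in seq_along(records)) {
    r <- records[[i]]
    ok <- is.list(r) &&
      is.character(r$id %||% NULL) && nzchar(r$id) &&
      is.character(r$formal_name %||% NULL) && nzchar(r$formal_name) &&
      (is.null(r$parent) || (is.character(r$parent) && nzchar(r$parent))) &&
      (is.null(r$aliases) || all(vapply(r$aliases, is.character, logical(1))))
    if (!ok) {
      stop("ontology format error in record ", i, " (id: ",
           if (is.list(r) && !is.null(r$id)) r$id else "<missing>",
           "): each record needs id, formal_name, aliases, parent",
           call. = FALSE)
    }
    if (any(!nzchar(unlist(r$aliases)))) {
      stop("ontology format error in record ", i, " (id: ", r$id,
           "): aliases must not contain the empty string", call. = FALSE)
    }
  }
  ont <- build_ontology(records)
  if (validate) {
    report <- validate_ontology(ont)
    if (length(report$problems) > 0L) {
      stop("ontology validation error:\n  ",
           paste(report$problems, collapse = "\n  "), call. = FALSE)
    }
  }
  ont
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# safe lookup in the alias index: node id, or NULL when the key is absent
index_get <- function(index, key) {
  i <- match(key, names(index))
  if (is.na(i)) NULL else unname(index[i])
}

build_ontology <- function(records) {
  ids <- vapply(records, function(r) r$id, character(1))
  nodes <- list()
  for (r in records) {
    aliases <- as.character(unlist(r$aliases))
    terms <- c(r$formal_name, aliases)
    keys <- unique(vapply(terms, alias_key, character(1), USE.NAMES = FALSE))
    keys <- keys[nzchar(keys)]
    nodes[[r$id]] <- list(
      id = r$id,
      formal_name = r$formal_name,
      aliases = aliases,
      parent = if (is.null(r$parent)) NA_character_ else r$parent,
      depth = NA_integer_,
      alias_keys = keys
    )
  }
  # depth by following parent chains; NA on cycle or dangling parent
  for (id in ids) {
    chain <- character(0)
    cur <- id
    depth <- 0L
    repeat {
      parent <- nodes[[cur]]$parent
      if (is.na(parent)) break
      if (parent %in% chain || parent == cur || !(parent %in% ids)) {
        depth <- NA_integer_
        break
      }
      chain <- c(chain, cur)
      cur <- parent
      depth <- depth + 1L
    }
    nodes[[id]]$depth <- depth
  }
  # alias index: first writer wins; collisions surface in validate_ontology()
  alias_index <- character(0)
  for (id in ids) {
    for (k in nodes[[id]]$alias_keys) {
      if (!k %in% names(alias_index)) alias_index[[k]] <- id
    }
  }
  max_tokens <- max(lengths(strsplit(names(alias_index), " ", fixed = TRUE)))
  structure(
    list(
      nodes = nodes,
      roots = ids[vapply(nodes, function(n) is.na(n$parent), logical(1))],
      alias_index = alias_index,
      max_alias_tokens = max_tokens
    ),
    class = "thbp_ontology"
  )
}

#' Load the packaged THBP ontology
#'
#' @return the packaged ontology (cached after the first call).
#' @export
thbp_ontology <- function() {
  if (is.null(.thbp_cache$ontology)) {
    .thbp_cache$ontology <- load_ontology(thbp_file("thbp.json"))
  }
  .thbp_cache$ontology
}

#' Serialize an ontology back to its JSON file format
#'
#' Writes the same JSON dialect read by [load_ontology()]; a load/write/load
#' round trip yields a field-by-field identical ontology.
#'
#' @param ontology a `thbp_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  stopifnot(inherits(ontology, "thbp_ontology"))
  records <- lapply(ontology$nodes, function(n) {
    list(id = n$id, formal_name = n$formal_name,
         aliases = as.list(n$aliases),
         parent = if (is.na(n$parent)) NULL else n$parent)
  })
  json <- jsonlite::toJSON(unname(records), auto_unbox = TRUE, null = "null",
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Resolve a stemmed token sequence to a body part
#'
#' Exact lookup of a token sequence against the ontology's alias index
#' (which covers every formal name and alias, stemmed). Absence is a valid
#' outcome, not an error.
#'
#' @param ontology a `thbp_ontology`.
#' @param tokens character vector of lowercased, stemmed tokens (the output
#'   of [stem_and_clean()]).
#' @return the matching body-part record (a list), or `NULL`.
#' @examples
#' ont <- thbp_ontology()
#' resolve_term(ont, stem_and_clean("abd"))$formal_name     # "abdomen"
#' resolve_term(ont, stem_and_clean("myocarditis"))         # NULL
#' @export
resolve_term <- function(ontology, tokens) {
  stopifnot(inherits(ontology, "thbp_ontology"))
  if (length(tokens) == 0L) return(NULL)
  key <- paste(tokens, collapse = " ")
  id <- index_get(ontology$alias_index, key)
  if (is.null(id)) NULL else ontology$nodes[[id]]
}

#' Find all body-part occurrences in a token stream
#'
#' Scans a preprocessed token sequence left to right with
#' longest-match-wins over multi-token aliases ("lower extremity" matches
#' the lower-extremity node, not additionally "extremity" inside it).
#' Matches never overlap. Each matched span contributes the 0-based offset
#' of its first token; occurrences of different aliases of the same part
#' accumulate in one occurrence list. The occurrence count is the frequency
#' F(n) used by the scoring stage.
#'
#' @param ontology a `thbp_ontology`.
#' @param tokens preprocessed token stream (see [preprocess_explanation()]).
#' @return a list of occurrence lists, ordered by first occurrence; each is
#'   a list with `part_id`, `offsets` (strictly increasing, 0-based) and
#'   `count`.
#' @export
find_matches_in_text <- function(ontology, tokens) {
  stopifnot(inherits(ontology, "thbp_ontology"))
  n <- length(tokens)
  hits <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(ontology$max_alias_tokens, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      id <- index_get(ontology$alias_index, key)
      if (!is.null(id)) {
        hits[[id]] <- c(hits[[id]], i - 1L)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  out <- lapply(names(hits), function(id) {
    list(part_id = id, offsets = hits[[id]], count = length(hits[[id]]))
  })
  # order by first occurrence (list insertion order already is, but be explicit)
  out[order(vapply(out, function(o) o$offsets[1], numeric(1)))]
}

#' Validate an ontology and report violations
#'
#' Checks the structural invariants: exactly one tree membership per
#' non-root node (acyclic forest), unique formal names, no alias pointing
#' at two different nodes, consistent depths. The report is empty iff all
#' invariants hold.
#'
#' @param ontology a `thbp_ontology` (use `load_ontology(..., validate =
#'   FALSE)` to build one from a file without stopping on violations).
#' @return an object of class `thbp_validation`: list with `root_count`,
#'   `n_nodes`, and `problems` (character vector, empty when valid).
#' @export
validate_ontology <- function(ontology) {
  stopifnot(inherits(ontology, "thbp_ontology"))
  nodes <- ontology$nodes
  problems <- character(0)

  formals <- vapply(nodes, function(n) n$formal_name, character(1))
  dup <- unique(formals[duplicated(formals)])
  if (length(dup) > 0L) {
    problems <- c(problems, paste0("duplicate formal name: ", dup))
  }

  # alias collisions: one stemmed key claimed by two different nodes
  key_owner <- list()
  for (n in nodes) {
    for (k in n$alias_keys) key_owner[[k]] <- c(key_owner[[k]], n$id)
  }
  for (k in names(key_owner)) {
    owners <- unique(key_owner[[k]])
    if (length(owners) > 1L) {
      problems <- c(problems, paste0(
        "alias collision: '", k, "' maps to nodes ",
        paste(owners, collapse = ", ")))
    }
  }

  # reachability / cycles: walk down from roots
  children <- split(
    vapply(nodes, function(n) n$id, character(1)),
    vapply(nodes, function(n) ifelse(is.na(n$parent), "", n$parent),
           character(1)))
  reached <- character(0)
  frontier <- ontology$roots
  while (length(frontier) > 0L) {
    reached <- c(reached, frontier)
    frontier <- unlist(children[frontier], use.names = FALSE)
    frontier <- setdiff(frontier, reached)
  }
  orphans <- setdiff(names(nodes), reached)
  if (length(orphans) > 0L) {
    problems <- c(problems, paste0(
      "unreachable node (orphan or cycle): ", orphans))
  }

  for (n in nodes) {
    if (is.na(n$parent)) {
      if (!identical(n$depth, 0L)) {
        problems <- c(problems, paste0("depth inconsistency at root ", n$id))
      }
    } else if (n$parent %in% names(nodes)) {
      pd <- nodes[[n$parent]]$depth
      if (is.na(n$depth) || is.na(pd) || n$depth != pd + 1L) {
        problems <- c(problems, paste0("depth inconsistency at node ", n$id))
      }
    } else {
      problems <- c(problems, paste0("missing parent '", n$parent,
                                     "' for node ", n$id))
    }
  }

  structure(
    list(root_count = length(ontology$roots), n_nodes = length(nodes),
         problems = problems),
    class = "thbp_validation"
  )
}

#' @export
print.thbp_validation <- function(x, ...) {
  cat("THBP ontology validation: ", x$n_nodes, " nodes, ",
      x$root_count, " roots\n", sep = "")
  if (length(x$problems) == 0L) {
    cat("No violations.\n")
  } else {
    cat("Violations:\n")
    for (p in x$problems) cat("  - ", p, "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.thbp_ontology <- function(x, ...) {
  cat("<thbp_ontology> ", length(x$nodes), " body parts, ",
      length(x$roots), " top-level regions: ",
      paste(vapply(x$roots, function(id) x$nodes[[id]]$formal_name,
                   character(1)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
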