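# Run code under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

# Filler vocabulary: common non-anatomical, non-stopword nouns whose stems
# never touch the ontology's alias index (asserted at generation time).
.default_filler <- c(
  "quartz", "melody", "garden", "lantern", "pebble", "canyon", "harbor",
  "meadow", "timber", "copper", "violet", "saffron", "marble", "willow",
  "ember", "prairie", "tundra", "cobalt", "amber", "cedar", "fjord",
  "granite", "indigo", "jasper", "maple", "nectar", "onyx", "quill",
  "raven", "sepia", "topaz", "umber", "velvet", "wicker", "zephyr"
)

#' Specification of a planted explanation
#'
#' Describes a synthetic explanation text in which candidate body parts
#' occur at controlled token offsets, so the intended winner of the
#' scoring stage is known by construction and verifiable by the
#' independent reference scorer.
#'
#' @param target_part id of the intended winning part (its formal name
#'   must preprocess to a single token).
#' @param target_offsets 0-based token offsets of the target's
#'   occurrences (strictly increasing).
#' @param distractors named list: part id -> offset vector, all offsets
#'   disjoint from each other and from the target's.
#' @param filler_vocab words used to pad the remaining positions; none may
#'   be a stopword or stem into the ontology.
#' @param seed random seed controlling filler choice.
#' @param term the pseudo-term this explanation explains.
#' @return object of class `thbp_plant_spec`.
#' @export
plant_spec <- function(target_part, target_offsets, distractors = list(),
                       filler_vocab = .default_filler, seed = 1L,
                       term = paste0("synthetic_", target_part)) {
  all_off <- c(list(target_offsets), unname(distractors))
  flat <- unlist(all_off)
  stopifnot(length(target_offsets) >= 1L, all(flat >= 0),
            all(flat == floor(flat)))
  if (anyDuplicated(flat)) {
    stop("plant spec error: offset lists must be disjoint", call. = FALSE)
  }
  if (any(vapply(all_off, is.unsorted, logical(1)))) {
    stop("plant spec error: offsets must be ascending", call. = FALSE)
  }
  structure(
    list(target_part = target_part, target_offsets = as.integer(target_offsets),
         distractors = lapply(distractors, as.integer),
         filler_vocab = filler_vocab, seed = as.integer(seed), term = term),
    class = "thbp_plant_spec"
  )
}

#' Reference argmax by direct enumeration
#'
#' An independently coded scorer used to verify planted fixtures and to
#' cross-check [rank_candidates()]. It recomputes, with plain loops over
#' the raw offsets, the distance value, the cosine distance score, the
#' frequency score with its first-candidate boost, and the combined
#' score, then returns the strict argmax. It shares no code with the
#' scoring module.
#'
#' @param offset_sets named list: part id -> ascending 0-based offsets.
#' @param params a [scoring_params()] object.
#' @param depths optional named integer vector of node depths (only used
#'   to report, not to break ties).
#' @return the part id with the strictly largest score, or `NA_character_`
#'   when the top two scores tie within 1e-9.
#' @export
reference_argmax <- function(offset_sets, params = scoring_params(),
                             depths = NULL) {
  stopifnot(length(offset_sets) >= 1L, !is.null(names(offset_sets)))
  ids <- names(offset_sets)
  firsts <- numeric(length(ids))
  for (i in seq_along(ids)) firsts[i] <- offset_sets[[i]][1]
  first_id <- ids[which.min(firsts)]

  rk <- rank(firsts, ties.method = "first")
  Dv <- numeric(length(ids))
  for (i in seq_along(ids)) {
    offs <- offset_sets[[i]]
    Dv[i] <- switch(params$distance_mode,
      mean_offset = sum(offs) / length(offs),
      first_offset = offs[1],
      matched_rank = rk[i])
  }
  mx <- max(Dv)
  scores <- numeric(length(ids))
  for (i in seq_along(ids)) {
    fd <- if (mx == 0) 0 else if (mx == 1) 1 else cos(Dv[i] * (pi / 2) / mx)
    ff <- length(offset_sets[[i]])
    if (ids[i] == first_id) ff <- params$first_multiplier * ff
    scores[i] <- switch(params$algorithm,
      combined = params$a * fd + params$b * ff,
      distance = fd,
      frequency = ff)
  }
  ord <- order(scores, decreasing = TRUE)
  if (length(ids) > 1L && scores[ord[1]] - scores[ord[2]] <= 1e-9) {
    return(NA_character_)
  }
  ids[ord[1]]
}

#' Generate a synthetic explanation from a plant specification
#'
#' Emits prose whose preprocessed token stream places each candidate part
#' exactly at the specified offsets, padded with filler words, and
#' returns the reference-verified winner. A specification whose offsets
#' make a distractor win is rejected with an error, never silently
#' adjusted. Deterministic given the spec's seed.
#'
#' @param spec a [plant_spec()].
#' @param params a [scoring_params()] object.
#' @param ontology a `thbp_ontology`.
#' @param stopwords stopword list.
#' @return list with `explanation` (a `thbp_explanation`) and `winner`
#'   (the target part id).
#' @export
generate_explanation <- function(spec, params = scoring_params(),
                                 ontology = thbp_ontology(),
                                 stopwords = thbp_stopwords()) {
  stopifnot(inherits(spec, "thbp_plant_spec"))
  offset_sets <- c(stats::setNames(list(spec$target_offsets),
                                   spec$target_part),
                   spec$distractors)
  for (id in names(offset_sets)) {
    node <- ontology$nodes[[id]] %||%
      stop("plant spec error: unknown part id '", id, "'", call. = FALSE)
    if (length(stem_and_clean(node$formal_name, stopwords)) != 1L) {
      stop("plant spec error: part '", id,
           "' has a multi-token formal name; the generator places ",
           "single-token parts only", call. = FALSE)
    }
  }
  safe <- vapply(spec$filler_vocab, function(w) {
    toks <- stem_and_clean(w, stopwords)
    length(toks) == 1L && is.null(index_get(ontology$alias_index, toks))
  }, logical(1))
  if (!all(safe)) {
    stop("plant spec error: filler words stem into the ontology or the ",
         "stopword list: ",
         paste(spec$filler_vocab[!safe], collapse = ", "), call. = FALSE)
  }

  winner <- reference_argmax(offset_sets, params)
  if (is.na(winner) || winner != spec$target_part) {
    stop("generation error: specified offsets do not make '",
         spec$target_part, "' the strict winner (reference argmax: ",
         winner, ")", call. = FALSE)
  }

  total <- max(unlist(offset_sets)) + 3L
  tokens <- with_seed(spec$seed,
                      sample(spec$filler_vocab, total, replace = TRUE))
  for (id in names(offset_sets)) {
    tokens[offset_sets[[id]] + 1L] <- ontology$nodes[[id]]$formal_name
  }
  raw_text <- paste0(paste(tokens, collapse = " "), ".")

  # internal consistency: the rendered prose must preprocess back to the
  # planned stream, with every planted part at its planned offsets
  stream <- preprocess_explanation(raw_text, stopwords)
  if (length(stream) != total) {
    stop("generation error: rendered text does not preprocess to the ",
         "planned stream length", call. = FALSE)
  }
  occs <- find_matches_in_text(ontology, stream)
  got <- stats::setNames(lapply(occs, `[[`, "offsets"),
                         vapply(occs, `[[`, "", "part_id"))
  if (!identical(lapply(offset_sets[order(names(offset_sets))], as.integer),
                 lapply(got[order(names(got))], as.integer))) {
    stop("generation error: planted occurrences not recovered from the ",
         "rendered text", call. = FALSE)
  }

  expl <- structure(
    list(term = spec$term, raw_text = raw_text, tokens = stream,
         source = "fixture"),
    class = "thbp_explanation"
  )
  list(explanation = expl, winner = spec$target_part)
}

# parts whose formal names preprocess to one token (plantable in
# explanations and usable as single-word mentions)
single_token_parts <- function(ontology, stopwords = thbp_stopwords()) {
  ids <- names(ontology$nodes)
  ids[vapply(ids, function(id) {
    length(stem_and_clean(ontology$nodes[[id]]$formal_name, stopwords)) == 1L
  }, logical(1))]
}

# deterministic pseudo-term for knowledge-base-only mentions; never maps
# through the baseline string matcher, never repeats within a corpus
make_pseudo_term <- function(ontology, stopwords, exclude = character(0)) {
  syll <- c("vor", "mel", "tan", "dex", "lor", "fin", "sar", "bel", "tor",
            "nim", "gal", "res", "pol", "dar", "mex", "lun")
  suff <- c("osis", "oscopy", "ectomy", "ography", "opathy")
  for (try in 1:1000) {
    term <- paste0(paste(sample(syll, sample(2:3, 1)), collapse = ""),
                   sample(suff, 1))
    if (!term %in% exclude &&
        is.null(baseline_map(ontology, term, stopwords))) {
      return(term)
    }
  }
  stop("internal error: could not draw a non-matching pseudo-term")
}

#' Generate a synthetic benchmark corpus
#'
#' Emits a mention TSV, a gold TSV and a fixture knowledge-base directory
#' that together exercise every branch of the mapping cascade: directly
#' matchable mentions (formal names, aliases, pluralized and
#' positional-prefixed forms), multi-part and single-part abbreviations,
#' knowledge-base-only mentions backed by generated explanations whose
#' winner is verified by [reference_argmax()], and a noise fraction with
#' no knowledge-base entry (gold: unmatched). Of the non-noise mentions,
#' about 45% are direct, 15% abbreviations and 40% knowledge-base-only.
#' Fully reproducible from the seed.
#'
#' @param n number of mentions (>= 1).
#' @param ontology a `thbp_ontology`.
#' @param seed random seed.
#' @param noise fraction in `[0, 1)` of mentions with no knowledge-base
#'   entry; exactly `floor(noise * n)` such mentions are emitted.
#' @param dir output directory (created if needed); `mentions.tsv`,
#'   `gold.tsv` and `kb/` are written beneath it.
#' @param params scoring parameters used to verify planted explanations.
#' @param resources normalization resources.
#' @return list with `mentions` and `gold` data frames, `kb_dir`, and the
#'   written `paths`.
#' @export
generate_corpus <- function(n, ontology = thbp_ontology(), seed = 1L,
                            noise = 0, dir = tempfile("thbp_corpus_"),
                            params = scoring_params(),
                            resources = thbp_resources()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("input error: n must be >= 1", call. = FALSE)
  }
  stopifnot(noise >= 0, noise < 1)
  n <- as.integer(n)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kb_dir <- file.path(dir, "kb")
  dir.create(kb_dir, showWarnings = FALSE)
  stopwords <- resources$stopwords

  with_seed(seed, {
    n_noise <- floor(noise * n)
    n_rest <- n - n_noise
    n_kb <- round(0.40 * n_rest)
    n_ab <- min(round(0.15 * n_rest), n_rest - n_kb)
    n_dir <- n_rest - n_kb - n_ab

    kinds <- sample(c(rep("direct", n_dir), rep("abbrev", n_ab),
                      rep("kb", n_kb), rep("noise", n_noise)))
    plantable <- single_token_parts(ontology, stopwords)
    all_ids <- names(ontology$nodes)
    abbrev_keys <- names(resources$abbrev)
    # only dictionary abbreviations every variant can ground in the ontology
    abbrev_keys <- abbrev_keys[vapply(abbrev_keys, function(k) {
      all(vapply(resources$abbrev[[k]], function(f) {
        sp <- strip_positional(stem_and_clean(f, stopwords),
                               resources$positional, ontology)
        !is.null(string_match(ontology, sp$core))
      }, logical(1)))
    }, logical(1))]
    pos_surfaces <- c("left", "right", "bilateral", "upper", "lower")

    mentions <- data.frame(doc_id = character(n), mention_id = character(n),
                           start = character(n), end = character(n),
                           surface = character(n),
                           coref_chain_id = character(n),
                           stringsAsFactors = FALSE)
    gold <- data.frame(mention_id = character(n), part_ids = character(n),
                       stringsAsFactors = FALSE)
    variant_cycle <- c("formal", "alias", "plural", "positional")
    vi <- 0L
    offset <- 0L
    used_terms <- character(0)

    for (i in seq_len(n)) {
      kind <- kinds[i]
      mid <- sprintf("m%05d", i)
      surface <- ""
      gold_ids <- character(0)

      if (kind == "direct") {
        id <- sample(all_ids, 1)
        node <- ontology$nodes[[id]]
        vi <- vi + 1L
        variant <- variant_cycle[(vi - 1L) %% 4L + 1L]
        surface <- switch(variant,
          formal = node$formal_name,
          alias = if (length(node$aliases) > 0L) {
            sample(node$aliases, 1)
          } else {
            node$formal_name
          },
          plural = paste0(node$formal_name, "s"),
          positional = paste(sample(pos_surfaces, 1), node$formal_name)
        )
        # positional prefix may not collide with a longer alias elsewhere
        if (!is.null(string_match(ontology,
                                  stem_and_clean(surface, stopwords)))) {
          gold_ids <- string_match(ontology,
            strip_positional(stem_and_clean(surface, stopwords),
                             resources$positional, ontology)$core)$id
        } else {
          surface <- node$formal_name
          gold_ids <- id
        }
      } else if (kind == "abbrev") {
        key <- sample(abbrev_keys, 1)
        surface <- toupper(gsub(" ", "", key))
        gold_ids <- unique(vapply(resources$abbrev[[key]], function(f) {
          sp <- strip_positional(stem_and_clean(f, stopwords),
                                 resources$positional, ontology)
          string_match(ontology, sp$core)$id
        }, character(1)))
      } else if (kind == "kb") {
        surface <- make_pseudo_term(ontology, stopwords, used_terms)
        used_terms <- c(used_terms, surface)
        target <- sample(plantable, 1)
        distractor_pool <- setdiff(plantable, target)
        n_dis <- sample(0:2, 1)
        dis <- if (n_dis > 0L) sample(distractor_pool, n_dis) else character(0)
        # target occurs first and at least as often as any distractor, so
        # with the first-appearance boost it wins strictly
        t_count <- sample(2:4, 1)
        t_off <- c(0L, sort(sample(seq(2L, 14L, by = 2L), t_count - 1L)))
        used <- t_off
        distractors <- list()
        for (d in dis) {
          d_count <- sample(1:t_count, 1)
          pool <- setdiff(seq(15L, 60L), used)
          d_off <- sort(sample(pool, d_count))
          used <- c(used, d_off)
          distractors[[d]] <- d_off
        }
        spec <- plant_spec(target, t_off, distractors,
                           seed = seed + i, term = surface)
        gen <- generate_explanation(spec, params, ontology, stopwords)
        writeLines(gen$explanation$raw_text,
                   file.path(kb_dir, paste0(kb_slug(surface), ".txt")))
        gold_ids <- gen$winner
      } else {  # noise: no knowledge-base entry anywhere
        surface <- make_pseudo_term(ontology, stopwords, used_terms)
        used_terms <- c(used_terms, surface)
        gold_ids <- character(0)
      }

      mentions$doc_id[i] <- paste0("doc", (i - 1L) %% 5L + 1L)
      mentions$mention_id[i] <- mid
      mentions$start[i] <- as.character(offset)
      mentions$end[i] <- as.character(offset + nchar(surface))
      mentions$surface[i] <- surface
      offset <- offset + nchar(surface) + 1L
      gold$mention_id[i] <- mid
      gold$part_ids[i] <- paste(gold_ids, collapse = ";")
    }

    paths <- list(mentions = file.path(dir, "mentions.tsv"),
                  gold = file.path(dir, "gold.tsv"))
    utils::write.table(mentions, paths$mentions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(gold, paths$gold, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(mentions = mentions, gold = gold, kb_dir = kb_dir, paths = paths)
  })
}
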