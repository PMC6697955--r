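#' Scoring parameters
#'
#' Bundles the tunable constants of the candidate-scoring stage. The
#' combined score of a candidate body part n found in an explanation is
#'
#'   Score(n) = a * f(D(n)) + b * f(F(n))
#'
#' where f(D) is the cosine-transformed occurrence distance (in `[0, 1]`,
#' 1 at the onset of the explanation, 0 at the last-matched candidate)
#' and f(F) is the occurrence frequency, boosted by `first_multiplier`
#' for the candidate that appears first. The defaults a = 15, b = 1 and
#' first_multiplier = 2.5 are the shipped operating point (originally
#' selected by cross-validation on clinical text); no re-estimation is
#' attempted here.
#'
#' @param a distance-term coefficient (> 0).
#' @param b frequency-term coefficient (> 0).
#' @param first_multiplier frequency boost for the first-appearing
#'   candidate (> 0).
#' @param distance_mode how the distance value D(n) summarizes a
#'   candidate's offsets: `"mean_offset"` (arithmetic mean of its 0-based
#'   token offsets; the default), `"first_offset"` (offset of its first
#'   occurrence), or `"matched_rank"` (1-based rank of its first
#'   occurrence among all candidates' first occurrences).
#' @param tie_break order of candidates whose combined scores tie within
#'   1e-9: `"deeper_node"` (prefer the node deeper in the ontology, the
#'   default, consistent with mapping to the lowest layer),
#'   `"earliest_occurrence"`, or `"lexicographic"`.
#' @param algorithm `"combined"` (default), `"distance"` (rank by f(D)
#'   only), or `"frequency"` (rank by f(F) only).
#' @return object of class `thbp_params`.
#' @export
scoring_params <- function(a = 15, b = 1, first_multiplier = 2.5,
                           distance_mode = c("mean_offset", "first_offset",
                                             "matched_rank"),
                           tie_break = c("deeper_node",
                                         "earliest_occurrence",
                                         "lexicographic"),
                           algorithm = c("combined", "distance",
                                         "frequency")) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L, b > 0,
            is.numeric(first_multiplier), length(first_multiplier) == 1L,
            first_multiplier > 0)
  structure(
    list(a = a, b = b, first_multiplier = first_multiplier,
         distance_mode = match.arg(distance_mode),
         tie_break = match.arg(tie_break),
         algorithm = match.arg(algorithm)),
    class = "thbp_params"
  )
}

#' Distance value of a candidate's occurrences
#'
#' Summarizes an occurrence list into a single distance value D(n). The
#' default mode is the arithmetic mean of the candidate's 0-based token
#' offsets ("the average distance between each appearance and the onset
#' of the explanation"); `first_offset` and `matched_rank` are alternative
#' readings provided as configuration.
#'
#' @param occ an occurrence list (see [find_matches_in_text()]).
#' @param mode one of `"mean_offset"`, `"first_offset"`, `"matched_rank"`.
#' @param rank for `matched_rank` mode, the candidate's 1-based rank by
#'   first occurrence among all candidates (supplied by the caller).
#' @return the distance value (non-negative number).
#' @export
distance_value <- function(occ, mode = "mean_offset", rank = NULL) {
  if (is.null(occ$offsets) || length(occ$offsets) == 0L) {
    stop("contract violation: empty occurrence list", call. = FALSE)
  }
  switch(mode,
    mean_offset = mean(occ$offsets),
    first_offset = occ$offsets[1],
    matched_rank = {
      if (is.null(rank)) stop("matched_rank mode needs the rank argument",
                              call. = FALSE)
      rank
    },
    stop("unknown distance mode: ", mode, call. = FALSE)
  )
}

#' Cosine-transformed distance score
#'
#' Maps a distance value into `[0, 1]`:
#' `cos(D * (pi/2) / maxD)` when `maxD > 1`, exactly 1 when `maxD == 1`,
#' and exactly 0 when `maxD == 0` (all candidates at the onset, so the
#' distance term carries no information and scoring degenerates to the
#' frequency term). A candidate at the onset scores 1; the last-matched
#' candidate (D == maxD) scores 0. For the fractional case 0 < maxD < 1,
#' which can arise under mean offsets, the cosine branch applies
#' (continuous extension).
#'
#' @param D distance value, `0 <= D <= maxD`.
#' @param maxD maximum distance value over the candidates of one
#'   explanation.
#' @return the distance sub-score f(D) in `[0, 1]`.
#' @examples
#' distance_score(0, 5)    # 1
#' distance_score(5, 10)   # cos(pi/4)
#' distance_score(8, 8)    # 0 (within floating point)
#' @export
distance_score <- function(D, maxD) {
  stopifnot(is.numeric(D), is.numeric(maxD), length(maxD) == 1L)
  if (any(D < 0) || any(D > maxD + 1e-9)) {
    stop("contract violation: need 0 <= D <= maxD", call. = FALSE)
  }
  if (maxD == 0) return(rep(0, length(D)))
  if (maxD == 1) return(rep(1, length(D)))
  cos(D * (pi / 2) / maxD)
}

#' Frequency score
#'
#' The raw occurrence frequency F(n), multiplied by `first_multiplier`
#' (default 2.5) for the first-appearing candidate, which is strongly
#' related to the mapping result.
#'
#' @param F occurrence count (>= 0).
#' @param is_first logical: is this the candidate with the minimal
#'   earliest offset?
#' @param first_multiplier the boost constant.
#' @return the frequency sub-score f(F).
#' @export
frequency_score <- function(F, is_first, first_multiplier = 2.5) {
  stopifnot(is.numeric(F), is.logical(is_first))
  if (any(F < 0)) {
    stop("contract violation: negative frequency", call. = FALSE)
  }
  ifelse(is_first, first_multiplier * F, F)
}

#' Combined score
#'
#' `a * f_D + b * f_F` with the coefficients in `params`.
#'
#' @param f_D distance sub-score.
#' @param f_F frequency sub-score.
#' @param params a [scoring_params()] object.
#' @return the combined score.
#' @export
combined_score <- function(f_D, f_F, params = scoring_params()) {
  params$a * f_D + params$b * f_F
}

#' Score and rank candidate body parts found in one explanation
#'
#' Computes, for every candidate, the distance value D (per
#' `params$distance_mode`), the maximum distance over candidates, the
#' first-appearing flag (minimal earliest offset; offset ties go to the
#' candidate appearing first in text order), the sub-scores f(D) and
#' f(F), and the score under `params$algorithm`. Candidates are returned
#' in descending score order; scores that tie within 1e-9 are ordered by
#' `params$tie_break`. The head of the list is the selected mapping.
#'
#' @param occs occurrence lists from [find_matches_in_text()] on one
#'   explanation's token stream.
#' @param ontology the ontology (for node depth and formal names).
#' @param params a [scoring_params()] object.
#' @return a data frame (one row per candidate, best first) with columns
#'   `part_id`, `formal_name`, `depth`, `first_offset`, `D`, `F`,
#'   `is_first`, `f_D`, `f_F`, `score`; zero rows when `occs` is empty.
#' @export
rank_candidates <- function(occs, ontology, params = scoring_params()) {
  empty <- data.frame(part_id = character(0), formal_name = character(0),
                      depth = integer(0), first_offset = numeric(0),
                      D = numeric(0), F = numeric(0), is_first = logical(0),
                      f_D = numeric(0), f_F = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(occs) == 0L) return(empty)
  stopifnot(inherits(ontology, "thbp_ontology"))

  first_offsets <- vapply(occs, function(o) o$offsets[1], numeric(1))
  counts <- vapply(occs, function(o) o$count, numeric(1))
  ids <- vapply(occs, function(o) o$part_id, character(1))

  # first entity: minimal earliest offset; offset tie -> first in text order
  is_first <- seq_along(occs) == which.min(first_offsets)

  ranks <- rank(first_offsets, ties.method = "first")
  D <- vapply(seq_along(occs), function(i) {
    distance_value(occs[[i]], params$distance_mode, rank = ranks[i])
  }, numeric(1))
  maxD <- max(D)
  f_D <- distance_score(D, maxD)
  f_F <- frequency_score(counts, is_first, params$first_multiplier)
  score <- switch(params$algorithm,
    combined = combined_score(f_D, f_F, params),
    distance = f_D,
    frequency = f_F
  )

  depth <- vapply(ids, function(id) ontology$nodes[[id]]$depth, integer(1))
  formal <- vapply(ids, function(id) ontology$nodes[[id]]$formal_name,
                   character(1))

  # group scores that tie within 1e-9, then apply the configured tie-break
  ord0 <- order(-score)
  group <- integer(length(score))
  g <- 0L
  last <- Inf
  for (i in ord0) {
    if (last - score[i] > 1e-9) g <- g + 1L
    group[i] <- g
    last <- score[i]
  }
  ord <- switch(params$tie_break,
    deeper_node = order(group, -depth, first_offsets, formal),
    earliest_occurrence = order(group, first_offsets, -depth, formal),
    lexicographic = order(group, formal, first_offsets)
  )

  out <- data.frame(part_id = ids, formal_name = formal, depth = depth,
                    first_offset = first_offsets, D = D, F = counts,
                    is_first = is_first, f_D = f_D, f_F = f_F, score = score,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
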