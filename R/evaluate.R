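#' Evaluate predicted mappings against gold mappings
#'
#' Micro-averaged precision, recall and F1 over (mention_id, part) pairs:
#' a true positive is a pair present in both predictions and gold, a false
#' positive is predicted-only, a false negative is gold-only. Unmatched
#' predictions assert nothing and contribute no pairs. Multi-part mappings
#' (e.g. abbreviations expanding to several body parts) contribute one
#' pair per part. By default pairs are keyed by part id, so positional
#' prefixes do not affect agreement; `strict_labels = TRUE` keys pairs by
#' the full final label instead.
#'
#' @param predictions result data frame from [map_corpus()] or path to a
#'   result TSV (columns `mention_id` and `part_ids`, semicolon-separated;
#'   `parts` for strict-label scoring).
#' @param gold gold data frame or TSV path (columns `mention_id`,
#'   `part_ids`; `parts` for strict-label scoring). Mention ids must be
#'   unique; an unmatched gold mention has an empty `part_ids`.
#' @param strict_labels match on positional-prefixed labels rather than
#'   part ids.
#' @return object of class `thbp_eval`: list with counts `tp`, `fp`, `fn`
#'   and ratios `precision`, `recall`, `f1` in `[0, 1]`. The print method
#'   renders percentages to two decimals.
#' @examples
#' pred <- data.frame(mention_id = "m1", part_ids = "heart")
#' gold <- data.frame(mention_id = "m1", part_ids = "heart")
#' evaluate_mappings(pred, gold)
#' @export
evaluate_mappings <- function(predictions, gold, strict_labels = FALSE) {
  read_tab <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      utils::read.delim(x, colClasses = "character")
    } else {
      x
    }
  }
  predictions <- read_tab(predictions)
  gold <- read_tab(gold)
  col <- if (strict_labels) "parts" else "part_ids"
  for (nm in list(list(predictions, "predictions"), list(gold, "gold"))) {
    if (!all(c("mention_id", col) %in% names(nm[[1]]))) {
      stop("input error: ", nm[[2]], " need columns mention_id and ", col,
           call. = FALSE)
    }
  }
  if (anyDuplicated(gold$mention_id)) {
    stop("input error: duplicate mention_id in gold", call. = FALSE)
  }
  stray <- setdiff(predictions$mention_id, gold$mention_id)
  if (length(stray) > 0L) {
    stop("input error: prediction references mention_id absent from gold: ",
         stray[1], call. = FALSE)
  }

  pairs <- function(df) {
    vals <- strsplit(as.character(df[[col]]), ";", fixed = TRUE)
    out <- mapply(function(id, v) {
      v <- v[nzchar(v)]
      if (length(v) == 0L) character(0) else paste(id, v, sep = "\r")
    }, df$mention_id, vals, SIMPLIFY = FALSE)
    unique(unlist(out, use.names = FALSE))
  }
  p <- pairs(predictions)
  g <- pairs(gold)
  tp <- length(intersect(p, g))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  structure(
    list(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1),
    class = "thbp_eval"
  )
}

#' @export
print.thbp_eval <- function(x, ...) {
  cat(sprintf(
    "Mention-level evaluation (micro pairs)\n  TP %d  FP %d  FN %d\n  Precision %.2f%%  Recall %.2f%%  F1 %.2f%%\n",
    x$tp, x$fp, x$fn, 100 * x$precision, 100 * x$recall, 100 * x$f1))
  invisible(x)
}
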