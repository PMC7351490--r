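## Threshold-gated sort decisions and the false-positive error bound.

#' Sorting thresholds on the Wavelet OD
#'
#' Droplets with a score inside `[lower, upper]` (inclusive on both ends)
#' are classified as slow-growing colonies and kept; below is empty, above
#' is a dense colony. Defaults are the empirically identified gate
#' (0.3, 0.7).
#'
#' @param lower,upper Gate bounds, `0 <= lower < upper <= 1`.
#' @return An object of class `sort_thresholds`.
#' @export
sort_thresholds <- function(lower = 0.3, upper = 0.7) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      lower < 0 || upper > 1 || lower >= upper) {
    stop_invalid("need 0 <= lower < upper <= 1")
  }
  structure(list(lower = lower, upper = upper), class = "sort_thresholds")
}

#' Classify a Wavelet OD score
#'
#' @param score Score in `[0, 1]`.
#' @param thresholds A [sort_thresholds()].
#' @return One of `"empty"`, `"slow"`, `"dense"`.
#' @export
classify_od <- function(score, thresholds = sort_thresholds()) {
  if (!is.numeric(score) || any(is.na(score)) ||
      any(score < 0) || any(score > 1)) {
    stop_invalid("`score` must lie in [0, 1]")
  }
  ifelse(score < thresholds$lower, "empty",
    ifelse(score > thresholds$upper, "dense", "slow")
  )
}

#' Sort a stream of scores
#'
#' Applies [classify_od()] to each score; droplets classified `"slow"` are
#' kept, the rest go to waste. The decision log is a pure function of
#' `(scores, thresholds)`.
#'
#' @param scores Numeric vector of Wavelet OD values.
#' @param thresholds A [sort_thresholds()].
#' @param ids Optional droplet identifiers (defaults to `seq_along(scores)`).
#' @return A list with `decisions` (data frame: `id`, `score`, `class`,
#'   `keep`) and `counts` (named vector over empty/slow/dense).
#' @export
sort_stream <- function(scores, thresholds = sort_thresholds(), ids = NULL) {
  if (length(scores) == 0) {
    return(list(
      decisions = data.frame(
        id = integer(), score = numeric(),
        class = character(), keep = logical()
      ),
      counts = c(empty = 0L, slow = 0L, dense = 0L)
    ))
  }
  cls <- classify_od(scores, thresholds)
  decisions <- data.frame(
    id = ids %||% seq_along(scores),
    score = scores,
    class = cls,
    keep = cls == "slow",
    stringsAsFactors = FALSE
  )
  counts <- c(
    empty = sum(cls == "empty"),
    slow = sum(cls == "slow"),
    dense = sum(cls == "dense")
  )
  list(decisions = decisions, counts = counts)
}

#' Write a decision log as JSON lines
#'
#' @param decisions Decision data frame from [sort_stream()].
#' @param path Output path (`.jsonl`).
#' @export
write_decision_log <- function(decisions, path) {
  lines <- vapply(seq_len(nrow(decisions)), function(i) {
    jsonlite::toJSON(as.list(decisions[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Upper bound on the false-positive sorting rate
#'
#' Given the fraction of slow-growing colonies in the unsorted stream,
#' `f_un`, and in the kept (sorted) stream, `f_s`, the false-positive rate
#' is bounded by `epsilon <= f_un (1 - f_s) / (f_s (1 - f_un))`. The bound
#' is an equality when the false-negative rate is zero.
#'
#' @param f_un,f_s Slow-grower fractions in (0, 1).
#' @return The bound `epsilon`.
#' @examples
#' false_positive_bound(0.05, 0.5)
#' @export
false_positive_bound <- function(f_un, f_s) {
  if (!is.numeric(f_un) || !is.numeric(f_s) ||
      f_un <= 0 || f_un >= 1 || f_s <= 0 || f_s >= 1) {
    stop_invalid("`f_un` and `f_s` must lie strictly in (0, 1)")
  }
  (f_un * (1 - f_s)) / (f_s * (1 - f_un))
}
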