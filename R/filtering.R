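## Dead/nonviable-DNA carryover filtering of ASV count tables.
##
## DNA from dead or nonviable cells in the inoculum contributes reads to a
## cultured sample in proportion to the stool composition. The filter (i)
## fits the carryover fraction p_nv on ASVs that are clearly depleted
## relative to stool, (ii) computes a 90% maximum-likelihood confidence
## interval for each ASV's proportion on the log-odds (logit) scale, and
## (iii) discards ASVs whose lower confidence limit does not exceed their
## expected carryover contribution.

props <- function(x) {
  if (any(x < 0) || sum(x) <= 0) {
    stop_invalid("counts must be non-negative with positive sum")
  }
  x / sum(x)
}

#' Fit the dead/nonviable carryover fraction
#'
#' ASVs whose sample proportion is at least `fold_threshold` times below
#' their stool proportion are assumed to be pure carryover; on those the
#' model `sample_prop = p_nv * stool_prop` is fitted. The default estimator
#' is the least-squares slope through the origin; `method = "ratio"` uses
#' the median of per-ASV ratios instead (robust to single outliers).
#'
#' @param sample_counts Integer count vector for the cultured sample.
#' @param stool_counts Integer count vector for the raw-stool reference
#'   (same ASVs, same order or shared names).
#' @param fold_threshold Depletion factor defining qualifying ASVs
#'   (default 10).
#' @param method `"ls"` (least squares through the origin) or `"ratio"`
#'   (median of ratios).
#' @return An object of class `nonviable_fit`: list with `p_nv`,
#'   `qualifying` (ASV names or indices), `fold_threshold`, `method`.
#' @export
fit_nonviable_fraction <- function(sample_counts, stool_counts,
                                   fold_threshold = 10,
                                   method = c("ls", "ratio")) {
  method <- match.arg(method)
  if (length(sample_counts) != length(stool_counts)) {
    stop_invalid("sample and stool columns must share the ASV index")
  }
  s <- props(sample_counts)
  q <- props(stool_counts)
  qual <- which(q > 0 & s <= q / fold_threshold)
  if (length(qual) == 0) {
    stop_invalid("no ASV qualifies for the carryover fit",
                 class = "dropcult_no_fit")
  }
  p_nv <- if (method == "ls") {
    sum(s[qual] * q[qual]) / sum(q[qual]^2)
  } else {
    stats::median(s[qual] / q[qual])
  }
  structure(
    list(
      p_nv = p_nv,
      qualifying = if (is.null(names(s))) qual else names(s)[qual],
      fold_threshold = fold_threshold,
      method = method
    ),
    class = "nonviable_fit"
  )
}

#' @export
print.nonviable_fit <- function(x, ...) {
  cat(sprintf(
    "Carryover fit: p_nv = %.4f (%d qualifying ASVs, %s, fold threshold %g)\n",
    x$p_nv, length(x$qualifying), x$method, x$fold_threshold
  ))
  invisible(x)
}

#' Logit-scale MLE confidence interval for a read proportion
#'
#' For `x` reads of an ASV among `n` total, the proportion `p` is
#' reparametrized as `theta = ln(p / (1 - p))`. The log likelihood is
#' `l(theta) = x theta - n ln(1 + e^theta)` (plus a constant), with maximum
#' at `theta_hat = ln(x / (n - x))` and observed information
#' `-l''(theta_hat) = n p_hat (1 - p_hat)`. The interval is
#' `theta_hat +/- z / sqrt(n p_hat (1 - p_hat))`, transformed back to the
#' proportion and count scales.
#'
#' `x = 0` raises a degenerate-proportion error (the logit is undefined;
#' such ASVs are treated as absent upstream). `x = n` uses a continuity
#' correction `x - 0.5` for the lower limit and sets the upper limit to 1.
#'
#' @param x ASV read count, `0 < x <= n`.
#' @param n Total reads in the sample.
#' @param level Confidence level (default 0.90, i.e. `z = 1.645`).
#' @return An object of class `proportion_ci`: list with `p_hat`,
#'   `theta_hat`, `level`, `z`, `lower_p`, `upper_p`, `lower_count`,
#'   `upper_count`.
#' @export
proportion_ci <- function(x, n, level = 0.90) {
  if (n < 1 || x < 0 || x > n) stop_invalid("need 0 <= x <= n, n >= 1")
  if (level <= 0 || level >= 1) stop_invalid("`level` must lie in (0, 1)")
  if (x == 0) {
    stop_invalid("x = 0: proportion degenerate at the boundary",
                 class = "dropcult_degenerate")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  at_upper <- x == n
  xe <- if (at_upper) x - 0.5 else x  # continuity correction at x = n
  p_hat <- xe / n
  theta_hat <- log(p_hat / (1 - p_hat))
  half <- z / sqrt(n * p_hat * (1 - p_hat))
  lower_p <- stats::plogis(theta_hat - half)
  upper_p <- if (at_upper) 1 else stats::plogis(theta_hat + half)
  structure(
    list(
      p_hat = x / n, theta_hat = theta_hat, level = level, z = z,
      lower_p = lower_p, upper_p = upper_p,
      lower_count = lower_p * n, upper_count = upper_p * n
    ),
    class = "proportion_ci"
  )
}

#' Filter ASVs against the carryover expectation
#'
#' For each ASV detected in the sample, the expected carryover count is
#' `p_nv * stool_proportion * n`. The ASV is discarded when the lower limit
#' of its [proportion_ci()] falls below that threshold -- i.e. retained only
#' when its abundance is demonstrably above what dead-DNA carryover alone
#' would produce. ASVs absent from stool have threshold 0 and are always
#' retained; zero-count ASVs pass through as absent.
#'
#' @param sample_counts,stool_counts Count vectors sharing the ASV index.
#' @param fit A [fit_nonviable_fraction()] result.
#' @param level Confidence level for the per-ASV interval.
#' @return A list with `retained` (names/indices of ASVs kept),
#'   `filtered_counts` (sample counts with discarded ASVs zeroed) and `log`
#'   (data frame: `asv_id`, `x`, `n`, `lower_count`, `threshold_count`,
#'   `decision`).
#' @export
filter_asvs <- function(sample_counts, stool_counts, fit, level = 0.90) {
  stopifnot(inherits(fit, "nonviable_fit"))
  if (length(sample_counts) != length(stool_counts)) {
    stop_invalid("sample and stool columns must share the ASV index")
  }
  n <- sum(sample_counts)
  q <- props(stool_counts)
  ids <- names(sample_counts) %||% as.character(seq_along(sample_counts))
  present <- which(sample_counts > 0)
  rows <- lapply(present, function(i) {
    x <- sample_counts[[i]]
    ci <- proportion_ci(x, n, level)
    threshold <- fit$p_nv * q[[i]] * n
    data.frame(
      asv_id = ids[i], x = x, n = n,
      lower_count = ci$lower_count,
      threshold_count = threshold,
      decision = if (ci$lower_count < threshold) "discard" else "retain",
      stringsAsFactors = FALSE
    )
  })
  log <- do.call(rbind, rows) %||% data.frame(
    asv_id = character(), x = integer(), n = integer(),
    lower_count = numeric(), threshold_count = numeric(),
    decision = character()
  )
  retained <- log$asv_id[log$decision == "retain"]
  filtered <- sample_counts
  filtered[!(ids %in% retained)] <- 0L
  list(retained = retained, filtered_counts = filtered, log = log)
}
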