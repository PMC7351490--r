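## TSV readers/writers and run configuration.

#' Read an ASV count table
#'
#' Expects a TSV whose header starts with `asv_id` followed by sample ids,
#' with non-negative integer cells. Parse failures name the offending line.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, rows = ASVs (rownames), columns = samples.
#' @export
read_asv_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_invalid("ASV table needs a header and at least one row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "asv_id") {
    stop_invalid("line 1: first column header must be 'asv_id'")
  }
  samples <- header[-1]
  if (anyDuplicated(samples)) stop_invalid("line 1: duplicate sample ids")
  ncol_expect <- length(header)
  ids <- character(length(lines) - 1L)
  mat <- matrix(0L, length(lines) - 1L, length(samples))
  for (i in seq_along(lines)[-1]) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(cells) != ncol_expect) {
      stop_invalid(sprintf(
        "line %d: expected %d columns, found %d", i, ncol_expect, length(cells)
      ))
    }
    ids[i - 1L] <- cells[1]
    vals <- suppressWarnings(as.numeric(cells[-1]))
    if (any(is.na(vals)) || any(vals < 0) || any(vals != floor(vals))) {
      stop_invalid(sprintf("line %d: counts must be non-negative integers", i))
    }
    mat[i - 1L, ] <- as.integer(vals)
  }
  if (anyDuplicated(ids)) {
    stop_invalid(sprintf(
      "line %d: duplicate ASV id '%s'",
      which(duplicated(ids))[1] + 1L, ids[duplicated(ids)][1]
    ))
  }
  dimnames(mat) <- list(ids, samples)
  mat
}

#' Write an ASV count table
#'
#' Writes the TSV format read by [read_asv_table()], LF line endings, so a
#' write-then-read round trip is byte-identical.
#'
#' @param table Integer matrix, rows = ASVs, columns = samples.
#' @param path Output path.
#' @export
write_asv_table <- function(table, path) {
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    stop_invalid("table needs ASV rownames and sample colnames")
  }
  header <- paste(c("asv_id", colnames(table)), collapse = "\t")
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], format(table[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")  # binary mode forces LF on every platform
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

## run-config schema: key -> validator
.config_schema <- list(
  seed = is.numeric,
  community = is.list,
  thresholds = is.list,
  encapsulation = is.list,
  filter = is.list,
  sorting_window_quantiles = is.numeric,
  out_dir = is.character
)

#' Read and validate a run configuration
#'
#' YAML file with (all optional) keys `seed`, `community` (arguments of
#' [community_spec()]), `thresholds` (`lower`, `upper`), `encapsulation`
#' (arguments of [encapsulation_model()]), `filter` (`level`,
#' `fold_threshold`), `sorting_window_quantiles` (two quantiles of the
#' positive colony-size distribution defining the keep window), `out_dir`.
#' Unknown or mistyped keys raise a schema error naming the key.
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop_invalid("config must be a mapping")
  for (key in names(cfg)) {
    if (!key %in% names(.config_schema)) {
      stop_invalid(sprintf("unknown config key '%s'", key))
    }
    if (!.config_schema[[key]](cfg[[key]])) {
      stop_invalid(sprintf("config key '%s' has the wrong type", key))
    }
  }
  structure(cfg, class = "run_config")
}
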