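# JSON/CSV result serialization. JSON is written at full double precision
# (digits = NA) so numeric fields survive a write -> read round trip
# bit-exactly.

as_report_list <- function(x) UseMethod("as_report_list")

#' @export
as_report_list.default <- function(x) x

#' @export
as_report_list.gni_result <- function(x) {
  list(
    type = "gni_result",
    gni = x$gni,
    n_slices = x$n_slices,
    n_macro_pixels = x$n_macro_pixels,
    bin_width = x$histogram$bin_width,
    params = x$params,
    histogram = list(bin_edges = x$histogram$bin_edges,
                     counts = x$histogram$counts,
                     n_total = x$histogram$n_total)
  )
}

#' @export
as_report_list.voi_measurement <- function(x) {
  c(list(type = "voi_measurement"), unclass(x))
}

#' @export
as_report_list.roc_result <- function(x) {
  c(list(type = "roc_result"), unclass(x))
}

#' @export
as_report_list.ks_result <- function(x) {
  c(list(type = "ks_result"), unclass(x))
}

#' @export
as_report_list.correlation_result <- function(x) {
  c(list(type = "correlation_result"), unclass(x))
}

#' @export
as_report_list.slice_gni_series <- function(x) {
  c(list(type = "slice_gni_series"), unclass(x))
}

#' Write a machine-readable results report
#'
#' Serializes a (named) collection of results -- GNI results, VOI
#' measurements, test statistics, ROC analyses, data frames -- to one JSON
#' file at full numeric precision, plus one CSV per data-frame entry.
#'
#' @param results Non-empty (preferably named) list of result objects.
#' @param path Output JSON path; sibling CSVs take the entry name as suffix.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (length(results) == 0) stop("io error: empty results collection", call. = FALSE)
  if (inherits(results, c("gni_result", "voi_measurement", "roc_result",
                          "ks_result", "correlation_result"))) {
    results <- list(result = results)
  }
  if (is.null(names(results))) {
    names(results) <- paste0("result_", seq_along(results))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  payload <- lapply(results, as_report_list)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("io error: cannot write ", path, call. = FALSE)
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      csv <- sub("\\.json$", paste0("_", nm, ".csv"), path)
      utils::write.csv(results[[nm]], csv, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path JSON report path.
#' @return Nested list of results.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a noise histogram as CSV
#'
#' Columns `bin_left`, `bin_right`, `count`.
#'
#' @param hist A [noise_histogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "noise_histogram"))
  df <- data.frame(
    bin_left = head(hist$bin_edges, -1),
    bin_right = tail(hist$bin_edges, -1),
    count = hist$counts
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
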