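#' Write an analysis report
#'
#' Serializes a named list of results to JSON or CSV with stable key order,
#' floats at 6 significant digits, and an embedded configuration echo plus
#' the package version, so a run can be reproduced from its own report.
#'
#' @param results named list (JSON) or data.frame (CSV) of results.
#' @param path output file path.
#' @param format "json" or "csv".
#' @param config named list echoed into the report (seeds, parameters).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         config = list()) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "json") {
    payload <- list(
      package = "monosurf",
      version = as.character(utils::packageVersion("monosurf")),
      config = config,
      results = signif_rec(results, 6L))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    if (!is.data.frame(results)) abort_input("CSV reports need a data.frame")
    num <- vapply(results, is.numeric, logical(1))
    results[num] <- lapply(results[num], signif, 6L)
    utils::write.csv(results, path, row.names = FALSE)
  }
  invisible(path)
}

# round all numeric leaves to 6 significant digits, preserving structure
signif_rec <- function(x, digits) {
  if (is.list(x)) lapply(x, signif_rec, digits = digits)
  else if (is.numeric(x)) signif(x, digits)
  else x
}

#' Read back a JSON report
#'
#' @param path report path written by [write_report()].
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
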