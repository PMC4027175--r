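#' Trace CSV input/output
#'
#' Traces are written as plain CSV with a header line `t,<series...>`,
#' preceded by `#` comment lines carrying the units and model metadata.
#' The round trip is deterministic: `read_trace_csv(write_trace_csv(x))`
#' reproduces the numeric content exactly (values are written with full
#' double precision).
#'
#' @param trace an `iffl_trace` (or any data.frame with a `t` column).
#' @param path file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns an `iffl_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# units: ", attr(trace, "units") %||% "unspecified"),
    paste0("# model: ", attr(trace, "model") %||% "unspecified")), con)
  utils::write.table(format(as.data.frame(trace), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NA_character_
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  structure(df, class = c("iffl_trace", "data.frame"),
            units = get_meta("units"), model = get_meta("model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
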