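#' Write a result table to TSV or JSON
#'
#' Deterministic column order (as supplied), floats serialised with 12
#' significant digits in both formats.
#'
#' @param rows a data frame, or a list of named lists sharing one schema.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(rows)) {
    if (!is.list(rows) || !length(rows)) {
      rlang::abort("rows must be a data frame or a non-empty list of named lists.",
                   class = "anchortraj_validation_error")
    }
    schemas <- lapply(rows, names)
    if (any(vapply(schemas, function(s) !identical(s, schemas[[1]]), TRUE))) {
      rlang::abort("rows have mismatched schemas (differing column names).",
                   class = "anchortraj_format_error")
    }
    rows <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }
  rows <- tibble::as_tibble(rows)
  if (format == "tsv") {
    out <- rows
    num <- vapply(out, is.double, TRUE)
    out[num] <- lapply(out[num], function(x) {
      ifelse(is.na(x), NA_character_, formatC(x, digits = 12, format = "g"))
    })
    readr::write_tsv(out, path, progress = FALSE, na = "NA")
  } else {
    jsonlite::write_json(rows, path, digits = 12, dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Read back a table written by [write_table()]
#' @param path file written by `write_table`.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble with numeric columns restored.
#' @export
read_table_file <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
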