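# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# ";"-separated list fields in rulebase CSVs
split_list_field <- function(x) {
  if (length(x) == 0L || is.null(x) || is.na(x) || !nzchar(trimws(x))) return(character(0))
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

join_list_field <- function(x) paste(x, collapse = ";")

read_csv_strict <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8", comment.char = "#",
                  na.strings = character(0), stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    abort_fmt("%s: missing required column(s): %s", path, paste(missing, collapse = ", "))
  invisible(df)
}

as_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) as.Date(NA))
  if (length(d) != 1L || is.na(d))
    abort_fmt("invalid %s: '%s' (expected ISO-8601 YYYY-MM-DD)", what, as.character(x))
  d
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
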