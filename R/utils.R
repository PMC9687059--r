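# Shared low-level helpers: delimited I/O with case-insensitive headers,
# atomic file writes, element bookkeeping.

# 2005-vintage IUPAC standard atomic weights (g/mol). Pinned so that
# formula weights agree with the reference druglikeness tables to 0.01.
ATOMIC_WEIGHTS <- c(
  H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994, S = 32.065,
  P = 30.973762, F = 18.9984032, Cl = 35.453, Br = 79.904, I = 126.90447
)

ELEMENT_NUMBERS <- c(
  H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17, Br = 35, I = 53
)

#' Read a delimited table with flexible separators and headers
#'
#' Accepts TSV or CSV (sniffed from the first line) and matches column
#' names case-insensitively.
#'
#' @param path file path.
#' @return data.frame with lower-cased column names.
#' @keywords internal
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  names(df) <- tolower(trimws(names(df)))
  df
}

# Find one column among aliases (case-insensitive); NULL if absent.
match_column <- function(df, aliases) {
  hit <- intersect(tolower(aliases), names(df))
  if (length(hit) == 0L) return(NULL)
  df[[hit[[1L]]]]
}

# Write a file atomically: stage into a sibling temp file, then rename,
# so a failed run never leaves a truncated output behind.
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write_atomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

write_json_out <- function(x, path) {
  write_atomic(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

stop_if_not_number <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}
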