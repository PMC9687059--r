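# GC-MS composition profiling: peak tables -> area-percentage profiles.
# A constituent's relative concentration in an essential oil is taken as
# its share of the total integrated chromatogram area.

#' Load a GC-MS peak table
#'
#' Reads a TSV/CSV peak table with columns for peak index, retention
#' time (minutes), compound name and raw integrated area. Column order
#' is free and headers are matched case-insensitively; common aliases
#' (`peak`/`peak_number`, `rt_min`/`retention_time`) are accepted.
#'
#' @param path path to a TSV or CSV peak table.
#' @return data.frame with columns `peak`, `rt_min`, `compound`, `area`,
#'   one row per data row, input order preserved.
#' @examples
#' tab <- system.file("extdata", "guava_peaks.tsv", package = "phytodock")
#' peaks <- read_peak_table(tab)
#' nrow(peaks)
#' @export
read_peak_table <- function(path) {
  df <- read_table_auto(path)
  peak <- match_column(df, c("peak", "peak_number", "index", "s.n.", "sn"))
  rt <- match_column(df, c("rt_min", "retention_time", "retention_time_min", "rt"))
  compound <- match_column(df, c("compound", "name", "compound_name"))
  area <- match_column(df, c("area", "raw_area", "peak_area"))
  for (col in list(c("compound", is.null(compound)), c("area", is.null(area)),
                   c("rt_min", is.null(rt)))) {
    if (isTRUE(as.logical(col[[2]])))
      stop("peak table is missing a required column: ", col[[1]], call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(data.frame(peak = integer(), rt_min = numeric(),
                      compound = character(), area = numeric()))
  }
  area_num <- suppressWarnings(as.numeric(gsub("[, ]", "", as.character(area))))
  if (anyNA(area_num)) {
    bad <- which(is.na(area_num))[1L]
    stop("non-numeric area in row ", bad, ": '", area[bad], "'", call. = FALSE)
  }
  if (any(area_num < 0)) stop("negative peak area in row ",
                              which(area_num < 0)[1L], call. = FALSE)
  if (is.null(peak)) peak <- seq_len(nrow(df))
  peak <- as.integer(peak)
  if (anyDuplicated(peak)) stop("duplicate peak indices", call. = FALSE)
  data.frame(peak = peak, rt_min = as.numeric(rt),
             compound = as.character(compound), area = area_num,
             stringsAsFactors = FALSE)
}

#' Derive the area-percentage composition profile
#'
#' Each peak's percentage is 100 * area / total area. Unrounded values
#' are retained in the result; the print method and exported tables
#' round to one decimal, the convention of GC-MS composition tables.
#'
#' @param peaks data.frame as returned by [read_peak_table()].
#' @return object of class `composition_profile`: the peak table with an
#'   `area_pct` column, plus attributes `total_area`.
#' @examples
#' peaks <- read_peak_table(system.file("extdata", "guava_peaks.tsv",
#'                                      package = "phytodock"))
#' prof <- area_percentages(peaks)
#' head(prof)
#' @export
area_percentages <- function(peaks) {
  if (!is.data.frame(peaks) || nrow(peaks) == 0L)
    stop("need at least one peak", call. = FALSE)
  stop_if_not_number(peaks$area, "area")
  total <- sum(peaks$area)
  if (total <= 0) stop("total area is zero: cannot form percentages",
                       call. = FALSE)
  out <- peaks
  out$area_pct <- 100 * peaks$area / total
  attr(out, "total_area") <- total
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("GC-MS composition profile:", nrow(x), "peaks, total area",
      format(attr(x, "total_area"), big.mark = ","), "\n")
  shown <- as.data.frame(x)
  shown$area_pct <- round(shown$area_pct, 1)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Major components of a composition profile
#'
#' @param profile a `composition_profile`.
#' @param min_pct minimum (unrounded) area percentage, in `[0, 100]`.
#' @return data.frame with `compound` and `area_pct`, sorted by
#'   descending percentage.
#' @examples
#' peaks <- read_peak_table(system.file("extdata", "guava_peaks.tsv",
#'                                      package = "phytodock"))
#' major_components(area_percentages(peaks), min_pct = 4)
#' @export
major_components <- function(profile, min_pct = 4) {
  stopifnot(inherits(profile, "composition_profile"),
            min_pct >= 0, min_pct <= 100)
  keep <- profile$area_pct >= min_pct
  out <- data.frame(compound = profile$compound[keep],
                    area_pct = profile$area_pct[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$area_pct), , drop = FALSE]
}
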