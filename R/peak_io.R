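#' Peak-table input/output
#'
#' Fragment-analysis software exports an electropherogram as a discrete peak
#' table: one row per detected peak with its dye channel, apparent size in
#' bp and height in RFU. One canonical CSV dialect is fixed here (columns
#' `Sample, Run, Dye, Size, Height`, comma separated, UTF-8, header
#' required); dye names are channel colour words (PET=red, 6-FAM=blue,
#' VIC=green, NED=black).
#'
#' @name peak_io
NULL

#' Construct a peak table for one sample
#'
#' Peaks are sorted by (dye, size); off-scale heights are clipped to the
#' saturation ceiling (with a warning) rather than rejected, mirroring how
#' saturated peaks appear on the instrument.
#'
#' @param sample_id,run_id Identifiers.
#' @param peaks Data frame with columns `dye`, `size` (bp), `height` (RFU).
#' @param saturation_rfu Saturation ceiling for clipping (default 32000).
#' @return A `peak_table` object.
#' @export
peak_table <- function(sample_id, run_id = "run1",
                       peaks = data.frame(dye = character(), size = numeric(),
                                          height = numeric()),
                       saturation_rfu = 32000) {
  stopifnot(all(c("dye", "size", "height") %in% names(peaks)))
  peaks <- data.frame(dye = as.character(peaks$dye),
                      size = round(as.numeric(peaks$size), 1),
                      height = as.integer(round(as.numeric(peaks$height))))
  if (nrow(peaks)) {
    if (any(!is.finite(peaks$size)) || any(peaks$size <= 0))
      stop("peak sizes must be positive numbers", call. = FALSE)
    if (any(peaks$height < 0))
      stop("peak heights must be non-negative", call. = FALSE)
    over <- peaks$height > saturation_rfu
    if (any(over)) {
      warning(sum(over), " off-scale peak(s) clipped to ", saturation_rfu,
              " RFU in sample ", sample_id, call. = FALSE)
      peaks$height[over] <- as.integer(saturation_rfu)
    }
    peaks <- peaks[order(peaks$dye, peaks$size), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(sample_id = as.character(sample_id),
                 run_id = as.character(run_id), peaks = peaks),
            class = "peak_table")
}

#' Read peak tables from CSV
#'
#' @param path CSV file with header `Sample, Run, Dye, Size, Height`.
#' @param saturation_rfu Clipping ceiling passed to [peak_table()].
#' @return List of `peak_table` objects, one per distinct (Sample, Run),
#'   in file order of first appearance. Rows with a blank Size are skipped
#'   with a warning; non-numeric Size/Height raise an error naming the line.
#' @export
read_peak_tables <- function(path, saturation_rfu = 32000) {
  if (!file.exists(path)) stop("peak CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("Sample", "Run", "Dye", "Size", "Height")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("peak CSV format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  blank <- !nzchar(trimws(df$Size))
  if (any(blank)) {
    warning("skipping ", sum(blank), " row(s) with blank Size in ", path,
            call. = FALSE)
    df <- df[!blank, , drop = FALSE]
  }
  size <- suppressWarnings(as.numeric(df$Size))
  height <- suppressWarnings(as.numeric(df$Height))
  bad <- which(is.na(size) | is.na(height))
  if (length(bad))
    stop("peak CSV row error: non-numeric Size/Height at data line ",
         bad[1] + 1L, call. = FALSE)
  key <- paste(df$Sample, df$Run, sep = "\r")
  out <- lapply(unique(key), function(k) {
    rows <- key == k
    peak_table(df$Sample[rows][1], df$Run[rows][1],
               data.frame(dye = df$Dye[rows], size = size[rows],
                          height = height[rows]),
               saturation_rfu = saturation_rfu)
  })
  out
}

#' Write peak tables to CSV
#'
#' Fixed numeric formatting: Size with one decimal, Height as integer, so
#' that write–read round-trips are exact. Tables with zero peaks contribute
#' no rows (a warning notes their omission); an empty list yields a
#' header-only file.
#'
#' @param tables List of `peak_table` objects (or a single one).
#' @param path Output CSV path.
#' @export
write_peak_tables <- function(tables, path) {
  if (inherits(tables, "peak_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    if (!nrow(tb$peaks)) {
      warning("sample ", tb$sample_id, " has no peaks; omitted from ", path,
              call. = FALSE)
      return(NULL)
    }
    data.frame(Sample = tb$sample_id, Run = tb$run_id, Dye = tb$peaks$dye,
               Size = sprintf("%.1f", tb$peaks$size),
               Height = tb$peaks$height, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(Sample = character(), Run = character(), Dye = character(),
               Size = character(), Height = integer()))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("Peak table: sample %s (run %s), %d peak(s)\n", x$sample_id,
              x$run_id, nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}
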