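#' Write an image or time stack to multi-page TIFF
#'
#' Grayscale 16-bit TIFF, one page per frame (the page axis is time).
#' Intensities are rounded to the uint16 grid, so values must lie in
#' `[0, 65535]`.
#'
#' @param frames a matrix, a list of matrices, or a rows x cols x frames
#'   array.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  pages <- lapply(frames, function(m) {
    m <- as_intensity_matrix(m)
    if (max(m) > 65535)
      stop_with("format_error", "intensities exceed the uint16 range")
    round(m) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a grayscale TIFF image or stack
#'
#' @param path TIFF file; multi-page files are read as a time stack.
#' @return list of numeric matrices (integer-valued intensities, native
#'   bit-depth scale).
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path))
    stop_with("format_error", "TIFF file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) {
      if (dim(m)[3] != 1L)
        stop_with("format_error", "%s page %d is not single-channel", path, i)
      m <- m[, , 1L]
    }
    storage.mode(m) <- "numeric"
    if (any(!is.finite(m)) || any(m < 0))
      stop_with("format_error",
                "%s page %d has negative or non-finite intensities", path, i)
    m
  })
}

# strict CSV reader: header row required, rejects NA/NaN in required columns
read_table_csv <- function(path, required = character()) {
  if (!file.exists(path))
    stop_with("format_error", "CSV file not found: %s", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_with("format_error", "%s: missing column(s) %s", path,
              paste(miss, collapse = ", "))
  for (col in required) {
    v <- df[[col]]
    bad <- if (is.numeric(v)) !is.finite(v) else is.na(v)
    if (any(bad))
      stop_with("format_error",
                "%s: missing or non-finite value in column %s (line %d)",
                path, col, which(bad)[1] + 1L)
  }
  df
}

#' Read a FRAP trace CSV
#'
#' Expected layout: comment header lines `# background: <value>` and
#' `# prebleach_index: <integer>`, then columns `time_s`, `roi`,
#' `reference`.
#'
#' @param path CSV file.
#' @return a [frap_trace()].
#' @export
read_frap_csv <- function(path) {
  if (!file.exists(path))
    stop_with("format_error", "FRAP CSV not found: %s", path)
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  get_field <- function(name) {
    ln <- grep(paste0("^#\\s*", name, "\\s*:"), hdr, value = TRUE)
    if (!length(ln))
      stop_with("format_error", "%s: missing '# %s:' header line", path, name)
    as.numeric(sub(".*:", "", ln[1]))
  }
  df <- read_table_csv(path, c("time_s", "roi", "reference"))
  frap_trace(df$time_s, df$roi, df$reference,
             background = get_field("background"),
             prebleach_index = as.integer(get_field("prebleach_index")))
}

#' Write a FRAP trace CSV
#'
#' Inverse of [read_frap_csv()].
#'
#' @param trace a [frap_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frap_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# background: %.10g", trace$background),
               sprintf("# prebleach_index: %d", trace$prebleach_index)), con)
  write.csv(data.frame(time_s = trace$times, roi = trace$roi,
                       reference = trace$reference),
            con, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text pipeline configuration
#'
#' One `key: value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric. A `seed` key is the conventional place to pin
#' the run's RNG.
#'
#' @param path config file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop_with("config_error", "config file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- grep(":", lines, invert = TRUE)
  if (length(bad))
    stop_with("config_error", "config line %d is not 'key: value'", bad[1])
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  num <- suppressWarnings(as.numeric(vals))
  out <- lapply(seq_along(vals), function(i)
    if (!is.na(num[i])) num[i] else vals[i])
  names(out) <- keys
  out
}
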