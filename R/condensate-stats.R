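#' Circularity shape descriptor
#'
#' \deqn{\mathrm{Circularity} = 4\pi \frac{\mathrm{area}}{\mathrm{perimeter}^2}}
#' Equals 1 for a perfect circle and decreases toward 0 as a shape of fixed
#' area becomes more irregular or elongated. On rasterized regions the value
#' inherits the perimeter estimator's small bias (see
#' [perimeter_crofton()]).
#'
#' @param area region area (pixels^2 or any consistent unit); vectorized.
#' @param perimeter region perimeter (same length unit); must be positive.
#' @return dimensionless circularity, same length as the inputs.
#' @examples
#' circularity(pi * 10^2, 2 * pi * 10)  # analytic circle -> 1
#' circularity(1, 4)                    # unit square -> pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(perimeter)) || any(perimeter <= 0))
    stop_with("domain_error", "perimeter must be positive")
  if (any(!is.finite(area)) || any(area < 0))
    stop_with("domain_error", "area must be non-negative")
  4 * pi * area / perimeter^2
}

# Per-region intensity statistic P(i) used by both ratio forms:
# mode "mean" is the region's mean intensity, "sum" its integrated intensity.
region_intensity <- function(cset, intensity_mode) {
  switch(intensity_mode,
         mean = cset$regions$mean_intensity,
         sum  = cset$regions$mean_intensity * cset$regions$area,
         stop_with("invalid_argument", "intensity_mode must be 'mean' or 'sum'"))
}

#' Partition ratio of a condensate set
#'
#' Mean condensate intensity divided by the background intensity, where the
#' background is the whole-frame mean for in-vitro droplet images and the
#' whole-nucleus mean for in-vivo images (recorded in the set's
#' `background_mean_intensity`). A sample in which no condensates were
#' detected returns exactly 1 — the conventional value for samples that
#' failed to form particles.
#'
#' @param cset a [condensate_set()].
#' @param intensity_mode `"mean"` (default) treats each photobody's intensity
#'   as its mean pixel intensity; `"sum"` uses its integrated intensity.
#' @return dimensionless ratio; 1 means no enrichment.
#' @export
partition_ratio <- function(cset, intensity_mode = c("mean", "sum")) {
  intensity_mode <- match.arg(intensity_mode)
  if (cset$background_mean_intensity <= 0)
    stop_with("domain_error", "background intensity must be positive")
  if (cset$n == 0L) return(1)
  mean(region_intensity(cset, intensity_mode)) / cset$background_mean_intensity
}

#' Per-time-point partition ratio (BiFC form)
#'
#' \deqn{\mathrm{PR}(t) = \frac{\sum_{i} P(i)}{n \cdot N}}
#' where \eqn{P(i)} is the intensity of each photobody, \eqn{n} the photobody
#' count in the nucleus and \eqn{N} the nucleus mean intensity. Algebraically
#' this is the mean of \eqn{P(i)/N}. A nucleus with no photobodies returns 1,
#' inheriting the failed-sample convention.
#'
#' @inheritParams partition_ratio
#' @return dimensionless ratio.
#' @export
partition_ratio_timepoint <- function(cset,
                                      intensity_mode = c("mean", "sum")) {
  intensity_mode <- match.arg(intensity_mode)
  if (cset$n == 0L) return(1)
  N <- cset$nucleus_mean_intensity
  if (!is.finite(N) || N <= 0)
    stop_with("domain_error", "nucleus mean intensity must be positive")
  sum(region_intensity(cset, intensity_mode)) / (cset$n * N)
}

#' Fraction of condensates above a size cutoff
#'
#' `count(area > threshold) / count(total)` — the "particles (%)" statistic
#' of a size-distribution plot. Areas and the 0.75 default cutoff are in
#' whatever (typically normalized) units the caller's distribution uses.
#'
#' @param areas non-empty numeric vector of condensate areas.
#' @param threshold size cutoff; strictly-greater comparison.
#' @return fraction in `[0, 1]`.
#' @export
size_fraction <- function(areas, threshold = 0.75) {
  if (!length(areas)) stop_with("domain_error", "areas must be non-empty")
  if (any(!is.finite(areas))) stop_with("domain_error", "areas must be finite")
  mean(areas > threshold)
}

#' Condensate count per unit nucleus area
#'
#' Number of photobodies divided by the nucleus area — in per-pixel^2 units,
#' or per square physical unit (e.g. per um^2) when the set carries a pixel
#' size.
#'
#' @param cset a [condensate_set()].
#' @return density, count per area.
#' @export
count_per_area <- function(cset) {
  if (!is.finite(cset$nucleus_area) || cset$nucleus_area <= 0)
    stop_with("domain_error", "nucleus_area must be positive")
  a <- cset$nucleus_area
  if (!is.na(cset$pixel_size)) a <- a * cset$pixel_size^2
  cset$n / a
}

#' Normalized condensate size over time
#'
#' For each time point, the mean relative condensate size is averaged over
#' nuclei: per nucleus, mean condensate area divided by nucleus area (0 for
#' nuclei without condensates). The series is then divided by its first
#' value, so the first time point is 1 and later values are fold changes in
#' relative condensate size.
#'
#' @param times numeric vector of time points.
#' @param csets_by_time list (same length) of lists of [condensate_set()]s,
#'   the nuclei measured at each time.
#' @return data frame with columns `time`, `relative_size` (pre-scaling) and
#'   `normalized_size`.
#' @export
normalized_size_series <- function(times, csets_by_time) {
  if (length(times) != length(csets_by_time))
    stop_with("invalid_argument", "times and csets_by_time differ in length")
  if (!length(csets_by_time) || !length(csets_by_time[[1]]))
    stop_with("domain_error", "first time point has no nuclei")
  rel <- vapply(csets_by_time, function(nuclei) {
    mean(vapply(nuclei, function(cs) {
      if (cs$n == 0L) 0 else mean(cs$regions$area) / cs$nucleus_area
    }, numeric(1)))
  }, numeric(1))
  if (!is.finite(rel[1]) || rel[1] <= 0)
    stop_with("domain_error",
              "first time point has zero mean condensate size")
  data.frame(time = times, relative_size = rel,
             normalized_size = rel / rel[1])
}

#' Summary statistics table for a set of measured frames
#'
#' Convenience wrapper producing one row per frame with the statistics the
#' pipeline writes to `stats.csv`.
#'
#' @param csets list of [condensate_set()]s, one per frame.
#' @param times optional time stamps (seconds); defaults to the frame index.
#' @param size_threshold cutoff for [size_fraction()], applied to areas
#'   normalized by nucleus area... in pixel units when no normalization
#'   applies (see `size_units`).
#' @param size_units `"normalized"` divides areas by nucleus area before the
#'   cutoff; `"pixels"` applies it to raw pixel areas.
#' @param intensity_mode passed to the partition-ratio functions.
#' @return data frame: `time`, `n`, `partition_ratio`, `partition_ratio_tp`,
#'   `count_per_area`, `size_fraction`.
#' @export
condensate_stats_table <- function(csets, times = seq_along(csets),
                                   size_threshold = 0.75,
                                   size_units = c("normalized", "pixels"),
                                   intensity_mode = c("mean", "sum")) {
  size_units <- match.arg(size_units)
  intensity_mode <- match.arg(intensity_mode)
  rows <- lapply(seq_along(csets), function(i) {
    cs <- csets[[i]]
    areas <- cs$regions$area
    if (size_units == "normalized" && cs$nucleus_area > 0)
      areas <- areas / cs$nucleus_area * 100   # percent of nucleus area
    data.frame(time = times[i], n = cs$n,
               partition_ratio = partition_ratio(cs, intensity_mode),
               partition_ratio_tp =
                 partition_ratio_timepoint(cs, intensity_mode),
               count_per_area = count_per_area(cs),
               size_fraction = if (length(areas))
                 size_fraction(areas, size_threshold) else NA_real_)
  })
  do.call(rbind, rows)
}
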