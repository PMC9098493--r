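#' Describe a synthetic nucleus-with-condensates scene
#'
#' A `scene_truth` holds the ground-truth geometry and photometry of one
#' synthetic nucleus: a bright disk (nucleoplasm) on a dark background, with
#' zero or more condensate disks enriched over the nucleoplasm by a
#' fold-enrichment factor. [generate_condensate_image()] rasterizes it.
#'
#' @param dim integer length-2, raster size as `c(rows, cols)`.
#' @param nucleus_center numeric length-2 `(row, col)` of the nucleus center,
#'   1-based pixel coordinates.
#' @param nucleus_radius nucleus radius in pixels; must be positive and the
#'   nucleus disk must fit inside the raster.
#' @param condensates data frame with columns `row`, `col`, `radius`, `fold`
#'   (one row per condensate), or `NULL` for a condensate-free nucleus. Every
#'   condensate must lie fully inside the nucleus disk and have `fold >= 1`.
#' @param background_level,nucleoplasm_level mean intensities (arbitrary
#'   units) outside and inside the nucleus; condensate pixels take
#'   `nucleoplasm_level * fold`.
#' @param noise_sd standard deviation of additive Gaussian read noise
#'   (intensity units); the rendered image is clipped at 0.
#' @param blur_sigma optional Gaussian blur sigma (pixels) applied before
#'   noise to emulate optics; 0 (default) keeps disk edges hard so analytic
#'   pixel-sum checks are exact.
#' @param hexanediol fraction in `[0, 1]` scaling fold-enrichment toward 1,
#'   emulating aliphatic-alcohol dissolution of the condensates; 1 (default)
#'   leaves the scene untreated, 0 dissolves completely.
#' @param seed integer RNG seed for the noise; `NULL` draws from the current
#'   stream.
#' @return an object of class `scene_truth`.
#' @examples
#' sc <- scene_truth(condensates = disk_condensates(3, radius = 4, fold = 5))
#' img <- generate_condensate_image(sc)
#' @export
scene_truth <- function(dim = c(128L, 128L),
                        nucleus_center = (dim + 1) / 2,
                        nucleus_radius = min(dim) * 0.35,
                        condensates = NULL,
                        background_level = 200,
                        nucleoplasm_level = 2000,
                        noise_sd = 100,
                        blur_sigma = 0,
                        hexanediol = 1,
                        seed = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 2L || any(dim < 4L))
    stop_with("invalid_scene", "dim must be two integers >= 4")
  if (!is.numeric(nucleus_radius) || length(nucleus_radius) != 1L ||
      !is.finite(nucleus_radius) || nucleus_radius <= 0)
    stop_with("invalid_scene", "nucleus_radius must be a positive number")
  check_number(background_level, "background_level", 0)
  check_number(nucleoplasm_level, "nucleoplasm_level", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(blur_sigma, "blur_sigma", 0)
  check_number(hexanediol, "hexanediol", 0)
  if (hexanediol > 1)
    stop_with("invalid_scene", "hexanediol must be in [0, 1]")
  if (nucleus_center[1] - nucleus_radius < 1 ||
      nucleus_center[1] + nucleus_radius > dim[1] ||
      nucleus_center[2] - nucleus_radius < 1 ||
      nucleus_center[2] + nucleus_radius > dim[2])
    stop_with("invalid_scene", "nucleus disk does not fit inside the raster")
  if (is.null(condensates))
    condensates <- data.frame(row = numeric(), col = numeric(),
                              radius = numeric(), fold = numeric())
  condensates <- as.data.frame(condensates)
  need <- c("row", "col", "radius", "fold")
  if (!all(need %in% names(condensates)))
    stop_with("invalid_scene", "condensates needs columns row, col, radius, fold")
  if (nrow(condensates)) {
    if (any(condensates$radius <= 0))
      stop_with("invalid_scene", "condensate radius must be positive")
    if (any(condensates$fold < 1))
      stop_with("invalid_scene", "fold_enrichment must be >= 1")
    d <- sqrt((condensates$row - nucleus_center[1])^2 +
              (condensates$col - nucleus_center[2])^2)
    if (any(d + condensates$radius > nucleus_radius))
      stop_with("invalid_scene",
                "condensate %d extends outside the nucleus disk",
                which.max(d + condensates$radius))
  }
  structure(list(dim = dim, nucleus_center = as.numeric(nucleus_center),
                 nucleus_radius = nucleus_radius, condensates = condensates,
                 background_level = background_level,
                 nucleoplasm_level = nucleoplasm_level, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, hexanediol = hexanediol,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "scene_truth")
}

#' Place condensates evenly on a ring inside the nucleus
#'
#' Convenience layout: `n` identical condensates at angles `2*pi*k/n` on a
#' ring at half the nucleus radius. Guaranteed pairwise-disjoint for small
#' radii.
#'
#' @param n number of condensates.
#' @param radius condensate radius, pixels.
#' @param fold fold-enrichment over nucleoplasm.
#' @param ring_fraction ring radius as a fraction of the nucleus radius.
#' @param dim,nucleus_center,nucleus_radius scene geometry (defaults match
#'   [scene_truth()]).
#' @return data frame suitable for the `condensates` argument of
#'   [scene_truth()].
#' @export
disk_condensates <- function(n, radius = 4, fold = 5, ring_fraction = 0.5,
                             dim = c(128L, 128L),
                             nucleus_center = (dim + 1) / 2,
                             nucleus_radius = min(dim) * 0.35) {
  if (n == 0)
    return(data.frame(row = numeric(), col = numeric(),
                      radius = numeric(), fold = numeric()))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  r <- nucleus_radius * ring_fraction
  data.frame(row = nucleus_center[1] + r * sin(ang),
             col = nucleus_center[2] + r * cos(ang),
             radius = radius, fold = fold)
}

# Rasterize the disk masks of a scene: list with logical `nucleus` matrix and
# integer `condensate` matrix (0 = none, i = i-th condensate; overlaps keep
# the larger fold).
scene_masks <- function(truth) {
  nr <- truth$dim[1]; nc <- truth$dim[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  nucleus <- (rows - truth$nucleus_center[1])^2 +
             (cols - truth$nucleus_center[2])^2 <= truth$nucleus_radius^2
  cond <- matrix(0L, nr, nc)
  cdf <- truth$condensates
  if (nrow(cdf)) {
    ord <- order(cdf$fold)             # higher fold painted last
    for (i in ord) {
      inside <- (rows - cdf$row[i])^2 + (cols - cdf$col[i])^2 <= cdf$radius[i]^2
      cond[inside] <- i
    }
  }
  list(nucleus = nucleus, condensate = cond)
}

# Effective fold after the optional hexanediol scaling toward 1.
effective_fold <- function(truth) 1 + truth$hexanediol * (truth$condensates$fold - 1)

#' Render a synthetic condensate image
#'
#' Rasterizes a [scene_truth()]: pixels outside the nucleus take
#' `background_level`, nucleoplasm pixels `nucleoplasm_level`, condensate
#' pixels `nucleoplasm_level * fold`; an optional Gaussian blur is applied,
#' then i.i.d. Gaussian noise of sd `noise_sd` is added and the image clipped
#' at zero. With `noise_sd = 0` and `blur_sigma = 0` the raster is exactly
#' piecewise-constant, so pixel-sum identities over the truth masks hold
#' exactly.
#'
#' @param truth a [scene_truth()].
#' @return a list with elements `image` (numeric matrix), `truth` (the input,
#'   unmodified) and `masks` (rasterized truth masks: logical `nucleus`,
#'   integer-labelled `condensate`).
#' @seealso [segment_nucleus()], [detect_condensates()]
#' @export
generate_condensate_image <- function(truth) {
  if (!inherits(truth, "scene_truth"))
    stop_with("invalid_scene", "truth must be a scene_truth")
  masks <- scene_masks(truth)
  img <- matrix(truth$background_level, truth$dim[1], truth$dim[2])
  img[masks$nucleus] <- truth$nucleoplasm_level
  if (nrow(truth$condensates)) {
    fold <- effective_fold(truth)
    sel <- masks$condensate > 0L
    img[sel] <- truth$nucleoplasm_level * fold[masks$condensate[sel]]
  }
  if (truth$blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = truth$blur_sigma))
  if (truth$noise_sd > 0)
    img <- with_seed(truth$seed,
                     img + matrix(rnorm(length(img), 0, truth$noise_sd),
                                  nrow(img)))
  img[img < 0] <- 0
  list(image = img, truth = truth, masks = masks)
}

#' Programmed light on/off schedule
#'
#' An ordered sequence of illumination intervals, e.g. the 10-min-on /
#' 10-min-off cycles used to drive reversible photobody assembly.
#'
#' @param durations interval lengths in seconds, all positive.
#' @param states character vector of `"on"`/`"off"`, same length.
#' @return a `light_schedule` data frame with columns `duration`, `state`,
#'   `start`, `end`, `cycle` (a cycle starts at each on-interval).
#' @examples
#' light_schedule(rep(600, 4), rep(c("on", "off"), 2))  # two 10/10-min cycles
#' @export
light_schedule <- function(durations, states) {
  if (length(durations) < 1L)
    stop_with("invalid_schedule", "schedule needs at least one interval")
  if (length(durations) != length(states))
    stop_with("invalid_schedule", "durations and states differ in length")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop_with("invalid_schedule", "durations must be positive")
  states <- match.arg(states, c("on", "off"), several.ok = TRUE)
  end <- cumsum(durations)
  sched <- data.frame(duration = as.numeric(durations), state = states,
                      start = c(0, end[-length(end)]), end = end,
                      cycle = cumsum(states == "on"))
  sched$cycle[sched$cycle == 0L] <- 1L   # leading off-interval joins cycle 1
  class(sched) <- c("light_schedule", "data.frame")
  sched
}

# Map times (seconds) to schedule rows; error for times outside the schedule.
schedule_lookup <- function(schedule, times) {
  if (!inherits(schedule, "light_schedule"))
    stop_with("invalid_schedule", "not a light_schedule")
  total <- schedule$end[nrow(schedule)]
  if (any(times < 0 | times > total))
    stop_with("outside_schedule",
              "time %.1f s falls outside the %.1f s schedule",
              times[which(times < 0 | times > total)[1]], total)
  idx <- findInterval(times, schedule$start, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx
}

#' Simulate a light-cycle image stack with known assembly/disassembly
#'
#' Evolves the common condensate fold-enrichment through a [light_schedule()]:
#' during on-phases it relaxes toward the plateau `fold_max` with first-order
#' rate `k_on`; during off-phases it decays toward
#' `1 + residual * (fold_at_lights_off - 1)` with rate `k_off`, so
#' `residual = 0` means complete disassembly and `residual = 1` none. Each
#' frame is rendered with [generate_condensate_image()] and the analytic
#' (noise-free, pixel-exact) partition-ratio trajectory is returned alongside.
#'
#' @param schedule a [light_schedule()].
#' @param scene a [scene_truth()] providing geometry, levels and noise; the
#'   per-condensate `fold` column is overridden by the evolving common fold.
#' @param k_on,k_off first-order rates, per second.
#' @param fold_max on-phase plateau fold-enrichment.
#' @param residual_fraction_per_cycle fraction in `[0, 1]` of the assembled
#'   enrichment that persists through an off-phase.
#' @param frame_interval seconds between frames.
#' @param seed RNG seed for the per-frame noise.
#' @return list with `frames` (list of matrices), `truth` (data frame: frame,
#'   time_s, state, cycle, fold, partition_ratio), `schedule` and `scene`.
#' @export
generate_cycle_stack <- function(schedule, scene,
                                 k_on = 1 / 60, k_off = 1 / 60,
                                 fold_max = 5,
                                 residual_fraction_per_cycle = 0,
                                 frame_interval = 60, seed = NULL) {
  if (!inherits(schedule, "light_schedule"))
    stop_with("invalid_schedule", "schedule must be a light_schedule")
  if (!nrow(scene$condensates))
    stop_with("invalid_scene", "cycle scene needs at least one condensate")
  check_number(k_on, "k_on", 0, strict = TRUE)
  check_number(k_off, "k_off", 0, strict = TRUE)
  check_number(fold_max, "fold_max", 1, strict = TRUE)
  r <- check_number(residual_fraction_per_cycle,
                    "residual_fraction_per_cycle", 0)
  if (r > 1) stop_with("invalid_argument", "residual fraction must be <= 1")

  total <- schedule$end[nrow(schedule)]
  times <- seq(0, total, by = frame_interval)
  idx <- schedule_lookup(schedule, times)

  # piecewise-exponential fold at each segment boundary, then at frame times
  f_start <- numeric(nrow(schedule))   # fold entering each interval
  f_target <- numeric(nrow(schedule))
  f <- 1
  for (s in seq_len(nrow(schedule))) {
    f_start[s] <- f
    f_target[s] <- if (schedule$state[s] == "on") fold_max else 1 + r * (f - 1)
    k <- if (schedule$state[s] == "on") k_on else k_off
    f <- f_target[s] + (f_start[s] - f_target[s]) * exp(-k * schedule$duration[s])
  }
  seg_k <- ifelse(schedule$state == "on", k_on, k_off)
  dt <- times - schedule$start[idx]
  fold_t <- f_target[idx] + (f_start[idx] - f_target[idx]) * exp(-seg_k[idx] * dt)

  masks <- scene_masks(scene)
  a_nuc <- sum(masks$nucleus)
  a_cond <- sum(masks$condensate > 0L)
  # in-vivo truth ratio: mean condensate intensity over nucleus mean
  pr <- fold_t * a_nuc / (a_nuc + (fold_t - 1) * a_cond)

  frames <- vector("list", length(times))
  seeds <- if (is.null(seed)) rep(list(NULL), length(times))
           else with_seed(seed, as.list(sample.int(.Machine$integer.max,
                                                   length(times))))
  for (i in seq_along(times)) {
    sc <- scene
    sc$condensates$fold <- fold_t[i]
    sc$seed <- seeds[[i]]
    frames[[i]] <- generate_condensate_image(sc)$image
  }
  list(frames = frames,
       truth = data.frame(frame = seq_along(times), time_s = times,
                          state = schedule$state[idx],
                          cycle = schedule$cycle[idx],
                          fold = fold_t, partition_ratio = pr),
       schedule = schedule, scene = scene)
}
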