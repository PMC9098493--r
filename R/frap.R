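#' Construct a FRAP trace
#'
#' Raw intensities of one bleach-and-recovery experiment: the bleached region
#' of interest `I(t)`, a non-bleached reference region `R(t)` that tracks
#' acquisition photofading, and a scalar background `B` collected at the
#' pre-bleach time.
#'
#' @param times time points, seconds.
#' @param roi ROI intensity `I(t)`, same length as `times`.
#' @param reference reference-region intensity `R(t)`, same length.
#' @param background scalar background intensity `B`.
#' @param prebleach_index index `p` of the pre-bleach time point (default 1,
#'   a single pre-bleach frame).
#' @return object of class `frap_trace`.
#' @export
frap_trace <- function(times, roi, reference, background,
                       prebleach_index = 1L) {
  n <- length(times)
  if (n < 3L) stop_with("invalid_trace", "need at least 3 time points")
  if (length(roi) != n || length(reference) != n)
    stop_with("invalid_trace", "times, roi and reference differ in length")
  if (any(!is.finite(times)) || any(!is.finite(roi)) ||
      any(!is.finite(reference)))
    stop_with("invalid_trace", "trace values must be finite")
  check_number(background, "background", 0)
  p <- as.integer(prebleach_index)
  if (p < 1L || p > n)
    stop_with("invalid_trace", "prebleach_index out of range")
  structure(list(times = as.numeric(times), roi = as.numeric(roi),
                 reference = as.numeric(reference), background = background,
                 prebleach_index = p),
            class = "frap_trace")
}

#' Double-normalize a FRAP trace
#'
#' Applies the four-step normalization in order: background subtraction
#' \eqn{I_{c1}(t) = I(t) - B} and \eqn{R_{c1}(t) = R(t) - B}, reference
#' correction \eqn{I_{c2}(t) = I_{c1}(t)/R_{c1}(t)} (removing acquisition
#' photofading), and pre-bleach scaling
#' \eqn{I_{c3}(t) = I_{c2}(t)/I_{c2}(p)} so the pre-bleach intensity is
#' exactly 1. The result is invariant under rescaling `I`, `R` and `B` by a
#' common positive factor.
#'
#' @param trace a [frap_trace()].
#' @return object of class `normalized_frap`: `times`, `intensity`
#'   (\eqn{I_{c3}}), `prebleach_index`.
#' @export
normalize_frap <- function(trace) {
  if (!inherits(trace, "frap_trace"))
    stop_with("invalid_trace", "trace must be a frap_trace")
  p <- trace$prebleach_index
  r_c1 <- trace$reference - trace$background
  if (any(r_c1 <= 0))
    stop_with("domain_error",
              "reference does not exceed background at index %d",
              which(r_c1 <= 0)[1])
  i_c1 <- trace$roi - trace$background
  if (i_c1[p] <= 0)
    stop_with("domain_error",
              "pre-bleach ROI intensity does not exceed background")
  i_c2 <- i_c1 / r_c1
  i_c3 <- i_c2 / i_c2[p]
  structure(list(times = trace$times, intensity = i_c3, prebleach_index = p),
            class = "normalized_frap")
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of
#' \deqn{f(t) = f_0 + (\mathrm{plateau} - f_0)(1 - e^{-k t})}
#' to the post-bleach points (time measured from the first post-bleach
#' frame). The mobile fraction is
#' \eqn{A = (\mathrm{plateau} - f_0)/(1 - f_0)} — the recovered share of the
#' bleached signal — and the half-time of recovery is \eqn{\ln 2 / k}.
#'
#' @param norm a [normalized_frap()] curve.
#' @param bleach_index index of the first post-bleach frame; defaults to the
#'   frame after the pre-bleach point.
#' @return list of class `frap_fit`: `mobile_fraction`, `rate`, `half_time`,
#'   `f0`, `plateau`, `residual_sd`, `n_points`.
#' @export
fit_recovery <- function(norm, bleach_index = norm$prebleach_index + 1L) {
  if (!inherits(norm, "normalized_frap"))
    stop_with("invalid_trace", "norm must be a normalized_frap")
  i0 <- as.integer(bleach_index)
  n <- length(norm$times)
  if (i0 < 1L || n - i0 + 1L < 5L)
    stop_with("invalid_trace", "need at least 5 post-bleach points")
  tt <- norm$times[i0:n] - norm$times[i0]
  y <- norm$intensity[i0:n]
  if (sd(y) < 1e-10) {                     # flat curve: nothing recovers
    return(structure(list(mobile_fraction = 0, rate = NA_real_,
                          half_time = NA_real_, f0 = mean(y),
                          plateau = mean(y), residual_sd = sd(y),
                          n_points = length(y)),
                     class = "frap_fit"))
  }
  span <- max(tt[tt > 0])
  start <- list(f0 = y[1],
                plateau = mean(tail(y, max(3L, length(y) %/% 10L))),
                k = log(2) / (span / 4))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ f0 + (plateau - f0) * (1 - exp(-k * tt)),
                      start = start,
                      lower = c(f0 = -Inf, plateau = -Inf, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_with("fit_error",
                "recovery fit did not converge (%s); residual sd at start %.3g",
                conditionMessage(e), sd(y)))
  cf <- coef(fit)
  A <- (cf[["plateau"]] - cf[["f0"]]) / (1 - cf[["f0"]])
  structure(list(mobile_fraction = A, rate = cf[["k"]],
                 half_time = log(2) / cf[["k"]], f0 = cf[["f0"]],
                 plateau = cf[["plateau"]],
                 residual_sd = sd(residuals(fit)), n_points = length(y)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP recovery fit (%d points): mobile fraction A = %.3f, k = %s /s, t1/2 = %s s\n",
    x$n_points, x$mobile_fraction,
    format(x$rate, digits = 3), format(x$half_time, digits = 3)))
  invisible(x)
}

#' Partition-ratio trajectory of a light-cycle image stack
#'
#' Runs nucleus segmentation, condensate detection and the partition ratio on
#' every frame of a time-lapse stack acquired under a programmed on/off light
#' schedule, and tags each value with its cycle number and phase. Frames in
#' which segmentation finds no nucleus, or detection finds no condensates,
#' take the failed-sample default ratio of 1.
#'
#' @param frames list of matrices (or `image_frame`s), one per time point.
#' @param times frame acquisition times in seconds; must fall inside the
#'   schedule.
#' @param schedule a [light_schedule()] covering the acquisition.
#' @param k_sigma,min_area,min_nucleus_area segmentation settings (see
#'   [detect_condensates()], [segment_nucleus()]).
#' @param intensity_mode passed to [partition_ratio()].
#' @return data frame: `frame`, `time_s`, `cycle`, `state`,
#'   `partition_ratio`, `n`.
#' @export
cycle_trajectory <- function(frames, times, schedule, k_sigma = 3,
                             min_area = 4, min_nucleus_area = 50,
                             intensity_mode = c("mean", "sum")) {
  intensity_mode <- match.arg(intensity_mode)
  if (length(frames) != length(times))
    stop_with("invalid_argument", "frames and times differ in length")
  idx <- schedule_lookup(schedule, times)
  pr <- numeric(length(frames)); nn <- integer(length(frames))
  for (i in seq_along(frames)) {
    res <- tryCatch({
      mask <- segment_nucleus(frames[[i]], min_nucleus_area = min_nucleus_area)
      cs <- detect_condensates(frames[[i]], mask, k_sigma = k_sigma,
                               min_area = min_area, context = "in_vivo")
      list(pr = partition_ratio(cs, intensity_mode), n = cs$n)
    }, no_nucleus_found = function(e) list(pr = 1, n = 0L))
    pr[i] <- res$pr; nn[i] <- res$n
  }
  data.frame(frame = seq_along(frames), time_s = times,
             cycle = schedule$cycle[idx], state = schedule$state[idx],
             partition_ratio = pr, n = nn)
}

#' Reversibility of condensate assembly over one light cycle
#'
#' Compares the partition ratio at the end of a cycle's dark (off) phase with
#' the ratio at the end of its light (on) phase:
#' \deqn{\mathrm{index} = \frac{\mathrm{PR}_\mathrm{end\,off} - 1}
#'                             {\mathrm{PR}_\mathrm{end\,on} - 1}.}
#' 0 means the condensates disassembled completely in the dark, 1 that they
#' persisted unchanged. End-of-phase values are the mean of the phase's last
#' `tail_n` frames for noise robustness.
#'
#' @param trajectory data frame from [cycle_trajectory()] (or with the same
#'   columns).
#' @param cycle which cycle to score.
#' @param tail_n frames averaged at each phase end.
#' @return fraction, usually in `[0, 1]` (noise can push it slightly
#'   outside).
#' @export
reversibility_index <- function(trajectory, cycle = 1L, tail_n = 3L) {
  tr <- trajectory[trajectory$cycle == cycle, , drop = FALSE]
  on <- tr[tr$state == "on", , drop = FALSE]
  off <- tr[tr$state == "off", , drop = FALSE]
  if (!nrow(on) || !nrow(off))
    stop_with("invalid_argument", "cycle %d lacks an on or off phase", cycle)
  end_of <- function(d) mean(tail(d$partition_ratio, tail_n))
  pr_on <- end_of(on); pr_off <- end_of(off)
  if (pr_on <= 1)
    stop_with("undefined_index",
              "no assembly in cycle %d (end-of-on partition ratio %.3f <= 1)",
              cycle, pr_on)
  (pr_off - 1) / (pr_on - 1)
}
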