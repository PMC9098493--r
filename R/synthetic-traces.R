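#' Ground truth for a synthetic FRAP experiment
#'
#' Parameters of an idealized bleach-and-recovery trace with a single
#' pre-bleach time point. The region of interest (ROI) intensity follows
#' \deqn{I(t) = B + L\,e^{-\phi t}\,[(1-d) + d\,A\,(1-e^{-k\,t'})]}
#' after the bleach (with \eqn{t'} measured from the first post-bleach frame,
#' \eqn{L} the pre-bleach signal above background, \eqn{d} the bleach depth,
#' \eqn{A} the mobile fraction, \eqn{k} the recovery rate and \eqn{\phi} the
#' acquisition photofading rate), and the reference region fades with the
#' same \eqn{\phi}, so double normalization removes the fading exactly and
#' the ideal normalized curve is \eqn{(1-d) + d A (1 - e^{-k t'})}.
#'
#' @param pre_bleach_level ROI intensity at the pre-bleach frame (must exceed
#'   `background`).
#' @param bleach_depth fraction of the signal removed by the bleach, in
#'   `(0, 1]`.
#' @param mobile_fraction fraction `A` of the bleached signal that recovers,
#'   in `[0, 1]`.
#' @param rate recovery rate `k`, per second; positive.
#' @param background scalar background intensity `B`.
#' @param reference_fade acquisition photofading rate, per second.
#' @param n_timepoints number of frames including the pre-bleach one (>= 3).
#' @param dt frame interval, seconds.
#' @param noise_sd Gaussian noise sd added to ROI and reference intensities.
#' @param seed RNG seed for the noise.
#' @return object of class `frap_truth`.
#' @export
frap_truth <- function(pre_bleach_level = 1.1, bleach_depth = 0.9,
                       mobile_fraction = 0.8, rate = 0.1,
                       background = 0.1, reference_fade = 0.002,
                       n_timepoints = 100L, dt = 1, noise_sd = 0,
                       seed = NULL) {
  check_number(pre_bleach_level, "pre_bleach_level", background, strict = TRUE)
  check_number(bleach_depth, "bleach_depth", 0, strict = TRUE)
  if (bleach_depth > 1) stop_with("invalid_argument", "bleach_depth must be <= 1")
  check_number(mobile_fraction, "mobile_fraction", 0)
  if (mobile_fraction > 1)
    stop_with("invalid_argument", "mobile_fraction must be <= 1")
  check_number(rate, "rate", 0, strict = TRUE)
  check_number(background, "background", 0)
  check_number(reference_fade, "reference_fade", 0)
  check_number(noise_sd, "noise_sd", 0)
  if (n_timepoints < 3L)
    stop_with("invalid_argument", "n_timepoints must be >= 3")
  check_number(dt, "dt", 0, strict = TRUE)
  structure(list(pre_bleach_level = pre_bleach_level,
                 bleach_depth = bleach_depth,
                 mobile_fraction = mobile_fraction, rate = rate,
                 background = background, reference_fade = reference_fade,
                 n_timepoints = as.integer(n_timepoints), dt = dt,
                 noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "frap_truth")
}

#' Simulate a FRAP trace from known recovery parameters
#'
#' @param truth a [frap_truth()].
#' @return list with `trace` (a [frap_trace()] ready for
#'   [normalize_frap()]) and `truth` (the input augmented with
#'   `normalized_ideal`, the noise-free double-normalized curve).
#' @export
generate_frap_trace <- function(truth) {
  if (!inherits(truth, "frap_truth"))
    stop_with("invalid_argument", "truth must be a frap_truth")
  n <- truth$n_timepoints
  p <- 1L                                   # single pre-bleach frame
  times <- (seq_len(n) - 1) * truth$dt
  t_post <- pmax(times - times[p + 1L], 0)
  L <- truth$pre_bleach_level - truth$background
  recovery <- (1 - truth$bleach_depth) +
    truth$bleach_depth * truth$mobile_fraction * (1 - exp(-truth$rate * t_post))
  ideal <- ifelse(seq_len(n) <= p, 1, recovery)
  fade <- exp(-truth$reference_fade * times)
  roi <- truth$background + L * fade * ideal
  ref <- truth$background + L * fade
  if (truth$noise_sd > 0) {
    eps <- with_seed(truth$seed, rnorm(2L * n, 0, truth$noise_sd))
    roi <- pmax(roi + eps[seq_len(n)], truth$background + 1e-6)
    ref <- pmax(ref + eps[n + seq_len(n)], truth$background + 1e-6)
  }
  truth$normalized_ideal <- ideal
  list(trace = frap_trace(times, roi, ref, background = truth$background,
                          prebleach_index = p),
       truth = truth)
}

#' Simulate a damped circadian bioluminescence trace
#'
#' Counts follow a damped cosine around a mesor,
#' \deqn{y(t) = m\,[1 + a\,e^{-\lambda t}\cos(2\pi (t-\varphi)/T)],}
#' optionally with the oscillation amplitude multiplied inside a pulse
#' window (emulating a light-pulse perturbation), plus Gaussian noise,
#' clipped at zero.
#'
#' @param mesor mean count level `m`, positive.
#' @param amplitude relative oscillation amplitude `a` (>= 0).
#' @param period period `T` in hours, positive.
#' @param phase acrophase `phi` in hours.
#' @param damping damping rate `lambda`, per hour.
#' @param times sampling times in hours (default: 0-96 h every 20 min, the
#'   usual plate-reader cadence).
#' @param pulse `NULL`, or `list(window = c(t0, t1), multiplier = x)`
#'   multiplying the oscillation amplitude inside the window.
#' @param noise_sd count noise sd.
#' @param n_replicates number of replicate wells.
#' @param seed RNG seed.
#' @return a [luminescence_trace()] whose `counts` has one column per
#'   replicate.
#' @export
generate_luminescence_trace <- function(mesor = 1000, amplitude = 0.3,
                                        period = 24, phase = 0, damping = 0,
                                        times = seq(0, 96, by = 1 / 3),
                                        pulse = NULL, noise_sd = 0,
                                        n_replicates = 1L, seed = NULL) {
  check_number(mesor, "mesor", 0, strict = TRUE)
  check_number(amplitude, "amplitude", 0)
  check_number(period, "period", 0, strict = TRUE)
  check_number(damping, "damping", 0)
  check_number(noise_sd, "noise_sd", 0)
  amp <- rep(amplitude, length(times))
  if (!is.null(pulse)) {
    win <- pulse$window
    if (length(win) != 2L || win[2] <= win[1])
      stop_with("invalid_argument", "pulse$window must be c(t0, t1), t1 > t0")
    amp[times >= win[1] & times <= win[2]] <- amplitude * pulse$multiplier
  }
  y <- mesor * (1 + amp * exp(-damping * times) *
                  cos(2 * pi * (times - phase) / period))
  counts <- matrix(rep(y, n_replicates), ncol = n_replicates)
  if (noise_sd > 0)
    counts <- with_seed(seed, pmax(counts +
      matrix(rnorm(length(counts), 0, noise_sd), nrow(counts)), 0))
  colnames(counts) <- paste0("rep", seq_len(n_replicates))
  luminescence_trace(times, counts,
                     regime = if (is.null(pulse)) NULL else
                       ifelse(times >= pulse$window[1] &
                              times <= pulse$window[2], "pulse", "free_run"))
}

#' Simulate a ChIP-qPCR Ct table with known enrichment
#'
#' Constructs, for each region, a sample (IP) Ct such that the percent-input
#' arithmetic recovers the chosen enrichment exactly in the noiseless case:
#' `sample_ct = (base_input_ct - log2(aliquot_fraction)) - log2(enrichment)`.
#'
#' @param enrichments named numeric vector of true IP/Input folds per
#'   amplicon region (names become the `region` column); all positive.
#' @param base_input_ct raw input Ct before the aliquot correction.
#' @param aliquot_fraction aliquot used for the input qPCR, in the printed
#'   percent convention (1.25 means a 1.25\% aliquot).
#' @param noise_sd Gaussian Ct noise added independently to input and sample
#'   Ct values.
#' @param n_replicates replicate measurements per region.
#' @param seed RNG seed.
#' @return data frame with columns `region`, `replicate`, `raw_input_ct`,
#'   `sample_ct`, `aliquot_fraction`, `true_enrichment`.
#' @export
generate_ct_table <- function(enrichments = c(TBS = 8, MC = 1),
                              base_input_ct = 20, aliquot_fraction = 1.25,
                              noise_sd = 0, n_replicates = 1L, seed = NULL) {
  if (!is.numeric(enrichments) || !length(enrichments) ||
      any(enrichments <= 0))
    stop_with("invalid_argument", "enrichments must be positive numbers")
  check_number(aliquot_fraction, "aliquot_fraction", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  regions <- if (is.null(names(enrichments)))
    paste0("region", seq_along(enrichments)) else names(enrichments)
  tab <- expand.grid(replicate = seq_len(n_replicates),
                     region = regions, stringsAsFactors = FALSE)
  e <- enrichments[match(tab$region, regions)]
  tab$raw_input_ct <- base_input_ct
  tab$sample_ct <- (base_input_ct - log2(aliquot_fraction)) - log2(e)
  if (noise_sd > 0) {
    eps <- with_seed(seed, rnorm(2L * nrow(tab), 0, noise_sd))
    tab$raw_input_ct <- tab$raw_input_ct + eps[seq_len(nrow(tab))]
    tab$sample_ct <- tab$sample_ct + eps[nrow(tab) + seq_len(nrow(tab))]
  }
  tab$aliquot_fraction <- aliquot_fraction
  tab$true_enrichment <- as.numeric(e)
  tab[c("region", "replicate", "raw_input_ct", "sample_ct",
        "aliquot_fraction", "true_enrichment")]
}
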