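#' Aliquot-corrected input Ct
#'
#' Corrects the raw input Ct for the fraction of the input chromatin used in
#' the qPCR reaction. Two conventions are supported:
#' \describe{
#'   \item{`"paper"` (default)}{`raw_input_ct - log2(fraction)` with the
#'     fraction written as the printed percent figure, so a 1.25\% aliquot
#'     subtracts `log2(1.25) = 0.32`.}
#'   \item{`"standard"`}{the conventional percent-input dilution correction
#'     `raw_input_ct - log2(100 / fraction)`, i.e. a 1.25\% aliquot subtracts
#'     `log2(80) = 6.32`.}
#' }
#' The two differ by the constant `log2(100)`; within one experiment either
#' yields self-consistent relative enrichments, but absolute IP/Input values
#' differ by a factor of 100, so the convention must be stated.
#'
#' @param raw_input_ct raw input threshold cycle(s); vectorized.
#' @param aliquot_fraction aliquot as a percent figure (1.25 for a 1.25\%
#'   aliquot); positive.
#' @param convention `"paper"` or `"standard"`.
#' @return adjusted input Ct, cycles.
#' @examples
#' adjusted_input(20, 1.25)              # 20 - 0.32...
#' adjusted_input(20, 1.25, "standard")  # 20 - 6.32...
#' @export
adjusted_input <- function(raw_input_ct, aliquot_fraction,
                           convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  if (any(!is.finite(raw_input_ct)))
    stop_with("domain_error", "raw_input_ct must be finite")
  if (any(!is.finite(aliquot_fraction)) || any(aliquot_fraction <= 0))
    stop_with("domain_error", "aliquot_fraction must be positive")
  corr <- if (convention == "paper") log2(aliquot_fraction)
          else log2(100 / aliquot_fraction)
  raw_input_ct - corr
}

#' IP/Input enrichment from adjusted Ct values
#'
#' \deqn{\mathrm{IP/Input} = 2^{Ct(\mathrm{adjusted\ input}) - Ct(\mathrm{sample})}}
#' assuming perfect (two-fold per cycle) amplification efficiency.
#'
#' @param adjusted adjusted input Ct from [adjusted_input()]; vectorized.
#' @param sample_ct Ct of the immunoprecipitated sample.
#' @return fold enrichment.
#' @export
ip_over_input <- function(adjusted, sample_ct) {
  if (any(!is.finite(adjusted)) || any(!is.finite(sample_ct)))
    stop_with("domain_error", "Ct values must be finite")
  2^(adjusted - sample_ct)
}

#' ChIP-qPCR enrichment table
#'
#' Adds `adjusted_input` and `ip_over_input` columns to a Ct table.
#'
#' @param ct_table data frame with columns `region`, `raw_input_ct`,
#'   `sample_ct`, `aliquot_fraction` (e.g. from [generate_ct_table()] or
#'   read from CSV).
#' @param convention passed to [adjusted_input()].
#' @return the input with the two derived columns appended.
#' @export
chip_enrichment <- function(ct_table, convention = c("paper", "standard")) {
  need <- c("region", "raw_input_ct", "sample_ct", "aliquot_fraction")
  if (!all(need %in% names(ct_table)))
    stop_with("invalid_argument", "ct_table needs columns %s",
              paste(need, collapse = ", "))
  ct_table$adjusted_input <- adjusted_input(ct_table$raw_input_ct,
                                            ct_table$aliquot_fraction,
                                            convention)
  ct_table$ip_over_input <- ip_over_input(ct_table$adjusted_input,
                                          ct_table$sample_ct)
  ct_table
}

#' Construct a bioluminescence trace
#'
#' @param times sampling times, hours.
#' @param counts numeric vector, or matrix with one column per replicate
#'   well; non-negative.
#' @param regime optional per-time annotation (e.g. `"dark"`, `"blue"`,
#'   `"pulse"`).
#' @return object of class `luminescence_trace`.
#' @export
luminescence_trace <- function(times, counts, regime = NULL) {
  counts <- as.matrix(counts)
  if (length(times) != nrow(counts))
    stop_with("invalid_trace", "times and counts differ in length")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_with("invalid_trace", "counts must be finite and non-negative")
  if (!is.null(regime) && length(regime) != length(times))
    stop_with("invalid_trace", "regime annotation length mismatch")
  structure(list(times = as.numeric(times), counts = counts, regime = regime),
            class = "luminescence_trace")
}

#' Normalize a bioluminescence trace
#'
#' Two modes, applied per replicate:
#' \describe{
#'   \item{`"first_point"`}{divide by the value at the first time point, so
#'     every replicate starts at 1 — used for dark-to-light induction
#'     kinetics.}
#'   \item{`"first_then_max"`}{first-point normalization followed by
#'     division by the series maximum, so the peak is 1 — used for free-run
#'     rhythm traces.}
#' }
#' Both are idempotent and invariant under rescaling the raw counts.
#'
#' @param trace a [luminescence_trace()], or a numeric vector/matrix of
#'   counts.
#' @param mode `"first_point"` or `"first_then_max"`.
#' @return same shape as the input (a `luminescence_trace` in, one out).
#' @export
normalize_luminescence <- function(trace,
                                   mode = c("first_point", "first_then_max")) {
  mode <- match.arg(mode)
  if (inherits(trace, "luminescence_trace")) {
    out <- trace
    out$counts <- normalize_luminescence(trace$counts, mode)
    return(out)
  }
  x <- as.matrix(trace)
  norm1 <- function(v) {
    if (!is.finite(v[1]) || v[1] <= 0)
      stop_with("domain_error", "first time point must be positive")
    v <- v / v[1]
    if (mode == "first_then_max") v <- v / max(v)
    v
  }
  out <- apply(x, 2L, norm1)
  if (is.vector(trace)) as.numeric(out) else out
}

#' Oscillation amplitude within a time window
#'
#' Half the peak-to-trough range of a (typically normalized) trace inside a
#' window — the operator used to compare rhythm amplitude with and without a
#' light-pulse perturbation. For a pure cosine sampled over a full period the
#' value equals the cosine amplitude up to discretization error.
#'
#' @param times time points, hours.
#' @param values trace values, same length (a matrix is averaged across
#'   columns first).
#' @param window `c(t0, t1)`; must contain at least 3 samples.
#' @return amplitude, same units as `values`.
#' @export
pulse_amplitude <- function(times, values, window) {
  if (is.matrix(values)) values <- rowMeans(values)
  if (length(times) != length(values))
    stop_with("invalid_argument", "times and values differ in length")
  if (length(window) != 2L || window[2] <= window[1])
    stop_with("invalid_argument", "window must be c(t0, t1) with t1 > t0")
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3L)
    stop_with("window_error", "window contains %d < 3 points", sum(sel))
  (max(values[sel]) - min(values[sel])) / 2
}

# Rough period estimate by smoothed periodogram; plumbing for QC plots only
# (rhythm fitting proper is out of scope here).
#' @noRd
estimate_period <- function(times, values) {
  dt <- median(diff(times))
  sp <- stats::spec.pgram(stats::ts(values - mean(values), deltat = dt),
                          plot = FALSE, detrend = TRUE)
  1 / sp$freq[which.max(sp$spec)]
}
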