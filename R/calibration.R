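#' Aequorin calibration parameters
#'
#' Constants of the linear pCa calibration used to convert an aequorin
#' luminescence rate constant \eqn{k} into a free-Ca2+ concentration:
#' \deqn{pCa = slope \cdot (-\log_{b} k) + intercept}
#' with \eqn{pCa = -\log_{10}[Ca^{2+}]} (molar). The defaults are the
#' published constants for mitochondrially and cytosolically targeted
#' aequorin in seedlings.
#'
#' @param slope Dimensionless multiplier of \eqn{-\log k}. Must be > 0.
#' @param intercept Intercept in pCa units. Must be > 0.
#' @param log_base Base of the logarithm in the formula; pCa conventions are
#'   base 10, which is the default.
#' @return An object of class `calibration_params`.
#' @examples
#' calibration_params()
#' @export
calibration_params <- function(slope = 0.332588, intercept = 5.5593,
                               log_base = 10) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(log_base), length(log_base) == 1L, is.finite(log_base))
  if (slope <= 0) stop("`slope` must be > 0")
  if (intercept <= 0) stop("`intercept` must be > 0")
  if (log_base <= 1) stop("`log_base` must be > 1")
  structure(list(slope = slope, intercept = intercept, log_base = log_base),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf("aequorin calibration: pCa = %g * (-log%g(k)) + %g\n",
              x$slope, x$log_base, x$intercept))
  invisible(x)
}

#' Luminescence rate constant k
#'
#' The rate constant of aequorin luminescence is the fraction of the total
#' available photon counts emitted by the stimulus-induced response:
#' k = CaL / (DisL + CaL), where CaL are the stimulus-induced counts and
#' DisL the counts released by discharging the remaining aequorin pool.
#'
#' @param stimulus_counts Stimulus-induced luminescence counts (a.u., >= 0).
#' @param discharge_counts Discharge counts of the remaining aequorin pool
#'   (a.u., >= 0). Recycled against `stimulus_counts`.
#' @return Numeric vector of rate constants in \[0, 1\]. Entries where
#'   `stimulus_counts` is exactly zero are returned as 0 and flagged in the
#'   logical attribute `below_detection` (the signal is below the counting
#'   floor, not a measured zero calcium level).
#' @examples
#' compute_k(900, 0)   # 1: every count was stimulus-induced
#' compute_k(100, 900) # 0.1
#' @export
compute_k <- function(stimulus_counts, discharge_counts) {
  stopifnot(is.numeric(stimulus_counts), is.numeric(discharge_counts))
  n <- max(length(stimulus_counts), length(discharge_counts))
  s <- rep_len(as.numeric(stimulus_counts), n)
  d <- rep_len(as.numeric(discharge_counts), n)
  if (any(!is.finite(s)) || any(!is.finite(d))) stop("counts must be finite")
  if (any(s < 0) || any(d < 0)) stop("counts must be non-negative")
  if (any(s + d == 0))
    stop("invalid trace: stimulus and discharge counts are both zero")
  k <- s / (d + s)
  attr(k, "below_detection") <- s == 0
  k
}

#' Convert a rate constant to pCa
#'
#' Applies the linear aequorin calibration \eqn{pCa = slope(-\log k) +
#' intercept}. pCa is monotonically non-increasing in k; k = 1 (all counts
#' stimulus-induced) returns the intercept.
#'
#' @param k Rate constant(s) in (0, 1\].
#' @param params A [calibration_params()] object.
#' @return Numeric vector of pCa values.
#' @examples
#' k_to_pca(1)    # the calibration intercept
#' k_to_pca(0.1)  # intercept + slope
#' @export
k_to_pca <- function(k, params = calibration_params()) {
  stopifnot(inherits(params, "calibration_params"), is.numeric(k))
  if (any(!is.finite(k)) || any(k <= 0) || any(k > 1))
    stop("`k` must lie in (0, 1]")
  params$slope * (-log(k, base = params$log_base)) + params$intercept
}

#' pCa to molar Ca2+ concentration
#'
#' @param pca pCa value(s), pCa = -log10 of the molar concentration.
#' @return Molar Ca2+ concentration(s), strictly positive.
#' @seealso [concentration_to_pca()]
#' @export
pca_to_concentration <- function(pca) {
  stopifnot(is.numeric(pca))
  if (any(!is.finite(pca))) stop("`pca` must be finite")
  10^(-pca)
}

#' Molar Ca2+ concentration to pCa
#'
#' @param concentration Molar Ca2+ concentration(s), > 0.
#' @return pCa value(s).
#' @export
concentration_to_pca <- function(concentration) {
  stopifnot(is.numeric(concentration))
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("`concentration` must be positive and finite")
  -log10(concentration)
}

#' A raw aequorin luminescence trace
#'
#' Container for one luminometer recording of a single seedling: photon
#' counts per read interval, the total counts released when the remaining
#' aequorin was discharged, and the time at which the stimulus (e.g. NaCl or
#' mannitol) was applied.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param counts Luminescence counts per interval (a.u.), >= 0, same length
#'   as `times`.
#' @param discharge_counts Total discharge counts (a.u.), >= 0.
#' @param stimulus_time Stimulus application time in seconds; must lie
#'   within the sampled time range.
#' @param label Free-text label (genotype / treatment).
#' @return An object of class `luminescence_trace`.
#' @export
luminescence_trace <- function(times, counts, discharge_counts,
                               stimulus_time, label = "") {
  stopifnot(is.numeric(times), is.numeric(counts),
            length(times) == length(counts), length(times) >= 2L,
            is.numeric(discharge_counts), length(discharge_counts) == 1L,
            is.numeric(stimulus_time), length(stimulus_time) == 1L)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("`times` must be finite and strictly increasing")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be finite and non-negative")
  if (!is.finite(discharge_counts) || discharge_counts < 0)
    stop("`discharge_counts` must be finite and non-negative")
  if (stimulus_time < times[1L] || stimulus_time > times[length(times)])
    stop("`stimulus_time` must lie within the sampled time range")
  structure(list(times = as.numeric(times), counts = as.numeric(counts),
                 discharge_counts = as.numeric(discharge_counts),
                 stimulus_time = as.numeric(stimulus_time),
                 label = as.character(label)),
            class = "luminescence_trace")
}

#' @export
print.luminescence_trace <- function(x, ...) {
  cat(sprintf(
    "luminescence trace '%s': %d samples over [%g, %g] s, stimulus at %g s,\n  %g total counts + %g discharge counts\n",
    x$label, length(x$times), x$times[1L], x$times[length(x$times)],
    x$stimulus_time, sum(x$counts), x$discharge_counts))
  invisible(x)
}

#' Calibrate a luminescence trace to a Ca2+ concentration trace
#'
#' Converts per-interval luminescence counts into molar Ca2+ using the
#' aequorin calibration. Two accounting modes are supported:
#'
#' * `"aggregate"` (default): each interval's counts are treated as CaL
#'   against a fixed DisL equal to the trace's `discharge_counts`, matching
#'   the single-k-per-seedling computation used for reported response
#'   signatures. k is invariant under joint rescaling of counts and
#'   discharge counts.
#' * `"pointwise"`: the denominator at time t is the aequorin pool still
#'   available at t, i.e. `discharge_counts` plus all counts emitted from t
#'   to the end of the trace (classical consumption accounting). This mode
#'   exactly inverts a consumption-model simulation on noise-free data.
#'
#' Zero counts are floored at `count_floor` (a half-count continuity
#' correction) before computing k, so the log never sees 0.
#'
#' @param trace A [luminescence_trace()].
#' @param params A [calibration_params()] object.
#' @param mode `"aggregate"` or `"pointwise"`.
#' @param resting_window Length (s) of the pre-stimulus window over which
#'   the resting concentration is averaged; samples with
#'   `stimulus_time - resting_window <= t < stimulus_time` are used.
#' @param count_floor Floor applied to zero/low counts before k computation.
#' @return An object of class `calcium_trace`: times, molar `concentration`,
#'   `resting_level`, plus the mode and stimulus time carried over. The
#'   pointwise remaining-pool denominator is attached as attribute
#'   `denominator` for auditing.
#' @export
calibrate_trace <- function(trace, params = calibration_params(),
                            mode = c("aggregate", "pointwise"),
                            resting_window = 60, count_floor = 0.5) {
  stopifnot(inherits(trace, "luminescence_trace"),
            inherits(params, "calibration_params"),
            is.numeric(resting_window), resting_window > 0,
            is.numeric(count_floor), count_floor > 0)
  mode <- match.arg(mode)
  cnts <- pmax(trace$counts, count_floor)
  if (mode == "aggregate") {
    denom <- trace$discharge_counts + cnts
  } else {
    if (trace$discharge_counts <= 0)
      stop("pointwise mode requires discharge_counts > 0")
    # pool remaining at t: discharge + everything still to be emitted (incl. t)
    denom <- trace$discharge_counts + rev(cumsum(rev(cnts)))
  }
  k <- cnts / denom
  conc <- pca_to_concentration(k_to_pca(k, params))
  pre <- trace$times < trace$stimulus_time &
    trace$times >= trace$stimulus_time - resting_window
  if (!any(pre))
    stop("empty pre-stimulus window: no samples within `resting_window` before the stimulus")
  ca <- structure(list(times = trace$times, concentration = conc,
                       resting_level = mean(conc[pre]),
                       stimulus_time = trace$stimulus_time,
                       mode = mode, label = trace$label),
                  class = "calcium_trace")
  attr(ca, "denominator") <- denom
  ca
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf(
    "calcium trace '%s' (%s mode): %d samples, resting [Ca2+] = %.3g M\n",
    x$label, x$mode, length(x$times), x$resting_level))
  invisible(x)
}

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

#' Extract the Ca2+ response signature of a calibrated trace
#'
#' Quantifies a stimulus-induced Ca2+ transient by the three signatures
#' reported for aequorin recordings: peak amplitude (peak concentration
#' minus resting level), curve area (time integral of the positive
#' baseline-subtracted excursion, trapezoidal rule) and peak time (time of
#' the maximum after the stimulus). The peak search is restricted to
#' post-stimulus samples; ties are broken by the earliest time. A trace with
#' no excursion above the resting level has amplitude and area 0 and a
#' missing (`NA`) peak time.
#'
#' @param ca A `calcium_trace` from [calibrate_trace()].
#' @param stimulus_time Stimulus time (s); defaults to the one stored in the
#'   trace.
#' @return An object of class `ca_signature` with fields `amplitude` (M),
#'   `curve_area` (M s), `peak_time` (s after stimulus) and `resting_level`
#'   (M).
#' @export
extract_signature <- function(ca, stimulus_time = ca$stimulus_time) {
  stopifnot(inherits(ca, "calcium_trace"),
            is.numeric(stimulus_time), length(stimulus_time) == 1L)
  post <- ca$times >= stimulus_time
  if (sum(post) < 2L)
    stop("need at least two post-stimulus samples to extract a signature")
  t_post <- ca$times[post]
  c_post <- ca$concentration[post]
  i_peak <- which.max(c_post)  # which.max is first-max: earliest tie wins
  amplitude <- c_post[i_peak] - ca$resting_level
  peak_time <- if (amplitude > 0) t_post[i_peak] - stimulus_time else NA_real_
  amplitude <- max(amplitude, 0)
  excess <- pmax(c_post - ca$resting_level, 0)
  structure(list(amplitude = amplitude,
                 curve_area = trapezoid(t_post, excess),
                 peak_time = peak_time,
                 resting_level = ca$resting_level),
            class = "ca_signature")
}

#' @export
print.ca_signature <- function(x, ...) {
  cat(sprintf(
    "Ca2+ signature: amplitude %.3g M, curve area %.3g M*s, peak at %s s post-stimulus\n",
    x$amplitude, x$curve_area,
    if (is.na(x$peak_time)) "NA" else format(x$peak_time)))
  invisible(x)
}

#' Summarize a group of Ca2+ signatures
#'
#' Field-wise mean and standard error of the mean over a group of
#' signatures (e.g. all seedlings of one genotype under one stimulus).
#' Missing peak times (flat traces) are dropped from the peak-time summary,
#' with the per-field n reported.
#'
#' @param signatures A list of `ca_signature` objects, length >= 2.
#' @return A data.frame with columns `field`, `mean`, `sem`, `n`.
#' @export
summarize_group <- function(signatures) {
  if (length(signatures) == 0L) stop("empty signature list")
  if (length(signatures) < 2L)
    stop("need at least two signatures to summarize a group")
  if (!all(vapply(signatures, inherits, logical(1), "ca_signature")))
    stop("all elements must be `ca_signature` objects")
  fields <- c("amplitude", "curve_area", "peak_time", "resting_level")
  rows <- lapply(fields, function(f) {
    v <- vapply(signatures, function(s) as.numeric(s[[f]]), numeric(1))
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(field = f,
               mean = if (n > 0L) mean(v) else NA_real_,
               sem = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_,
               n = n)
  })
  do.call(rbind, rows)
}
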