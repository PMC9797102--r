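#' Relative evolutionary rate and correction coefficient
#'
#' From the within-focal-genome Ks peak of a shared reference
#' polyploidy event (`k_focal_ech`) and the same event's peak in a
#' reference genome (`k_ref_ech`), computes the focal lineage's
#' relative rate `(k_focal - k_ref) / k_ref` and the correction
#' coefficient `w = 1 / (1 + r)`. Rescaling the focal Ks axis by `w`
#' maps the focal event peak exactly onto the reference peak, making
#' peak positions comparable in time across lineages.
#'
#' @param k_focal_ech Within-focal-genome Ks peak of the calibration
#'   event (e.g. the core-eudicot hexaploidy).
#' @param k_ref_ech The same event's within-reference-genome Ks peak.
#' @return A one-row tibble of class `rate_correction` with columns
#'   `k_focal_ech`, `k_ref_ech`, `r`, `w`.
#' @examples
#' relative_rate(2, 1) # focal lineage evolving twice as fast
#' @export
relative_rate <- function(k_focal_ech, k_ref_ech) {
  if (!is.numeric(k_focal_ech) || !is.numeric(k_ref_ech) ||
      k_focal_ech <= 0 || k_ref_ech <= 0) {
    rlang::abort("peak Ks values must be positive",
                 class = "wgdclock_domain_error")
  }
  r <- (k_focal_ech - k_ref_ech) / k_ref_ech
  out <- tibble::tibble(k_focal_ech = k_focal_ech, k_ref_ech = k_ref_ech,
                        r = r, w = 1 / (1 + r))
  class(out) <- c("rate_correction", class(out))
  out
}

#' Rescale between-genome ortholog Ks peaks by a correction coefficient
#'
#' Applies `k_corrected = w * k` so that between-genome divergence
#' peaks measured on the faster lineage's Ks axis are brought onto the
#' reference lineage's time scale.
#'
#' @param k Uncorrected Ks peak value(s).
#' @param correction A `rate_correction` from [relative_rate()].
#' @return Numeric vector of corrected Ks values.
#' @export
correct_ks <- function(k, correction) {
  stopifnot(inherits(correction, "rate_correction"))
  correction$w * k
}

#' Substitution rate from a dated Ks peak
#'
#' `rate = K / (2 T)` with `T` in years: the per-site per-year
#' substitution rate implied by a Ks peak of known age (both paralog
#' copies accumulate substitutions, hence the factor 2).
#'
#' @param k_peak Ks peak value.
#' @param t_ma Age of the event in Ma.
#' @return Substitutions per site per year.
#' @examples
#' substitution_rate(1, 100) # 5e-9
#' @export
substitution_rate <- function(k_peak, t_ma) {
  if (any(k_peak <= 0) || any(t_ma <= 0)) {
    rlang::abort("k_peak and t_ma must be positive",
                 class = "wgdclock_domain_error")
  }
  k_peak / (2 * t_ma * 1e6)
}

#' Date Ks peaks against a calibration event
#'
#' Converts within-genome Ks peaks into absolute ages using a
#' calibration polyploidy event of known age interval: the focal
#' genome's calibration peak `k_focal_ech` is pinned to the calibration
#' ages, and every other peak is dated proportionally,
#' `T = (peak_ks / k_focal_ech) * T_cal`. This is algebraically
#' identical to applying the rate correction of [relative_rate()] and
#' dividing by the reference lineage's substitution rate; the reference
#' genome's own peak value cancels and is not needed.
#'
#' @param peaks A data frame with columns `event` and `peak_ks`, or a
#'   `ks_peaks` fit (component means become `peak_ks`, events are
#'   numbered), or a named numeric vector of peaks.
#' @param k_focal_ech The focal genome's calibration-event peak.
#' @param cal Calibration age interval in Ma, `c(lower, upper)`
#'   (default `c(115, 130)`, the usual core-eudicot hexaploidy range).
#' @param correction Optional `rate_correction`; when supplied,
#'   `corrected_ks = w * peak_ks` is reported (ages are unaffected).
#' @return A tibble with columns `event`, `peak_ks`, `corrected_ks`,
#'   `age_lower`, `age_upper` (Ma), `reference_rate_lower`,
#'   `reference_rate_upper` (per site per year, the focal rate implied
#'   by each calibration bound) and `flags` (`predates_calibration`
#'   when a peak is older than the calibration anchor).
#' @examples
#' date_peaks(c(HRT = 0.329, HAT = 0.502), k_focal_ech = 2.019)
#' @export
date_peaks <- function(peaks, k_focal_ech, cal = c(115, 130),
                       correction = NULL) {
  if (inherits(peaks, "ks_peaks")) {
    peaks <- tibble::tibble(event = paste0("peak", peaks$components$component),
                            peak_ks = peaks$components$mean)
  } else if (is.numeric(peaks)) {
    peaks <- tibble::tibble(
      event = if (is.null(names(peaks))) paste0("peak", seq_along(peaks))
              else names(peaks),
      peak_ks = as.numeric(peaks))
  }
  stopifnot(all(c("event", "peak_ks") %in% names(peaks)))
  if (any(peaks$peak_ks <= 0) || k_focal_ech <= 0) {
    rlang::abort("Ks peaks must be positive", class = "wgdclock_domain_error")
  }
  if (!(cal[1] > 0 && cal[1] <= cal[2])) {
    rlang::abort("calibration interval must satisfy 0 < lower <= upper",
                 class = "wgdclock_domain_error")
  }
  scale <- peaks$peak_ks / k_focal_ech
  out <- tibble::tibble(
    event = peaks$event,
    peak_ks = peaks$peak_ks,
    corrected_ks = if (is.null(correction)) NA_real_
                   else correct_ks(peaks$peak_ks, correction),
    age_lower = scale * cal[1],
    age_upper = scale * cal[2],
    reference_rate_lower = substitution_rate(k_focal_ech, cal[2]),
    reference_rate_upper = substitution_rate(k_focal_ech, cal[1]),
    flags = ifelse(peaks$peak_ks > k_focal_ech, "predates_calibration", "")
  )
  if (any(out$flags == "predates_calibration")) {
    rlang::warn("some peaks predate the calibration anchor",
                class = "wgdclock_predates_calibration")
  }
  out
}
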