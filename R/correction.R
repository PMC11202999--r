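#' Inner-filter correction of measured fluorescence
#'
#' Attenuation of the excitation beam and re-absorption of emitted light by
#' the sample ("inner filter effect") depress measured intensities as
#' absorbance grows along a titration. The standard correction multiplies
#' each measured intensity by the exponential of the mean of the absorbances
#' at the excitation and emission wavelengths:
#'
#'   F_corrected = F_measured * exp((A_ex + A_em) / 2)
#'
#' Every downstream fit (Stern-Volmer, binding constant) should be run on
#' corrected intensities whenever absorbances were recorded.
#'
#' @param series A [titration_series()] in which every point carries `a_ex`
#'   and `a_em`.
#' @return The series with `f_corrected` filled; concentrations and point
#'   order are unchanged.
#' @export
#' @examples
#' s <- titration_series(c(0, 1e-4), c(100, 90), 298.15, 3.28e-6,
#'                       a_ex = c(0.05, 0.10), a_em = c(0.02, 0.04))
#' apply_inner_filter(s)$f_corrected
apply_inner_filter <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  missing_abs <- which(is.na(series$a_ex) | is.na(series$a_em))
  if (length(missing_abs))
    stop(sprintf("point %d is missing absorbance values (A_ex/A_em); cannot correct",
                 missing_abs[1]), call. = FALSE)
  high <- which(series$a_ex > 0.3 | series$a_em > 0.3)
  if (length(high))
    warning(sprintf(
      "absorbance exceeds 0.3 at %d point(s) (first: %d); the inner-filter correction is approximate there",
      length(high), high[1]), call. = FALSE)
  series$f_corrected <- series$f_measured * exp((series$a_ex + series$a_em) / 2)
  series
}

# Fluorescence used by the fitting stages: corrected when available,
# otherwise raw measured values.
.effective_fluorescence <- function(series) {
  ifelse(is.na(series$f_corrected), series$f_measured, series$f_corrected)
}
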