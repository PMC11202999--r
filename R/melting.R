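#' Normalize a melting curve to single-strand fraction
#'
#' DNA denaturation is followed through the hyperchromic rise of absorbance
#' at 258 nm. The curve is normalized to the single-strand fraction
#'
#'   fss = (A - A20) / (A100 - A20)
#'
#' using the readings closest to 20 and 100 degrees C as the duplex and
#' fully-denatured baselines, so fss is 0 and 1 at those anchors by
#' construction.
#'
#' @param curve A [melting_curve()] spanning (or bracketing) 20-100 C.
#' @return An object of class `"melting_result"` with the `fss` profile
#'   filled (`tm`, `delta_tm` and `shift_class` unset until
#'   [melting_temperature()] / [classify_tm_shift()] are applied).
#' @export
compute_fss <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  a <- curve$absorbance
  t <- curve$temperature
  a20 <- a[which.min(abs(t - 20))]
  a100 <- a[which.min(abs(t - 100))]
  if (a100 == a20)
    stop("degenerate melting curve: A(100 C) equals A(20 C)", call. = FALSE)
  structure(list(tm = NA_real_,
                 fss = data.frame(temperature = t,
                                  fraction = (a - a20) / (a100 - a20)),
                 delta_tm = NA_real_,
                 shift_class = "unassigned",
                 label = attr(curve, "label")),
            class = "melting_result")
}

#' Melting temperature from the single-strand fraction profile
#'
#' Tm is the temperature at which half the duplex is denatured, read off as
#' the first upward crossing of `fss = 0.5`, linearly interpolated between
#' the two bracketing readings. No sigmoid fit is performed.
#'
#' @param result A [compute_fss()] result.
#' @return The result with `tm` (degrees C) filled.
#' @export
melting_temperature <- function(result) {
  stopifnot(inherits(result, "melting_result"))
  f <- result$fss$fraction
  t <- result$fss$temperature
  below <- f < 0.5
  cross <- which(below[-length(f)] & f[-1] >= 0.5)
  if (!length(cross)) {
    if (any(f == 0.5)) {
      result$tm <- t[which(f == 0.5)[1]]
      return(result)
    }
    stop("curve does not bracket Tm (fss never crosses 0.5 upward)",
         call. = FALSE)
  }
  i <- cross[1]
  result$tm <- t[i] + (0.5 - f[i]) * (t[i + 1] - t[i]) / (f[i + 1] - f[i])
  result
}

#' @export
print.melting_result <- function(x, ...) {
  cat(sprintf("Melting analysis%s\n",
              if (!is.null(x$label) && nzchar(x$label))
                paste0(" '", x$label, "'") else ""))
  if (!is.na(x$tm)) cat(sprintf("  Tm = %.2f C\n", x$tm))
  if (!is.na(x$delta_tm))
    cat(sprintf("  dTm = %+.2f C -> %s\n", x$delta_tm, x$shift_class))
  invisible(x)
}

#' Classify a melting-temperature shift
#'
#' Intercalation stiffens and stabilizes the duplex, raising Tm by roughly
#' 5-8 degrees C; groove or external binding leaves Tm essentially
#' unchanged (or slightly lowers it). A complex-minus-free shift at or
#' above the configured threshold (default +5 C, boundary inclusive) is
#' classed intercalative.
#'
#' @param delta_tm Tm(complex) - Tm(free ligand-free DNA), degrees C.
#' @param config An [analysis_config()]; supplies `tm_intercalation_shift`.
#' @return `"intercalative"` or `"non_intercalative"`.
#' @export
#' @examples
#' classify_tm_shift(-2.4) # non_intercalative
classify_tm_shift <- function(delta_tm, config = analysis_config()) {
  stopifnot(is.finite(delta_tm))
  if (delta_tm >= config$tm_intercalation_shift) "intercalative"
  else "non_intercalative"
}

#' Full melting comparison of free DNA versus ligand-DNA complex
#'
#' Convenience wrapper: normalizes both curves, extracts both melting
#' temperatures, and classifies the shift.
#'
#' @param free_curve,complex_curve [melting_curve()] objects for DNA alone
#'   and for the ligand-DNA complex.
#' @param config An [analysis_config()].
#' @return The complex's `"melting_result"` with `delta_tm`
#'   (complex minus free) and `shift_class` filled, plus a `tm_free` field.
#' @export
melting_analysis <- function(free_curve, complex_curve,
                             config = analysis_config()) {
  free_res <- melting_temperature(compute_fss(free_curve))
  cplx_res <- melting_temperature(compute_fss(complex_curve))
  cplx_res$tm_free <- free_res$tm
  cplx_res$delta_tm <- cplx_res$tm - free_res$tm
  cplx_res$shift_class <- classify_tm_shift(cplx_res$delta_tm, config)
  cplx_res
}
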