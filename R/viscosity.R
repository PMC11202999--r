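#' Relative viscosity from capillary flow times
#'
#' Ubbelohde viscometry reduces to flow times: `eta = (t - t0) / t0` with
#' `t` the mean sample flow time and `t0` the buffer flow time.
#'
#' @param flow_time Sample flow time, seconds.
#' @param buffer_time Buffer flow time t0, seconds.
#' @return The relative viscosity (dimensionless).
#' @export
#' @examples
#' relative_viscosity(150, 100) # 0.5
relative_viscosity <- function(flow_time, buffer_time) {
  stopifnot(all(flow_time > 0), buffer_time > 0)
  if (any(flow_time <= buffer_time))
    stop("flow_time must exceed buffer_time: the DNA solution cannot flow faster than buffer",
         call. = FALSE)
  (flow_time - buffer_time) / buffer_time
}

#' Cube-root viscosity profile and intercalation call
#'
#' Intercalation separates base pairs and lengthens the helix, which raises
#' solution viscosity roughly as length cubed; the classical diagnostic
#' plots `(eta/eta0)^(1/3)` against the ligand/DNA concentration ratio,
#' where a classical intercalator climbs steeply and a groove binder stays
#' flat. The zero-ligand entry defines `eta0`, so the ordinate at ratio 0
#' is exactly 1. The slope comes from an ordinary least-squares line; a
#' slope of at least 0.1 per unit concentration ratio is classed
#' intercalative.
#'
#' @param series A [viscosity_series()] whose first entry has zero ligand.
#' @return An object of class `"viscosity_result"` with fields `eta0`,
#'   `profile` (data frame of `ratio`, `cube_root_eta`), `slope` and
#'   `viscosity_class`.
#' @export
viscosity_profile <- function(series) {
  stopifnot(inherits(series, "viscosity_series"))
  if (length(series$flow_times) < 3)
    stop("viscosity profile needs >= 3 concentrations", call. = FALSE)
  if (series$ligand_concs[1] != 0)
    stop("first entry must be the zero-ligand (DNA alone) measurement",
         call. = FALSE)
  eta <- relative_viscosity(series$flow_times, series$buffer_time)
  eta0 <- eta[1]
  ratio <- series$ligand_concs / series$dna_conc
  ord <- (eta / eta0)^(1 / 3)
  fit <- stats::lm(ord ~ ratio)
  slope <- unname(stats::coef(fit)[2])
  structure(list(eta0 = eta0,
                 profile = data.frame(ratio = ratio, cube_root_eta = ord),
                 slope = slope,
                 viscosity_class = if (slope >= 0.1) "intercalative"
                                   else "non_intercalative"),
            class = "viscosity_result")
}

#' @export
print.viscosity_result <- function(x, ...) {
  cat(sprintf("Viscosity profile: slope %.4f per unit [ligand]/[DNA] -> %s\n",
              x$slope, x$viscosity_class))
  invisible(x)
}
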