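#' Binding constant and site number from the double-logarithm plot
#'
#' For static quenching by ground-state complex formation, the association
#' constant `Ka` and binding-site number `n` follow from the double-log
#' relation
#'
#'   log10((F0 - F)/F) = n log10(Ka) + n log10(\[Qt\] - (F0 - F) \[Pt\] / F0)
#'
#' where `[Qt]` is total quencher (DNA) and `[Pt]` total fluorophore; the
#' bracketed term is the free-quencher concentration corrected for the bound
#' fraction. A straight line of the left side against
#' `log10([Qt] - (F0-F)[Pt]/F0)` has slope `n` and intercept `n log10(Ka)`.
#'
#' Points with `[Q] = 0`, `F >= F0`, or a non-positive free-quencher term
#' are excluded (and counted); at least 3 usable points are required.
#'
#' @param series A [titration_series()] (corrected fluorescence is used
#'   when present).
#' @return An object of class `"binding_fit_result"` with fields `ka`
#'   (L mol^-1), `n` (dimensionless), `r` (Pearson correlation of the
#'   regression), `temperature` (K), `n_points_used` and
#'   `n_points_excluded`.
#' @export
#' @examples
#' s <- simulate_titration(ka = 1.75e4, f0 = 1000, ligand_conc = 3.28e-6,
#'                         quencher_grid = seq(0, 2e-4, length.out = 11))
#' binding_fit(s)
binding_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  f <- .effective_fluorescence(series)
  f0 <- f[1]
  qt <- series$quencher_conc
  pt <- attr(series, "ligand_conc")
  candidate <- qt > 0
  free_q <- qt - (f0 - f) * pt / f0
  usable <- candidate & f < f0 & free_q > 0
  n_excl <- sum(candidate) - sum(usable)
  if (sum(usable) < 3)
    stop(sprintf(
      "binding fit needs >= 3 usable points, got %d (%d excluded: F >= F0 or non-positive free-quencher term)",
      sum(usable), n_excl), call. = FALSE)
  y <- log10((f0 - f[usable]) / f[usable])
  x <- log10(free_q[usable])
  fit <- stats::lm(y ~ x)
  n_sites <- unname(stats::coef(fit)[2])
  if (!is.finite(n_sites) || n_sites == 0)
    stop("degenerate double-log fit (zero slope); no binding signal",
         call. = FALSE)
  ka <- 10^(unname(stats::coef(fit)[1]) / n_sites)
  structure(list(ka = ka,
                 n = n_sites,
                 r = stats::cor(x, y),
                 temperature = attr(series, "temperature"),
                 n_points_used = sum(usable),
                 n_points_excluded = n_excl),
            class = "binding_fit_result")
}

#' @export
print.binding_fit_result <- function(x, ...) {
  cat(sprintf("Double-log binding fit at %.2f K\n", x$temperature))
  cat(sprintf("  Ka = %.4g L/mol, n = %.3f (r = %.4f; %d points used, %d excluded)\n",
              x$ka, x$n, x$r, x$n_points_used, x$n_points_excluded))
  invisible(x)
}

#' Van't Hoff analysis of the binding constant
#'
#' The temperature dependence of the association constant yields the binding
#' enthalpy and entropy through
#'
#'   log10(Ka) = -dH / (ln(10) R T) + dS / (ln(10) R)
#'
#' fitted by ordinary least squares of `log10(Ka)` against `1/T`; the Gibbs
#' energy at each input temperature follows as `dG = dH - T dS`.
#'
#' @param ka_by_temperature Named numeric vector (or list) of Ka values
#'   (L mol^-1), names giving the temperature in kelvin.
#' @param config An [analysis_config()]; supplies the gas constant.
#' @return An object of class `"thermo_result"` with fields `delta_h`
#'   (kJ mol^-1), `delta_s` (J mol^-1 K^-1), `delta_g_by_temperature`
#'   (named, kJ mol^-1), `fit_r` and `force_verdict` (see
#'   [classify_forces()]).
#' @export
#' @examples
#' vant_hoff(c("298.15" = 1.75e4, "304.15" = 1.62e4, "310.15" = 1.27e4))
vant_hoff <- function(ka_by_temperature, config = analysis_config()) {
  ka <- unlist(ka_by_temperature)
  temps <- as.numeric(names(ka))
  if (length(ka) < 2)
    stop("van't Hoff analysis needs Ka at >= 2 temperatures", call. = FALSE)
  if (any(is.na(temps)) || any(temps <= 0))
    stop("names of ka_by_temperature must be temperatures in kelvin",
         call. = FALSE)
  if (any(!is.finite(ka) | ka <= 0))
    stop("all Ka values must be positive", call. = FALSE)
  R <- config$gas_constant
  x <- 1 / temps
  y <- log10(ka)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  delta_h <- -log(10) * R * slope / 1000      # kJ/mol
  delta_s <- log(10) * R * intercept          # J/(mol K)
  dg <- gibbs(delta_h, delta_s, temps)
  names(dg) <- names(ka)
  structure(list(delta_h = delta_h,
                 delta_s = delta_s,
                 delta_g_by_temperature = dg,
                 fit_r = if (stats::sd(y) == 0) 1 else stats::cor(x, y),
                 force_verdict = classify_forces(delta_h, delta_s)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("Van't Hoff thermodynamics\n")
  cat(sprintf("  dH = %.2f kJ/mol, dS = %.2f J/(mol K)  [%s]\n",
              x$delta_h, x$delta_s, x$force_verdict))
  for (nm in names(x$delta_g_by_temperature))
    cat(sprintf("  dG(%s K) = %.2f kJ/mol\n", nm,
                x$delta_g_by_temperature[[nm]]))
  invisible(x)
}

#' Gibbs free energy of binding
#'
#' `dG = dH - T dS`, with `dH` in kJ mol^-1 and `dS` in J mol^-1 K^-1
#' (hence the factor 1000).
#'
#' @param delta_h Enthalpy change, kJ mol^-1.
#' @param delta_s Entropy change, J mol^-1 K^-1.
#' @param temperature Temperature(s), kelvin.
#' @return Gibbs energy in kJ mol^-1 (vectorized over `temperature`).
#' @export
#' @examples
#' gibbs(-20.68, 12.05, 298.15) # -24.27
gibbs <- function(delta_h, delta_s, temperature) {
  stopifnot(all(temperature > 0))
  delta_h - temperature * delta_s / 1000
}

#' Classify the dominant binding forces from the thermodynamic signature
#'
#' The signs of the binding enthalpy and entropy indicate which
#' non-covalent forces dominate: an enthalpy near zero with positive
#' entropy points to electrostatic interactions; exothermic binding with an
#' entropy gain reflects combined hydrogen bonding and hydrophobic
#' contacts (the water released from the groove pays the entropy); both
#' positive means hydrophobic; both negative means hydrogen bonding plus
#' van der Waals. The near-zero electrostatic band is |dH| < 4 kJ mol^-1
#' and is tested first, so that a small negative enthalpy is not
#' over-interpreted as hydrogen bonding.
#'
#' @param delta_h Enthalpy change, kJ mol^-1.
#' @param delta_s Entropy change, J mol^-1 K^-1.
#' @return One of `"hydrogen_bond_and_hydrophobic"`, `"hydrophobic"`,
#'   `"hbond_vdw"`, `"electrostatic"`, `"indeterminate"`.
#' @export
#' @examples
#' classify_forces(-20.68, 12.05) # hydrogen_bond_and_hydrophobic
classify_forces <- function(delta_h, delta_s) {
  if (abs(delta_h) < 4 && delta_s > 0) return("electrostatic")
  if (delta_h < 0 && delta_s > 0) return("hydrogen_bond_and_hydrophobic")
  if (delta_h > 0 && delta_s > 0) return("hydrophobic")
  if (delta_h < 0 && delta_s < 0) return("hbond_vdw")
  "indeterminate"
}
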