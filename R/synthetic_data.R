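# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a 1:1 static-quenching fluorescence titration
#'
#' Ground-truth model: ligand P (the fluorophore, fixed concentration) and
#' quencher Q (DNA, titrated) form a non-fluorescent 1:1 complex with
#' association constant `ka`. Mass action gives the complex concentration
#' in closed form,
#'
#'   C = ((P + Q + 1/ka) - sqrt((P + Q + 1/ka)^2 - 4 P Q)) / 2,
#'
#' and the true fluorescence is `F = f0 (1 - C/P)` (the bound ligand is
#' completely quenched, consistent with static quenching). The stored
#' measured value divides out the inner-filter factor
#' `exp((a_ex + a_em)/2)` — so that [apply_inner_filter()] restores the
#' true value — and applies multiplicative Gaussian noise.
#'
#' For `n != 1` the mechanistic 1:1 model does not apply; the generator
#' instead inverts the double-log binding relation phenomenologically
#' (fixed-point iteration on `F = f0 / (1 + (ka Qfree)^n)` with
#' `Qfree = Qt - (f0 - F) Pt / f0`).
#'
#' @param ka Ground-truth association constant, L mol^-1.
#' @param n Binding-site number (default 1, the mechanistic case).
#' @param f0 Zero-quencher fluorescence intensity.
#' @param ligand_conc Fluorophore concentration Pt, mol L^-1.
#' @param quencher_grid Quencher concentrations, mol L^-1, starting at 0.
#' @param a_ex,a_em Per-point absorbances at excitation/emission wavelengths
#'   (recycled; default 0 = no inner-filter attenuation).
#' @param noise_sd_fraction SD of the multiplicative Gaussian noise as a
#'   fraction of the signal (default 0 = noiseless).
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param temperature Temperature, K.
#' @param label Free-text label.
#' @return A [titration_series()] with ground-truth parameters attached as
#'   attribute `"truth"`.
#' @export
#' @examples
#' s <- simulate_titration(ka = 1.75e4, f0 = 1000, ligand_conc = 3.28e-6,
#'                         quencher_grid = seq(0, 2e-4, length.out = 11))
#' binding_fit(s)$ka # recovers 1.75e4
simulate_titration <- function(ka, n = 1, f0 = 1000,
                               ligand_conc = 3.28e-6,
                               quencher_grid = seq(0, 2e-4, length.out = 11),
                               a_ex = 0, a_em = 0,
                               noise_sd_fraction = 0, seed = NULL,
                               temperature = 298.15, label = "simulated") {
  stopifnot(ka >= 0, f0 > 0, ligand_conc > 0, noise_sd_fraction >= 0,
            quencher_grid[1] == 0)
  m <- length(quencher_grid)
  a_ex <- rep_len(a_ex, m)
  a_em <- rep_len(a_em, m)
  p <- ligand_conc
  if (n == 1) {
    if (ka == 0) {
      f_true <- rep(f0, m)
    } else {
      s <- p + quencher_grid + 1 / ka
      disc <- s^2 - 4 * p * quencher_grid
      stopifnot(all(disc >= 0)) # guaranteed by AM-GM for physical inputs
      cc <- (s - sqrt(disc)) / 2
      f_true <- f0 * (1 - cc / p)
    }
  } else {
    f_true <- vapply(quencher_grid, function(qt) {
      if (qt == 0 || ka == 0) return(f0)
      f <- f0
      for (iter in 1:200) {
        q_free <- max(qt - (f0 - f) * p / f0, .Machine$double.xmin)
        f_new <- f0 / (1 + (ka * q_free)^n)
        if (abs(f_new - f) < 1e-12 * f0) { f <- f_new; break }
        f <- f_new
      }
      f
    }, numeric(1))
  }
  f_meas <- f_true / exp((a_ex + a_em) / 2)
  if (noise_sd_fraction > 0)
    f_meas <- .with_seed(seed,
      f_meas * (1 + stats::rnorm(m, 0, noise_sd_fraction)))
  series <- titration_series(quencher_grid, f_meas, temperature, ligand_conc,
                             a_ex = a_ex, a_em = a_em, label = label)
  attr(series, "truth") <- list(ka = ka, n = n, f0 = f0,
                                noise_sd_fraction = noise_sd_fraction,
                                seed = seed)
  series
}

#' Simulate a two-state DNA melting curve
#'
#' A logistic hyperchromic transition
#' `A(T) = a20 + (a100 - a20) / (1 + exp(-(T - tm)/width))`
#' sampled over 20-100 degrees C, with optional additive Gaussian noise.
#' The logistic midpoint is the ground-truth Tm.
#'
#' @param tm Ground-truth melting temperature, degrees C.
#' @param width Transition width parameter, degrees C (> 0; a value below
#'   1e-6 is treated as a step).
#' @param a20,a100 Baseline (duplex) and plateau (denatured) absorbances;
#'   `a100 > a20` (hyperchromicity).
#' @param sample_interval Sampling interval, degrees C (default 5, the
#'   conventional bath increment).
#' @param noise_sd SD of additive absorbance noise (default 0).
#' @param seed Integer seed.
#' @return A [melting_curve()] with attribute `"truth"`.
#' @export
simulate_melting <- function(tm, width, a20 = 0.60, a100 = 0.95,
                             sample_interval = 5, noise_sd = 0,
                             seed = NULL) {
  stopifnot(width >= 0, a100 > a20, sample_interval > 0, noise_sd >= 0)
  temps <- seq(20, 100, by = sample_interval)
  a <- if (width < 1e-6) a20 + (a100 - a20) * as.numeric(temps >= tm)
       else a20 + (a100 - a20) / (1 + exp(-(temps - tm) / width))
  if (noise_sd > 0)
    a <- .with_seed(seed, a + stats::rnorm(length(a), 0, noise_sd))
  curve <- melting_curve(temps, a, label = sprintf("simulated Tm=%.1f", tm))
  attr(curve, "truth") <- list(tm = tm, width = width, seed = seed)
  curve
}

#' Simulate a viscometry series under intercalative or groove geometry
#'
#' The target cube-root profile is linear in the concentration ratio,
#' `(eta/eta0)^(1/3) = 1 + s * ratio`, with slope `s = 0.25` for an
#' intercalator (helix lengthening) and `s = 0.01` for a groove binder
#' (length preserved). Flow times are back-computed from the profile and
#' perturbed with seeded timing jitter clamped to +/- 0.2 s.
#'
#' @param mode `"intercalative"` or `"groove"`.
#' @param buffer_time Buffer flow time t0, seconds.
#' @param base_eta Relative viscosity of DNA alone (eta0).
#' @param ratios Ligand/DNA concentration ratios, starting at 0.
#' @param dna_conc DNA concentration, mol L^-1.
#' @param jitter_sd SD of the timing jitter, seconds (default 0).
#' @param seed Integer seed.
#' @return A [viscosity_series()] with attribute `"truth"`.
#' @export
simulate_viscosity <- function(mode = c("intercalative", "groove"),
                               buffer_time = 100, base_eta = 0.5,
                               ratios = seq(0, 1.2, by = 0.12),
                               dna_conc = 2.73e-5,
                               jitter_sd = 0, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(ratios[1] == 0, buffer_time > 0, base_eta > 0, jitter_sd >= 0)
  slope <- if (mode == "intercalative") 0.25 else 0.01
  eta <- base_eta * (1 + slope * ratios)^3
  flow <- buffer_time * (1 + eta)
  if (jitter_sd > 0) {
    jitter <- .with_seed(seed, stats::rnorm(length(flow), 0, jitter_sd))
    flow <- flow + pmin(pmax(jitter, -0.2), 0.2)
  }
  series <- viscosity_series(buffer_time, flow, ratios * dna_conc, dna_conc)
  attr(series, "truth") <- list(mode = mode, slope = slope, seed = seed)
  series
}

#' Reference evidence set: indole-3-propionic acid binding calf thymus DNA
#'
#' Packages the observations of a complete solution study of the plant
#' growth regulator indole-3-propionic acid (IPA) with calf thymus DNA: a
#' 2 nm UV redshift, Ka of 1.75e4 L/mol at 25 C, equivalent iodide
#' quenching of free and bound ligand, a single-/double-stranded Ksv ratio
#' of 5.09/3.55, no ionic-strength effect, a -2.4 C melting shift,
#' a non-intercalative viscosity profile, slight CD perturbation,
#' a hydrogen-bond-plus-hydrophobic thermodynamic signature, and no
#' plasmid cleavage. Used as the worked example and documentation fixture;
#' the classifier calls it a groove binder.
#'
#' @return An [evidence_set()].
#' @export
#' @examples
#' classify_binding_mode(ipa_ctdna_evidence())$mode
ipa_ctdna_evidence <- function() {
  evidence_set(
    redshift_nm = 2,
    ka = 1.75e4,
    ki_equivalence = "equivalent",
    ss_over_ds_ksv = 5.09e3 / 3.55e3,
    salt_effect = "none",
    delta_tm = -2.4,
    viscosity_class = "non_intercalative",
    cd_perturbation = "slight",
    force_verdict = "hydrogen_bond_and_hydrophobic",
    gel_cleavage = "none")
}
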