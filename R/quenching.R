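#' Stern-Volmer quenching fit
#'
#' Fits the linear Stern-Volmer law
#'
#'   F0 / F = 1 + Ksv \[Q\] = 1 + Kq tau0 \[Q\]
#'
#' by ordinary least squares of `F0/F` against quencher concentration.
#' `F0` is the fluorescence of the zero-quencher point (corrected when
#' available), not a fitted intercept. The bimolecular quenching rate
#' constant is `kq = ksv / tau0`.
#'
#' @param series A [titration_series()] with at least 3 points.
#' @param config An [analysis_config()]; `tau0` converts Ksv to Kq.
#' @return An object of class `"stern_volmer_result"` with fields `ksv`
#'   (L mol^-1), `ksv_stderr`, `intercept`, `r` (Pearson correlation of the
#'   regression), `kq` (L mol^-1 s^-1) and `temperature` (K).
#' @export
#' @examples
#' s <- simulate_titration(ka = 3.55e3, f0 = 1000, ligand_conc = 3.28e-6,
#'                         quencher_grid = seq(0, 3e-4, length.out = 8))
#' stern_volmer_fit(s)
stern_volmer_fit <- function(series, config = analysis_config()) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 3)
    stop("Stern-Volmer fit needs at least 3 titration points", call. = FALSE)
  f <- .effective_fluorescence(series)
  if (any(!is.finite(f) | f <= 0))
    stop("all fluorescence values must be positive", call. = FALSE)
  f0 <- f[1]
  q <- series$quencher_conc
  y <- f0 / f
  if (stats::sd(y) == 0) {
    # perfectly flat series: zero slope exactly, undefined correlation -> 0
    return(structure(list(ksv = 0, ksv_stderr = 0, intercept = y[1], r = 0,
                          kq = 0, temperature = attr(series, "temperature")),
                     class = "stern_volmer_result"))
  }
  fit <- stats::lm(y ~ q)
  r <- stats::cor(q, y)
  ksv <- unname(stats::coef(fit)[2])
  # slope standard error computed directly (summary.lm warns on the
  # numerically perfect fits the generators produce)
  dof <- length(q) - 2
  se <- sqrt(sum(stats::resid(fit)^2) / dof / sum((q - mean(q))^2))
  structure(list(ksv = ksv,
                 ksv_stderr = se,
                 intercept = unname(stats::coef(fit)[1]),
                 r = r,
                 kq = ksv / config$tau0,
                 temperature = attr(series, "temperature")),
            class = "stern_volmer_result")
}

#' @export
print.stern_volmer_result <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit at %.2f K\n", x$temperature))
  cat(sprintf("  Ksv = %.4g +/- %.2g L/mol  (intercept %.4f, r = %.4f)\n",
              x$ksv, x$ksv_stderr, x$intercept, x$r))
  cat(sprintf("  Kq  = %.4g L/(mol s)\n", x$kq))
  invisible(x)
}

#' Classify the quenching mechanism from a temperature series
#'
#' Static quenching (ground-state complex formation) weakens as temperature
#' rises, so Ksv falls with temperature, and the apparent bimolecular rate
#' constant Kq exceeds the diffusion-controlled collisional limit
#' (about 2e10 L mol^-1 s^-1). Dynamic (collisional) quenching shows the
#' opposite signature: Ksv rises with temperature and Kq stays at or below
#' the limit. Anything else is indeterminate.
#'
#' Monotonicity is judged on the Ksv point estimates; ties count as flat.
#'
#' @param results_by_temperature List of [stern_volmer_fit()] results sorted
#'   by ascending temperature.
#' @param config An [analysis_config()]; supplies `kq_static_threshold`.
#' @return An object of class `"mechanism_verdict"` with fields `mechanism`
#'   (`"static"`, `"dynamic"` or `"indeterminate"`), `ksv_trend`
#'   (`"decreasing"`, `"increasing"` or `"flat"`),
#'   `kq_exceeds_diffusion_limit` and `note`.
#' @export
classify_mechanism <- function(results_by_temperature,
                               config = analysis_config()) {
  stopifnot(is.list(results_by_temperature),
            all(vapply(results_by_temperature, inherits, logical(1),
                       "stern_volmer_result")))
  temps <- vapply(results_by_temperature, `[[`, numeric(1), "temperature")
  if (is.unsorted(temps, strictly = TRUE))
    stop("results must be sorted by strictly ascending temperature",
         call. = FALSE)
  ksv <- vapply(results_by_temperature, `[[`, numeric(1), "ksv")
  kq <- vapply(results_by_temperature, `[[`, numeric(1), "kq")
  exceeds <- all(kq > config$kq_static_threshold)
  if (length(ksv) < 2) {
    return(structure(list(mechanism = "indeterminate", ksv_trend = "flat",
                          kq_exceeds_diffusion_limit = exceeds,
                          note = "a single temperature cannot reveal the Ksv trend; measure at least two"),
                     class = "mechanism_verdict"))
  }
  d <- diff(ksv)
  trend <- if (all(d < 0)) "decreasing"
           else if (all(d > 0)) "increasing"
           else "flat"
  mechanism <- if (trend == "decreasing" && exceeds) "static"
               else if (trend == "increasing" && all(kq <= config$kq_static_threshold)) "dynamic"
               else "indeterminate"
  structure(list(mechanism = mechanism, ksv_trend = trend,
                 kq_exceeds_diffusion_limit = exceeds, note = ""),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s (Ksv trend %s; Kq %s diffusion limit)\n",
              x$mechanism, x$ksv_trend,
              if (x$kq_exceeds_diffusion_limit) "exceeds" else "within"))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Compare two Stern-Volmer constants
#'
#' Used for the comparative quenching assays: iodide quenching of the free
#' versus DNA-bound fluorophore (an intercalated ligand is shielded from
#' anionic quenchers; a groove-bound one is not), and single- versus
#' double-stranded DNA quenching (groove binders interact more strongly
#' with the unfolded strand).
#'
#' Two constants are called `"equivalent"` when they differ by no more than
#' twice the sum of their standard errors; otherwise the verdict names the
#' larger one.
#'
#' @param result_a,result_b [stern_volmer_fit()] results carrying `ksv` and
#'   `ksv_stderr`.
#' @return A list with `verdict` (`"equivalent"`, `"a_greater"` or
#'   `"b_greater"`), `ratio` (`ksv_a / ksv_b`) and `difference`.
#' @export
#' @examples
#' a <- structure(list(ksv = 8.76, ksv_stderr = 0.21), class = "stern_volmer_result")
#' b <- structure(list(ksv = 8.70, ksv_stderr = 0.12), class = "stern_volmer_result")
#' compare_quenching(a, b)$verdict # "equivalent"
compare_quenching <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "stern_volmer_result"),
            inherits(result_b, "stern_volmer_result"))
  if (is.null(result_a$ksv_stderr) || is.null(result_b$ksv_stderr) ||
      is.na(result_a$ksv_stderr) || is.na(result_b$ksv_stderr))
    stop("both results must carry a standard error", call. = FALSE)
  diff_ab <- result_a$ksv - result_b$ksv
  band <- 2 * (result_a$ksv_stderr + result_b$ksv_stderr)
  verdict <- if (abs(diff_ab) <= band) "equivalent"
             else if (diff_ab > 0) "a_greater" else "b_greater"
  list(verdict = verdict,
       ratio = result_a$ksv / result_b$ksv,
       difference = diff_ab)
}
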