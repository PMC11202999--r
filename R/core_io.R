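#' Analysis configuration
#'
#' Physical constants and decision thresholds shared by all pipeline stages.
#'
#' @param tau0 Fluorophore excited-state lifetime in seconds. For small
#'   organic fluorophores in aqueous buffer the canonical value is 1e-8 s;
#'   it converts the Stern-Volmer constant into the bimolecular quenching
#'   rate constant `kq = ksv / tau0`.
#' @param gas_constant Universal gas constant, J mol^-1 K^-1.
#' @param celsius_offset Additive offset converting degrees Celsius to kelvin.
#' @param kq_static_threshold Maximum diffusion-controlled collisional
#'   quenching rate constant, L mol^-1 s^-1. Apparent `kq` above this value
#'   cannot arise from collisional encounters and indicates ground-state
#'   complex formation (static quenching).
#' @param redshift_intercalation_nm UV absorption redshift (nm) above which
#'   complexation is read as intercalative stacking.
#' @param tm_intercalation_shift Melting-temperature increase (degrees C)
#'   at or above which a ligand is classed as an intercalator.
#'
#' @return An object of class `"analysis_config"`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$kq_static_threshold
analysis_config <- function(tau0 = 1e-8,
                            gas_constant = 8.314,
                            celsius_offset = 273.15,
                            kq_static_threshold = 2.0e10,
                            redshift_intercalation_nm = 10,
                            tm_intercalation_shift = 5) {
  vals <- c(tau0 = tau0, gas_constant = gas_constant,
            celsius_offset = celsius_offset,
            kq_static_threshold = kq_static_threshold,
            redshift_intercalation_nm = redshift_intercalation_nm,
            tm_intercalation_shift = tm_intercalation_shift)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all configuration values must be positive and finite", call. = FALSE)
  structure(as.list(vals), class = "analysis_config")
}

#' Construct a fluorescence titration series
#'
#' One quenching titration at a fixed temperature: a fixed fluorophore
#' (ligand) concentration with increasing quencher (DNA or iodide)
#' concentration. The zero-quencher point defines `F0`.
#'
#' @param quencher_conc Quencher concentrations, mol L^-1, strictly
#'   increasing, first value 0.
#' @param f_measured Measured fluorescence intensities (arbitrary units),
#'   all positive.
#' @param temperature Temperature in kelvin.
#' @param ligand_conc Fixed fluorophore concentration, mol L^-1.
#' @param a_ex,a_em Optional per-point absorbances at the excitation and
#'   emission wavelengths (dimensionless), for inner-filter correction.
#' @param f_corrected Corrected intensities; normally filled by
#'   [apply_inner_filter()], not supplied directly.
#' @param label Free-text label.
#'
#' @return An object of class `"titration_series"`: a data frame of points
#'   with attributes `temperature`, `ligand_conc` and `label`.
#' @export
titration_series <- function(quencher_conc, f_measured,
                             temperature, ligand_conc,
                             a_ex = NULL, a_em = NULL,
                             f_corrected = NULL, label = "") {
  n <- length(quencher_conc)
  if (length(f_measured) != n)
    stop("quencher_conc and f_measured must have the same length", call. = FALSE)
  if (n > 0) {
    if (any(!is.finite(quencher_conc)) || quencher_conc[1] != 0)
      stop("first point must have quencher_conc = 0 (defines F0)", call. = FALSE)
    bad <- which(diff(quencher_conc) <= 0)
    if (length(bad))
      stop(sprintf("non-increasing concentration at row %d", bad[1] + 1),
           call. = FALSE)
    badf <- which(!is.finite(f_measured) | f_measured <= 0)
    if (length(badf))
      stop(sprintf("non-positive fluorescence at row %d (column F_measured)",
                   badf[1]), call. = FALSE)
  }
  for (nm in c("a_ex", "a_em")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != n)
        stop(sprintf("%s must have one value per point", nm), call. = FALSE)
      if (any(is.finite(v) & v < 0))
        stop(sprintf("negative absorbance in column %s", toupper(nm)),
             call. = FALSE)
    }
  }
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)", call. = FALSE)
  if (!is.finite(ligand_conc) || ligand_conc <= 0)
    stop("ligand_conc must be positive (mol/L)", call. = FALSE)
  pts <- data.frame(quencher_conc = as.numeric(quencher_conc),
                    f_measured = as.numeric(f_measured))
  pts$a_ex <- if (is.null(a_ex)) NA_real_ else as.numeric(a_ex)
  pts$a_em <- if (is.null(a_em)) NA_real_ else as.numeric(a_em)
  pts$f_corrected <- if (is.null(f_corrected)) NA_real_ else as.numeric(f_corrected)
  structure(pts,
            temperature = as.numeric(temperature),
            ligand_conc = as.numeric(ligand_conc),
            label = as.character(label),
            class = c("titration_series", "data.frame"))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series%s: %d points, T = %.2f K, [ligand] = %.3g M\n",
              if (nzchar(attr(x, "label"))) paste0(" '", attr(x, "label"), "'") else "",
              nrow(x), attr(x, "temperature"), attr(x, "ligand_conc")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Construct a DNA melting curve
#'
#' Absorbance at 258 nm versus temperature, tracking the hyperchromic
#' effect of duplex denaturation.
#'
#' @param temperatures Temperatures in degrees Celsius, strictly increasing.
#' @param absorbances Absorbance readings (dimensionless), same length.
#' @param label Free-text label.
#' @return An object of class `"melting_curve"`.
#' @export
melting_curve <- function(temperatures, absorbances, label = "") {
  if (length(temperatures) != length(absorbances))
    stop("temperatures and absorbances must have the same length", call. = FALSE)
  if (length(temperatures) < 2)
    stop("a melting curve needs at least two readings", call. = FALSE)
  bad <- which(diff(temperatures) <= 0)
  if (length(bad))
    stop(sprintf("non-increasing temperature at row %d", bad[1] + 1),
         call. = FALSE)
  structure(data.frame(temperature = as.numeric(temperatures),
                       absorbance = as.numeric(absorbances)),
            label = as.character(label),
            class = c("melting_curve", "data.frame"))
}

#' Construct a viscometer flow-time series
#'
#' Mean Ubbelohde capillary flow times for DNA solutions at increasing
#' ligand concentration, plus the buffer-alone flow time used to calibrate
#' relative viscosity.
#'
#' @param buffer_time Buffer flow time t0, seconds.
#' @param flow_times Mean sample flow times t, seconds, one per ligand
#'   concentration (replicates averaged before construction).
#' @param ligand_concs Ligand concentrations, mol L^-1 (first is usually 0).
#' @param dna_conc Fixed DNA concentration, mol L^-1.
#' @return An object of class `"viscosity_series"`.
#' @export
viscosity_series <- function(buffer_time, flow_times, ligand_concs, dna_conc) {
  if (length(flow_times) != length(ligand_concs))
    stop("flow_times and ligand_concs must have the same length", call. = FALSE)
  if (!is.finite(buffer_time) || buffer_time <= 0)
    stop("buffer_time must be positive", call. = FALSE)
  if (any(!is.finite(flow_times) | flow_times <= 0))
    stop("all flow times must be positive", call. = FALSE)
  if (!is.finite(dna_conc) || dna_conc <= 0)
    stop("dna_conc must be positive", call. = FALSE)
  structure(list(buffer_time = as.numeric(buffer_time),
                 flow_times = as.numeric(flow_times),
                 ligand_concs = as.numeric(ligand_concs),
                 dna_conc = as.numeric(dna_conc)),
            class = "viscosity_series")
}

#' Read a titration CSV file
#'
#' Expects UTF-8, "." decimal separator, `#`-prefixed comment lines. Header
#' columns: `quencher_mol_per_L`, `F_measured`, and optionally `A_ex`,
#' `A_em`. Metadata comment rows `# temperature_K=...` and
#' `# ligand_conc_M=...` set the series attributes.
#'
#' @param path Path to the CSV file.
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  meta <- grep("^\\s*#", raw, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^\\s*#\\s*", key, "\\s*="), meta, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^\\s*#\\s*", key, "\\s*="), "", hit[1]))
  }
  temperature <- get_meta("temperature_K", NA_real_)
  ligand_conc <- get_meta("ligand_conc_M", NA_real_)
  if (is.na(temperature) || is.na(ligand_conc))
    stop("missing '# temperature_K=' or '# ligand_conc_M=' metadata row",
         call. = FALSE)
  df <- utils::read.csv(text = raw, comment.char = "#",
                        stringsAsFactors = FALSE)
  for (col in c("quencher_mol_per_L", "F_measured"))
    if (!col %in% names(df))
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
  titration_series(
    quencher_conc = df$quencher_mol_per_L,
    f_measured = df$F_measured,
    temperature = temperature,
    ligand_conc = ligand_conc,
    a_ex = if ("A_ex" %in% names(df)) df$A_ex else NULL,
    a_em = if ("A_em" %in% names(df)) df$A_em else NULL,
    label = basename(path))
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_csv()]; a written file re-read reproduces the
#' in-memory values.
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# temperature_K=%.17g", attr(series, "temperature")),
    sprintf("# ligand_conc_M=%.17g", attr(series, "ligand_conc"))), con)
  out <- data.frame(quencher_mol_per_L = series$quencher_conc,
                    F_measured = series$f_measured)
  if (!all(is.na(series$a_ex))) out$A_ex <- series$a_ex
  if (!all(is.na(series$a_em))) out$A_em <- series$a_em
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a melting-curve CSV file
#'
#' Columns `temperature_C` and `A258`; `#` comments allowed.
#'
#' @param path Path to the CSV file.
#' @return A [melting_curve()].
#' @export
read_melting_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("temperature_C", "A258"))
    if (!col %in% names(df))
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
  melting_curve(df$temperature_C, df$A258, label = basename(path))
}

#' Read a viscometry CSV file
#'
#' Columns `ligand_mol_per_L` and `flow_time_s`; metadata rows
#' `# buffer_time_s=` and `# dna_conc_M=` are required.
#'
#' @param path Path to the CSV file.
#' @return A [viscosity_series()].
#' @export
read_viscosity_csv <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  meta <- grep("^\\s*#", raw, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^\\s*#\\s*", key, "\\s*="), meta, value = TRUE)
    if (!length(hit))
      stop(sprintf("missing '# %s=' metadata row", key), call. = FALSE)
    as.numeric(sub(paste0("^\\s*#\\s*", key, "\\s*="), "", hit[1]))
  }
  df <- utils::read.csv(text = raw, comment.char = "#",
                        stringsAsFactors = FALSE)
  for (col in c("ligand_mol_per_L", "flow_time_s"))
    if (!col %in% names(df))
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
  viscosity_series(buffer_time = get_meta("buffer_time_s"),
                   flow_times = df$flow_time_s,
                   ligand_concs = df$ligand_mol_per_L,
                   dna_conc = get_meta("dna_conc_M"))
}

# Result classes understood by write_result_json(), with their stage tags.
.result_stage_tags <- c(stern_volmer_result = "stern_volmer",
                        binding_fit_result  = "binding_fit",
                        thermo_result       = "thermodynamics",
                        melting_result      = "melting",
                        viscosity_result    = "viscosity",
                        mode_verdict        = "mode_classification")

#' Write a stage result to JSON
#'
#' Serializes any pipeline result object (Stern-Volmer, binding fit,
#' thermodynamics, melting, viscosity, mode verdict) to a JSON document
#' tagged with its stage name, `schema_version` 1, and the configuration
#' snapshot used. All numeric fields are in the SI-based units documented
#' on the corresponding constructor.
#'
#' @param result A stage result object.
#' @param path Output path.
#' @param config The [analysis_config()] the result was computed under.
#' @return Invisibly, `path`.
#' @export
write_result_json <- function(result, path, config = analysis_config()) {
  hit <- intersect(class(result), names(.result_stage_tags))
  if (!length(hit))
    stop("not a recognized stage result: ",
         paste(class(result), collapse = "/"), call. = FALSE)
  payload <- c(list(schema_version = 1L,
                    stage = unname(.result_stage_tags[hit[1]])),
               unclass(result),
               list(config = unclass(config)))
  # 17 significant digits round-trips IEEE doubles bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a stage result written by [write_result_json()]
#'
#' @param path Path to the JSON file.
#' @return A list with the stored fields (class restored from the stage tag).
#' @export
read_result_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- names(.result_stage_tags)[match(x$stage, .result_stage_tags)]
  if (!is.na(cls)) {
    fields <- x[setdiff(names(x), c("schema_version", "stage", "config"))]
    return(structure(fields, class = cls))
  }
  x
}

#' Convert degrees Celsius to kelvin
#'
#' @param celsius Temperature(s) in degrees Celsius.
#' @param config An [analysis_config()] supplying the offset.
#' @return Temperature(s) in kelvin.
#' @export
#' @examples
#' celsius_to_kelvin(25) # 298.15
celsius_to_kelvin <- function(celsius, config = analysis_config()) {
  celsius + config$celsius_offset
}
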