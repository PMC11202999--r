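.evidence_fields <- c("redshift_nm", "ka", "ki_equivalence", "ss_over_ds_ksv",
                      "salt_effect", "delta_tm", "viscosity_class",
                      "cd_perturbation", "force_verdict", "gel_cleavage")

#' Assemble an evidence set for binding-mode classification
#'
#' Collects the qualitative and quantitative observables of a full
#' ligand-DNA binding study into one validated record. Every field is
#' optional, but at least three must be present before
#' [classify_binding_mode()] will return a verdict.
#'
#' @param redshift_nm UV absorption redshift of the ligand on complexation,
#'   nm.
#' @param ka Association constant, L mol^-1.
#' @param ki_equivalence Verdict from [compare_quenching()] on iodide
#'   quenching of free versus DNA-bound ligand: `"equivalent"`,
#'   `"a_greater"` or `"b_greater"`.
#' @param ss_over_ds_ksv Ratio of the single-stranded to double-stranded
#'   DNA Stern-Volmer constants.
#' @param salt_effect Effect of added NaCl on the complex: `"none"` or
#'   `"decreasing_binding"`.
#' @param delta_tm Melting-temperature shift, complex minus free, degrees C.
#' @param viscosity_class `"intercalative"` or `"non_intercalative"`, from
#'   [viscosity_profile()].
#' @param cd_perturbation Perturbation of the B-form circular-dichroism
#'   bands: `"none"`, `"slight"` or `"strong"`.
#' @param force_verdict Driving-force class from [classify_forces()].
#' @param gel_cleavage Plasmid cleavage seen on a gel: `"none"`, `"nicked"`
#'   or `"linearized"`.
#' @return An object of class `"evidence_set"` (a named list; absent fields
#'   are `NULL`).
#' @export
evidence_set <- function(redshift_nm = NULL, ka = NULL, ki_equivalence = NULL,
                         ss_over_ds_ksv = NULL, salt_effect = NULL,
                         delta_tm = NULL, viscosity_class = NULL,
                         cd_perturbation = NULL, force_verdict = NULL,
                         gel_cleavage = NULL) {
  check_enum <- function(value, name, levels) {
    if (!is.null(value) && !(is.character(value) && value %in% levels))
      stop(sprintf("%s must be one of: %s", name,
                   paste(levels, collapse = ", ")), call. = FALSE)
  }
  check_num <- function(value, name, lower = -Inf) {
    if (!is.null(value) && (!is.numeric(value) || !is.finite(value) ||
                            value < lower))
      stop(sprintf("%s must be a finite number%s", name,
                   if (lower > -Inf) sprintf(" >= %g", lower) else ""),
           call. = FALSE)
  }
  check_num(redshift_nm, "redshift_nm", 0)
  check_num(ka, "ka", 0)
  check_enum(ki_equivalence, "ki_equivalence",
             c("equivalent", "a_greater", "b_greater"))
  check_num(ss_over_ds_ksv, "ss_over_ds_ksv", 0)
  check_enum(salt_effect, "salt_effect", c("none", "decreasing_binding"))
  check_num(delta_tm, "delta_tm")
  check_enum(viscosity_class, "viscosity_class",
             c("intercalative", "non_intercalative"))
  check_enum(cd_perturbation, "cd_perturbation",
             c("none", "slight", "strong"))
  check_enum(force_verdict, "force_verdict",
             c("hydrogen_bond_and_hydrophobic", "hydrophobic", "hbond_vdw",
               "electrostatic", "indeterminate"))
  check_enum(gel_cleavage, "gel_cleavage", c("none", "nicked", "linearized"))
  ev <- list(redshift_nm = redshift_nm, ka = ka,
             ki_equivalence = ki_equivalence,
             ss_over_ds_ksv = ss_over_ds_ksv, salt_effect = salt_effect,
             delta_tm = delta_tm, viscosity_class = viscosity_class,
             cd_perturbation = cd_perturbation,
             force_verdict = force_verdict, gel_cleavage = gel_cleavage)
  structure(ev, class = "evidence_set")
}

#' Read an evidence set from JSON
#'
#' @param path Path to a JSON object with any of the [evidence_set()]
#'   field names.
#' @return An [evidence_set()].
#' @export
read_evidence_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), .evidence_fields)
  if (length(unknown))
    stop("unknown evidence field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(evidence_set, x)
}

#' Classify the DNA binding mode from aggregated evidence
#'
#' Each assay in the evidence set casts one equal-weight vote for a binding
#' mode, following the standard interpretive rules of solution-phase
#' ligand-DNA studies:
#'
#' * UV redshift above the configured threshold (default 10 nm, exclusive)
#'   votes intercalation; a slight shift votes groove.
#' * Ka between 1e3 and 1e5 L mol^-1 is groove-binder scale and votes
#'   groove; above 1e5 (ethidium-scale affinity) votes intercalation;
#'   below 1e3 casts no mode vote.
#' * Iodide quenching equivalent on free and bound ligand votes groove
#'   (an intercalated ligand would be shielded from the anionic quencher);
#'   non-equivalence votes intercalation.
#' * A single-/double-stranded Ksv ratio above 1 votes groove (groove
#'   binders engage the unfolded strand more readily); below 1 votes
#'   intercalation; exactly 1 casts no vote.
#' * No salt effect removes a vote from electrostatic; salt-weakened
#'   binding votes electrostatic.
#' * A Tm shift at or above +5 C votes intercalation; otherwise groove.
#' * The viscosity class votes for itself (intercalative -> intercalation,
#'   else groove).
#' * None-to-slight CD perturbation votes groove; strong votes
#'   intercalation.
#' * An electrostatic driving-force verdict votes electrostatic; other
#'   force verdicts are recorded in the audit trail without a mode vote
#'   (they identify chemistry, not geometry).
#' * Absence of plasmid cleavage is groove-consistent and votes groove;
#'   nicking or linearization flags covalent/cleavage chemistry in the
#'   audit trail without a mode vote.
#'
#' The verdict is the mode with the most votes; ties (or an all-zero tally)
#' are `"indeterminate"`. Electrostatic can only receive positive votes
#' from the salt and driving-force rules.
#'
#' @param evidence An [evidence_set()] with at least 3 fields present.
#' @param config An [analysis_config()].
#' @return An object of class `"mode_verdict"`: `mode` (one of
#'   `"intercalation"`, `"groove"`, `"electrostatic"`, `"indeterminate"`),
#'   `votes` (named counts), and `contributions` (data frame with one row
#'   per present evidence field: `evidence`, `vote`, `rule`).
#' @export
#' @examples
#' classify_binding_mode(ipa_ctdna_evidence())$mode # "groove"
classify_binding_mode <- function(evidence, config = analysis_config()) {
  stopifnot(inherits(evidence, "evidence_set"))
  present <- names(evidence)[!vapply(evidence, is.null, logical(1))]
  if (length(present) < 3)
    stop(sprintf(
      "insufficient evidence: %d field(s) present, need at least 3 for a verdict",
      length(present)), call. = FALSE)
  votes <- c(intercalation = 0, groove = 0, electrostatic = 0)
  contributions <- list()
  cast <- function(field, vote, rule) {
    if (!is.na(vote)) votes[vote] <<- votes[vote] + 1
    contributions[[length(contributions) + 1]] <<-
      data.frame(evidence = field,
                 vote = if (is.na(vote)) "none" else vote,
                 rule = rule)
  }
  ev <- evidence
  if ("redshift_nm" %in% present) {
    if (ev$redshift_nm > config$redshift_intercalation_nm)
      cast("redshift_nm", "intercalation",
           sprintf("UV redshift > %g nm indicates base stacking",
                   config$redshift_intercalation_nm))
    else
      cast("redshift_nm", "groove",
           "slight UV shift is characteristic of groove/external binding")
  }
  if ("ka" %in% present) {
    if (ev$ka >= 1e3 && ev$ka <= 1e5)
      cast("ka", "groove", "Ka in the 1e3-1e5 L/mol groove-binder range")
    else if (ev$ka > 1e5)
      cast("ka", "intercalation", "Ka above 1e5 L/mol, intercalator-scale affinity")
    else
      cast("ka", NA_character_, "Ka below 1e3 L/mol: too weak to assign a mode")
  }
  if ("ki_equivalence" %in% present) {
    if (ev$ki_equivalence == "equivalent")
      cast("ki_equivalence", "groove",
           "iodide quenches free and bound ligand alike: ligand is solvent-exposed")
    else
      cast("ki_equivalence", "intercalation",
           "bound ligand shielded from iodide quenching")
  }
  if ("ss_over_ds_ksv" %in% present) {
    if (ev$ss_over_ds_ksv > 1)
      cast("ss_over_ds_ksv", "groove",
           "single-stranded DNA quenches more strongly than duplex")
    else if (ev$ss_over_ds_ksv < 1)
      cast("ss_over_ds_ksv", "intercalation",
           "duplex quenches more strongly: ligand requires intact base stack")
    else
      cast("ss_over_ds_ksv", NA_character_,
           "equal ss/ds quenching: uninformative for geometry")
  }
  if ("salt_effect" %in% present) {
    if (ev$salt_effect == "none") {
      votes["electrostatic"] <- votes["electrostatic"] - 1
      contributions[[length(contributions) + 1]] <-
        data.frame(evidence = "salt_effect", vote = "against_electrostatic",
                   rule = "ionic strength does not perturb binding: electrostatic mode excluded")
    } else {
      cast("salt_effect", "electrostatic",
           "added Na+ weakens binding: phosphate-backbone interaction")
    }
  }
  if ("delta_tm" %in% present) {
    if (ev$delta_tm >= config$tm_intercalation_shift)
      cast("delta_tm", "intercalation",
           sprintf("Tm raised by >= %g C: duplex stabilized by insertion",
                   config$tm_intercalation_shift))
    else
      cast("delta_tm", "groove", "no substantial Tm increase")
  }
  if ("viscosity_class" %in% present) {
    if (ev$viscosity_class == "intercalative")
      cast("viscosity_class", "intercalation",
           "viscosity rises with ligand load: helix lengthening")
    else
      cast("viscosity_class", "groove",
           "viscosity essentially unchanged: helix length preserved")
  }
  if ("cd_perturbation" %in% present) {
    if (ev$cd_perturbation == "strong")
      cast("cd_perturbation", "intercalation",
           "strong perturbation of B-form CD bands")
    else
      cast("cd_perturbation", "groove",
           "B-form CD bands essentially preserved")
  }
  if ("force_verdict" %in% present) {
    if (ev$force_verdict == "electrostatic")
      cast("force_verdict", "electrostatic",
           "thermodynamic signature of electrostatic binding")
    else
      cast("force_verdict", NA_character_,
           sprintf("driving forces (%s) identify chemistry, not geometry",
                   ev$force_verdict))
  }
  if ("gel_cleavage" %in% present) {
    if (ev$gel_cleavage == "none")
      cast("gel_cleavage", "groove",
           "no plasmid cleavage: consistent with non-disruptive groove contact")
    else
      cast("gel_cleavage", NA_character_,
           sprintf("plasmid %s: covalent/cleavage chemistry flagged, no mode vote",
                   ev$gel_cleavage))
  }
  tally <- votes
  top <- max(tally)
  winners <- names(tally)[tally == top]
  mode <- if (length(winners) != 1 || top <= 0) "indeterminate" else winners
  structure(list(mode = mode,
                 votes = as.list(tally),
                 contributions = do.call(rbind, contributions)),
            class = "mode_verdict")
}

#' @export
print.mode_verdict <- function(x, ...) {
  cat(sprintf("Binding-mode verdict: %s\n", x$mode))
  cat(sprintf("  votes: intercalation %g, groove %g, electrostatic %g\n",
              x$votes$intercalation, x$votes$groove, x$votes$electrostatic))
  for (i in seq_len(nrow(x$contributions)))
    cat(sprintf("  - %s -> %s (%s)\n", x$contributions$evidence[i],
                x$contributions$vote[i], x$contributions$rule[i]))
  invisible(x)
}
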