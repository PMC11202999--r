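test_that("the full groove-binder evidence vector is classified groove with a complete audit trail", {
  verdict <- classify_binding_mode(ipa_ctdna_evidence())
  expect_identical(verdict$mode, "groove")
  present <- names(ipa_ctdna_evidence())
  expect_setequal(verdict$contributions$evidence, present)
  expect_equal(nrow(verdict$contributions), 10)
  expect_true(all(nzchar(verdict$contributions$rule)))
})

test_that("unanimous intercalation evidence yields an intercalation verdict", {
  ev <- evidence_set(redshift_nm = 14, delta_tm = 7,
                     viscosity_class = "intercalative")
  verdict <- classify_binding_mode(ev)
  expect_identical(verdict$mode, "intercalation")
  expect_equal(verdict$votes$intercalation, 3)
})

test_that("salt sensitivity plus an electrostatic force signature yields electrostatic", {
  ev <- evidence_set(salt_effect = "decreasing_binding",
                     force_verdict = "electrostatic", ka = 5e2)
  verdict <- classify_binding_mode(ev)
  expect_identical(verdict$mode, "electrostatic")
  # weak ka contributes to the audit trail but casts no geometric vote
  ka_row <- verdict$contributions[verdict$contributions$evidence == "ka", ]
  expect_identical(ka_row$vote, "none")
})

test_that("fewer than three evidence fields is insufficient", {
  expect_error(classify_binding_mode(evidence_set(redshift_nm = 2)),
               "insufficient evidence")
  expect_error(
    classify_binding_mode(evidence_set(redshift_nm = 2, delta_tm = -1)),
    "insufficient evidence")
})

test_that("the verdict is invariant to the order evidence is supplied", {
  fields <- list(redshift_nm = 2, ka = 1.75e4, ki_equivalence = "equivalent",
                 delta_tm = -2.4, viscosity_class = "non_intercalative",
                 cd_perturbation = "slight")
  base <- classify_binding_mode(do.call(evidence_set, fields))
  set.seed(42)
  for (i in 1:5) {
    shuffled <- do.call(evidence_set, sample(fields))
    v <- classify_binding_mode(shuffled)
    expect_identical(v$mode, base$mode)
    expect_identical(v$votes, base$votes)
  }
})

test_that("adding evidence never removes existing contributions", {
  ev1 <- list(redshift_nm = 2, delta_tm = -2.4,
              viscosity_class = "non_intercalative")
  base <- classify_binding_mode(do.call(evidence_set, ev1))
  grown <- classify_binding_mode(
    do.call(evidence_set, c(ev1, list(cd_perturbation = "slight",
                                      gel_cleavage = "nicked"))))
  expect_true(all(base$contributions$evidence %in%
                    grown$contributions$evidence))
  base_rows <- base$contributions[order(base$contributions$evidence), ]
  kept <- grown$contributions[grown$contributions$evidence %in%
                                base_rows$evidence, ]
  kept <- kept[order(kept$evidence), ]
  expect_equal(kept$vote, base_rows$vote)
})

test_that("ties and all-negative tallies are indeterminate", {
  ev <- evidence_set(redshift_nm = 14,            # intercalation
                     delta_tm = -2.4,             # groove
                     salt_effect = "none")        # -1 electrostatic
  expect_identical(classify_binding_mode(ev)$mode, "indeterminate")
})

test_that("gel cleavage anomalies are flagged without a geometric vote", {
  ev <- evidence_set(redshift_nm = 2, delta_tm = -2.4,
                     gel_cleavage = "linearized")
  v <- classify_binding_mode(ev)
  gel <- v$contributions[v$contributions$evidence == "gel_cleavage", ]
  expect_identical(gel$vote, "none")
  expect_match(gel$rule, "cleavage")
})

test_that("evidence fields are validated against their enums and ranges", {
  expect_error(evidence_set(redshift_nm = -1), "redshift_nm")
  expect_error(evidence_set(salt_effect = "maybe"), "salt_effect")
  expect_error(evidence_set(cd_perturbation = "huge"), "cd_perturbation")
  expect_error(evidence_set(ka = "big"), "ka")
})

test_that("evidence JSON is read, validated and classified", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(redshift_nm = 2, delta_tm = -2.4,
                            viscosity_class = "non_intercalative",
                            cd_perturbation = "slight"),
                       path, auto_unbox = TRUE)
  ev <- read_evidence_json(path)
  expect_s3_class(ev, "evidence_set")
  expect_identical(classify_binding_mode(ev)$mode, "groove")

  jsonlite::write_json(list(redshift = 2), path, auto_unbox = TRUE)
  expect_error(read_evidence_json(path), "unknown evidence")
})
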