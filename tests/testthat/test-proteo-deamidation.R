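psm_row <- function(peptide, mods = "", confidence = 99,
                    sample = "s1", protein = "COL1A1") {
  tibble::tibble(sample = sample, protein = protein, peptide = peptide,
                 modifications = mods, confidence = confidence)
}

test_that("confidence filter keeps the boundary and logs removals", {
  psms <- dplyr::bind_rows(
    psm_row("GPAGPQGPR", confidence = 94.9),
    psm_row("GPAGPQGPR", confidence = 95.0),
    psm_row("GPAGPQGPR", confidence = 99)
  )
  expect_message(kept <- filter_psms(psms), "removed 1 of 3")
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$confidence >= 95))

  expect_message(none <- filter_psms(psm_row("AAA", confidence = 10)),
                 "removed 1")
  expect_equal(nrow(none), 0)
  expect_message(all_kept <- filter_psms(psms, min_confidence = 0),
                 "removed 0")
  expect_equal(nrow(all_kept), 3)
  expect_warning(filter_psms(psms[0, ]), "empty")
})

test_that("deamidation rates follow the sequence-level even-once rule", {
  psms <- dplyr::bind_rows(
    # peptide seen 5x, deamidated exactly once -> counts as deamidated
    psm_row("GPAGPQGPR"), psm_row("GPAGPQGPR"), psm_row("GPAGPQGPR"),
    psm_row("GPAGPQGPR", mods = "Deamidated(Q)@6"), psm_row("GPAGPQGPR"),
    # no N/Q: excluded from the denominator entirely
    psm_row("GAVLG"),
    # N/Q peptide never deamidated
    psm_row("AANAA"),
    # oxidation on P must not count as deamidation
    psm_row("APQPA", mods = "Oxidation(P)@2")
  )
  r <- deamidation_rates(psms)
  expect_equal(r$n_sequences_with_nq, 3)
  expect_equal(r$n_deamidated, 1)
  expect_equal(r$rate, 1 / 3)
})

test_that("10 distinct N/Q sequences with 4 flagged give rate 0.40", {
  peps <- paste0("AAQA", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                 "K")
  psms <- dplyr::bind_rows(lapply(seq_along(peps), function(i) {
    psm_row(peps[i], mods = if (i <= 4) "Deamidated(Q)@3" else "")
  }))
  r <- deamidation_rates(psms)
  expect_equal(r$rate, 0.4)
})

test_that("rates are invariant to row order and duplicated rows; warn without N/Q", {
  psms <- dplyr::bind_rows(
    psm_row("GPAGPQGPR", mods = "Deamidated(Q)@6"),
    psm_row("AANAA"), psm_row("GGQGG")
  )
  r1 <- deamidation_rates(psms)
  r2 <- deamidation_rates(psms[c(3, 1, 2), ])
  r3 <- deamidation_rates(dplyr::bind_rows(psms, psms[1, ]))
  expect_equal(r1$rate, r2$rate)
  expect_equal(r1$rate, r3$rate)

  # an extra deamidated PSM for an already-flagged sequence: no change;
  # for an unflagged N/Q sequence: rate strictly increases
  r4 <- deamidation_rates(dplyr::bind_rows(
    psms, psm_row("GPAGPQGPR", mods = "Deamidated(Q)@6")))
  expect_equal(r4$rate, r1$rate)
  r5 <- deamidation_rates(dplyr::bind_rows(
    psms, psm_row("AANAA", mods = "Deamidated(N)@3")))
  expect_gt(r5$rate, r1$rate)

  expect_warning(deamidation_rates(psm_row("GAVLG")), "undefined")
})

test_that("per-protein grouping splits rates by protein", {
  psms <- dplyr::bind_rows(
    psm_row("GPAGPQGPR", mods = "Deamidated(Q)@6", protein = "COL1A1"),
    psm_row("AANAAK", protein = "COL1A2")
  )
  r <- deamidation_rates(psms, grouping = "sample_protein")
  expect_equal(nrow(r), 2)
  expect_equal(r$rate[r$protein == "COL1A1"], 1)
  expect_equal(r$rate[r$protein == "COL1A2"], 0)
})

test_that("rate comparison wraps Fisher's exact test", {
  a <- list(n_sequences_with_nq = 4, n_deamidated = 3)
  b <- list(n_sequences_with_nq = 4, n_deamidated = 1)
  cmp <- compare_deamidation(a, b)
  expect_equal(cmp$p, 34 / 70)

  same <- list(n_sequences_with_nq = 10, n_deamidated = 5)
  expect_equal(compare_deamidation(same, same)$p, 1)

  big_a <- list(n_sequences_with_nq = 100, n_deamidated = 50)
  big_b <- list(n_sequences_with_nq = 100, n_deamidated = 10)
  expect_lt(compare_deamidation(big_a, big_b)$p, 1e-8)

  expect_error(compare_deamidation(list(n_sequences_with_nq = 0,
                                        n_deamidated = 0), a),
               "zero denominator")
})

test_that("deamidation mass shift computed from monoisotopic masses", {
  sh <- deamidation_mass_shift()
  expect_equal(round(sh$deamidation, 3), 0.984)
  expect_equal(round(sh$isotopologue, 4), 1.0034)
  expect_equal(sh$difference, sh$isotopologue - sh$deamidation)
  expect_equal(round(sh$difference, 4), 0.0193)
  out <- capture.output(print(sh))
  expect_match(out[1], "\\+0.984 Da")
  expect_match(out[2], "\\+1.0 Da")
})

test_that("modification parser rejects malformed strings and bad indices", {
  expect_error(parse_modifications("Deamidated(Q)"), "unparseable")
  expect_error(psm_is_deamidated("AAA", "Deamidated(Q)@9"), "outside")
  expect_false(psm_is_deamidated("AQA", ""))
  expect_true(psm_is_deamidated("AQA", "Deamidated(Q)@2"))
  # deamidation annotation pointing at a non-N/Q residue does not count
  expect_false(psm_is_deamidated("AGA", "Deamidated(Q)@2"))
})

test_that("XIC decomposition recovers generator areas with interference", {
  tr <- sim_xic_trace(data.frame(
    channel = c("nondeamidated", "deamidated", "deamidated"),
    rt = c(40, 40, 43), area = c(100, 30, 50), width = c(0.3, 0.3, 0.3)
  ), peptide = "GPAGPQGPR")
  dec <- decompose_xic(tr)
  expect_equal(dec$deamidated_area, 50, tolerance = 0.02)
  expect_equal(dec$interference_area, 30, tolerance = 0.02)
  expect_equal(dec$deamidated_fraction, 1 / 3, tolerance = 0.02)
  expect_false(dec$unresolved)
  # consistency check reports the fitted interference ratio
  expect_equal(dec$isotope_check$fitted_interference_ratio, 0.3,
               tolerance = 0.02)
})

test_that("flat deamidated channel gives fraction 0; co-elution flags unresolved", {
  flat <- sim_xic_trace(data.frame(channel = "nondeamidated", rt = 40,
                                   area = 100, width = 0.3))
  dec <- decompose_xic(flat)
  expect_identical(dec$deamidated_fraction, 0)

  co <- sim_xic_trace(data.frame(
    channel = c("nondeamidated", "deamidated"),
    rt = c(40, 40.05), area = c(100, 50), width = c(0.3, 0.3)
  ))
  expect_warning(dec2 <- decompose_xic(co), "co-elutes")
  expect_true(dec2$unresolved)
  expect_true(is.na(dec2$deamidated_fraction))
  expect_true(dec2$fraction_bounds[1] >= 0 && dec2$fraction_bounds[2] <= 1)
})

test_that("fitted channel areas conserve the trace integral within 2%", {
  tr <- sim_xic_trace(data.frame(
    channel = c("nondeamidated", "deamidated", "deamidated"),
    rt = c(40, 40, 42), area = c(80, 20, 35), width = c(0.25, 0.25, 0.35)
  ))
  dec <- decompose_xic(tr)
  expect_equal(dec$fitted_channel_areas[["nondeamidated"]],
               dec$trapz_channel_areas[["nondeamidated"]], tolerance = 0.02)
  expect_equal(dec$fitted_channel_areas[["deamidated"]],
               dec$trapz_channel_areas[["deamidated"]], tolerance = 0.02)
})

test_that("averagine-style M+1 ratio grows with peptide size", {
  small <- isotope_m1_ratio("GPAGPQGPR")
  large <- isotope_m1_ratio("GFSGLQGPPGPPGSPGEQGPSGASGPAGPR")
  expect_gt(large, small)
  expect_gt(small, 0.2)  # ~38 carbons dominate
  expect_lt(small, 0.7)
  expect_error(isotope_m1_ratio("ABZ"), "non-standard")
})
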