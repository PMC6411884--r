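test_that("nucleus stack generator handles empty and zero-damage cases", {
  p0 <- image_sim_params(grid_shape = c(8, 16, 16), nuclei = list(), seed = 1)
  sim0 <- sim_nucleus_stack(p0)
  expect_equal(nrow(sim0$truth), 0)
  # pure background: every voxel near the background level
  expect_lt(abs(mean(sim0$stack$voxels) - p0$background), 1)

  p1 <- image_sim_params(
    grid_shape = c(16, 32, 32), voxel_size = c(1, 1, 1),
    nuclei = list(list(centroid = c(8, 16, 16), radius = 4,
                       h2b_brightness = 50, damage_level = 0)),
    seed = 2
  )
  sim1 <- sim_nucleus_stack(p1)
  expect_identical(sim1$truth$gamma_integral, 0)
  expect_gt(sim1$truth$h2b_integral, 0)
})

test_that("nucleus stack generator rejects boundary-crossing nuclei", {
  p <- image_sim_params(
    grid_shape = c(16, 32, 32), voxel_size = c(1, 1, 1),
    nuclei = list(list(centroid = c(2, 16, 16), radius = 4,
                       h2b_brightness = 50, damage_level = 1))
  )
  expect_error(sim_nucleus_stack(p), "boundary")
})

test_that("nucleus stack generator is deterministic and truth scales with brightness", {
  mk <- function(bright, seed = 5) image_sim_params(
    grid_shape = c(16, 32, 32), voxel_size = c(1, 1, 1),
    nuclei = list(list(centroid = c(8, 16, 16), radius = 4,
                       h2b_brightness = bright, damage_level = 1)),
    seed = seed
  )
  a <- sim_nucleus_stack(mk(50))
  b <- sim_nucleus_stack(mk(50))
  expect_identical(a$stack$voxels, b$stack$voxels)

  # truth integral linear in brightness across three levels
  ints <- vapply(c(25, 50, 100),
                 function(br) sim_nucleus_stack(mk(br))$truth$h2b_integral,
                 numeric(1))
  expect_equal(ints / ints[1], c(1, 2, 4))
})

test_that("DDI cohort generator honours the reference group and errors on unknown ones", {
  spec <- cohort_spec(
    list(fresh = list(n = 15, damage_mean = 1),
         ft = list(n = 15, damage_mean = 3)),
    reference_group = "fresh"
  )
  coh <- sim_ddi_cohort(spec, seed = 3)
  expect_equal(nrow(coh), 30)
  d <- compute_ddi(coh, "fresh")
  expect_identical(median(d$ddi[d$group == "fresh"]), 1)
  expect_error(cohort_spec(list(a = list(n = 5, damage_mean = 1)), "b"),
               "unknown reference group")
})

test_that("development outcome declines with true damage", {
  spec <- cohort_spec(
    list(low = list(n = 300, damage_mean = 0.5, damage_cv = 0.1),
         high = list(n = 300, damage_mean = 5, damage_cv = 0.1)),
    reference_group = "low"
  )
  coh <- sim_ddi_cohort(spec, seed = 4)
  rate <- tapply(coh$developed, coh$group, mean)
  expect_gt(rate[["low"]], rate[["high"]] + 0.3)
})

test_that("PSM generator truth flags match the per-residue probability limits", {
  none <- sim_psm_table(n_peptides = 20, per_residue_deamid_prob = 0,
                        seed = 6)
  expect_false(any(none$truth$deamidated))

  all_q <- sim_psm_table(n_peptides = 20, per_residue_deamid_prob = 1,
                         seed = 7)
  with_nq <- all_q$truth$has_nq
  expect_true(all(all_q$truth$deamidated[with_nq]))
  expect_false(any(all_q$truth$deamidated[!with_nq]))
})

test_that("scoring stage reproduces the PSM generator's truth flags exactly", {
  sim <- sim_psm_table(n_peptides = 50, spectra_per_peptide = 5,
                       per_residue_deamid_prob = 0.3, seed = 8)
  rates <- suppressWarnings(deamidation_rates(sim$psms))
  expect_equal(rates$n_sequences_with_nq, sum(sim$truth$has_nq))
  expect_equal(rates$n_deamidated,
               sum(sim$truth$deamidated & sim$truth$has_nq))
})

test_that("XIC generator conserves requested areas and renders flat traces", {
  tr <- sim_xic_trace(data.frame(channel = "nondeamidated", rt = 40,
                                 area = 100, width = 0.3))
  expect_equal(pracma::trapz(tr$time, tr$nondeamidated), 100,
               tolerance = 0.005)
  expect_true(all(tr$deamidated == 0))

  flat <- sim_xic_trace(data.frame(channel = character(0), rt = numeric(0),
                                   area = numeric(0), width = numeric(0)))
  expect_true(all(flat$nondeamidated == 0) && all(flat$deamidated == 0))
  expect_error(
    sim_xic_trace(data.frame(channel = "deamidated", rt = 1, area = 1,
                             width = 0)),
    "width")
})

test_that("ancient-read generator: no damage, degenerate decay, closed-form frequencies", {
  ref <- sim_reference(3000, seed = 9)

  clean <- sim_ancient_reads(ref, damage_sim_params(n_reads = 300, delta0 = 0,
                                                    seed = 10))
  for (r in seq_len(50)) {
    expect_identical(
      clean$reads$seq[r],
      substring(ref, clean$reads$start[r] + 1,
                clean$reads$start[r] + nchar(clean$reads$seq[r])))
  }
  expect_true(all(clean$truth$n_damaged == 0))

  # decay 0: damage only possible at the terminal base
  deg <- sim_ancient_reads(ref, damage_sim_params(n_reads = 500, delta0 = 0.5,
                                                  decay = 0, seed = 11))
  pos <- unlist(deg$truth$damaged_positions)
  ends <- unlist(mapply(function(p, l) p %in% c(0L, l - 1L),
                        deg$truth$damaged_positions, deg$truth$length))
  expect_true(all(ends))

  big <- sim_ancient_reads(sim_reference(20000, seed = 12),
                           damage_sim_params(n_reads = 10000, delta0 = 0.3,
                                             decay = 0.5, seed = 13))
  prof <- terminal_damage_profile(big$reads, sim_reference(20000, seed = 12),
                                  K = 5)
  # binomial 99.9% CI half-widths at ~2500 opportunities per position
  expected <- 0.3 * 0.5^(0:2)
  for (i in 1:3) {
    ci <- 3.3 * sqrt(expected[i] * (1 - expected[i]) / prof$ct5_den[i])
    expect_lt(abs(prof$ct5_freq[i] - expected[i]), ci)
    ci3 <- 3.3 * sqrt(expected[i] * (1 - expected[i]) / prof$ga3_den[i])
    expect_lt(abs(prof$ga3_freq[i] - expected[i]), ci3)
  }
})

test_that("same seed gives bit-identical generator output, different seed differs", {
  ref <- sim_reference(2000, seed = 1)
  a <- sim_ancient_reads(ref, damage_sim_params(n_reads = 100, seed = 42))
  b <- sim_ancient_reads(ref, damage_sim_params(n_reads = 100, seed = 42))
  c <- sim_ancient_reads(ref, damage_sim_params(n_reads = 100, seed = 43))
  expect_identical(a$reads, b$reads)
  expect_false(identical(a$reads$seq, c$reads$seq))

  p1 <- sim_psm_table(seed = 5)
  p2 <- sim_psm_table(seed = 5)
  expect_identical(p1$psms, p2$psms)
})

test_that("modal fragment length lands in the dominant mixture component", {
  ref <- sim_reference(3000, seed = 2)
  mix <- list(c(mean = 158, sd = 8, weight = 0.8),
              c(mean = 320, sd = 30, weight = 0.2))
  ok <- vapply(1:8, function(s) {
    rd <- sim_ancient_reads(ref, damage_sim_params(
      n_reads = 5000, frag_length_mix = mix, seed = s))
    fld <- fragment_length_distribution(rd$reads)
    abs(fld$modal_length - 158) <= 8
  }, logical(1))
  expect_gte(mean(ok), 7 / 8)
})
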