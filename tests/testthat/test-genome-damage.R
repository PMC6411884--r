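test_that("read filtering drops N reads, low quality, and duplicates; idempotent", {
  q <- function(mean_q, len) intToUtf8(rep(33L + mean_q, len))
  reads <- make_reads(
    seqs = c("ACGTACGT", "ACGNACGT", "ACGTACGT", "TTTTTTTT", "CCCCCCCC"),
    starts = c(0, 10, 0, 20, 30),
    quals = c(q(30, 8), q(30, 8), q(25, 8), q(19, 8), q(20, 8))
  )
  suppressMessages(kept <- filter_reads(reads))
  # read 2 has N; read 3 duplicates read 1's coordinates; read 4 mean QV 19
  expect_equal(kept$id, c("r01", "r05"))
  suppressMessages(kept2 <- filter_reads(kept))
  expect_identical(kept, kept2)

  # boundary: mean quality exactly 20 retained, 19.9 removed
  mixed <- make_reads(c("AAAA", "AAAA"), c(0, 10),
                      quals = c(intToUtf8(33L + c(20L, 20L, 20L, 20L)),
                                intToUtf8(33L + c(20L, 20L, 20L, 19L))))
  suppressMessages(k <- filter_reads(mixed))
  expect_equal(k$id, "r01")
})

test_that("pileup counts, consensus and conservation match a literal recount", {
  ref <- "ACGTACGTACGTACGTACGT"
  set.seed(71)
  starts <- sample(0:12, 30, replace = TRUE)
  lens <- sample(4:8, 30, replace = TRUE)
  seqs <- vapply(1:30, function(i) {
    ch <- strsplit(substring(ref, starts[i] + 1, starts[i] + lens[i]),
                   "")[[1]]
    flip <- runif(length(ch)) < 0.2
    ch[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  reads <- make_reads(seqs, starts)
  pu <- build_pileup(reads, nchar(ref), reference = ref)
  expect_true(all(pu$n_common + pu$n_different == pu$depth))
  for (s in pu$site) {
    oracle <- recount_site(reads, s)
    row <- pu[pu$site == s, ]
    expect_equal(unname(row$A), unname(oracle[["A"]]))
    expect_equal(unname(row$C), unname(oracle[["C"]]))
    expect_equal(unname(row$G), unname(oracle[["G"]]))
    expect_equal(unname(row$T), unname(oracle[["T"]]))
    expect_equal(row$n_common, max(oracle[c("A", "C", "G", "T")]))
  }
})

test_that("pileup consensus tie-breaks to reference, else alphabetical, and flags", {
  # site 0: 2xA vs 2xG, reference G -> consensus G, ambiguous
  reads <- make_reads(c("A", "A", "G", "G"), c(0, 0, 0, 0))
  pu_ref <- build_pileup(reads, 1, reference = "G")
  expect_equal(pu_ref$consensus, "G")
  expect_true(pu_ref$ambiguous)
  pu_noref <- build_pileup(reads, 1)
  expect_equal(pu_noref$consensus, "A")   # alphabetical
  # all agree: n_different 0
  agree <- build_pileup(make_reads(c("T", "T", "T"), c(0, 0, 0)), 1)
  expect_equal(agree$n_different, 0)
  # 3xA vs 2xG: plurality
  mix <- build_pileup(make_reads(c("A", "A", "A", "G", "G"), rep(0, 5)), 1)
  expect_equal(mix$consensus, "A")
  expect_equal(mix$n_common, 3)
  expect_equal(mix$n_different, 2)
})

test_that("damage profile is zero on undamaged reads and strand-aware", {
  ref <- sim_reference(2000, seed = 81)
  clean <- sim_ancient_reads(ref, damage_sim_params(n_reads = 400, delta0 = 0,
                                                    seed = 82))
  prof <- terminal_damage_profile(clean$reads, ref, K = 15)
  expect_true(all(prof$ct5_freq == 0, na.rm = TRUE))
  expect_true(all(prof$ga3_freq == 0, na.rm = TRUE))

  dmg <- sim_ancient_reads(ref, damage_sim_params(n_reads = 800, delta0 = 0.4,
                                                  decay = 0.4, seed = 83))
  p1 <- terminal_damage_profile(dmg$reads, ref, K = 10)
  # flip every read to the opposite strand, reverse-complementing the stored
  # sequence and mirroring the start; profile must be identical
  L <- nchar(ref)
  rc_ref <- paste(rev(strsplit(chartr("ACGT", "TGCA", ref), "")[[1]]),
                  collapse = "")
  flipped <- dmg$reads
  flipped$strand <- ifelse(dmg$reads$strand == "+", "-", "+")
  flipped$seq <- vapply(dmg$reads$seq, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  flipped$start <- L - (dmg$reads$start + nchar(dmg$reads$seq))
  p2 <- terminal_damage_profile(flipped, rc_ref, K = 10)
  expect_equal(p1$ct5_freq, p2$ct5_freq)
  expect_equal(p1$ga3_freq, p2$ga3_freq)
})

test_that("profile truncates with a warning when K exceeds read length", {
  reads <- make_reads(c("ACGT", "ACGT"), c(0, 4))
  expect_warning(prof <- terminal_damage_profile(reads, strrep("ACGT", 4),
                                                 K = 10), "truncated")
  expect_equal(nrow(prof), 4)
})

test_that("profile on a reference without C gives zero denominators", {
  reads <- make_reads(c("GGGG", "GGGG"), c(0, 4))
  prof <- terminal_damage_profile(reads, strrep("G", 8), K = 4)
  expect_true(all(prof$ct5_den == 0))
  expect_true(all(is.na(prof$ct5_freq)))
})

test_that("noiseless geometric profiles invert exactly; degenerate fits flagged", {
  prof <- tibble::tibble(
    position = 0:9,
    ct5_num = round(1000 * 0.3 * 0.5^(0:9)), ct5_den = 1000,
    ct5_freq = 0.3 * 0.5^(0:9),
    ga3_num = round(1000 * 0.3 * 0.5^(0:9)), ga3_den = 1000,
    ga3_freq = 0.3 * 0.5^(0:9)
  )
  f <- fit_damage_model(prof)
  expect_equal(f$delta0_hat, 0.3, tolerance = 1e-3)
  expect_equal(f$decay_hat, 0.5, tolerance = 1e-3)

  zero <- tibble::tibble(position = 0:5, ct5_num = 0L, ct5_den = 500L,
                         ct5_freq = 0, ga3_num = 0L, ga3_den = 500L,
                         ga3_freq = 0)
  fz <- fit_damage_model(zero)
  expect_identical(fz$delta0_hat, 0)
  expect_true(is.na(fz$decay_hat))
  expect_true(fz$all_zero)
})

test_that("fragment length distribution: modes and nucleosome flag", {
  all160 <- make_reads(rep(strrep("A", 160), 5), seq(0, 800, by = 200))
  f <- fragment_length_distribution(all160)
  expect_equal(f$modal_length, 162.5)
  expect_true(f$nucleosome_peak)

  all600 <- make_reads(rep(strrep("A", 600), 5), seq(0, 4000, by = 1000))
  f2 <- fragment_length_distribution(all600)
  expect_false(f2$nucleosome_peak)
})

test_that("SNV calling boundary behaviour and monotonicity vs brute force", {
  ref <- strrep("A", 40)
  # depth 3, alt 2 at site 0 -> called; depth 2 alt 2 at site 10 -> not;
  # depth 5 alt 1 at site 20 -> not
  reads <- make_reads(
    c("G", "G", "A", "G", "G", "G", "A", "A", "A", "A"),
    c(0, 0, 0, 10, 10, 20, 20, 20, 20, 20)
  )
  pu <- build_pileup(reads, 40, reference = ref)
  calls <- call_snvs(pu, ref)
  expect_equal(calls$site, 0)
  expect_equal(calls$alt, "G")
  expect_equal(calls$alt_count, 2)

  # monotonicity on randomized pileups: relaxing thresholds never loses calls
  set.seed(91)
  for (i in 1:10) {
    n <- 60
    seqs <- vapply(1:n, function(j) {
      paste(sample(c("A", "C", "G", "T"), sample(3:6, 1), replace = TRUE,
                   prob = c(0.55, 0.15, 0.15, 0.15)), collapse = "")
    }, character(1))
    reads <- make_reads(seqs, sample(0:30, n, replace = TRUE))
    pu <- build_pileup(reads, 40, reference = ref)
    strict <- call_snvs(pu, ref, min_depth = 4, min_alt = 3)
    relaxed_d <- call_snvs(pu, ref, min_depth = 3, min_alt = 3)
    relaxed_a <- call_snvs(pu, ref, min_depth = 4, min_alt = 2)
    expect_true(all(strict$site %in% relaxed_d$site))
    expect_true(all(strict$site %in% relaxed_a$site))
    # brute-force check of the emit condition at every covered site
    for (s in pu$site) {
      oracle <- recount_site(reads, s)[c("A", "C", "G", "T")]
      alt <- oracle[names(oracle) != "A"]  # reference is all-A
      should <- sum(oracle) >= 4 && max(alt) >= 3
      expect_equal(s %in% strict$site, should,
                   info = sprintf("iter %d site %d", i, s))
    }
  }
})

test_that("SAM and TSV round trips agree with the generator output", {
  ref <- sim_reference(1500, seed = 61)
  rd <- sim_ancient_reads(ref, damage_sim_params(n_reads = 50, seed = 62))
  sam <- tempfile(fileext = ".sam")
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fasta")
  write_sam(rd$reads, nchar(ref), sam)
  write_reads_tsv(rd$reads, tsv)
  write_reference_fasta(ref, fa)

  from_tsv <- read_reads_tsv(tsv)
  expect_identical(from_tsv$seq, rd$reads$seq)
  expect_identical(from_tsv$start, rd$reads$start)

  from_sam <- read_reads_sam(sam)
  from_sam <- from_sam[match(rd$reads$id, from_sam$id), ]
  expect_identical(from_sam$seq, rd$reads$seq)
  expect_identical(as.integer(from_sam$start), rd$reads$start)
  expect_identical(from_sam$strand, rd$reads$strand)

  expect_identical(read_reference_fasta(fa), ref)

  # identical damage profiles whichever dialect carried the reads
  p_tsv <- terminal_damage_profile(from_tsv, ref, K = 10)
  p_sam <- terminal_damage_profile(
    from_sam[order(from_sam$id), ], ref, K = 10)
  expect_equal(p_tsv$ct5_freq, p_sam$ct5_freq)
})

test_that("VCF output is well-formed", {
  calls <- tibble::tibble(site = c(4L, 9L), ref = c("A", "C"),
                          alt = c("G", "T"), depth = c(5L, 7L),
                          alt_count = c(3L, 4L))
  path <- tempfile(fileext = ".vcf")
  write_snv_vcf(calls, path, chrom = "chrM")
  lines <- readLines(path)
  expect_match(lines[1], "^##fileformat=VCFv4")
  body <- lines[!grepl("^#", lines)]
  expect_equal(length(body), 2)
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(f[1], "chrM")
  expect_equal(f[2], "5")        # 1-based POS
  expect_equal(f[8], "DP=5;AD=3")
})
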