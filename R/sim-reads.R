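#' Parameters for the ancient-read simulator
#'
#' Post-mortem DNA carries two signatures this generator reproduces with
#' known ground truth: cytosine deamination near fragment ends (C-to-T at
#' the 5' end and, symmetrically, G-to-A at the 3' end, with probability
#' `delta0 * decay^i` at distance `i` from the end) and a nucleosome-scale
#' fragment-length distribution, modelled as a mixture of normal components.
#' The default single component (mean 158 bp, sd 10) sits in the 150-170 bp
#' band expected when histone octamers have protected ~146 bp units from
#' nucleases.
#'
#' @param n_reads number of fragments to simulate.
#' @param delta0 terminal deamination probability in \[0, 1\].
#' @param decay per-position geometric decay in \[0, 1).
#' @param frag_length_mix list of mixture components, each
#'   `c(mean = bp, sd = bp, weight = w)`; weights must sum to 1.
#' @param mean_quality mean per-base Phred quality.
#' @param seed integer seed.
#' @return A `damage_sim_params` object.
#' @seealso [sim_ancient_reads()]
#' @export
damage_sim_params <- function(n_reads = 1000L, delta0 = 0.3, decay = 0.5,
                              frag_length_mix = list(
                                c(mean = 158, sd = 10, weight = 1)),
                              mean_quality = 30, seed = 1L) {
  assert_that(n_reads >= 1, "n_reads must be >= 1")
  assert_that(delta0 >= 0 && delta0 <= 1, "delta0 must be in [0, 1]")
  assert_that(decay >= 0 && decay < 1, "decay must be in [0, 1)")
  w <- vapply(frag_length_mix, function(x) x[["weight"]], numeric(1))
  assert_that(abs(sum(w) - 1) < 1e-8, "mixture weights must sum to 1")
  for (comp in frag_length_mix) {
    assert_that(all(c("mean", "sd", "weight") %in% names(comp)),
                "each mixture component needs mean, sd, weight")
    assert_that(comp[["mean"]] > 0 && comp[["sd"]] >= 0,
                "component means must be > 0 and sds >= 0")
  }
  structure(
    list(n_reads = as.integer(n_reads), delta0 = delta0, decay = decay,
         frag_length_mix = frag_length_mix, mean_quality = mean_quality,
         seed = as.integer(seed)),
    class = "damage_sim_params"
  )
}

#' Simulate a random reference sequence
#'
#' @param length reference length in bp.
#' @param seed integer seed.
#' @param gc GC content in \[0, 1\].
#' @return Character scalar of A/C/G/T.
#' @export
sim_reference <- function(length = 5000L, seed = 1L, gc = 0.42) {
  assert_that(length >= 1, "length must be >= 1")
  withr::with_seed(as.integer(seed), {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

#' Simulate deaminated nucleosomal reads aligned to a reference
#'
#' Fragments are sampled from the length mixture (rounded, clamped to at
#' least 20 bp and at most the reference length), placed uniformly on the
#' reference with a uniform random strand. Deamination is applied in the
#' orientation of the original molecule: position `i` from the molecule's
#' 5' end converts C to T with probability `delta0 * decay^i`, and position
#' `j` from its 3' end converts G to A with the same law. Per-base Phred
#' qualities are normal around `mean_quality` (sd 3, clamped to \[2, 41\]).
#' Sequences are stored in reference-forward orientation (as in SAM), so
#' for minus-strand reads the molecule-level C-to-T damage appears as
#' G-to-A on the stored sequence — exactly the strand bookkeeping the
#' profiling stage must undo.
#'
#' @param reference reference sequence (character scalar, A/C/G/T).
#' @param params a [damage_sim_params()] object.
#' @param ref_name reference name used in the read table / SAM output.
#' @return List with `reads` (tibble: `id`, `rname`, `start` 0-based,
#'   `strand`, `seq`, `qual` Phred+33) and `truth` (tibble per read:
#'   `length`, `strand`, `n_damaged`, list-column `damaged_positions` of
#'   0-based molecule coordinates).
#' @export
sim_ancient_reads <- function(reference, params, ref_name = "ref") {
  stopifnot(inherits(params, "damage_sim_params"))
  assert_that(is.character(reference) && length(reference) == 1 &&
                nchar(reference) > 0, "reference must be a non-empty string")
  L <- nchar(reference)
  max_mean <- max(vapply(params$frag_length_mix, function(x) x[["mean"]],
                         numeric(1)))
  assert_that(L > max_mean,
              "reference must be longer than the largest mean fragment length")
  refv <- strsplit(reference, "")[[1]]
  weights <- vapply(params$frag_length_mix, function(x) x[["weight"]],
                    numeric(1))

  withr::with_seed(params$seed, {
    n <- params$n_reads
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    means <- vapply(params$frag_length_mix, function(x) x[["mean"]], numeric(1))
    sds <- vapply(params$frag_length_mix, function(x) x[["sd"]], numeric(1))
    len <- pmin(L, pmax(20L, as.integer(round(rnorm(n, means[comp],
                                                    sds[comp])))))
    start <- vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L,
                    integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    seqs <- character(n)
    quals <- character(n)
    n_damaged <- integer(n)
    damaged_positions <- vector("list", n)
    for (r in seq_len(n)) {
      mol <- refv[(start[r] + 1L):(start[r] + len[r])]
      if (strand[r] == "-") mol <- rev(chartr("ACGT", "TGCA", mol))
      pos <- seq_len(len[r]) - 1L
      p5 <- params$delta0 * params$decay^pos
      p3 <- rev(p5)
      hit5 <- mol == "C" & runif(len[r]) < p5
      hit3 <- mol == "G" & runif(len[r]) < p3
      mol[hit5] <- "T"
      mol[hit3] <- "A"
      dmg <- which(hit5 | hit3) - 1L
      n_damaged[r] <- length(dmg)
      damaged_positions[[r]] <- dmg
      if (strand[r] == "-") mol <- rev(chartr("ACGT", "TGCA", mol))
      seqs[r] <- paste(mol, collapse = "")
      q <- pmin(41L, pmax(2L, as.integer(round(rnorm(len[r],
                                                     params$mean_quality, 3)))))
      quals[r] <- intToUtf8(q + 33L)
    }
    list(
      reads = tibble::tibble(
        id = sprintf("read_%06d", seq_len(n)),
        rname = ref_name, start = start, strand = strand,
        seq = seqs, qual = quals
      ),
      truth = tibble::tibble(
        id = sprintf("read_%06d", seq_len(n)),
        length = len, strand = strand, n_damaged = n_damaged,
        damaged_positions = damaged_positions
      )
    )
  })
}

#' Write reads in the tab-separated read dialect
#'
#' Columns: `id`, `rname`, `start` (0-based), `strand`, `seq`, `qual`
#' (Phred+33), with a header line.
#'
#' @param reads read tibble (see [sim_ancient_reads()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(
    reads[, c("id", "rname", "start", "strand", "seq", "qual")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write reads as a minimal SAM file
#'
#' Emits an @HD/@SQ header and the 11 mandatory columns; all reads are
#' gapless (`<len>M` CIGAR), minus-strand reads get FLAG 16. Sequence and
#' quality are stored reference-forward, matching the SAM convention.
#'
#' @param reads read tibble.
#' @param reference_length reference length for the @SQ line.
#' @param path output path.
#' @param ref_name reference name (defaults to the reads' `rname`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference_length, path, ref_name = NULL) {
  ref_name <- ref_name %||% reads$rname[1]
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(reference_length))
  )
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  reads$id, flag, ref_name, reads$start + 1L,
                  nchar(reads$seq), reads$seq, reads$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a reference sequence as FASTA
#'
#' @param reference character scalar.
#' @param path output path.
#' @param name sequence name.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path, name = "ref") {
  dna <- Biostrings::DNAStringSet(reference)
  names(dna) <- name
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
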