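#' Quality-filter an aligned read set
#'
#' Three standard ancient-DNA QC steps, in order: drop reads whose *mean*
#' base quality is below `min_mean_quality` (strictly less than the
#' threshold is removed, so a mean of exactly 20 survives the default);
#' drop reads containing the ambiguous base N; collapse PCR duplicates,
#' defined as identical (reference, start, strand, length), to their first
#' occurrence. The counts removed by each step are reported via `message()`.
#' The operation is idempotent.
#'
#' @param reads read tibble (`id`, `rname`, `start`, `strand`, `seq`,
#'   `qual`).
#' @param min_mean_quality Phred threshold on the mean base quality
#'   (default 20).
#' @param drop_N drop reads containing N (default TRUE).
#' @param dedup collapse coordinate duplicates (default TRUE).
#' @return The retained reads.
#' @export
filter_reads <- function(reads, min_mean_quality = 20, drop_N = TRUE,
                         dedup = TRUE) {
  reads <- tibble::as_tibble(reads)
  n0 <- nrow(reads)
  if (n0 == 0) return(reads)
  mq <- mean_read_quality(reads$qual)
  low_q <- mq < min_mean_quality
  reads <- reads[!low_q, , drop = FALSE]
  n_with_n <- 0L
  if (drop_N && nrow(reads) > 0) {
    has_n <- grepl("N", reads$seq, fixed = TRUE)
    n_with_n <- sum(has_n)
    reads <- reads[!has_n, , drop = FALSE]
  }
  n_dup <- 0L
  if (dedup && nrow(reads) > 0) {
    key <- paste(reads$rname, reads$start, reads$strand, nchar(reads$seq),
                 sep = "\r")
    dup <- duplicated(key)
    n_dup <- sum(dup)
    reads <- reads[!dup, , drop = FALSE]
  }
  message(sprintf(paste0(
    "filter_reads: %d in; removed %d low-quality (mean QV < %g), ",
    "%d containing N, %d duplicate(s); %d retained"),
    n0, sum(low_q), min_mean_quality, n_with_n, n_dup, nrow(reads)))
  reads
}

#' Per-site pileup with plurality consensus
#'
#' Counts A/C/G/T/other per reference site over all (gapless) reads, takes
#' the plurality base as the consensus, and splits the depth into reads
#' matching the consensus (`n_common`) and mismatching it (`n_different`),
#' so `n_common + n_different = depth` at every site. Ties for the
#' consensus are resolved to the reference base when one is supplied and is
#' among the tied bases, otherwise to the alphabetically first tied base;
#' tied sites are flagged `ambiguous`.
#'
#' @param reads filtered read tibble.
#' @param reference_length reference length in bp.
#' @param reference optional reference sequence (character scalar) used
#'   only for the tie-break.
#' @return Tibble with one row per covered site: `site` (0-based), `depth`,
#'   `A`, `C`, `G`, `T`, `other`, `consensus`, `n_common`, `n_different`,
#'   `ambiguous`.
#' @export
build_pileup <- function(reads, reference_length, reference = NULL) {
  reads <- tibble::as_tibble(reads)
  L <- as.integer(reference_length)
  bases <- c("A", "C", "G", "T")
  if (nrow(reads) == 0) {
    return(tibble::tibble(site = integer(), depth = integer(),
                          A = integer(), C = integer(), G = integer(),
                          T = integer(), other = integer(),
                          consensus = character(), n_common = integer(),
                          n_different = integer(), ambiguous = logical()))
  }
  len <- nchar(reads$seq)
  assert_that(all(reads$start + len <= L),
              "read extends past the reference end")
  pos <- sequence(len) - 1L + rep(reads$start, len)
  base <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
  base[!base %in% bases] <- "other"
  counts <- table(factor(pos, levels = 0:(L - 1)),
                  factor(base, levels = c(bases, "other")))
  counts <- matrix(as.integer(counts), ncol = 5,
                   dimnames = list(NULL, c(bases, "other")))
  depth <- rowSums(counts)
  covered <- which(depth > 0)
  acgt <- counts[covered, bases, drop = FALSE]
  maxc <- apply(acgt, 1, max)
  tied <- acgt == maxc
  n_tied <- rowSums(tied)
  cons_idx <- apply(tied, 1, which.max)  # alphabetically first tied base
  if (!is.null(reference)) {
    refb <- strsplit(reference, "")[[1]][covered]
    ref_idx <- match(refb, bases)
    use_ref <- n_tied > 1 & !is.na(ref_idx) &
      tied[cbind(seq_along(covered), ifelse(is.na(ref_idx), 1L, ref_idx))]
    cons_idx[use_ref] <- ref_idx[use_ref]
  }
  consensus <- bases[cons_idx]
  n_common <- acgt[cbind(seq_along(covered), cons_idx)]
  tibble::tibble(
    site = covered - 1L,
    depth = depth[covered],
    A = acgt[, "A"], C = acgt[, "C"], G = acgt[, "G"], T = acgt[, "T"],
    other = counts[covered, "other"],
    consensus = consensus,
    n_common = n_common,
    n_different = depth[covered] - n_common,
    ambiguous = n_tied > 1
  )
}

#' Terminal deamination damage profile
#'
#' For every read, positions are counted from the ends of the original
#' molecule: minus-strand reads (stored reference-forward) are
#' reverse-complemented together with their reference window before
#' counting, so the 5' end always means the molecule's 5' end. The profile
#' reports, for each distance `i = 0..K-1`, the frequency of T where the
#' reference has C (5' end) and of A where the reference has G (3' end),
#' with the per-position opportunity counts as denominators. Positions with
#' zero opportunities get `NA` frequencies.
#'
#' @param reads filtered read tibble.
#' @param reference reference sequence (character scalar).
#' @param K number of positions from each end (default 25).
#' @return Tibble of class `damage_profile`: `position` (0-based distance
#'   from the end), `ct5_num`, `ct5_den`, `ct5_freq`, `ga3_num`, `ga3_den`,
#'   `ga3_freq`.
#' @export
terminal_damage_profile <- function(reads, reference, K = 25L) {
  reads <- tibble::as_tibble(reads)
  assert_that(nchar(reference) > 0, "empty reference")
  K <- as.integer(K)
  len <- nchar(reads$seq)
  if (nrow(reads) > 0 && K > max(len)) {
    warning(sprintf("K = %d exceeds the longest read (%d bp); profile truncated",
                    K, max(len)))
    K <- max(len)
  }
  num5 <- den5 <- num3 <- den3 <- integer(K)
  if (nrow(reads) > 0) {
    refstr <- toupper(reference)
    for (r in seq_len(nrow(reads))) {
      l <- len[r]
      rd <- strsplit(reads$seq[r], "")[[1]]
      rf <- strsplit(substring(refstr, reads$start[r] + 1L,
                               reads$start[r] + l), "")[[1]]
      if (reads$strand[r] == "-") {
        rd <- rev(chartr("ACGTN", "TGCAN", rd))
        rf <- rev(chartr("ACGTN", "TGCAN", rf))
      }
      k <- min(K, l)
      i5 <- seq_len(k)
      isC <- rf[i5] == "C"
      den5[1:k] <- den5[1:k] + isC
      num5[1:k] <- num5[1:k] + (isC & rd[i5] == "T")
      i3 <- l - i5 + 1L
      isG <- rf[i3] == "G"
      den3[1:k] <- den3[1:k] + isG
      num3[1:k] <- num3[1:k] + (isG & rd[i3] == "A")
    }
  }
  out <- tibble::tibble(
    position = 0:(K - 1),
    ct5_num = num5, ct5_den = den5,
    ct5_freq = ifelse(den5 > 0, num5 / den5, NA_real_),
    ga3_num = num3, ga3_den = den3,
    ga3_freq = ifelse(den3 > 0, num3 / den3, NA_real_)
  )
  class(out) <- c("damage_profile", class(out))
  out
}

#' Fit a geometric decay model to a damage profile
#'
#' Models the mismatch frequency at distance `i` from the fragment end as
#' `p(i) = delta0 * decay^i` — the simplest curve consistent with damage
#' concentrated at the termini — and fits it by weighted least squares on
#' the log frequencies, pooling the 5' C-to-T and 3' G-to-A points. Weights
#' are the observed event counts, the delta-method inverse variance of a
#' log frequency (`Var(log f) ~ (1-p)/(n p)`); this keeps deep-tail
#' positions, where only the occasional lucky nonzero count survives the
#' log, from flattening the decay. Zero-frequency positions carry no
#' log-scale information and are excluded; an all-zero profile returns
#' `delta0_hat = 0` with `decay_hat = NA` and the `all_zero` flag.
#'
#' @param profile a `damage_profile` from [terminal_damage_profile()].
#' @return Object of class `damage_fit`: `delta0_hat` (clamped to \[0, 1\]),
#'   `decay_hat` (clamped to \[0, 1)), weighted `residual` sum of squares on
#'   the log scale, `n_points`, and `all_zero`.
#' @export
fit_damage_model <- function(profile) {
  pts <- rbind(
    data.frame(i = profile$position, f = profile$ct5_freq,
               n = profile$ct5_den, w = profile$ct5_num),
    data.frame(i = profile$position, f = profile$ga3_freq,
               n = profile$ga3_den, w = profile$ga3_num)
  )
  pts <- pts[!is.na(pts$f) & pts$n > 0, , drop = FALSE]
  assert_that(nrow(pts) >= 3,
              "need >= 3 profile positions with nonzero denominators")
  pos <- pts[pts$f > 0, , drop = FALSE]
  if (nrow(pos) == 0) {
    return(structure(list(delta0_hat = 0, decay_hat = NA_real_,
                          residual = 0, n_points = 0L, all_zero = TRUE),
                     class = "damage_fit"))
  }
  if (nrow(pos) < 2 || length(unique(pos$i)) < 2) {
    # a single informative position pins delta0 but not the decay
    return(structure(list(delta0_hat = min(1, max(pos$f)),
                          decay_hat = NA_real_, residual = 0,
                          n_points = nrow(pos), all_zero = FALSE),
                     class = "damage_fit"))
  }
  fit <- lm(log(f) ~ i, data = pos, weights = pos$w)
  delta0 <- min(1, max(0, exp(coef(fit)[[1]])))
  decay <- min(1 - 1e-9, max(0, exp(coef(fit)[[2]])))
  structure(
    list(delta0_hat = delta0, decay_hat = decay,
         residual = sum(pos$w * stats::residuals(fit)^2),
         n_points = nrow(pos), all_zero = FALSE),
    class = "damage_fit"
  )
}

#' @export
print.damage_fit <- function(x, ...) {
  if (isTRUE(x$all_zero)) {
    cat("<damage_fit> no damage detected (all-zero profile)\n")
  } else {
    cat(sprintf(
      "<damage_fit> delta0 = %.4f, decay = %s (%d points, wRSS %.3g)\n",
      x$delta0_hat,
      ifelse(is.na(x$decay_hat), "NA", sprintf("%.4f", x$decay_hat)),
      x$n_points, x$residual))
  }
  invisible(x)
}

#' Fragment-length distribution and nucleosome-footprint flag
#'
#' Histograms read lengths at `bin` bp resolution, smooths with a centred
#' moving average over `smooth` bins, and reports the modal length (centre
#' of the maximal smoothed bin; ties go to the shortest). The
#' `nucleosome_peak` flag is set when the mode falls in
#' `nucleosome_window` — the 140-180 bp band expected when histone
#' octamers (146 bp of DNA per unit) protected the DNA from degradation.
#'
#' @param reads read tibble.
#' @param bin histogram bin width, bp.
#' @param smooth moving-average window, bins (odd recommended).
#' @param nucleosome_window length window in bp, `c(low, high)`.
#' @return Object of class `fragment_length_distribution`: `histogram`
#'   (tibble: `length_mid`, `count`, `smoothed`), `modal_length`,
#'   `nucleosome_peak`, `n_reads`.
#' @export
fragment_length_distribution <- function(reads, bin = 5L, smooth = 3L,
                                         nucleosome_window = c(140, 180)) {
  reads <- tibble::as_tibble(reads)
  assert_that(nrow(reads) >= 1, "need at least one read")
  len <- nchar(reads$seq)
  lo <- floor(min(len) / bin) * bin
  hi <- ceiling((max(len) + 1) / bin) * bin
  breaks <- seq(lo, hi, by = bin)
  counts <- tabulate(findInterval(len, breaks), nbins = length(breaks) - 1)
  mids <- breaks[-length(breaks)] + bin / 2
  half <- floor(smooth / 2)
  smoothed <- vapply(seq_along(counts), function(i) {
    j <- max(1, i - half):min(length(counts), i + half)
    mean(counts[j])
  }, numeric(1))
  modal <- mids[which.max(smoothed)]
  structure(
    list(histogram = tibble::tibble(length_mid = mids, count = counts,
                                    smoothed = smoothed),
         modal_length = modal,
         nucleosome_peak = modal >= nucleosome_window[1] &
           modal <= nucleosome_window[2],
         n_reads = nrow(reads)),
    class = "fragment_length_distribution"
  )
}

#' @export
print.fragment_length_distribution <- function(x, ...) {
  cat(sprintf(
    "<fragment_length_distribution> %d reads, mode %.1f bp, nucleosome peak: %s\n",
    x$n_reads, x$modal_length, x$nucleosome_peak))
  invisible(x)
}

#' Threshold-based SNV filtering on a pileup
#'
#' A site is emitted iff its depth is at least `min_depth` and the count of
#' its most frequent non-reference base is at least `min_alt` (both bounds
#' inclusive, so depth 3 with 2 alternate reads is called at the defaults).
#' Multi-allelic sites report the top alternate only (ties broken
#' alphabetically).
#'
#' @param pileup pileup tibble from [build_pileup()].
#' @param reference reference sequence (character scalar).
#' @param min_depth minimum read depth (default 3).
#' @param min_alt minimum alternate-supporting reads (default 2).
#' @return Tibble: `site` (0-based), `ref`, `alt`, `depth`, `alt_count`.
#' @export
call_snvs <- function(pileup, reference, min_depth = 3L, min_alt = 2L) {
  bases <- c("A", "C", "G", "T")
  if (nrow(pileup) == 0) {
    return(tibble::tibble(site = integer(), ref = character(),
                          alt = character(), depth = integer(),
                          alt_count = integer()))
  }
  refv <- strsplit(toupper(reference), "")[[1]]
  assert_that(max(pileup$site) < length(refv),
              "pileup site beyond reference end")
  refb <- refv[pileup$site + 1L]
  cnt <- as.matrix(pileup[, bases])
  ref_idx <- match(refb, bases)
  cnt_alt <- cnt
  cnt_alt[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L  # mask the ref base
  alt_count <- apply(cnt_alt, 1, max)
  alt_idx <- apply(cnt_alt, 1, which.max)  # alphabetical tie-break
  keep <- pileup$depth >= min_depth & alt_count >= min_alt
  tibble::tibble(
    site = pileup$site[keep],
    ref = refb[keep],
    alt = bases[alt_idx[keep]],
    depth = pileup$depth[keep],
    alt_count = as.integer(alt_count[keep])
  )
}

#' Write SNV calls as a minimal VCF
#'
#' CHROM/POS (1-based)/ID/REF/ALT/QUAL/FILTER/INFO with `DP` (depth) and
#' `AD` (alternate count).
#'
#' @param calls tibble from [call_snvs()].
#' @param path output path.
#' @param chrom chromosome / reference name.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(calls, path, chrom = "ref") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate-supporting reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(calls) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d",
            chrom, calls$site + 1L, calls$ref, calls$alt,
            calls$depth, calls$alt_count)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
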