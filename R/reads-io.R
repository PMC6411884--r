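# Readers for aligned-read input: SAM/BAM (via Rsamtools) and the TSV
# dialect, plus FASTA references (via Biostrings). All coordinates are
# converted to 0-based half-open on read.

#' Read aligned reads from SAM or BAM
#'
#' SAM files are converted with `Rsamtools::asBam()` and scanned; unmapped
#' reads are dropped, and reads whose CIGAR contains anything but a single
#' match run (indels, clips, skips) are skipped with a reported count — the
#' pipeline consumes gapless unique alignments only.
#'
#' @param path SAM (`.sam`) or BAM path.
#' @return Read tibble: `id`, `rname`, `start` (0-based), `strand`, `seq`,
#'   `qual` (Phred+33).
#' @export
read_reads_sam <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq", "qual", "flag",
             "cigar")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  gapless <- grepl("^[0-9]+M$", b$cigar)
  skipped <- sum(mapped & !gapless)
  if (skipped > 0) {
    message(sprintf("read_reads_sam: skipped %d read(s) with non-gapless CIGAR",
                    skipped))
  }
  keep <- mapped & gapless
  tibble::tibble(
    id = b$qname[keep],
    rname = as.character(b$rname[keep]),
    start = b$pos[keep] - 1L,
    strand = as.character(b$strand[keep]),
    seq = as.character(b$seq[keep]),
    qual = as.character(b$qual[keep])
  )
}

#' Read aligned reads from the TSV dialect
#'
#' Expects the header written by [write_reads_tsv()]: `id`, `rname`,
#' `start` (0-based), `strand`, `seq`, `qual`.
#'
#' @param path TSV path.
#' @return Read tibble in the same layout.
#' @export
read_reads_tsv <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character", rname = "character",
                                         start = "integer",
                                         strand = "character",
                                         seq = "character",
                                         qual = "character"))
  assert_that(all(c("id", "rname", "start", "strand", "seq", "qual") %in%
                    names(df)),
              "TSV must have columns id, rname, start, strand, seq, qual")
  assert_that(all(df$start >= 0), "starts must be >= 0 (0-based)")
  assert_that(all(nchar(df$seq) == nchar(df$qual)),
              "sequence and quality lengths differ")
  assert_that(all(df$strand %in% c("+", "-")), "strand must be + or -")
  tibble::as_tibble(df)
}

#' Read the first sequence of a FASTA file as a character scalar
#'
#' @param path FASTA path.
#' @return Character scalar (uppercase).
#' @export
read_reference_fasta <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  dna <- Biostrings::readDNAStringSet(path)
  assert_that(length(dna) >= 1, "FASTA contains no sequence")
  toupper(as.character(dna[[1]]))
}
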