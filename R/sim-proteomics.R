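#' Simulate a peptide-spectrum-match (PSM) table with known deamidation truth
#'
#' Random tryptic-sized peptides are drawn from the 20 amino acids; each
#' peptide is observed in `spectra_per_peptide` spectra, and in each spectrum
#' every asparagine (N) or glutamine (Q) residue is independently deamidated
#' with probability `per_residue_deamid_prob`. Occasional proline oxidation
#' is added as a decoy modification that must not count as deamidation.
#' Confidence values are uniform on \[80, 100\] so downstream
#' confidence filtering has something to do.
#'
#' @param n_peptides number of distinct peptides.
#' @param spectra_per_peptide spectra per peptide.
#' @param per_residue_deamid_prob per-N/Q-residue deamidation probability in
#'   \[0, 1\].
#' @param seed integer seed.
#' @param sample sample label for the table.
#' @param peptide_length inclusive range of peptide lengths.
#' @return List with `psms` (tibble: `sample`, `peptide`, `modifications`,
#'   `confidence`) and `truth` (tibble per peptide: `has_nq`, `deamidated` =
#'   whether any spectrum carries a deamidated N/Q). Modifications are
#'   encoded `"Name(Residue)@index"`, semicolon-separated, 1-based indices.
#' @export
sim_psm_table <- function(n_peptides = 50L, spectra_per_peptide = 5L,
                          per_residue_deamid_prob = 0.3, seed = 1L,
                          sample = "sample_1", peptide_length = c(7L, 15L)) {
  assert_that(per_residue_deamid_prob >= 0 && per_residue_deamid_prob <= 1,
              "per_residue_deamid_prob must be in [0, 1]")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(as.integer(seed), {
    peptides <- unique(vapply(seq_len(n_peptides), function(i) {
      len <- sample(seq(peptide_length[1], peptide_length[2]), 1)
      paste(sample(aa, len, replace = TRUE), collapse = "")
    }, character(1)))
    rows <- vector("list", length(peptides) * spectra_per_peptide)
    truth_deam <- logical(length(peptides))
    r <- 1L
    for (i in seq_along(peptides)) {
      pep <- strsplit(peptides[i], "")[[1]]
      nq <- which(pep %in% c("N", "Q"))
      pro <- which(pep == "P")
      for (s in seq_len(spectra_per_peptide)) {
        mods <- character(0)
        if (length(nq) > 0) {
          hit <- nq[runif(length(nq)) < per_residue_deamid_prob]
          if (length(hit) > 0) {
            truth_deam[i] <- TRUE
            mods <- c(mods, sprintf("Deamidated(%s)@%d", pep[hit], hit))
          }
        }
        if (length(pro) > 0) {
          ox <- pro[runif(length(pro)) < 0.1]
          if (length(ox) > 0) mods <- c(mods, sprintf("Oxidation(P)@%d", ox))
        }
        rows[[r]] <- tibble::tibble(
          sample = sample, peptide = peptides[i],
          modifications = paste(mods, collapse = ";"),
          confidence = runif(1, 80, 100)
        )
        r <- r + 1L
      }
    }
    list(
      psms = dplyr::bind_rows(rows),
      truth = tibble::tibble(
        peptide = peptides,
        has_nq = grepl("[NQ]", peptides),
        deamidated = truth_deam
      )
    )
  })
}

#' Simulate an extracted-ion chromatogram as a sum of Gaussian peaks
#'
#' Each requested peak is rendered as a Gaussian of the requested area
#' centred at its retention time; channels are sampled on a common,
#' strictly increasing time axis extending five widths beyond the outermost
#' peaks, so the numeric integral of every rendered peak matches the
#' requested area to well within 0.5 %.
#'
#' @param peaks data frame with columns `channel` (one of `"nondeamidated"`,
#'   `"deamidated"`), `rt` (min), `area` (a.u. x min) and `width` (Gaussian
#'   sigma, min, > 0). Zero rows give a flat zero trace.
#' @param sampling_step sampling interval, min.
#' @param peptide optional peptide sequence carried as an attribute (used by
#'   [decompose_xic()]'s isotope-ratio consistency check).
#' @return An `xic_trace`: tibble with `time`, `nondeamidated`,
#'   `deamidated`.
#' @export
sim_xic_trace <- function(peaks, sampling_step = 0.01, peptide = NULL) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) > 0) {
    assert_that(all(c("channel", "rt", "area", "width") %in% names(peaks)),
                "peaks needs columns channel, rt, area, width")
    assert_that(all(peaks$width > 0), "peak widths must be > 0")
    assert_that(all(peaks$channel %in% c("nondeamidated", "deamidated")),
                "channel must be 'nondeamidated' or 'deamidated'")
    t0 <- min(peaks$rt - 5 * peaks$width)
    t1 <- max(peaks$rt + 5 * peaks$width)
  } else {
    t0 <- 0; t1 <- 10
  }
  time <- seq(t0, t1, by = sampling_step)
  render <- function(chan) {
    y <- numeric(length(time))
    sub <- peaks[peaks$channel == chan, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      y <- y + sub$area[i] * dnorm(time, sub$rt[i], sub$width[i])
    }
    y
  }
  out <- tibble::tibble(
    time = time,
    nondeamidated = render("nondeamidated"),
    deamidated = render("deamidated")
  )
  attr(out, "peptide") <- peptide
  class(out) <- c("xic_trace", class(out))
  out
}
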