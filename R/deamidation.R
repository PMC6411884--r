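# Monoisotopic atomic masses (Da) and minor/major isotope abundance ratios.
.monoisotopic <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)
.c13_minus_c12 <- 13.0033548378 - 12
.m1_abundance_ratio <- c(C = 0.0107 / 0.9893, H = 0.000115 / 0.999885,
                         N = 0.00364 / 0.99636, O = 0.00038 / 0.99757,
                         S = 0.0075 / 0.9499)

# Elemental composition (C, H, N, O, S) of amino-acid residues
# (residue = amino acid - H2O).
.residue_formula <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)

#' Filter peptide-spectrum matches by identification confidence
#'
#' Removes PSMs whose confidence is below `min_confidence`; the boundary is
#' inclusive (a confidence of exactly the threshold is kept, since only
#' identifications *lower* than the threshold are rejected).
#'
#' @param psms data frame with at least a `confidence` column (percent).
#' @param min_confidence percent threshold (default 95).
#' @return The retained rows; the number removed is reported via `message()`.
#' @export
filter_psms <- function(psms, min_confidence = 95) {
  psms <- tibble::as_tibble(psms)
  if (nrow(psms) == 0) {
    warning("empty PSM table")
    return(psms)
  }
  assert_that("confidence" %in% names(psms), "psms needs a confidence column")
  assert_that(all(psms$confidence >= 0 & psms$confidence <= 100),
              "confidence must be in [0, 100]")
  keep <- psms$confidence >= min_confidence
  message(sprintf("filter_psms: removed %d of %d PSM(s) below %g%% confidence",
                  sum(!keep), nrow(psms), min_confidence))
  psms[keep, , drop = FALSE]
}

# Parse "Name(Residue)@index;..." into a data frame (name, index).
parse_modifications <- function(mod_string) {
  if (is.na(mod_string) || !nzchar(mod_string)) {
    return(data.frame(name = character(0), index = integer(0)))
  }
  parts <- strsplit(mod_string, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^(@]+)(?:\\(([A-Z])\\))?@(\\d+)$", parts))
  bad <- vapply(m, length, integer(1)) == 0
  assert_that(!any(bad),
              sprintf("unparseable modification(s): %s",
                      paste(parts[bad], collapse = ", ")))
  data.frame(
    name = vapply(m, `[`, character(1), 2),
    index = as.integer(vapply(m, `[`, character(1), 4))
  )
}

# TRUE when a PSM carries a deamidation on an N or Q residue of its peptide.
psm_is_deamidated <- function(peptide, mod_string) {
  mods <- parse_modifications(mod_string)
  if (nrow(mods) == 0) return(FALSE)
  deam <- grepl("deamid", mods$name, ignore.case = TRUE)
  if (!any(deam)) return(FALSE)
  idx <- mods$index[deam]
  assert_that(all(idx >= 1 & idx <= nchar(peptide)),
              "modification index outside peptide")
  any(substring(peptide, idx, idx) %in% c("N", "Q"))
}

#' Sequence-level deamidation rates
#'
#' For each group, the denominator is the number of *distinct* peptide
#' sequences containing at least one N or Q; the numerator is the number of
#' those sequences observed deamidated in at least one PSM — a sequence
#' counts as deamidated even if only a single one of its spectra carries the
#' modification. Sequences without N/Q cannot deamidate and are excluded
#' from the denominator entirely. Input should already be
#' confidence-filtered (see [filter_psms()]).
#'
#' @param psms data frame with `sample`, `peptide`, `modifications`; a
#'   `protein` column is required for `grouping = "sample_protein"`.
#' @param grouping `"sample"` (whole-sample rate) or `"sample_protein"`.
#' @return Tibble of class `deamidation_rates`: one row per group with
#'   `n_sequences_with_nq`, `n_deamidated` and `rate` (`NA` with a warning
#'   when a group has no N/Q-containing sequence).
#' @export
deamidation_rates <- function(psms, grouping = c("sample", "sample_protein")) {
  grouping <- match.arg(grouping)
  psms <- tibble::as_tibble(psms)
  assert_that(all(c("sample", "peptide", "modifications") %in% names(psms)),
              "psms needs columns sample, peptide, modifications")
  if (grouping == "sample_protein") {
    assert_that("protein" %in% names(psms),
                "grouping by protein needs a protein column")
  }
  keys <- if (grouping == "sample") "sample" else c("sample", "protein")
  psms$.deam <- mapply(psm_is_deamidated, psms$peptide, psms$modifications,
                       USE.NAMES = FALSE)
  psms$.has_nq <- grepl("[NQ]", psms$peptide)
  per_seq <- dplyr::summarise(
    dplyr::group_by(psms, dplyr::across(dplyr::all_of(c(keys, "peptide")))),
    has_nq = any(.data$.has_nq),
    deamidated = any(.data$.deam),
    .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_seq, dplyr::across(dplyr::all_of(keys))),
    n_sequences_with_nq = sum(.data$has_nq),
    n_deamidated = sum(.data$has_nq & .data$deamidated),
    .groups = "drop"
  )
  out$rate <- ifelse(out$n_sequences_with_nq > 0,
                     out$n_deamidated / out$n_sequences_with_nq, NA_real_)
  if (any(is.na(out$rate))) {
    warning("group(s) without N/Q-containing sequences: rate undefined")
  }
  class(out) <- c("deamidation_rates", class(out))
  out
}

#' Compare two deamidation rates with Fisher's exact test
#'
#' Builds the 2x2 table (deamidated, not deamidated) x (sample a, sample b)
#' from sequence counts and applies [fisher_exact_outcome()].
#'
#' @param a,b one-row slices of a [deamidation_rates()] result (or lists
#'   with `n_sequences_with_nq` and `n_deamidated`).
#' @return List with `p`, `odds_ratio` and the 2x2 `table`.
#' @export
compare_deamidation <- function(a, b) {
  geti <- function(x, f) as.integer(x[[f]][1])
  na <- geti(a, "n_sequences_with_nq"); ka <- geti(a, "n_deamidated")
  nb <- geti(b, "n_sequences_with_nq"); kb <- geti(b, "n_deamidated")
  assert_that(na > 0 && nb > 0, "zero denominator: rates are undefined")
  tab <- matrix(c(ka, na - ka, kb, nb - kb), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("deamidated", "not")))
  ft <- fisher_exact_outcome(tab)
  list(p = ft$p, odds_ratio = ft$odds_ratio, table = tab)
}

#' Deamidation mass shift vs the 13C isotopologue spacing
#'
#' Deamidation converts an amide side chain (N or Q) to the acid (D or E):
#' chemically NH2 is replaced by OH, a monoisotopic change of O - N - H =
#' +0.984 Da. That is nearly degenerate in m/z with the first 13C
#' isotopologue of the non-deamidated peptide (+1.0034 Da, printed +1.0);
#' the ~0.019 Da gap is below typical chromatographic-MS working resolution,
#' which is why the two forms must be separated by retention time rather
#' than by mass.
#'
#' @return Object of class `deamidation_shift` with `deamidation` (Da),
#'   `isotopologue` (Da) and `difference` (Da), all computed from
#'   monoisotopic atomic masses.
#' @export
deamidation_mass_shift <- function() {
  shift <- .monoisotopic[["O"]] - .monoisotopic[["N"]] - .monoisotopic[["H"]]
  structure(
    list(deamidation = shift,
         isotopologue = .c13_minus_c12,
         difference = .c13_minus_c12 - shift),
    class = "deamidation_shift"
  )
}

#' @export
print.deamidation_shift <- function(x, ...) {
  cat(sprintf("Deamidation (N->D / Q->E): %+.3f Da  (%.7f)\n",
              x$deamidation, x$deamidation))
  cat(sprintf("13C isotopologue spacing:  %+.1f Da    (%.7f)\n",
              x$isotopologue, x$isotopologue))
  cat(sprintf("Difference:                 %.4f Da\n", x$difference))
  invisible(x)
}

#' Approximate M+1/M isotopologue abundance ratio of a peptide
#'
#' First-order estimate from elemental composition: the probability of one
#' heavy substitution is close to the sum of (minor/major) abundance ratios
#' over all atoms (13C dominates for peptides). Used by [decompose_xic()] as
#' a consistency check on the fitted isotope-interference amplitude.
#'
#' @param peptide amino-acid sequence (standard one-letter codes).
#' @return Expected intensity ratio of the M+1 isotopologue to the
#'   monoisotopic peak.
#' @export
isotope_m1_ratio <- function(peptide) {
  res <- strsplit(toupper(peptide), "")[[1]]
  assert_that(all(res %in% names(.residue_formula)),
              "peptide contains non-standard residues")
  counts <- Reduce(`+`, .residue_formula[res])
  # terminal H2O: +2 H, +1 O
  counts[2] <- counts[2] + 2
  counts[4] <- counts[4] + 1
  names(counts) <- c("C", "H", "N", "O", "S")
  sum(counts * .m1_abundance_ratio[names(counts)])
}
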