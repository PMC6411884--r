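#' Run one analysis track end to end
#'
#' Orchestrates the package's tracks with config validation, per-stage
#' messages and a machine-readable JSON report. Every report embeds the
#' package version, the config echo, and the seed, so each number it
#' contains is regenerable from the config alone.
#'
#' Tracks and their config keys (flat named list; `output_dir` and `seed`
#' are common, paths must exist at run start):
#' \describe{
#'   \item{`simulate`}{writes one synthetic instance of every input class:
#'     a DDI cohort CSV, a PSM CSV, an XIC CSV, a reference FASTA and
#'     reads as both SAM and TSV. Keys: `seed`, `output_dir`.}
#'   \item{`ddi`}{`measurements` (CSV: group, embryo/id, gamma_signal,
#'     h2b_signal) or `stack` (TIFF from [write_stack_tiff()]);
#'     `reference_group`; optional `threshold` (default 2). Writes
#'     per-nucleus CSV and a JSON summary whose reference-group median DDI
#'     is 1 by construction.}
#'   \item{`deamidation`}{`psms` (CSV), optional `min_confidence`
#'     (default 95). Writes per-sample rate CSV + JSON.}
#'   \item{`xic`}{`trace` (CSV: time, nondeamidated, deamidated), optional
#'     `charge`. Writes the decomposition JSON.}
#'   \item{`adna`}{`reads` (SAM or TSV), `reference` (FASTA); optional
#'     `min_depth`, `min_alt`, `profile_k`. Writes damage-profile CSV,
#'     fragment-histogram CSV, SNV VCF and a JSON summary with the fitted
#'     decay model.}
#'   \item{`stats`}{`values` (CSV: group,value) with `reference_group`,
#'     and/or `counts` (CSV: group,success,failure); optional
#'     `n_permutations`. Steel test vs the reference plus normality /
#'     homoscedasticity checks; Fisher exact on the counts.}
#' }
#'
#' @param config named list; must contain `track`.
#' @return The report list, invisibly; the JSON is written to
#'   `<output_dir>/report.json`.
#' @export
run_track <- function(config) {
  assert_that(is.list(config) && !is.null(config$track),
              "config must be a named list with a 'track' entry")
  tracks <- c("simulate", "ddi", "deamidation", "xic", "adna", "stats")
  assert_that(config$track %in% tracks,
              sprintf("unknown track '%s'; expected one of %s", config$track,
                      paste(tracks, collapse = ", ")))
  out_dir <- config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  path_keys <- intersect(names(config),
                         c("measurements", "stack", "psms", "trace", "reads",
                           "reference", "values", "counts"))
  missing <- path_keys[!vapply(config[path_keys], file.exists, logical(1))]
  assert_that(length(missing) == 0,
              sprintf("config path(s) do not exist: %s",
                      paste(sprintf("%s=%s", missing, config[missing]),
                            collapse = ", ")))

  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", config$track, name))
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    message(sprintf("[%s] %s done (%.2f s)", config$track, name,
                    proc.time()[["elapsed"]] - t0))
    v
  }

  results <- switch(
    config$track,
    simulate = run_simulate_track(config, out_dir, seed, stage),
    ddi = run_ddi_track(config, out_dir, seed, stage),
    deamidation = run_deamidation_track(config, out_dir, stage),
    xic = run_xic_track(config, out_dir, stage),
    adna = run_adna_track(config, out_dir, stage),
    stats = run_stats_track(config, out_dir, seed, stage)
  )

  report <- list(
    package = "paleoQC",
    version = as.character(utils::packageVersion("paleoQC")),
    track = config$track,
    seed = seed,
    config = config[setdiff(names(config), "track")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    results = results
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

run_simulate_track <- function(config, out_dir, seed, stage) {
  cohort <- stage("ddi cohort", {
    spec <- cohort_spec(
      groups = list(
        fresh = list(n = 20, damage_mean = 1),
        frozen_thawed = list(n = 20, damage_mean = 2.5),
        dnase = list(n = 20, damage_mean = 4)
      ),
      reference_group = "fresh"
    )
    df <- sim_ddi_cohort(spec, seed = seed)
    write.csv(df, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    df
  })
  psm <- stage("psm table", {
    p <- sim_psm_table(seed = seed)
    write.csv(p$psms, file.path(out_dir, "psms.csv"), row.names = FALSE)
    p
  })
  stage("xic trace", {
    tr <- sim_xic_trace(data.frame(
      channel = c("nondeamidated", "deamidated", "deamidated"),
      rt = c(40, 40, 43), area = c(100, 30, 50), width = c(0.3, 0.3, 0.3)
    ), peptide = "GPAGPQGPR")
    write.csv(tr, file.path(out_dir, "xic.csv"), row.names = FALSE)
  })
  reads <- stage("ancient reads", {
    ref <- sim_reference(5000, seed = seed)
    rd <- sim_ancient_reads(ref, damage_sim_params(n_reads = 2000,
                                                   seed = seed))
    write_reference_fasta(ref, file.path(out_dir, "reference.fasta"))
    write_sam(rd$reads, nchar(ref), file.path(out_dir, "reads.sam"))
    write_reads_tsv(rd$reads, file.path(out_dir, "reads.tsv"))
    rd
  })
  list(
    n_embryos = nrow(cohort),
    n_psms = nrow(psm$psms),
    n_reads = nrow(reads$reads),
    files = c("cohort.csv", "psms.csv", "xic.csv", "reference.fasta",
              "reads.sam", "reads.tsv")
  )
}

run_ddi_track <- function(config, out_dir, seed, stage) {
  assert_that(!is.null(config$measurements) || !is.null(config$stack),
              "ddi track needs 'measurements' (CSV) or 'stack' (TIFF)")
  if (!is.null(config$stack)) {
    meas <- stage("segment + measure", {
      stk <- read_stack_tiff(config$stack)
      df <- measure_frame(stk, frame = 1,
                          min_volume = as.integer(config$min_volume %||% 30))
      df$group <- config$group %||% "stack"
      df
    })
    write.csv(meas, file.path(out_dir, "measurements.csv"),
              row.names = FALSE)
    if (is.null(config$reference_group)) {
      return(list(n_nuclei = nrow(meas),
                  note = "no reference_group given; signals only"))
    }
  } else {
    meas <- read.csv(config$measurements, stringsAsFactors = FALSE)
  }
  threshold <- as.numeric(config$threshold %||% 2)
  ddi <- stage("compute DDI", {
    compute_ddi(meas, reference_group = config$reference_group,
                threshold = threshold)
  })
  write.csv(ddi, file.path(out_dir, "ddi.csv"), row.names = FALSE)
  ref <- ddi$group == config$reference_group
  list(
    n_nuclei = nrow(ddi),
    reference_group = config$reference_group,
    reference_median_ddi = median(ddi$ddi[ref]),
    threshold = threshold,
    n_incompetent = sum(!ddi$competent),
    group_median_ddi = as.list(tapply(ddi$ddi, ddi$group, median))
  )
}

run_deamidation_track <- function(config, out_dir, stage) {
  assert_that(!is.null(config$psms), "deamidation track needs 'psms' (CSV)")
  min_conf <- as.numeric(config$min_confidence %||% 95)
  psms <- read.csv(config$psms, stringsAsFactors = FALSE)
  rates <- stage("filter + rate", {
    deamidation_rates(filter_psms(psms, min_confidence = min_conf))
  })
  write.csv(rates, file.path(out_dir, "deamidation_rates.csv"),
            row.names = FALSE)
  shift <- deamidation_mass_shift()
  list(
    min_confidence = min_conf,
    rates = lapply(seq_len(nrow(rates)), function(i) as.list(rates[i, ])),
    deamidation_shift_da = shift$deamidation,
    isotopologue_spacing_da = shift$isotopologue
  )
}

run_xic_track <- function(config, out_dir, stage) {
  assert_that(!is.null(config$trace), "xic track needs 'trace' (CSV)")
  trace <- tibble::as_tibble(read.csv(config$trace))
  dec <- stage("decompose", {
    decompose_xic(trace, charge = as.integer(config$charge %||% 2))
  })
  list(
    nondeam_area = dec$nondeam_area,
    interference_area = dec$interference_area,
    deamidated_area = dec$deamidated_area,
    deamidated_fraction = dec$deamidated_fraction,
    unresolved = dec$unresolved
  )
}

run_adna_track <- function(config, out_dir, stage) {
  assert_that(!is.null(config$reads) && !is.null(config$reference),
              "adna track needs 'reads' (SAM/TSV) and 'reference' (FASTA)")
  reference <- read_reference_fasta(config$reference)
  reads <- stage("read + filter", {
    raw <- if (grepl("\\.tsv$", config$reads, ignore.case = TRUE)) {
      read_reads_tsv(config$reads)
    } else {
      read_reads_sam(config$reads)
    }
    filter_reads(raw,
                 min_mean_quality = as.numeric(config$min_mean_quality %||% 20))
  })
  profile <- stage("damage profile", {
    terminal_damage_profile(reads, reference,
                            K = as.integer(config$profile_k %||% 25))
  })
  write.csv(profile, file.path(out_dir, "damage_profile.csv"),
            row.names = FALSE)
  fit <- fit_damage_model(profile)
  fld <- stage("fragment lengths", fragment_length_distribution(reads))
  write.csv(fld$histogram, file.path(out_dir, "fragment_lengths.csv"),
            row.names = FALSE)
  calls <- stage("pileup + SNVs", {
    pu <- build_pileup(reads, nchar(reference), reference = reference)
    call_snvs(pu, reference,
              min_depth = as.integer(config$min_depth %||% 3),
              min_alt = as.integer(config$min_alt %||% 2))
  })
  write_snv_vcf(calls, file.path(out_dir, "snvs.vcf"),
                chrom = reads$rname[1] %||% "ref")
  list(
    n_reads = nrow(reads),
    delta0_hat = fit$delta0_hat,
    decay_hat = fit$decay_hat,
    modal_fragment_length = fld$modal_length,
    nucleosome_peak = fld$nucleosome_peak,
    n_snvs = nrow(calls)
  )
}

run_stats_track <- function(config, out_dir, seed, stage) {
  assert_that(!is.null(config$values) || !is.null(config$counts),
              "stats track needs 'values' and/or 'counts' (CSV)")
  results <- list()
  if (!is.null(config$values)) {
    df <- read.csv(config$values, stringsAsFactors = FALSE)
    assert_that(all(c("group", "value") %in% names(df)),
                "values CSV needs columns group,value")
    ref <- config$reference_group %||% df$group[1]
    assert_that(ref %in% df$group,
                sprintf("reference group '%s' not in values", ref))
    groups <- split(df$value, df$group)
    st <- stage("steel test", {
      steel_test(groups[[ref]], groups[setdiff(names(groups), ref)],
                 n_permutations = as.integer(config$n_permutations %||% 10000),
                 seed = seed)
    })
    results$steel <- lapply(seq_len(nrow(st)), function(i) as.list(st[i, ]))
    results$normality <- lapply(groups, function(v) {
      if (length(v) >= 3 && diff(range(v)) > 0) check_normality(v) else NULL
    })
    if (length(groups) >= 2) {
      results$bartlett <- check_homoscedasticity(groups)
    }
  }
  if (!is.null(config$counts)) {
    ct <- read.csv(config$counts, stringsAsFactors = FALSE)
    assert_that(all(c("group", "success", "failure") %in% names(ct)) &&
                  nrow(ct) == 2, "counts CSV needs 2 rows of group,success,failure")
    results$fisher <- stage("fisher exact", {
      fisher_exact_outcome(as.matrix(ct[, c("success", "failure")]))
    })
  }
  results
}
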