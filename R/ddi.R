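#' Compute the DNA damage index (DDI)
#'
#' The DDI of a nucleus is its gamma-H2A.X/H2B signal ratio divided by the
#' median ratio of the reference group (undamaged control, e.g. fresh sperm),
#' so the reference group's median DDI is 1 by construction. The median is
#' the conventional interpolated one (mean of the central pair for even n);
#' normalization is re-applied until the reference median is exactly 1, which
#' removes the last-ulp floating-point drift a single division can leave.
#'
#' Rows with non-positive H2B signal cannot be normalized and are dropped
#' with a warning (a zero structural signal means the measurement failed, not
#' that damage is infinite).
#'
#' @param measurements data frame with at least `group`, `gamma_signal`,
#'   `h2b_signal`; any other columns (id, frame, time) are carried through.
#' @param reference_group name of the reference group in `group`.
#' @param threshold competence threshold on the DDI scale; nuclei with
#'   DDI strictly greater than `threshold` are classified incompetent
#'   (default 2, the level above which development usually fails).
#' @return Tibble of the surviving rows plus `raw_ratio`, `ddi`, `competent`.
#' @seealso [classify_competence()], [steel_test()]
#' @export
compute_ddi <- function(measurements, reference_group, threshold = 2) {
  measurements <- tibble::as_tibble(measurements)
  assert_that(all(c("group", "gamma_signal", "h2b_signal") %in%
                    names(measurements)),
              "measurements needs columns group, gamma_signal, h2b_signal")
  assert_that(reference_group %in% measurements$group,
              sprintf("reference group '%s' has no rows", reference_group))
  bad <- measurements$h2b_signal <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with non-positive H2B signal",
                    sum(bad)))
    measurements <- measurements[!bad, , drop = FALSE]
  }
  assert_that(any(measurements$group == reference_group),
              "reference group empty after H2B filtering")
  measurements$raw_ratio <- measurements$gamma_signal / measurements$h2b_signal
  ref <- measurements$group == reference_group
  ddi <- measurements$raw_ratio / median(measurements$raw_ratio[ref])
  # second-pass renormalization: guarantees median(ddi[ref]) == 1 exactly
  for (i in 1:4) {
    m <- median(ddi[ref])
    if (m == 1) break
    ddi <- ddi / m
  }
  measurements$ddi <- ddi
  measurements$competent <- classify_competence(ddi, threshold = threshold)
  measurements
}

#' Classify developmental competence from the DDI
#'
#' A nucleus is called incompetent when its DDI is strictly greater than the
#' threshold ("more than" 2 on the normalized scale); a DDI of exactly the
#' threshold is competent.
#'
#' @param ddi numeric vector of DDI values.
#' @param threshold unitless DDI threshold (default 2).
#' @return Logical vector, `TRUE` = competent.
#' @export
classify_competence <- function(ddi, threshold = 2) {
  assert_that(is.numeric(ddi) && all(ddi >= 0, na.rm = TRUE),
              "ddi must be non-negative numeric")
  ddi <= threshold
}

#' Per-nucleus DDI time courses
#'
#' Orders each nucleus's records by time and summarises the trajectory:
#' initial and final DDI, the change `delta = final - initial`, and a
#' "repair-consistent" flag for declining series (delta < 0), the signature
#' of double-strand-break repair after activation. Single-frame nuclei get
#' `delta = NA` and are flagged `single_frame`.
#'
#' @param records data frame with `nucleus`, `time` (numeric, hours or
#'   minutes from imaging start) and `ddi`.
#' @return List with `series` (records sorted within nucleus by time) and
#'   `summary` (one row per nucleus: `initial`, `final`, `delta`,
#'   `repair_consistent`, `single_frame`).
#' @export
ddi_timecourse <- function(records) {
  records <- tibble::as_tibble(records)
  assert_that(all(c("nucleus", "time", "ddi") %in% names(records)),
              "records needs columns nucleus, time, ddi")
  series <- dplyr::arrange(records, .data$nucleus, .data$time)
  summary <- dplyr::summarise(
    dplyr::group_by(series, .data$nucleus),
    n_frames = dplyr::n(),
    initial = dplyr::first(.data$ddi),
    final = dplyr::last(.data$ddi),
    .groups = "drop"
  )
  summary$single_frame <- summary$n_frames < 2L
  summary$delta <- ifelse(summary$single_frame, NA_real_,
                          summary$final - summary$initial)
  summary$repair_consistent <- !summary$single_frame & summary$delta < 0
  if (any(summary$single_frame)) {
    warning(sprintf("%d nucleus/nuclei observed in a single frame; delta undefined",
                    sum(summary$single_frame)))
  }
  list(series = series, summary = summary)
}

#' Link nuclei across frames by nearest centroid
#'
#' Greedy frame-to-frame assignment: each nucleus in frame t+1 is linked to
#' the nearest unclaimed track endpoint within `max_displacement`
#' (micrometres per frame); anything further starts a new track. Time-lapse
#' DDI series are then built per track.
#'
#' @param frames list of per-frame measurement tibbles (from
#'   [measure_frame()]), in temporal order; each must carry
#'   `centroid_z/y/x` in voxels.
#' @param voxel_size micrometres per voxel, (z, y, x).
#' @param max_displacement maximum centroid displacement per frame, um.
#' @return A single tibble with a `nucleus` track id and `frame` column.
#' @export
track_nuclei <- function(frames, voxel_size, max_displacement = 5) {
  assert_that(length(frames) >= 1, "need at least one frame")
  out <- vector("list", length(frames))
  f1 <- tibble::as_tibble(frames[[1]])
  f1$nucleus <- seq_len(nrow(f1))
  out[[1]] <- f1
  next_id <- nrow(f1) + 1L
  prev <- f1
  um <- function(df) cbind(df$centroid_z * voxel_size[1],
                           df$centroid_y * voxel_size[2],
                           df$centroid_x * voxel_size[3])
  for (t in seq_along(frames)[-1]) {
    cur <- tibble::as_tibble(frames[[t]])
    cur$nucleus <- NA_integer_
    if (nrow(cur) > 0 && nrow(prev) > 0) {
      pc <- um(prev); cc <- um(cur)
      dmat <- outer(seq_len(nrow(cur)), seq_len(nrow(prev)),
                    Vectorize(function(i, j) sqrt(sum((cc[i, ] - pc[j, ])^2))))
      repeat {
        best <- which(dmat == min(dmat), arr.ind = TRUE)[1, , drop = TRUE]
        if (dmat[best[1], best[2]] > max_displacement) break
        cur$nucleus[best[1]] <- prev$nucleus[best[2]]
        dmat[best[1], ] <- Inf
        dmat[, best[2]] <- Inf
        if (all(is.infinite(dmat))) break
      }
    }
    new <- is.na(cur$nucleus)
    if (any(new)) {
      cur$nucleus[new] <- seq.int(next_id, length.out = sum(new))
      next_id <- next_id + sum(new)
    }
    out[[t]] <- cur
    prev <- cur
  }
  for (t in seq_along(out)) out[[t]]$frame <- t
  dplyr::bind_rows(out)
}
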