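#' Segment nuclei in one frame of a two-channel 3D stack
#'
#' Thresholds the H2B (structural) channel with Otsu's method on the volume
#' histogram, labels 26-connected foreground components and discards
#' components smaller than `min_volume` voxels. Segmentation runs on the H2B
#' channel because that is the probe co-injected for normalization; the
#' damage channel is never used to find objects. The procedure is
#' deterministic and the returned masks are pairwise disjoint.
#'
#' @param stack an `image_stack` (see [sim_nucleus_stack()] or
#'   [read_stack_tiff()]).
#' @param frame time frame index (1-based).
#' @param min_volume minimum component volume in voxels.
#' @return An object of class `nucleus_masks`: list with `labels` (integer
#'   3D array, 0 = background), `masks` (list of integer voxel-index vectors),
#'   `volumes`, and `centroids` (matrix of voxel coordinates (z, y, x)).
#'   Zero masks with a warning when the frame is all-constant.
#' @export
segment_nuclei <- function(stack, frame = 1L, min_volume = 30L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  assert_that(frame >= 1 && frame <= d[1], "frame index out of range")
  vol <- array(stack$voxels[frame, stack$channel_map[["H2B"]], , , ], d[3:5])
  thr <- otsu_threshold(vol)
  empty <- function() {
    structure(list(labels = array(0L, dim(vol)), masks = list(),
                   volumes = integer(0),
                   centroids = matrix(numeric(0), ncol = 3,
                                      dimnames = list(NULL, c("z", "y", "x")))),
              class = "nucleus_masks")
  }
  if (is.na(thr)) {
    warning("frame is constant; no nuclei segmented")
    return(empty())
  }
  lab <- label_components_3d(vol > thr)
  if (max(lab) == 0L) return(empty())
  keep <- which(tabulate(lab[lab > 0L]) >= min_volume)
  if (length(keep) == 0L) return(empty())
  masks <- lapply(keep, function(k) which(lab == k))
  labels <- array(0L, dim(vol))
  for (i in seq_along(masks)) labels[masks[[i]]] <- i
  centroids <- t(vapply(masks, function(m) {
    colMeans(arrayInd(m, dim(vol)))
  }, numeric(3)))
  colnames(centroids) <- c("z", "y", "x")
  structure(list(labels = labels, masks = masks,
                 volumes = lengths(masks), centroids = centroids),
            class = "nucleus_masks")
}

# Most frequent binned intensity of a vector (256 bins); background fallback
# when a mask's shell is empty.
intensity_mode <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  b <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
  rng[1] + (which.max(tabulate(b, n_bins)) - 0.5) / n_bins * diff(rng)
}

#' Measure background-subtracted channel signals of one nucleus
#'
#' The local background per channel is the median voxel intensity in a shell
#' obtained by dilating the mask twice (26-neighbourhood) and removing the
#' mask itself and any voxel belonging to another segmented nucleus; a local
#' shell is robust against a bright neighbour (e.g. the recipient oocyte's
#' metaphase chromosomes sitting next to the injected nucleus). The signal is
#' the sum of (voxel - background) over the mask, clipped below at 0.
#'
#' @param stack an `image_stack`.
#' @param masks a `nucleus_masks` object from [segment_nuclei()].
#' @param which_mask index of the mask to measure.
#' @param frame time frame index.
#' @return One-row tibble: `label`, `frame`, `volume`, `h2b_signal`,
#'   `gamma_signal`, per-channel `*_background` (per voxel), and the voxel
#'   centroid.
#' @export
measure_nucleus_signal <- function(stack, masks, which_mask, frame = 1L) {
  stopifnot(inherits(stack, "image_stack"), inherits(masks, "nucleus_masks"))
  idx <- masks$masks[[which_mask]]
  assert_that(length(idx) > 0, "mask is empty")
  d3 <- dim(masks$labels)
  m <- array(FALSE, d3)
  m[idx] <- TRUE
  shell <- dilate_3d(m, steps = 2L) & !(masks$labels > 0L)
  shell_idx <- which(shell)

  one_channel <- function(channel) {
    vol <- array(stack$voxels[frame, channel, , , ], d3)
    if (length(shell_idx) > 0L) {
      bg <- median(vol[shell_idx])
    } else {
      warning("empty background shell; falling back to whole-frame mode")
      bg <- intensity_mode(as.numeric(vol))
    }
    c(signal = max(0, sum(vol[idx] - bg)), background = bg)
  }
  h2b <- one_channel(stack$channel_map[["H2B"]])
  gam <- one_channel(stack$channel_map[["gammaH2AX"]])
  ctr <- masks$centroids[which_mask, ]
  tibble::tibble(
    label = which_mask, frame = frame, volume = length(idx),
    h2b_signal = h2b[["signal"]], gamma_signal = gam[["signal"]],
    h2b_background = h2b[["background"]], gamma_background = gam[["background"]],
    centroid_z = ctr[["z"]], centroid_y = ctr[["y"]], centroid_x = ctr[["x"]]
  )
}

#' Segment and measure every nucleus in one frame
#'
#' Convenience wrapper: [segment_nuclei()] followed by
#' [measure_nucleus_signal()] for each accepted mask.
#'
#' @inheritParams segment_nuclei
#' @return Tibble with one row per nucleus (possibly zero rows).
#' @export
measure_frame <- function(stack, frame = 1L, min_volume = 30L) {
  masks <- segment_nuclei(stack, frame = frame, min_volume = min_volume)
  if (length(masks$masks) == 0L) {
    return(tibble::tibble(label = integer(), frame = integer(),
                          volume = integer(), h2b_signal = numeric(),
                          gamma_signal = numeric(), h2b_background = numeric(),
                          gamma_background = numeric(), centroid_z = numeric(),
                          centroid_y = numeric(), centroid_x = numeric()))
  }
  dplyr::bind_rows(lapply(seq_along(masks$masks), function(i) {
    measure_nucleus_signal(stack, masks, i, frame = frame)
  }))
}
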