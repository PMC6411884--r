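# Multi-page TIFF I/O for two-channel 3D+t stacks. Pages are written in
# ImageJ hyperstack order (channel fastest, then z, then t) as 32-bit float,
# with a JSON sidecar recording dimensions, channel map and voxel size; TIFF
# alone cannot carry the 5D layout unambiguously.

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)   # (t, ch, z, y, x)
  pages <- vector("list", d[1] * d[3] * d[2])
  i <- 1L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[3])) {
      for (ch in seq_len(d[2])) {
        pages[[i]] <- matrix(stack$voxels[t, ch, z, , ], d[4], d[5])
        i <- i + 1L
      }
    }
  }
  # r-tiff expects [0,1] unless writing float; normalize and record the scale
  peak <- max(1, max(stack$voxels))
  tiff::writeTIFF(lapply(pages, function(p) p / peak), path,
                  bits.per.sample = 32L)
  meta <- list(
    dim = as.integer(d), order = "tzcyx_pages_czt",
    channel_map = as.list(stack$channel_map),
    voxel_size_um = stack$voxel_size, intensity_scale = peak
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  assert_that(file.exists(meta_path),
              sprintf("missing sidecar %s; cannot recover 5D layout", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  voxels <- array(0, d)
  i <- 1L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[3])) {
      for (ch in seq_len(d[2])) {
        voxels[t, ch, z, , ] <- pages[[i]] * meta$intensity_scale
        i <- i + 1L
      }
    }
  }
  structure(
    list(voxels = voxels,
         channel_map = unlist(meta$channel_map),
         voxel_size = as.numeric(meta$voxel_size_um)),
    class = "image_stack"
  )
}
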