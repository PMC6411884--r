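#' Parameters for the synthetic two-channel nucleus stack generator
#'
#' Describes a 3D+time two-channel acquisition of fluorescently labelled
#' nuclei: histone H2B (structural channel, used for segmentation) and
#' gamma-H2A.X (DNA double-strand-break channel). Each nucleus is rendered as
#' a uniform sphere, blurred by an isotropic Gaussian PSF, on a constant
#' background with additive Gaussian read noise.
#'
#' @param grid_shape integer(3), voxels as (z, y, x).
#' @param voxel_size numeric(3), micrometres per voxel along (z, y, x). The
#'   default 2 um z-spacing mirrors typical spinning-disk confocal stacks of
#'   oocytes; lateral sampling is finer.
#' @param n_frames number of time frames (nuclei are static; noise is drawn
#'   independently per frame).
#' @param nuclei list of nuclei, each a list with elements `centroid`
#'   (numeric(3), um, (z, y, x)), `radius` (um, > 0), `h2b_brightness`
#'   (a.u. per voxel, >= 0) and `damage_level` (unitless, >= 0).
#' @param gamma_per_damage gamma-H2A.X brightness (a.u. per voxel) contributed
#'   per unit of `damage_level`.
#' @param background constant background level, a.u.
#' @param noise_sd standard deviation of the additive Gaussian noise, a.u.
#' @param psf_sigma Gaussian PSF sigma in voxels (scalar or per-axis).
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#'
#' @return An object of class `image_sim_params`.
#' @seealso [sim_nucleus_stack()]
#' @export
image_sim_params <- function(grid_shape = c(24L, 64L, 64L),
                             voxel_size = c(2, 0.5, 0.5),
                             n_frames = 1L,
                             nuclei = list(),
                             gamma_per_damage = 40,
                             background = 10,
                             noise_sd = 2,
                             psf_sigma = 1,
                             seed = 1L) {
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 4),
              "grid_shape must be three voxel counts >= 4")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "voxel_size must be three positive lengths (um)")
  assert_that(n_frames >= 1, "n_frames must be >= 1")
  assert_that(background >= 0 && noise_sd >= 0 && gamma_per_damage >= 0,
              "background, noise_sd and gamma_per_damage must be >= 0")
  for (nuc in nuclei) {
    assert_that(all(c("centroid", "radius", "h2b_brightness", "damage_level")
                    %in% names(nuc)),
                "each nucleus needs centroid, radius, h2b_brightness, damage_level")
    assert_that(nuc$radius > 0, "nucleus radii must be > 0")
    assert_that(nuc$h2b_brightness >= 0 && nuc$damage_level >= 0,
                "brightness and damage_level must be >= 0")
  }
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         n_frames = as.integer(n_frames), nuclei = nuclei,
         gamma_per_damage = gamma_per_damage, background = background,
         noise_sd = noise_sd, psf_sigma = psf_sigma, seed = as.integer(seed)),
    class = "image_sim_params"
  )
}

#' Simulate a two-channel 3D+t nucleus stack with known ground truth
#'
#' Renders each nucleus of `params` as a Gaussian-blurred sphere in both
#' channels: the H2B channel at `h2b_brightness`, the gamma-H2A.X channel at
#' `gamma_per_damage * damage_level`. Noise is additive Gaussian only, so the
#' noise-free integrated signal of every nucleus is known exactly and returned
#' as the truth table. Nuclei whose sphere plus PSF support would cross the
#' image boundary are rejected, which keeps the truth integrals exact (no
#' blur mass is lost at the edges).
#'
#' @param params an [image_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{stack}{an `image_stack`: 5D voxel array (t, channel, z, y, x)
#'       with `channel_map = c(H2B = 1, gammaH2AX = 2)` and `voxel_size`.}
#'     \item{truth}{tibble with one row per nucleus: `nucleus`, voxel-grid
#'       centroid, `n_voxels`, exact noise-free `h2b_integral` and
#'       `gamma_integral`, `damage_level` and the true `ratio`
#'       (gamma/H2B integral; 0 when damage is 0).}
#'   }
#' @export
sim_nucleus_stack <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  d <- params$grid_shape
  vs <- params$voxel_size
  psf <- rep(params$psf_sigma, length.out = 3)
  blur_pad <- ceiling(3 * psf)

  h2b_field <- array(0, d)
  gamma_field <- array(0, d)
  truth <- vector("list", length(params$nuclei))

  # voxel-centre coordinates in um along each axis
  zc <- (seq_len(d[1]) - 0.5) * vs[1]
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  xc <- (seq_len(d[3]) - 0.5) * vs[3]

  for (i in seq_along(params$nuclei)) {
    nuc <- params$nuclei[[i]]
    ctr <- nuc$centroid
    r <- nuc$radius
    # reject spheres whose rendered support + blur support leaves the grid
    lo_vox <- (ctr - r) / vs - blur_pad
    hi_vox <- (ctr + r) / vs + blur_pad
    if (any(lo_vox < 0) || any(hi_vox > d)) {
      stop(sprintf(paste0(
        "nucleus %d (centroid %s um, radius %g um) overlaps the image ",
        "boundary once PSF support is included; enlarge the grid or move ",
        "the nucleus"), i, paste(signif(ctr, 4), collapse = ","), r),
        call. = FALSE)
    }
    dz2 <- ((zc - ctr[1]) / r)^2
    dy2 <- ((yc - ctr[2]) / r)^2
    dx2 <- ((xc - ctr[3]) / r)^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
    n_vox <- sum(inside)
    h2b_field[inside] <- h2b_field[inside] + nuc$h2b_brightness
    gb <- params$gamma_per_damage * nuc$damage_level
    gamma_field[inside] <- gamma_field[inside] + gb
    truth[[i]] <- tibble::tibble(
      nucleus = i,
      centroid_z = ctr[1] / vs[1], centroid_y = ctr[2] / vs[2],
      centroid_x = ctr[3] / vs[3],
      n_voxels = n_vox,
      h2b_integral = nuc$h2b_brightness * n_vox,
      gamma_integral = gb * n_vox,
      damage_level = nuc$damage_level,
      ratio = if (nuc$h2b_brightness > 0) gb / nuc$h2b_brightness else NA_real_
    )
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(nucleus = integer(), centroid_z = numeric(),
                   centroid_y = numeric(), centroid_x = numeric(),
                   n_voxels = integer(), h2b_integral = numeric(),
                   gamma_integral = numeric(), damage_level = numeric(),
                   ratio = numeric())

  h2b_blur <- gaussian_blur_3d(h2b_field, psf)
  gamma_blur <- gaussian_blur_3d(gamma_field, psf)

  voxels <- array(0, c(params$n_frames, 2L, d))
  withr::with_seed(params$seed, {
    for (t in seq_len(params$n_frames)) {
      voxels[t, 1, , , ] <- pmax(0, h2b_blur + params$background +
                                   rnorm(prod(d), 0, params$noise_sd))
      voxels[t, 2, , , ] <- pmax(0, gamma_blur + params$background +
                                   rnorm(prod(d), 0, params$noise_sd))
    }
  })

  stack <- structure(
    list(voxels = voxels,
         channel_map = c(H2B = 1L, gammaH2AX = 2L),
         voxel_size = vs),
    class = "image_stack"
  )
  list(stack = stack, truth = truth)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d frame(s), channels {%s}, %d x %d x %d voxels (z,y,x), voxel %s um\n",
              d[1], paste(names(x$channel_map), collapse = ", "),
              d[3], d[4], d[5],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}
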