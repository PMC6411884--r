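# Low-level 3D image primitives: separable Gaussian blur, Otsu threshold,
# binary dilation and 26-connected component labelling. Arrays are indexed
# (z, y, x); intensities are arbitrary units.

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Zero-padded separable convolution along one axis. Mass is conserved for
# structures whose kernel support lies inside the grid.
convolve_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(a, perm), nrow = n)
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    dest <- seq_len(n)
    src <- dest + off
    ok <- src >= 1L & src <= n
    out[dest[ok], ] <- out[dest[ok], ] + kernel[j] * m[src[ok], ]
  }
  aperm(array(out, d[perm]), order(perm))
}

gaussian_blur_3d <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) a <- convolve_axis(a, gaussian_kernel_1d(sigma[ax]), ax)
  a
}

# Otsu's threshold on the full volume histogram (maximize between-class
# variance over 256 bins).
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  h <- tabulate(
    pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
    nbins = n_bins
  )
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b2)]
}

# Linear indices of the 26-neighbourhood (or the 13 "positive" half used to
# build an undirected adjacency exactly once per pair).
neighbour_offsets <- function(half = TRUE) {
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  if (half) {
    keep <- off$dx > 0 | (off$dx == 0 & off$dy > 0) |
      (off$dx == 0 & off$dy == 0 & off$dz > 0)
    off <- off[keep, ]
  }
  off
}

# Label 26-connected foreground components of a logical 3D array.
# Returns an integer array, 0 = background, deterministic labelling in
# order of first (column-major) foreground voxel.
label_components_3d <- function(fg) {
  d <- dim(fg)
  idx <- which(fg)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  coord <- arrayInd(idx, d)
  ord <- integer(prod(d))
  ord[idx] <- seq_along(idx)
  off <- neighbour_offsets(half = TRUE)
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (i in seq_len(nrow(off))) {
    nz <- coord[, 1] + off$dz[i]
    ny <- coord[, 2] + off$dy[i]
    nx <- coord[, 3] + off$dx[i]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] & nx >= 1L & nx <= d[3]
    if (!any(ok)) next
    nidx <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
    hit <- fg[nidx]
    if (!any(hit)) next
    edges_from <- c(edges_from, ord[idx[ok][hit]])
    edges_to <- c(edges_to, ord[nidx[hit]])
  }
  g <- igraph::make_graph(rbind(edges_from, edges_to),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel so component ids follow first appearance in column-major order
  first <- match(unique(comp), comp)
  relab <- integer(max(comp))
  relab[comp[sort(first)]] <- seq_along(first)
  lab[idx] <- relab[comp]
  lab
}

# One-step 26-neighbourhood binary dilation, repeated `steps` times.
dilate_3d <- function(mask, steps = 1L) {
  d <- dim(mask)
  off <- neighbour_offsets(half = FALSE)
  for (s in seq_len(steps)) {
    idx <- which(mask)
    if (length(idx) == 0L) return(mask)
    coord <- arrayInd(idx, d)
    out <- mask
    for (i in seq_len(nrow(off))) {
      nz <- coord[, 1] + off$dz[i]
      ny <- coord[, 2] + off$dy[i]
      nx <- coord[, 3] + off$dx[i]
      ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] & nx >= 1L & nx <= d[3]
      out[nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]] <- TRUE
    }
    mask <- out
  }
  mask
}
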