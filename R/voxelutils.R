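# Voxel-level helpers shared by the atlas builder and the tracer.

#' Otsu's global threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the
#' intensity range. Returns a threshold value; foreground is `> threshold`.
#'
#' @param x numeric vector or array of intensities.
#' @param nbins histogram resolution.
#' @return scalar threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * nbins) + 1L, 1L),
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

#' Connected components of a binary stack
#'
#' Deterministic scan-order labelling at 6 or 26 connectivity.
#'
#' @param mask logical 3D array (or `image_stack` of 0/1).
#' @param connectivity 6 or 26.
#' @return integer array of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (inherits(mask, "image_stack")) mask <- mask$voxels != 0
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  lab <- cpp_label_components(as.logical(mask), dim(mask), as.integer(connectivity))
  array(lab, dim = dim(mask))
}

#' Keep only the largest connected component
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return logical array.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim = dim(mask)))
  if (max(lab) == 1L) return(lab == 1L)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Fill interior holes of a 3D mask
#'
#' Background components (6-connected) not touching the volume border are
#' interior cavities and are filled.
#'
#' @param mask logical 3D array.
#' @return logical array with cavities filled.
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  bg_lab <- label_components(!mask, connectivity = 6L)
  border <- unique(c(bg_lab[c(1, d[1]), , ], bg_lab[, c(1, d[2]), ],
                     bg_lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  mask | !(bg_lab %in% c(0L, border))
}

#' Euclidean distance transform (anisotropic)
#'
#' Physical distance (um) from each foreground voxel centre to the nearest
#' background voxel centre, by the exact separable parabola method.
#'
#' @param mask logical 3D array.
#' @param spacing `(dz, dy, dx)` um.
#' @return numeric array of distances (0 on background).
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  array(cpp_edt3d(as.logical(mask), dim(mask), as.numeric(spacing)),
        dim = dim(mask))
}

#' Separable Gaussian blur of a 3D array
#'
#' Sigma is given in physical um per axis (scalar recycled); kernels are
#' truncated at 3 sigma and renormalized at the borders (nearest-neighbour
#' edge handling via shift-and-add with clamped indices).
#'
#' @param x 3D numeric array.
#' @param sigma um, scalar or `(z, y, x)`.
#' @param spacing `(dz, dy, dx)` um.
#' @return blurred array.
#' @export
gaussian_blur3d <- function(x, sigma, spacing = c(1, 1, 1)) {
  sigma <- rep(as.numeric(sigma), length.out = 3)
  d <- dim(x)
  for (ax in 1:3) {
    s_vox <- sigma[ax] / spacing[ax]
    if (s_vox <= 0) next
    half <- max(1L, ceiling(3 * s_vox))
    w <- stats::dnorm(-half:half, sd = s_vox)
    w <- w / sum(w)
    acc <- array(0, dim = d)
    n <- d[ax]
    for (o in -half:half) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- switch(ax,
                        x[idx, , , drop = FALSE],
                        x[, idx, , drop = FALSE],
                        x[, , idx, drop = FALSE])
      acc <- acc + w[o + half + 1L] * shifted
    }
    x <- acc
  }
  x
}

#' Dice overlap coefficient of two masks
#' @param a,b logical arrays of equal dimension.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "image_stack")) a <- a$voxels != 0
  if (inherits(b, "image_stack")) b <- b$voxels != 0
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
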