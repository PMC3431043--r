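#' Landmark-based spatial transforms
#'
#' Three transform families cover the registration pipeline: rigid
#' (rotation + translation, no scaling -- size and shape are preserved, as
#' required when pooling individual brains into an average), affine (full
#' 12-parameter linear map) and 3D thin-plate spline (TPS; affine part plus
#' a radial warp that interpolates the landmarks exactly at `lambda = 0`).
#'
#' `fit_rigid` solves the orthogonal Procrustes problem by SVD with
#' reflections excluded (`det(R) = +1` always); a mirror image is never
#' produced silently -- use [mirror] explicitly for hemisphere flipping.
#'
#' The 3D TPS uses the biharmonic kernel `U(r) = r`, the Green's function
#' of the biharmonic operator in three dimensions (`r^2 log r` is the 2D
#' kernel). The fitted map is `f(x) = A [1; x] + sum_i w_i U(|x - s_i|)`
#' with side conditions `sum w_i = 0` and `S^T W = 0`, solved per output
#' coordinate from the standard bordered linear system; `lambda >= 0` on
#' the kernel diagonal trades interpolation for smoothness.
#'
#' @param src,dst `landmark_set` objects (paired by name, case-insensitive)
#'   or n x 3 coordinate matrices paired by row.
#' @param lambda TPS regularization (um units of the kernel); 0 interpolates.
#' @return a transform object of class `rigid_transform`,
#'   `affine_transform` or `tps_transform`.
#' @name transforms
NULL

as_pairs <- function(src, dst, min_pairs) {
  if (inherits(src, "landmark_set") && inherits(dst, "landmark_set"))
    return(pair_landmarks(src, dst, min_pairs = min_pairs))
  src <- rbind_matrix3(src)
  dst <- rbind_matrix3(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must have equal point counts")
  if (nrow(src) < min_pairs) stop("need at least ", min_pairs, " point pairs")
  list(names = NULL, src = src, dst = dst)
}

rank3_check <- function(X, what, need_rank) {
  Xc <- sweep(X, 2, colMeans(X))
  r <- qr(Xc, tol = 1e-10)$rank
  if (r < need_rank)
    stop("degenerate landmark geometry for ", what, ": points are ",
         if (need_rank == 2) "collinear" else "coplanar")
}

#' @rdname transforms
#' @export
fit_rigid <- function(src, dst) {
  p <- as_pairs(src, dst, 3L)
  rank3_check(p$src, "a rigid fit", 2L)
  ms <- colMeans(p$src)
  md <- colMeans(p$dst)
  H <- crossprod(sweep(p$src, 2, ms), sweep(p$dst, 2, md))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- as.numeric(md - R %*% ms)
  structure(list(rotation = R, translation = t_), class = "rigid_transform")
}

#' @rdname transforms
#' @export
fit_affine <- function(src, dst) {
  p <- as_pairs(src, dst, 4L)
  rank3_check(p$src, "an affine fit", 3L)
  X <- cbind(1, p$src)
  B <- qr.solve(X, p$dst)   # least squares, 4 x 3
  structure(list(matrix = unname(t(B[2:4, , drop = FALSE])),
                 translation = as.numeric(B[1, ])),
            class = "affine_transform")
}

tps_kernel <- function(r) r  # 3D biharmonic kernel U(r) = r

#' @rdname transforms
#' @export
fit_tps <- function(src, dst, lambda = 0) {
  p <- as_pairs(src, dst, 4L)
  if (lambda < 0) stop("lambda must be >= 0")
  rank3_check(p$src, "a thin-plate-spline fit", 3L)
  n <- nrow(p$src)
  K <- tps_kernel(as.matrix(stats::dist(p$src, diag = TRUE, upper = TRUE)))
  diag(K) <- diag(K) + lambda
  P <- cbind(1, p$src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(p$dst, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular thin-plate-spline system (near-degenerate landmark geometry): ",
         conditionMessage(e)))
  # one step of iterative refinement: the bordered system is often
  # ill-conditioned enough to cost ~1e-6 um at the landmarks without it
  sol <- sol + solve(L, rhs - L %*% sol)
  structure(list(source_landmarks = p$src, dest_landmarks = p$dst,
                 warp = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:4, , drop = FALSE],
                 lambda = lambda),
            class = "tps_transform")
}

#' Identity transform
#' @return a `rigid_transform` that maps every point to itself.
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0)),
            class = "rigid_transform")
}

#' Apply a transform to 3D points
#'
#' @param transform a fitted transform object.
#' @param points n x 3 matrix of `(x, y, z)` um.
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_points <- function(transform, points) UseMethod("apply_points")

#' @export
apply_points.rigid_transform <- function(transform, points) {
  points <- rbind_matrix3(points)
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

#' @export
apply_points.affine_transform <- function(transform, points) {
  points <- rbind_matrix3(points)
  sweep(points %*% t(transform$matrix), 2, -transform$translation)
}

#' @export
apply_points.tps_transform <- function(transform, points) {
  points <- rbind_matrix3(points)
  S <- transform$source_landmarks
  # distances by direct differencing: the |p|^2 + |s|^2 - 2 p.s identity
  # cancels catastrophically near r = 0, exactly where the kernel matters
  U <- matrix(0, nrow(points), nrow(S))
  for (i in seq_len(nrow(S)))
    U[, i] <- sqrt((points[, 1] - S[i, 1])^2 + (points[, 2] - S[i, 2])^2 +
                   (points[, 3] - S[i, 3])^2)
  cbind(1, points) %*% transform$affine + tps_kernel(U) %*% transform$warp
}

#' Invert a transform
#'
#' Rigid and affine transforms invert analytically. A TPS has no analytic
#' inverse; the returned transform is a TPS refitted with source and
#' destination landmarks exchanged -- exact at the landmarks, approximate
#' elsewhere, which is the standard device for inverse-direction image
#' resampling.
#'
#' @param transform a fitted transform object.
#' @return a transform of the same family mapping in the opposite direction.
#' @export
invert_transform <- function(transform) UseMethod("invert_transform")

#' @export
invert_transform.rigid_transform <- function(transform) {
  Rt <- t(transform$rotation)
  structure(list(rotation = Rt,
                 translation = as.numeric(-Rt %*% transform$translation)),
            class = "rigid_transform")
}

#' @export
invert_transform.affine_transform <- function(transform) {
  if (abs(det(transform$matrix)) < 1e-12)
    stop("affine transform is not invertible")
  Mi <- solve(transform$matrix)
  structure(list(matrix = Mi,
                 translation = as.numeric(-Mi %*% transform$translation)),
            class = "affine_transform")
}

#' @export
invert_transform.tps_transform <- function(transform) {
  fit_tps(transform$dest_landmarks, transform$source_landmarks,
          lambda = transform$lambda)
}

#' Transform a morphology's coordinates
#'
#' Maps every node position; node ids, types and parent topology are
#' untouched. Radii are left unchanged (`radius_policy = "fixed"`, the
#' default, matching a registration that transforms SWC geometry only) or
#' scaled by `|det J(x)|^(1/3)` of the local transform Jacobian estimated
#' by central differences (`"local_scale"`).
#'
#' @param transform a fitted transform.
#' @param m a `morphology`.
#' @param radius_policy `"fixed"` or `"local_scale"`.
#' @param h central-difference step (um) for the local Jacobian.
#' @return the transformed `morphology`.
#' @export
apply_morphology <- function(transform, m, radius_policy = c("fixed", "local_scale"),
                             h = 1e-3) {
  radius_policy <- match.arg(radius_policy)
  m <- validate_morphology(m)
  xyz <- morph_xyz(m)
  new_xyz <- apply_points(transform, xyz)
  if (any(!is.finite(new_xyz)))
    stop("transform maps ", sum(!is.finite(rowSums(new_xyz))),
         " node(s) to non-finite coordinates")
  out <- m
  out$nodes$x <- new_xyz[, 1]
  out$nodes$y <- new_xyz[, 2]
  out$nodes$z <- new_xyz[, 3]
  if (radius_policy == "local_scale") {
    n <- nrow(xyz)
    probes <- xyz[rep(seq_len(n), each = 6), ]
    step <- rbind(c(h, 0, 0), c(-h, 0, 0), c(0, h, 0),
                  c(0, -h, 0), c(0, 0, h), c(0, 0, -h))
    probes <- probes + step[rep(1:6, times = n), ]
    mapped <- apply_points(transform, probes)
    detj <- numeric(n)
    for (i in seq_len(n)) {
      b <- (i - 1) * 6
      J <- cbind(mapped[b + 1, ] - mapped[b + 2, ],
                 mapped[b + 3, ] - mapped[b + 4, ],
                 mapped[b + 5, ] - mapped[b + 6, ]) / (2 * h)
      detj[i] <- abs(det(J))
    }
    out$nodes$radius <- m$nodes$radius * detj^(1 / 3)
  }
  validate_morphology(out)
}

#' Transform a landmark set
#' @param transform a fitted transform.
#' @param lm a `landmark_set`.
#' @return the mapped `landmark_set`.
#' @export
apply_landmarks <- function(transform, lm) {
  stopifnot(inherits(lm, "landmark_set"))
  xyz <- apply_points(transform, landmark_xyz(lm))
  landmark_set(lm$name, xyz[, 1], xyz[, 2], xyz[, 3])
}

#' Resample an image stack through a transform
#'
#' Warps `stack` into the geometry of `reference` under `transform`
#' (a map from stack coordinates to reference coordinates). Implemented by
#' inverse-direction lookup: each output voxel centre is pulled back through
#' the inverse transform and sampled trilinearly; out-of-field voxels are 0.
#' For a TPS the inverse is the swapped-landmark refit (see
#' [invert_transform]).
#'
#' @param transform map from `stack` physical coordinates to `reference`
#'   physical coordinates.
#' @param stack the moving `image_stack`.
#' @param reference an `image_stack` (its voxels are ignored) or a list with
#'   `shape`, `spacing`, `origin` defining the output geometry.
#' @return an `image_stack` in the reference geometry.
#' @export
resample_image <- function(transform, stack, reference) {
  stopifnot_stack(stack)
  if (inherits(reference, "image_stack")) {
    shape <- dim(reference$voxels)
    spacing <- reference$spacing
    origin <- reference$origin
  } else if (is.list(reference) &&
             all(c("shape", "spacing", "origin") %in% names(reference))) {
    shape <- as.integer(reference$shape)
    spacing <- as.numeric(reference$spacing)
    origin <- as.numeric(reference$origin)
  } else {
    stop("reference must be an image_stack or a list(shape, spacing, origin)")
  }
  inv <- invert_transform(transform)
  out_geom <- image_stack(array(0, dim = shape), spacing = spacing, origin = origin)
  # physical (x,y,z) centres of all output voxels, z fastest (array order)
  k <- seq_len(shape[1]); j <- seq_len(shape[2]); i <- seq_len(shape[3])
  zz <- origin[1] + (k - 1) * spacing[1]
  yy <- origin[2] + (j - 1) * spacing[2]
  xx <- origin[3] + (i - 1) * spacing[3]
  pts <- cbind(rep(xx, each = shape[1] * shape[2]),
               rep(rep(yy, each = shape[1]), times = shape[3]),
               rep(zz, times = shape[2] * shape[3]))
  src_pts <- apply_points(inv, pts)
  vals <- interp_stack(stack, src_pts, fill = 0)
  out_geom$voxels <- array(vals, dim = shape)
  out_geom
}

#' Mirror an object about a volume midplane
#'
#' Reflects an image stack, morphology or landmark set about the midplane
#' orthogonal to `axis`. For a stack the midplane is its own physical
#' mid-extent; for point-based objects the reflection plane is derived from
#' `extent` (a `c(lo, hi)` physical range on that axis, or a reference
#' `image_stack`). Reflection is an isometry: cable lengths and pairwise
#' distances are preserved. With `rename_lr = TRUE` landmark names have a
#' leading `R`/`L` swapped (RMC <-> LMC), which is what makes a mirrored
#' left hemisphere alignable to a right-hemisphere reference by name.
#'
#' @param obj `image_stack`, `morphology` or `landmark_set`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param extent numeric `c(lo, hi)` um on `axis`, or an `image_stack` whose
#'   extent to use. Ignored for stacks.
#' @param rename_lr swap leading L/R in landmark names (landmark sets only).
#' @return the mirrored object, same class.
#' @export
mirror <- function(obj, axis = "x", extent = NULL, rename_lr = FALSE)
  UseMethod("mirror")

axis_index <- function(axis) match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))

mirror_center <- function(axis, extent) {
  if (inherits(extent, "image_stack")) {
    ext <- stack_extent(extent)
    return(mean(ext[, axis_index(axis)]))
  }
  if (is.numeric(extent) && length(extent) == 2L) return(mean(extent))
  if (is.numeric(extent) && length(extent) == 1L) return(extent)
  stop("extent must be c(lo, hi) on the mirror axis, a midplane coordinate, ",
       "or a reference image_stack")
}

#' @export
mirror.image_stack <- function(obj, axis = "x", extent = NULL, rename_lr = FALSE) {
  ai <- axis_index(axis)          # x,y,z -> array dims 3,2,1
  dimi <- c(3, 2, 1)[ai]
  idx <- rev(seq_len(dim(obj$voxels)[dimi]))
  obj$voxels <- switch(dimi,
                       obj$voxels[idx, , , drop = FALSE],
                       obj$voxels[, idx, , drop = FALSE],
                       obj$voxels[, , idx, drop = FALSE])
  obj
}

#' @export
mirror.morphology <- function(obj, axis = "x", extent = NULL, rename_lr = FALSE) {
  cc <- mirror_center(axis, extent)
  col <- c("x", "y", "z")[axis_index(axis)]
  obj$nodes[[col]] <- 2 * cc - obj$nodes[[col]]
  obj
}

#' @export
mirror.landmark_set <- function(obj, axis = "x", extent = NULL, rename_lr = FALSE) {
  cc <- mirror_center(axis, extent)
  col <- c("x", "y", "z")[axis_index(axis)]
  vals <- obj[[col]]
  nm <- obj$name
  if (rename_lr) {
    first <- substr(nm, 1, 1)
    swapped <- ifelse(toupper(first) == "L", "R",
                      ifelse(toupper(first) == "R", "L", first))
    nm <- paste0(swapped, substring(nm, 2))
  }
  out <- landmark_set(nm, obj$x, obj$y, obj$z)
  out[[col]] <- 2 * cc - vals
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform (rotation + translation, det(R) = +1)\n")
  cat("  translation:", sprintf("%.4g", x$translation), "um\n")
  invisible(x)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("affine_transform, det = %.6g\n", det(x$matrix)))
  invisible(x)
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("tps_transform: %d landmarks, lambda = %g, |warp| = %.3g\n",
              nrow(x$source_landmarks), x$lambda,
              sqrt(sum(x$warp^2))))
  invisible(x)
}
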