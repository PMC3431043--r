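#' Standard-brain (atlas) construction
#'
#' The averaging scheme treats the two hemispheres of each individual as
#' independent samples under a bilateral-symmetry assumption: left
#' hemispheres are mirrored about the sagittal (x) midplane, every stack is
#' rigidly aligned (rotation + translation only -- size and shape are never
#' rescaled) to a designated reference via five named landmarks (CCB, RMC,
#' LMC and the two antennal-lobe centres in the original workflow), the
#' aligned stacks are averaged voxelwise, and the average is binarized and
#' surfaced to give the standard outline.
#'
#' @name atlas
NULL

#' Re-anchor the brain coordinate origin
#'
#' Moves the stack origin so that a chosen in-plane point of a chosen slice
#' -- conventionally the centre of the esophageal foramen in the slice with
#' the largest brain outline (the "middle slice") -- becomes `(0, 0, 0)`.
#'
#' @param stack an `image_stack`.
#' @param esophagus_center `(x, y)` um of the anchor point (in current
#'   physical coordinates).
#' @param middle_slice_index 1-based z-slice index.
#' @return the stack with a shifted origin (voxels untouched).
#' @export
set_brain_origin <- function(stack, esophagus_center, middle_slice_index) {
  stopifnot_stack(stack)
  d <- dim(stack$voxels)
  if (middle_slice_index < 1 || middle_slice_index > d[1])
    stop("middle_slice_index outside 1..", d[1])
  z0 <- stack$origin[1] + (middle_slice_index - 1) * stack$spacing[1]
  ext <- stack_extent(stack)
  if (esophagus_center[1] < ext["min", 1] || esophagus_center[1] > ext["max", 1] ||
      esophagus_center[2] < ext["min", 2] || esophagus_center[2] > ext["max", 2])
    stop("esophagus_center lies outside the imaged field")
  # origin stored (z, y, x); subtract the anchor's physical position
  stack$origin <- stack$origin - c(z0, esophagus_center[2], esophagus_center[1])
  stack
}

#' Rigidly align a stack onto a reference via landmarks
#'
#' Fits a rigid transform from the stack's landmarks to the reference
#' landmarks (>= 3 shared names) and resamples the stack into the reference
#' geometry. The per-landmark least-squares residual RMS is attached as
#' attribute `"landmark_rms"` so alignment quality is always reported.
#'
#' @param stack the moving `image_stack`.
#' @param its_landmarks `landmark_set` in the stack's coordinates.
#' @param ref_landmarks `landmark_set` in the reference coordinates.
#' @param reference `image_stack` (or geometry list) defining the output
#'   grid; defaults to the moving stack's own geometry.
#' @return aligned `image_stack` with attribute `landmark_rms` (um).
#' @export
align_to_reference <- function(stack, its_landmarks, ref_landmarks,
                               reference = stack) {
  stopifnot_stack(stack)
  tf <- fit_rigid(its_landmarks, ref_landmarks)
  p <- pair_landmarks(its_landmarks, ref_landmarks, min_pairs = 3L)
  resid <- apply_points(tf, p$src) - p$dst
  rms <- sqrt(mean(rowSums(resid^2)))
  out <- resample_image(tf, stack, reference)
  attr(out, "landmark_rms") <- rms
  attr(out, "transform") <- tf
  out
}

#' Voxelwise mean of aligned stacks
#'
#' @param stacks list of `image_stack` objects on an identical grid.
#' @return floating-point `image_stack` of means.
#' @export
average_stacks <- function(stacks) {
  if (length(stacks) < 2L) stop("need at least 2 stacks to average")
  ref <- stacks[[1]]
  stopifnot_stack(ref)
  for (s in stacks[-1]) {
    stopifnot_stack(s)
    if (!identical(dim(s$voxels), dim(ref$voxels)) ||
        !isTRUE(all.equal(s$spacing, ref$spacing)) ||
        !isTRUE(all.equal(s$origin, ref$origin)))
      stop("stacks differ in geometry (shape, spacing or origin)")
  }
  acc <- Reduce(`+`, lapply(stacks, `[[`, "voxels"))
  image_stack(acc / length(stacks), spacing = ref$spacing, origin = ref$origin)
}

#' Extract the brain outline mask from an average stack
#'
#' Separates light from dark by a global threshold (Otsu by default, or a
#' fixed value), keeps the largest 26-connected foreground component and
#' fills interior cavities, yielding one solid outline.
#'
#' @param stack grayscale `image_stack`.
#' @param method `"otsu"` or `"fixed"`.
#' @param value threshold when `method = "fixed"` (foreground is `> value`).
#' @return binary (0/1) `image_stack`.
#' @export
binarize_outline <- function(stack, method = c("otsu", "fixed"), value = NULL) {
  stopifnot_stack(stack)
  method <- match.arg(method)
  thr <- if (method == "otsu") otsu_threshold(stack$voxels) else {
    if (is.null(value)) stop("method = 'fixed' needs a threshold value")
    value
  }
  mask <- stack$voxels > thr
  if (!any(mask)) stop("binarization produced an empty mask (threshold ", thr, ")")
  mask <- fill_holes(largest_component(mask, 26L))
  out <- image_stack(array(as.numeric(mask), dim = dim(mask)),
                     spacing = stack$spacing, origin = stack$origin)
  attr(out, "threshold") <- thr
  out
}

#' Surface mesh of a binary mask
#'
#' Builds the closed boundary surface of the mask in physical um
#' coordinates by emitting the square faces between foreground and
#' background voxels (each split into two triangles, wound outward). The
#' mesh is watertight by construction and its enclosed volume equals the
#' voxel count times the voxel volume exactly.
#'
#' @param mask binary `image_stack` or logical array.
#' @param spacing `(dz, dy, dx)` um (taken from the stack if given one).
#' @param origin `(z0, y0, x0)` um.
#' @return a `surface_mesh`.
#' @export
extract_surface <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(mask, "image_stack")) {
    spacing <- mask$spacing
    origin <- mask$origin
    mask <- mask$voxels != 0
  }
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("cannot surface an empty mask")
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask

  # corner-grid vertex ids: corners of voxel (k,j,i) live on an
  # (nz+1) x (ny+1) x (nx+1) lattice
  nzc <- d[1] + 1L; nyc <- d[2] + 1L
  corner_id <- function(k, j, i) k + (j - 1L) * nzc + (i - 1L) * nzc * nyc

  faces <- vector("list", 6)
  fg <- which(pad)
  pd <- dim(pad)
  kk <- ((fg - 1L) %% pd[1]) + 1L
  jj <- (((fg - 1L) %/% pd[1]) %% pd[2]) + 1L
  ii <- ((fg - 1L) %/% (pd[1] * pd[2])) + 1L
  # voxel indices in the unpadded grid
  k <- kk - 1L; j <- jj - 1L; i <- ii - 1L

  neighbour_empty <- function(dk, dj, di)
    !pad[cbind(kk + dk, jj + dj, ii + di)]

  # for each exposed face, its 4 corner ids wound so the normal points
  # outward (toward the empty neighbour); corners of voxel (k,j,i) are
  # lattice points (k..k+1, j..j+1, i..i+1)
  quad <- function(sel, c1, c2, c3, c4) {
    if (!any(sel)) return(NULL)
    cbind(c1[sel], c2[sel], c3[sel], c4[sel])
  }
  # corner shorthand: cKJI with K,J,I in {0,1} offsets
  c000 <- corner_id(k,      j,      i)
  c100 <- corner_id(k + 1L, j,      i)
  c010 <- corner_id(k,      j + 1L, i)
  c110 <- corner_id(k + 1L, j + 1L, i)
  c001 <- corner_id(k,      j,      i + 1L)
  c101 <- corner_id(k + 1L, j,      i + 1L)
  c011 <- corner_id(k,      j + 1L, i + 1L)
  c111 <- corner_id(k + 1L, j + 1L, i + 1L)

  quads <- rbind(
    quad(neighbour_empty(-1L, 0L, 0L), c000, c010, c011, c001),  # -z face
    quad(neighbour_empty(+1L, 0L, 0L), c100, c101, c111, c110),  # +z face
    quad(neighbour_empty(0L, -1L, 0L), c000, c001, c101, c100),  # -y face
    quad(neighbour_empty(0L, +1L, 0L), c010, c110, c111, c011),  # +y face
    quad(neighbour_empty(0L, 0L, -1L), c000, c100, c110, c010),  # -x face
    quad(neighbour_empty(0L, 0L, +1L), c001, c011, c111, c101)   # +x face
  )
  used <- sort(unique(as.vector(quads)))
  remap <- match(quads, used)
  dim(remap) <- dim(quads)
  # lattice point id -> physical coordinate (corner at index - 0.5)
  kq <- ((used - 1L) %% nzc)
  jq <- (((used - 1L) %/% nzc) %% nyc)
  iq <- ((used - 1L) %/% (nzc * nyc))
  verts <- cbind(x = origin[3] + (iq - 0.5) * spacing[3],
                 y = origin[2] + (jq - 0.5) * spacing[2],
                 z = origin[1] + (kq - 0.5) * spacing[1])
  tris <- rbind(remap[, c(1, 2, 3)], remap[, c(1, 3, 4)])
  mesh <- surface_mesh(verts, tris)
  if (mesh_volume(mesh) < 0)  # flip winding if normals point inward
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Build the standard brain from a set of hemisphere stacks
#'
#' Runs the full scheme: mirror left-hemisphere inputs about the sagittal
#' midplane (with R/L landmark renaming), rigidly align every stack to the
#' reference stack's landmarks, average, binarize and surface. All inputs
#' are validated before any computation starts.
#'
#' @param config list with elements `stacks` (list of `image_stack` or TIFF
#'   paths), `landmarks` (list of `landmark_set` or CSV paths, parallel to
#'   `stacks`), `hemisphere` (character vector of `"L"`/`"R"`), `reference`
#'   (index of the reference stack, default 1), and optionally `threshold`
#'   (`"otsu"` or a fixed number) and `spacing` (for stacks read from disk).
#' @return an `atlas_bundle`: list with `average_stack`, `outline_mask`,
#'   `surface`, `reference_landmarks`, `provenance`.
#' @export
build_standard_brain <- function(config) {
  need <- c("stacks", "landmarks", "hemisphere")
  if (!all(need %in% names(config)))
    stop("config must contain: ", paste(need, collapse = ", "))
  n <- length(config$stacks)
  if (length(config$landmarks) != n || length(config$hemisphere) != n)
    stop("stacks, landmarks and hemisphere must have equal length")
  if (!all(config$hemisphere %in% c("L", "R")))
    stop("hemisphere labels must be 'L' or 'R'")
  ref_idx <- if (is.null(config$reference)) 1L else as.integer(config$reference)
  if (ref_idx < 1L || ref_idx > n) stop("reference index out of range")

  load_stack <- function(s) {
    if (inherits(s, "image_stack")) return(s)
    if (is.character(s)) {
      if (!file.exists(s)) stop("missing stack file: ", s)
      return(read_stack(s, spacing = config$spacing))
    }
    stop("each stack must be an image_stack or a TIFF path")
  }
  load_lm <- function(l) {
    if (inherits(l, "landmark_set")) return(l)
    if (is.character(l)) {
      if (!file.exists(l)) stop("missing landmark file: ", l)
      return(read_landmarks(l))
    }
    stop("each landmark entry must be a landmark_set or a CSV path")
  }
  # validation-first: resolve every input before any computation
  stacks <- lapply(config$stacks, load_stack)
  lms <- lapply(config$landmarks, load_lm)

  for (idx in seq_len(n)) {
    if (config$hemisphere[idx] == "L") {
      stacks[[idx]] <- mirror(stacks[[idx]], axis = "x")
      lms[[idx]] <- mirror(lms[[idx]], axis = "x", extent = stacks[[idx]],
                           rename_lr = TRUE)
    }
  }
  reference <- stacks[[ref_idx]]
  ref_lm <- lms[[ref_idx]]

  aligned <- vector("list", n)
  prov <- vector("list", n)
  for (idx in seq_len(n)) {
    a <- tryCatch(
      align_to_reference(stacks[[idx]], lms[[idx]], ref_lm, reference),
      error = function(e) stop("alignment of input ", idx, " failed: ",
                               conditionMessage(e)))
    aligned[[idx]] <- a
    prov[[idx]] <- list(input = idx, hemisphere = config$hemisphere[idx],
                        landmark_rms = attr(a, "landmark_rms"))
  }
  avg <- if (n == 1L) aligned[[1]] else average_stacks(aligned)
  thr <- if (is.null(config$threshold)) "otsu" else config$threshold
  outline <- tryCatch({
    if (identical(thr, "otsu")) binarize_outline(avg, "otsu")
    else binarize_outline(avg, "fixed", value = as.numeric(thr))
  }, error = function(e) stop("binarization failed: ", conditionMessage(e)))
  surf <- extract_surface(outline)
  structure(list(average_stack = avg, outline_mask = outline, surface = surf,
                 reference_landmarks = ref_lm, provenance = prov),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("atlas_bundle: %d inputs averaged; outline %d voxels; surface %d faces\n",
              length(x$provenance), sum(x$outline_mask$voxels != 0),
              nrow(x$surface$faces)))
  invisible(x)
}

#' Write an atlas bundle to a directory
#'
#' Emits `average.tif` (16-bit, intensities rounded), `outline.tif` (binary
#' 8-bit), `surface.obj`, `landmarks.csv` and `provenance.json`.
#'
#' @param bundle an `atlas_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_atlas_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  avg <- bundle$average_stack
  avg$voxels <- round(pmin(pmax(avg$voxels, 0), 65535))
  write_stack(avg, file.path(dir, "average.tif"), bits = 16L)
  write_stack(bundle$outline_mask, file.path(dir, "outline.tif"), bits = 8L)
  write_obj(bundle$surface, file.path(dir, "surface.obj"))
  write_landmarks(bundle$reference_landmarks, file.path(dir, "landmarks.csv"))
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
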