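#' Synthetic cylinder-tree neuron phantoms
#'
#' The benchmark world: random branched tubular neurons ("connection of
#' cylinders") rendered into 3D stacks with exact SWC ground truth, under
#' four image conditions -- `raw` (clean), `biased_background` (a large
#' bright object covering the neuron), `noise` (additive white noise) and
#' `object` (a bright cylinder crossing the neuron). A `phantom_spec`
#' pins every generator parameter plus the seed, so output is
#' bit-reproducible.
#'
#' Defaults (not prescribed by any source; chosen once as a realistic
#' desk-scale confocal regime): a 256 x 256 um field, 128 optical sections
#' of 2 um, in-plane pitch 1 um; 8-bit intensities, foreground 200 on
#' background 20; 2-4 branching generations of 20-60 um segments at 20-70
#' degree branch angles; root radius 2 um tapering by 0.8 per generation;
#' noise sigma 30, bias amplitude 100, distractor cylinder radius 8 um.
#'
#' @param seed RNG seed (fully determines the phantom).
#' @param volume_shape voxels `(nz, ny, nx)`.
#' @param spacing `(dz, dy, dx)` um.
#' @param generations range of branching generations `c(min, max)`.
#' @param segment_length segment length range, um.
#' @param branch_angle branch half-angle range, degrees.
#' @param root_radius trunk radius, um.
#' @param taper radius multiplier per generation.
#' @param fg,bg foreground / background intensity (8-bit scale).
#' @param condition one of `"raw"`, `"biased_background"`, `"noise"`, `"object"`.
#' @param noise_sd white-noise sigma (intensity units).
#' @param bias_amplitude peak added intensity of the bias object.
#' @param object_radius distractor cylinder radius, um.
#' @param psf_sigma optional Gaussian blur sigma (um) applied after rendering.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 1L,
                         volume_shape = c(128L, 256L, 256L),
                         spacing = c(2, 1, 1),
                         generations = c(2L, 4L),
                         segment_length = c(20, 60),
                         branch_angle = c(20, 70),
                         root_radius = 2,
                         taper = 0.8,
                         fg = 200, bg = 20,
                         condition = c("raw", "biased_background", "noise", "object"),
                         noise_sd = 30,
                         bias_amplitude = 100,
                         object_radius = 8,
                         psf_sigma = 0) {
  condition <- match.arg(condition)
  if (fg <= bg) stop("foreground intensity must exceed background")
  structure(list(seed = as.integer(seed), volume_shape = as.integer(volume_shape),
                 spacing = as.numeric(spacing), generations = as.integer(generations),
                 segment_length = segment_length, branch_angle = branch_angle,
                 root_radius = root_radius, taper = taper, fg = fg, bg = bg,
                 condition = condition, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, object_radius = object_radius,
                 psf_sigma = psf_sigma),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

# random direction at `angle` degrees from `dir`, uniform in azimuth
deviate_direction <- function(dir, angle_deg) {
  dir <- unit_vec(dir)
  # orthonormal frame around dir
  helper <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit_vec(pracma_cross(dir, helper))
  v <- pracma_cross(dir, u)
  a <- angle_deg * pi / 180
  phi <- stats::runif(1, 0, 2 * pi)
  unit_vec(cos(a) * dir + sin(a) * (cos(phi) * u + sin(phi) * v))
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])

#' Generate a random cylinder-tree morphology
#'
#' Grows a rooted binary tree: a trunk followed by `generations` levels of
#' bifurcations (always >= 2 levels, so at least 3 bifurcation nodes), with
#' segment lengths, branch angles and directions drawn from the spec ranges
#' and radii tapering geometrically per generation. Intermediate nodes are
#' placed every ~5 um along segments. Directions whose endpoint would leave
#' the safe interior of the volume are re-drawn; if a whole tree cannot be
#' fitted after 100 attempts an error is raised.
#'
#' @param spec a `phantom_spec`.
#' @return a ground-truth `morphology`.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    ext <- spec$volume_shape[3:1] * spec$spacing[3:1]  # (x, y, z) physical size
    margin <- spec$root_radius + 3
    for (attempt in seq_len(100)) {
      m <- try(grow_tree_once(spec, ext, margin), silent = TRUE)
      if (!inherits(m, "try-error")) return(m)
    }
    stop("could not fit a phantom tree in the volume after 100 attempts")
  })
}

grow_tree_once <- function(spec, ext, margin) {
  lo <- rep(margin, 3)
  hi <- ext - margin
  inside <- function(p) all(p >= lo & p <= hi)
  gmax <- if (spec$generations[1] == spec$generations[2]) spec$generations[1]
          else sample(spec$generations[1]:spec$generations[2], 1)
  nodes <- data.frame(id = 1L, type = 1L,
                      x = stats::runif(1, ext[1] * 0.35, ext[1] * 0.65),
                      y = stats::runif(1, ext[2] * 0.35, ext[2] * 0.65),
                      z = stats::runif(1, ext[3] * 0.35, ext[3] * 0.65),
                      radius = spec$root_radius, parent = -1L)
  next_id <- 2L

  add_segment <- function(from_id, dir, len, r0, r1) {
    p0 <- as.numeric(nodes[match(from_id, nodes$id), c("x", "y", "z")])
    p1 <- p0 + dir * len
    if (!inside(p1)) stop("out of bounds")
    nsub <- max(1L, ceiling(len / 5))
    par <- from_id
    for (s in seq_len(nsub)) {
      t_ <- s / nsub
      p <- p0 + dir * len * t_
      nodes[nrow(nodes) + 1L, ] <<- list(next_id, 3L, p[1], p[2], p[3],
                                         r0 + (r1 - r0) * t_, par)
      par <- next_id
      next_id <<- next_id + 1L
    }
    par  # id of the segment end node
  }
  seg_len <- function() stats::runif(1, spec$segment_length[1], spec$segment_length[2])
  seg_ang <- function() stats::runif(1, spec$branch_angle[1], spec$branch_angle[2])

  # trunk
  trunk_dir <- unit_vec(stats::rnorm(3))
  tip <- tryadd(function() add_segment(1L, trunk_dir, seg_len(),
                                       spec$root_radius, spec$root_radius), 50,
                function() trunk_dir <<- unit_vec(stats::rnorm(3)))
  frontier <- list(list(id = tip, dir = trunk_dir, gen = 0L))
  for (g in seq_len(gmax)) {
    r0 <- spec$root_radius * spec$taper^(g - 1)
    r1 <- spec$root_radius * spec$taper^g
    new_frontier <- list()
    for (f in frontier) {
      for (child in 1:2) {
        dir <- f$dir
        ok <- FALSE
        for (tr in seq_len(50)) {
          d <- deviate_direction(f$dir, seg_ang())
          endid <- try(add_segment(f$id, d, seg_len(), r0, r1), silent = TRUE)
          if (!inherits(endid, "try-error")) {
            new_frontier[[length(new_frontier) + 1L]] <-
              list(id = endid, dir = d, gen = g)
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("out of bounds")
      }
    }
    frontier <- new_frontier
  }
  validate_morphology(morphology(nodes))
}

tryadd <- function(f, times, on_fail) {
  for (tr in seq_len(times)) {
    r <- try(f(), silent = TRUE)
    if (!inherits(r, "try-error")) return(r)
    on_fail()
  }
  stop("out of bounds")
}

#' Render a morphology into a voxel volume
#'
#' Paints each parent-child edge as a tapered frustum: a voxel is
#' foreground when its centre lies within the linearly interpolated local
#' radius of the nearest point on the segment axis. Optional Gaussian blur
#' (`psf_sigma` um) emulates a symmetric PSF.
#'
#' @param m a `morphology` (may be empty: `NULL` renders pure background).
#' @param volume_shape voxels `(nz, ny, nx)`.
#' @param spacing `(dz, dy, dx)` um.
#' @param fg,bg intensities.
#' @param psf_sigma blur sigma in um (0 = none).
#' @param origin physical origin, um.
#' @return an `image_stack` (values clamped to \code{[0, 255]} after blur).
#' @export
render_morphology <- function(m, volume_shape, spacing = c(2, 1, 1),
                              fg = 200, bg = 20, psf_sigma = 0,
                              origin = c(0, 0, 0)) {
  occ <- rasterize_frusta(m, volume_shape, spacing, origin, dilation = 0)
  vox <- array(bg, dim = volume_shape)
  vox[occ] <- fg
  if (psf_sigma > 0) {
    vox <- gaussian_blur3d(vox, psf_sigma, spacing)
    vox <- round(pmin(pmax(vox, 0), 255))
  }
  image_stack(vox, spacing = spacing, origin = origin)
}

# Occupancy rasterization of all edges of a morphology as frusta.
# Returns a logical array. dilation (um) grows every local radius.
rasterize_frusta <- function(m, volume_shape, spacing, origin = c(0, 0, 0),
                             dilation = 0) {
  occ <- array(FALSE, dim = volume_shape)
  if (is.null(m) || nrow(m$nodes) == 0L) return(occ)
  nd <- m$nodes
  pos <- match(nd$parent, nd$id)
  edges <- which(!is.na(pos))
  # include root nodes as spheres so single-node morphologies render too
  singles <- which(nd$parent == -1L)
  d <- volume_shape
  ax_z <- origin[1] + (seq_len(d[1]) - 1) * spacing[1]
  ax_y <- origin[2] + (seq_len(d[2]) - 1) * spacing[2]
  ax_x <- origin[3] + (seq_len(d[3]) - 1) * spacing[3]

  paint <- function(p0, p1, r0, r1) {
    rmax <- max(r0, r1) + dilation
    lo <- pmin(p0, p1) - rmax
    hi <- pmax(p0, p1) + rmax
    ks <- which(ax_z >= lo[3] & ax_z <= hi[3])
    js <- which(ax_y >= lo[2] & ax_y <= hi[2])
    is_ <- which(ax_x >= lo[1] & ax_x <= hi[1])
    if (!length(ks) || !length(js) || !length(is_)) return()
    nk <- length(ks); nj <- length(js); ni <- length(is_)
    gz <- rep(ax_z[ks], times = nj * ni)
    gy <- rep(rep(ax_y[js], each = nk), times = ni)
    gx <- rep(ax_x[is_], each = nk * nj)
    v <- p1 - p0
    L2 <- sum(v^2)
    if (L2 == 0) {
      dist2 <- (gx - p0[1])^2 + (gy - p0[2])^2 + (gz - p0[3])^2
      hit <- dist2 <= (r0 + dilation)^2
    } else {
      t_ <- ((gx - p0[1]) * v[1] + (gy - p0[2]) * v[2] + (gz - p0[3]) * v[3]) / L2
      t_ <- pmin(pmax(t_, 0), 1)
      cx <- p0[1] + t_ * v[1]; cy <- p0[2] + t_ * v[2]; cz <- p0[3] + t_ * v[3]
      dist2 <- (gx - cx)^2 + (gy - cy)^2 + (gz - cz)^2
      r <- r0 + (r1 - r0) * t_ + dilation
      hit <- dist2 <= r^2
    }
    if (!any(hit)) return()
    sub <- occ[ks, js, is_, drop = FALSE]
    sub[hit] <- TRUE
    occ[ks, js, is_] <<- sub
  }
  for (e in edges) {
    p <- pos[e]
    paint(c(nd$x[p], nd$y[p], nd$z[p]), c(nd$x[e], nd$y[e], nd$z[e]),
          nd$radius[p], nd$radius[e])
  }
  for (s in singles)
    paint(c(nd$x[s], nd$y[s], nd$z[s]), c(nd$x[s], nd$y[s], nd$z[s]),
          nd$radius[s], nd$radius[s])
  occ
}

#' Apply an image corruption condition
#'
#' `biased_background` adds a large smooth bright ellipsoidal intensity
#' gradient centred on `center` (default: the volume centre, overlapping
#' the tree); `noise` adds i.i.d. Gaussian noise; `object` paints one
#' bright cylinder through `center`. Results are clipped to \code{[0, 255]} and
#' rounded (8-bit semantics). Fully seeded and reproducible.
#'
#' @param stack an `image_stack`.
#' @param condition `"biased_background"`, `"noise"` or `"object"`.
#' @param params list of condition parameters: `noise_sd`, `bias_amplitude`,
#'   `object_radius`, `object_intensity`, `center` (x, y, z um), `axis`
#'   (direction of the distractor cylinder).
#' @param seed RNG seed for the stochastic conditions.
#' @return the corrupted `image_stack`.
#' @export
corrupt_stack <- function(stack, condition, params = list(), seed = 1L) {
  stopifnot_stack(stack)
  d <- dim(stack$voxels)
  ext <- stack_extent(stack)
  center <- params$center
  if (is.null(center)) center <- colMeans(ext)
  ax_z <- stack$origin[1] + (seq_len(d[1]) - 1) * stack$spacing[1]
  ax_y <- stack$origin[2] + (seq_len(d[2]) - 1) * stack$spacing[2]
  ax_x <- stack$origin[3] + (seq_len(d[3]) - 1) * stack$spacing[3]
  gz <- rep(ax_z, times = d[2] * d[3])
  gy <- rep(rep(ax_y, each = d[1]), times = d[3])
  gx <- rep(ax_x, each = d[1] * d[2])

  v <- stack$voxels
  if (condition == "biased_background") {
    amp <- if (is.null(params$bias_amplitude)) 100 else params$bias_amplitude
    semi <- if (is.null(params$semi_axes))
      (ext["max", ] - ext["min", ]) * c(0.3, 0.3, 0.35) else params$semi_axes
    q <- ((gx - center[1]) / semi[1])^2 + ((gy - center[2]) / semi[2])^2 +
      ((gz - center[3]) / semi[3])^2
    v <- v + array(amp * exp(-q), dim = d)
  } else if (condition == "noise") {
    sd_ <- if (is.null(params$noise_sd)) 30 else params$noise_sd
    if (sd_ > 0)
      v <- v + with_seed(seed, array(stats::rnorm(prod(d), 0, sd_), dim = d))
  } else if (condition == "object") {
    r <- if (is.null(params$object_radius)) 8 else params$object_radius
    inten <- if (is.null(params$object_intensity)) 200 else params$object_intensity
    axis <- if (is.null(params$axis))
      with_seed(seed, unit_vec(stats::rnorm(3))) else unit_vec(params$axis)
    dx <- gx - center[1]; dy <- gy - center[2]; dz <- gz - center[3]
    t_ <- dx * axis[1] + dy * axis[2] + dz * axis[3]
    dist2 <- (dx - t_ * axis[1])^2 + (dy - t_ * axis[2])^2 + (dz - t_ * axis[3])^2
    v[array(dist2 <= r^2, dim = d)] <- inten
  } else {
    stop("unknown corruption condition: ", condition)
  }
  stack$voxels <- round(pmin(pmax(v, 0), 255))
  stack
}

#' Generate the four-condition phantom benchmark
#'
#' Produces `n_per_condition` phantoms for each of the four conditions
#' (default 3, i.e. 12 stacks). Per-item seeds are derived deterministically
#' from `base_seed`, so the whole benchmark is reproducible.
#'
#' @param n_per_condition phantoms per condition (>= 1).
#' @param base_seed integer master seed.
#' @param spec_template a `phantom_spec` providing all non-seed parameters.
#' @return list of items, each `list(stack, gt, condition, seed)`.
#' @export
make_benchmark <- function(n_per_condition = 3L, base_seed = 1L,
                           spec_template = phantom_spec()) {
  stopifnot(n_per_condition >= 1L)
  conditions <- c("raw", "biased_background", "noise", "object")
  items <- list()
  idx <- 0L
  for (cond in conditions) {
    for (rep_ in seq_len(n_per_condition)) {
      idx <- idx + 1L
      seed_i <- (as.numeric(base_seed) * 7919 + idx * 104729) %% 2147483647
      spec <- spec_template
      spec$seed <- as.integer(seed_i)
      spec$condition <- cond
      gt <- generate_tree(spec)
      st <- render_morphology(gt, spec$volume_shape, spec$spacing,
                              fg = spec$fg, bg = spec$bg,
                              psf_sigma = spec$psf_sigma)
      if (cond != "raw") {
        prm <- list(noise_sd = spec$noise_sd,
                    bias_amplitude = spec$bias_amplitude,
                    object_radius = spec$object_radius)
        if (cond %in% c("biased_background", "object")) {
          # centre the corruption on the tree so it genuinely overlaps it
          prm$center <- colMeans(morph_xyz(gt))
        }
        st <- corrupt_stack(st, cond, prm, seed = spec$seed + 1L)
      }
      items[[idx]] <- list(stack = st, gt = gt, condition = cond,
                           seed = spec$seed)
    }
  }
  items
}
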