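#' Tracer parameters
#'
#' Parameters of the region-growing extraction pipeline. `threshold` is
#' `"otsu"` or a fixed intensity; `background_subtract` enables per-slice
#' coarse background removal (for the biased-background regime);
#' `seed_point` is the `(x, y, z)` um starting point (defaults to the
#' brightest foreground voxel); spurs shorter than `spur_prune_length` um
#' are removed; centerlines are resampled every `node_spacing` um; node
#' radii come from the distance transform, floored at `min_radius`.
#'
#' @param threshold `"otsu"` or numeric.
#' @param connectivity 6 or 26.
#' @param seed_point optional `(x, y, z)` um.
#' @param spur_prune_length um, >= 0.
#' @param node_spacing um, > 0.
#' @param min_radius um.
#' @param background_subtract logical.
#' @param block_size um, coarse grid pitch of the background estimator.
#' @return a `tracer_params` list.
#' @export
tracer_params <- function(threshold = "otsu", connectivity = 26L,
                          seed_point = NULL, spur_prune_length = 3,
                          node_spacing = 1, min_radius = 0.25,
                          background_subtract = FALSE, block_size = 32) {
  if (spur_prune_length < 0) stop("spur_prune_length must be >= 0")
  if (node_spacing <= 0) stop("node_spacing must be > 0")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(threshold = threshold, connectivity = as.integer(connectivity),
                 seed_point = seed_point, spur_prune_length = spur_prune_length,
                 node_spacing = node_spacing, min_radius = min_radius,
                 background_subtract = background_subtract,
                 block_size = block_size),
            class = "tracer_params")
}

#' Separate neuron foreground from background
#'
#' Global thresholding (Otsu by default). With
#' `params$background_subtract`, a per-slice smooth background estimate
#' (median over a coarse block grid, bilinearly interpolated) is removed
#' first, which suppresses large bright objects covering the neuron.
#'
#' @param stack grayscale `image_stack`.
#' @param params a `tracer_params`.
#' @return binary `image_stack`; errors if the mask comes out empty.
#' @export
segment_foreground <- function(stack, params = tracer_params()) {
  stopifnot_stack(stack)
  v <- stack$voxels
  if (isTRUE(params$background_subtract))
    v <- subtract_background(v, stack$spacing, params$block_size)
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(v)
         else as.numeric(params$threshold)
  mask <- v > thr
  if (!any(mask)) stop("foreground segmentation produced an empty mask")
  out <- image_stack(array(as.numeric(mask), dim = dim(mask)),
                     spacing = stack$spacing, origin = stack$origin)
  attr(out, "threshold") <- thr
  out
}

# Slicewise coarse background: per z-slice, medians over block_size-um
# blocks, bilinearly interpolated back to full resolution and subtracted.
subtract_background <- function(v, spacing, block_size = 32) {
  d <- dim(v)
  by <- max(2L, round(block_size / spacing[2]))
  bx <- max(2L, round(block_size / spacing[3]))
  jb <- ceiling(seq_len(d[2]) / by)
  ib <- ceiling(seq_len(d[3]) / bx)
  njb <- max(jb); nib <- max(ib)
  jc <- (tapply(seq_len(d[2]), jb, mean))
  ic <- (tapply(seq_len(d[3]), ib, mean))
  # block membership of every in-slice pixel, computed once
  block_of <- jb[rep(seq_len(d[2]), times = d[3])] +
    (ib[rep(seq_len(d[3]), each = d[2])] - 1L) * njb
  groups <- split(seq_len(d[2] * d[3]), block_of)
  out <- v
  for (k in seq_len(d[1])) {
    sl <- v[k, , ]
    med <- matrix(vapply(groups, function(g) stats::median(sl[g]), numeric(1)),
                  nrow = njb)
    bgk <- bilinear_grid(med, jc, ic, d[2], d[3])
    out[k, , ] <- pmax(sl - bgk, 0)
  }
  out
}

# interpolate a coarse njb x nib grid (values at centres jc, ic) to n x m
bilinear_grid <- function(med, jc, ic, n, m) {
  j_t <- stats::approx(jc, seq_along(jc), xout = seq_len(n), rule = 2)$y
  i_t <- stats::approx(ic, seq_along(ic), xout = seq_len(m), rule = 2)$y
  j0 <- pmin(floor(j_t), length(jc) - 1L); j0 <- pmax(j0, 1L)
  i0 <- pmin(floor(i_t), length(ic) - 1L); i0 <- pmax(i0, 1L)
  fj <- j_t - j0
  fi <- i_t - i0
  A <- med[cbind(rep(j0, m), rep(i0, each = n))]
  B <- med[cbind(rep(j0 + 1L, m), rep(i0, each = n))]
  C <- med[cbind(rep(j0, m), rep(i0 + 1L, each = n))]
  D <- med[cbind(rep(j0 + 1L, m), rep(i0 + 1L, each = n))]
  wfj <- rep(fj, m); wfi <- rep(fi, each = n)
  matrix(A * (1 - wfj) * (1 - wfi) + B * wfj * (1 - wfi) +
         C * (1 - wfj) * wfi + D * wfj * wfi, nrow = n)
}

#' Trace a neuron skeleton from an image stack
#'
#' The extraction pipeline: (1) threshold to a mask (or accept a binary
#' stack) and region-grow from the seed voxel, keeping only the connected
#' component containing the seed; (2) compute the Euclidean distance
#' transform and build the shortest-path tree from the seed over the
#' component, with edge weights `step_length / (1 + EDT)` so paths run
#' along the tube centres; (3) take the union of the tree paths to
#' locally-farthest voxels (geodesic local maxima) and prune spurs shorter
#' than `spur_prune_length`; (4) resample every branch at `node_spacing`
#' and assign each node the EDT value at its position as radius (floored
#' at `min_radius`); (5) return the result as a rooted morphology.
#'
#' Voxels of the mask not connected to the seed are not traced; their count
#' is attached as attribute `"uncovered_voxels"` (coverage warning).
#'
#' @param stack grayscale or binary `image_stack`.
#' @param params a `tracer_params`.
#' @return a single-rooted `morphology` with attributes `uncovered_voxels`
#'   and `seed_voxel`.
#' @export
trace_neurites <- function(stack, params = tracer_params()) {
  stopifnot_stack(stack)
  vals <- unique(as.vector(stack$voxels))
  is_binary <- all(vals %in% c(0, 1))
  mask_stack <- if (is_binary) stack else segment_foreground(stack, params)
  mask <- mask_stack$voxels != 0
  if (!any(mask)) stop("mask has zero foreground voxels")
  d <- dim(mask)
  sp <- stack$spacing

  # seed voxel: nearest foreground voxel to the given physical point,
  # or the brightest (first-in-scan-order among ties) foreground voxel
  fg_idx <- which(mask)
  if (!is.null(params$seed_point)) {
    vi <- physical_to_voxel(stack, matrix(params$seed_point, ncol = 3))
    kji <- arrayInd(fg_idx, d)
    dist2 <- ((kji[, 1] - vi[1]) * sp[1])^2 + ((kji[, 2] - vi[2]) * sp[2])^2 +
      ((kji[, 3] - vi[3]) * sp[3])^2
    seed_lin <- fg_idx[which.min(dist2)]
    # the stated seed must actually hit foreground (within one voxel pitch
    # of it); a distant point is a usage error
    if (min(dist2) > max(sp)^2 * 4)
      stop("seed point is outside the foreground (nearest mask voxel ",
           sprintf("%.1f", sqrt(min(dist2))), " um away)")
  } else {
    inten <- stack$voxels[fg_idx]
    seed_lin <- fg_idx[which.max(inten)]
  }

  # region growing: component containing the seed
  lab <- label_components(mask, params$connectivity)
  comp <- lab == lab[seed_lin]
  uncovered <- sum(mask) - sum(comp)
  if (uncovered > 0)
    warning(uncovered, " foreground voxel(s) in other components were not traced")

  edt <- distance_transform(comp, sp)
  node_cost <- array(NA_real_, dim = d)
  node_cost[comp] <- 1 / (1 + edt[comp])
  tr <- cpp_dijkstra_tree(as.vector(node_cost), d, sp, seed_lin,
                          params$connectivity)
  parent <- tr$parent
  pathlen <- tr$pathlen

  # locally-farthest voxels: geodesic path length a local max over the
  # neighbourhood within the component
  tips_lin <- local_maxima_lin(pathlen, comp, d, params$connectivity)
  tips_lin <- setdiff(tips_lin, seed_lin)

  # union of root paths to all candidate tips
  keep <- rep(FALSE, prod(d))
  for (t_ in tips_lin) {
    cur <- t_
    while (!keep[cur]) {
      keep[cur] <- TRUE
      p <- parent[cur]
      if (is.na(p) || p == 0L) break
      cur <- p
    }
  }
  keep[seed_lin] <- TRUE
  kept <- which(keep)
  if (length(kept) < 1L) stop("tracing produced no skeleton voxels")

  # voxel tree -> morphology (one node per kept voxel)
  id_of <- integer(prod(d))
  id_of[kept] <- seq_along(kept)
  kji <- arrayInd(kept, d)
  xyz <- voxel_to_physical(stack, kji)
  par_lin <- parent[kept]
  par_id <- ifelse(is.na(par_lin) | par_lin == 0L, -1L,
                   ifelse(keep[pmax(par_lin, 1L)], id_of[pmax(par_lin, 1L)], -1L))
  radii <- pmax(edt[kept], params$min_radius)
  vox_m <- morphology(data.frame(id = seq_along(kept), type = 3L,
                                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 radius = radii, parent = par_id))
  vox_m$nodes$type[vox_m$nodes$parent == -1L] <- 1L

  m <- prune_spurs(vox_m, params$spur_prune_length)
  m <- trim_terminal_caps(m)
  m <- resample_branches(m, params$node_spacing)
  # radii re-sampled from the EDT field at the final node positions
  edt_stack <- image_stack(edt, spacing = sp, origin = stack$origin)
  m$nodes$radius <- pmax(interp_stack(edt_stack, morph_xyz(m)),
                         params$min_radius)
  m <- validate_morphology(m)
  attr(m, "uncovered_voxels") <- uncovered
  attr(m, "seed_voxel") <- arrayInd(seed_lin, d)[1, ]
  m
}

local_maxima_lin <- function(pathlen, comp, d, connectivity) {
  offs <- expand.grid(dk = -1:1, dj = -1:1, di = -1:1)
  offs <- offs[!(offs$dk == 0 & offs$dj == 0 & offs$di == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dk) + abs(offs$dj) + abs(offs$di) == 1, ]
  lin <- which(comp & is.finite(pathlen))
  kji <- arrayInd(lin, d)
  best <- rep(TRUE, length(lin))
  pl <- array(pathlen, dim = d)
  for (o in seq_len(nrow(offs))) {
    k2 <- kji[, 1] + offs$dk[o]
    j2 <- kji[, 2] + offs$dj[o]
    i2 <- kji[, 3] + offs$di[o]
    ok <- k2 >= 1 & k2 <= d[1] & j2 >= 1 & j2 <= d[2] & i2 >= 1 & i2 <= d[3]
    nb <- rep(-Inf, length(lin))
    nb[ok] <- pl[cbind(k2[ok], j2[ok], i2[ok])]
    nb[!is.finite(nb)] <- -Inf
    best <- best & (pl[cbind(kji)] >= nb)
  }
  lin[best]
}

# Rounding correction: geodesic-farthest tracing runs to the apex of the
# rounded end cap, overshooting the true process end (the cap centre) by
# about one local radius. Inside a spherical cap the arc distance to the
# tip equals the EDT, so terminal nodes with arc_to_tip <= EDT (node radii
# here are the EDT values) are cap voxels and are trimmed.
trim_terminal_caps <- function(m) {
  nd <- m$nodes
  crit <- c(morph_roots(m), morph_bifurcations(m))
  drop_ids <- integer(0)
  for (tp in morph_tips(m)) {
    cur <- tp
    arc <- 0
    repeat {
      row <- match(cur, nd$id)
      par <- nd$parent[row]
      if (par == -1L || cur %in% crit) break
      if (arc > nd$radius[row] + 1e-9) break
      if (arc <= nd$radius[row]) drop_ids <- c(drop_ids, cur)
      prow <- match(par, nd$id)
      arc <- arc + sqrt((nd$x[row] - nd$x[prow])^2 + (nd$y[row] - nd$y[prow])^2 +
                        (nd$z[row] - nd$z[prow])^2)
      cur <- par
    }
  }
  drop_ids <- unique(drop_ids)
  if (!length(drop_ids) || length(drop_ids) >= nrow(nd) - 1L) return(m)
  morphology(nd[!(nd$id %in% drop_ids), , drop = FALSE])
}

# iteratively remove terminal branches shorter than prune_len (um)
prune_spurs <- function(m, prune_len) {
  if (prune_len <= 0) return(m)
  repeat {
    nd <- m$nodes
    if (nrow(nd) <= 2L) return(m)
    tips <- morph_tips(m)
    crit <- c(morph_roots(m), morph_bifurcations(m))
    drop_ids <- integer(0)
    for (tp in tips) {
      chain <- integer(0)
      cur <- tp
      len <- 0
      repeat {
        row <- match(cur, nd$id)
        par <- nd$parent[row]
        if (par == -1L || cur %in% crit) break
        prow <- match(par, nd$id)
        len <- len + sqrt((nd$x[row] - nd$x[prow])^2 +
                          (nd$y[row] - nd$y[prow])^2 +
                          (nd$z[row] - nd$z[prow])^2)
        chain <- c(chain, cur)
        if (par %in% crit || len >= prune_len) break
        cur <- par
      }
      if (len < prune_len && length(chain)) drop_ids <- c(drop_ids, chain)
    }
    drop_ids <- unique(drop_ids)
    if (!length(drop_ids) || length(drop_ids) >= nrow(nd) - 1L) return(m)
    m <- morphology(nd[!(nd$id %in% drop_ids), , drop = FALSE])
  }
}

# resample each branch (chain between critical nodes) at ~step um
resample_branches <- function(m, step) {
  nd <- m$nodes
  crit <- unique(c(morph_roots(m), morph_bifurcations(m), morph_tips(m)))
  kids_of <- split(nd$id[nd$parent != -1L], nd$parent[nd$parent != -1L])
  out <- list()
  new_id <- 0L
  id_map <- new.env()
  add_node <- function(xyzr, parent_new, type = 3L) {
    new_id <<- new_id + 1L
    out[[new_id]] <<- c(new_id, type, xyzr, parent_new)
    new_id
  }
  # emit critical nodes first (roots), then walk branches
  emit_branch <- function(start_id, parent_new) {
    # follow chain from start_id (a critical node) through its children
    for (child in kids_of[[as.character(start_id)]] %||% integer(0)) {
      chain <- child
      cur <- child
      while (!(cur %in% crit)) {
        nxt <- kids_of[[as.character(cur)]]
        cur <- nxt[1]
        chain <- c(chain, cur)
      }
      rows <- match(c(start_id, chain), nd$id)
      pts <- cbind(nd$x[rows], nd$y[rows], nd$z[rows], nd$radius[rows])
      seg <- sqrt(rowSums((pts[-1, 1:3, drop = FALSE] -
                           pts[-nrow(pts), 1:3, drop = FALSE])^2))
      s <- c(0, cumsum(seg))
      total <- s[length(s)]
      nsub <- max(1L, round(total / step))
      svals <- seq(0, total, length.out = nsub + 1L)[-1]
      prev <- parent_new
      last_new <- prev
      for (sv in svals) {
        p <- interp_polyline(pts, s, sv)
        last_new <- add_node(p, prev)
        prev <- last_new
      }
      assign(as.character(cur), last_new, envir = id_map)
      emit_branch(cur, last_new)
    }
  }
  for (r in morph_roots(m)) {
    row <- match(r, nd$id)
    rid <- add_node(c(nd$x[row], nd$y[row], nd$z[row], nd$radius[row]), -1L,
                    type = 1L)
    assign(as.character(r), rid, envir = id_map)
    emit_branch(r, rid)
  }
  tb <- do.call(rbind, out)
  morphology(data.frame(id = tb[, 1], type = tb[, 2], x = tb[, 3], y = tb[, 4],
                        z = tb[, 5], radius = tb[, 6], parent = tb[, 7]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

interp_polyline <- function(pts, s, sv) {
  i <- findInterval(sv, s, all.inside = TRUE)
  t_ <- (sv - s[i]) / max(s[i + 1] - s[i], .Machine$double.eps)
  pts[i, ] + t_ * (pts[i + 1, ] - pts[i, ])
}
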