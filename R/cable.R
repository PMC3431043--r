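#' Passive membrane parameters
#'
#' Conventional passive cable constants: membrane resistivity `Rm`
#' (Ohm cm^2), axial resistivity `Ra` (Ohm cm), specific capacitance `Cm`
#' (uF/cm^2, only relevant for transients) and resting potential `E_rest`
#' (mV). The defaults (10000, 100, 1, -65) are the standard textbook
#' conventions, stated as such rather than measured values.
#'
#' @param Rm membrane resistivity, Ohm cm^2.
#' @param Ra axial resistivity, Ohm cm.
#' @param Cm specific capacitance, uF/cm^2.
#' @param E_rest resting potential, mV.
#' @return a `passive_params` list.
#' @export
passive_params <- function(Rm = 10000, Ra = 100, Cm = 1, E_rest = -65) {
  if (any(c(Rm, Ra, Cm) <= 0)) stop("Rm, Ra and Cm must be positive")
  structure(list(Rm = Rm, Ra = Ra, Cm = Cm, E_rest = E_rest),
            class = "passive_params")
}

#' Compartmentalize a morphology into a passive cable model
#'
#' One compartment per SWC edge, treated as a conical frustum: lateral
#' membrane area `pi (r0 + r1) sqrt(L^2 + (r1 - r0)^2)` and axial
#' resistance `Ra L / (pi r0 r1)`. Voltages are solved at the nodes; each
#' node's membrane conductance collects half of every adjacent frustum's
#' area. Zero-length edges are merged into their parent node with a
#' warning. Requires a single-rooted tree (connect fragments first).
#'
#' @param m a single-tree `morphology`.
#' @param params a `passive_params`.
#' @return a `cable_model`: node table, axial conductances (S), membrane
#'   conductances (S), total membrane area (um^2).
#' @export
build_cable <- function(m, params = passive_params()) {
  m <- validate_morphology(m)
  if (length(morph_roots(m)) != 1L)
    stop("cable model needs a single-rooted tree; connect fragments first")
  nd <- m$nodes
  # merge zero-length edges (child takes over parent's identity)
  pos <- match(nd$parent, nd$id)
  has <- which(!is.na(pos))
  L <- sqrt((nd$x[has] - nd$x[pos[has]])^2 + (nd$y[has] - nd$y[pos[has]])^2 +
            (nd$z[has] - nd$z[pos[has]])^2)
  zero <- has[L == 0]
  if (length(zero)) {
    warning(length(zero), " zero-length edge(s) merged with their parent")
    for (row in zero) {
      gone <- nd$id[row]
      keepid <- nd$parent[row]
      nd$parent[nd$parent == gone] <- keepid
      nd <- nd[nd$id != gone, , drop = FALSE]
    }
    m <- validate_morphology(morphology(nd))
    nd <- m$nodes
    pos <- match(nd$parent, nd$id)
    has <- which(!is.na(pos))
    L <- sqrt((nd$x[has] - nd$x[pos[has]])^2 + (nd$y[has] - nd$y[pos[has]])^2 +
              (nd$z[has] - nd$z[pos[has]])^2)
  }
  r0 <- nd$radius[pos[has]]   # um
  r1 <- nd$radius[has]
  slant <- sqrt(L^2 + (r1 - r0)^2)
  area <- pi * (r0 + r1) * slant                  # um^2
  Ra_um <- params$Ra * 1e4                        # Ohm cm -> Ohm um
  R_ax <- Ra_um * L / (pi * r0 * r1)              # Ohm
  g_ax <- 1 / R_ax                                # S
  Rm_um2 <- params$Rm * 1e8                       # Ohm cm^2 -> Ohm um^2
  # membrane conductance per node: half of each adjacent edge's area
  g_m <- numeric(nrow(nd))
  half <- area / 2 / Rm_um2
  g_m[has] <- g_m[has] + half
  for (e in seq_along(has)) g_m[pos[has[e]]] <- g_m[pos[has[e]]] + half[e]
  structure(list(nodes = nd, edge_child = has, edge_parent = pos[has],
                 g_axial = g_ax, g_membrane = g_m, area = area,
                 total_area = sum(area), params = params),
            class = "cable_model")
}

#' Steady-state voltages under current injection
#'
#' Solves the sparse symmetric positive-definite conductance system
#' `(L_axial + diag(g_m)) v = i` for the steady deflection from rest, with
#' `I_inject` nA entering at the injection node (the root by default).
#'
#' @param model a `cable_model`.
#' @param I_inject injected current, nA.
#' @param inject_node node id of the injection site (default: root).
#' @return numeric vector of membrane potentials (mV), named by node id;
#'   attribute `"input_resistance"` in MOhm.
#' @export
steady_state <- function(model, I_inject, inject_node = NULL) {
  stopifnot(inherits(model, "cable_model"))
  nd <- model$nodes
  n <- nrow(nd)
  inj <- if (is.null(inject_node)) which(nd$parent == -1L)
         else match(inject_node, nd$id)
  if (is.na(inj)) stop("injection node not found")
  ii <- c(model$edge_child, model$edge_parent, model$edge_child,
          model$edge_parent, seq_len(n))
  jj <- c(model$edge_parent, model$edge_child, model$edge_child,
          model$edge_parent, seq_len(n))
  xx <- c(-model$g_axial, -model$g_axial, model$g_axial, model$g_axial,
          model$g_membrane)
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  rhs <- numeric(n)
  rhs[inj] <- I_inject * 1e-9                    # nA -> A
  v <- as.numeric(Matrix::solve(G, rhs))         # volts
  out <- model$params$E_rest + v * 1e3           # mV
  names(out) <- nd$id
  attr(out, "input_resistance") <- if (I_inject != 0)
    (v[inj] / (I_inject * 1e-9)) / 1e6 else NA_real_   # MOhm
  out
}

#' Transient step response of a passive cable
#'
#' Backward-Euler integration of `C dv/dt = -G v + i` for a current step
#' switched on at `t = 0`, with per-node capacitance `Cm * area / 2` pooled
#' like the membrane conductance. Under a purely passive membrane the
#' transient adds only time constants to the steady-state picture, so this
#' mode exists for completeness and convergence checks.
#'
#' @param model a `cable_model`.
#' @param I_inject current step amplitude, nA, at the root.
#' @param t_end simulated time, s.
#' @param dt time step, s (default 25 us).
#' @param record node ids to record (default: all tips and the root).
#' @return data.frame with `time` (s) and one mV column per recorded node.
#' @export
transient_response <- function(model, I_inject, t_end = 0.05, dt = 25e-6,
                               record = NULL) {
  stopifnot(inherits(model, "cable_model"))
  nd <- model$nodes
  n <- nrow(nd)
  ii <- c(model$edge_child, model$edge_parent, model$edge_child,
          model$edge_parent, seq_len(n))
  jj <- c(model$edge_parent, model$edge_child, model$edge_child,
          model$edge_parent, seq_len(n))
  xx <- c(-model$g_axial, -model$g_axial, model$g_axial, model$g_axial,
          model$g_membrane)
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # nodal capacitance: uF/cm^2 -> F/um^2 is 1e-14
  cap <- numeric(n)
  half_c <- model$params$Cm * 1e-14 * model$area / 2
  cap[model$edge_child] <- cap[model$edge_child] + half_c
  for (e in seq_along(model$edge_child))
    cap[model$edge_parent[e]] <- cap[model$edge_parent[e]] + half_c[e]
  inj <- which(nd$parent == -1L)
  rhs_i <- numeric(n)
  rhs_i[inj] <- I_inject * 1e-9
  A <- G + Matrix::Diagonal(n, cap / dt)
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  if (is.null(record)) record <- c(nd$id[inj], morph_tips(
    structure(list(nodes = nd), class = "morphology")))
  rec_idx <- match(record, nd$id)
  steps <- ceiling(t_end / dt)
  v <- numeric(n)
  out <- matrix(0, steps + 1L, length(rec_idx))
  for (s in seq_len(steps)) {
    v <- as.numeric(Matrix::solve(fac, rhs_i + cap / dt * v))
    out[s + 1L, ] <- v[rec_idx]
  }
  res <- data.frame(time = (0:steps) * dt)
  res[sprintf("node_%d", record)] <- model$params$E_rest + out * 1e3
  res
}

#' Electrical response error between two morphologies
#'
#' The passive-model validation: both trees are compartmentalized under the
#' same parameters, driven by the same steady current at their roots, and
#' compared at their tips. Tips are matched by nearest Euclidean pairing
#' (each test tip to its closest reference tip); the error is the mean
#' relative deflection difference `|V_test - V_gt| / |V_gt - E_rest|` over
#' matched tips. The relative input-resistance error is reported alongside.
#'
#' @param gt reference `morphology`.
#' @param test compared `morphology`.
#' @param params a `passive_params`.
#' @param I injected current, nA.
#' @return list with `tip_error`, `input_resistance_error`, `n_matched`,
#'   `Rin_gt`, `Rin_test` (MOhm).
#' @export
response_error <- function(gt, test, params = passive_params(), I = 0.1) {
  vg <- steady_state(build_cable(gt, params), I)
  vt <- steady_state(build_cable(test, params), I)
  tips_g <- as.character(morph_tips(gt))
  tips_t <- as.character(morph_tips(test))
  if (!length(tips_g) || !length(tips_t))
    stop("both morphologies need at least one tip")
  Pg <- morph_xyz(gt)[match(as.integer(tips_g), gt$nodes$id), , drop = FALSE]
  Pt <- morph_xyz(test)[match(as.integer(tips_t), test$nodes$id), , drop = FALSE]
  nn <- nn_match(Pt, Pg)
  dg <- vg[tips_g] - params$E_rest
  dt <- vt[tips_t] - params$E_rest
  err <- abs(dt - dg[nn$index]) / abs(dg[nn$index])
  rin_g <- attr(vg, "input_resistance")
  rin_t <- attr(vt, "input_resistance")
  list(tip_error = mean(err),
       input_resistance_error = abs(rin_t - rin_g) / rin_g,
       n_matched = length(err), Rin_gt = rin_g, Rin_test = rin_t)
}
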