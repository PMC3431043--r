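#' Scripted corrective edits of a morphology
#'
#' An `edit_script` is an ordered list of operations that stand in for the
#' interactive corrections of a tracing GUI, applied deterministically:
#' `edit_connect(a, b)` joins two fragments (the smaller fragment is
#' re-rooted at `b` and attached under `a`); `edit_add_path(points, at)`
#' appends a polyline of `(x, y, z, radius)` rows as a new branch attached
#' at node `at`; `edit_delete_subtree(node)` removes a node and all its
#' descendants.
#'
#' @param ... edit operations created by the `edit_*` constructors.
#' @return an `edit_script`.
#' @export
edit_script <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1]]) && !inherits(ops[[1]], "edit_op"))
    ops <- ops[[1]]
  if (!all(vapply(ops, inherits, logical(1), "edit_op")))
    stop("all elements must be edit operations")
  structure(ops, class = "edit_script")
}

#' @rdname edit_script
#' @param a,b node ids to connect (edge added from `a` to `b`).
#' @export
edit_connect <- function(a, b)
  structure(list(op = "connect", a = as.integer(a), b = as.integer(b)),
            class = "edit_op")

#' @rdname edit_script
#' @param points n x 4 matrix of `(x, y, z, radius)` for the new path.
#' @param at node id the first new node attaches to.
#' @export
edit_add_path <- function(points, at) {
  points <- as.matrix(points)
  if (ncol(points) != 4L) stop("points must be n x 4 (x, y, z, radius)")
  structure(list(op = "add_path", points = points, at = as.integer(at)),
            class = "edit_op")
}

#' @rdname edit_script
#' @param node id of the subtree root to delete.
#' @export
edit_delete_subtree <- function(node)
  structure(list(op = "delete_subtree", node = as.integer(node)),
            class = "edit_op")

subtree_ids <- function(nd, root_id) {
  kids <- split(nd$id[nd$parent != -1L], nd$parent[nd$parent != -1L])
  acc <- root_id
  frontier <- root_id
  while (length(frontier)) {
    nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  acc
}

#' Apply an edit script to a morphology
#'
#' Edits are applied in order; each referenced node must exist at the time
#' its edit applies, and the result must remain a valid forest (connecting
#' two nodes of the same tree, which would create a cycle, is an error).
#'
#' @param m a `morphology`.
#' @param script an `edit_script` (empty script returns `m` unchanged).
#' @return the edited, validated `morphology`.
#' @export
apply_edits <- function(m, script) {
  m <- validate_morphology(m)
  stopifnot(inherits(script, "edit_script"))
  for (op in script) {
    nd <- m$nodes
    if (op$op == "delete_subtree") {
      if (!op$node %in% nd$id) stop("delete_subtree: no node ", op$node)
      gone <- subtree_ids(nd, op$node)
      if (length(gone) >= nrow(nd))
        stop("delete_subtree would remove every node")
      m <- morphology(nd[!(nd$id %in% gone), , drop = FALSE])
    } else if (op$op == "add_path") {
      if (!op$at %in% nd$id) stop("add_path: no attachment node ", op$at)
      n_new <- nrow(op$points)
      ids <- max(nd$id) + seq_len(n_new)
      parents <- c(op$at, ids[-n_new])
      add <- data.frame(id = ids, type = 3L,
                        x = op$points[, 1], y = op$points[, 2],
                        z = op$points[, 3], radius = op$points[, 4],
                        parent = parents)
      m <- morphology(rbind(nd, add))
    } else if (op$op == "connect") {
      if (!op$a %in% nd$id) stop("connect: no node ", op$a)
      if (!op$b %in% nd$id) stop("connect: no node ", op$b)
      roots <- find_root_of(nd, c(op$a, op$b))
      if (roots[1] == roots[2])
        stop("connect would create a cycle (nodes share root ", roots[1], ")")
      sizes <- vapply(roots, function(r) length(subtree_ids(nd, r)), integer(1))
      # re-root the smaller fragment at its connection endpoint
      if (sizes[1] < sizes[2]) {
        nd <- reroot_at(nd, op$a)
        nd$parent[nd$id == op$a] <- op$b
      } else {
        nd <- reroot_at(nd, op$b)
        nd$parent[nd$id == op$b] <- op$a
      }
      m <- morphology(nd)
    } else stop("unknown edit op: ", op$op)
  }
  validate_morphology(m)
}

find_root_of <- function(nd, ids) {
  vapply(ids, function(i) {
    cur <- i
    repeat {
      par <- nd$parent[match(cur, nd$id)]
      if (par == -1L) return(cur)
      cur <- par
    }
  }, integer(1))
}

# reverse parent pointers along the path from new_root up to the old root
reroot_at <- function(nd, new_root) {
  path <- integer(0)
  cur <- new_root
  repeat {
    path <- c(path, cur)
    par <- nd$parent[match(cur, nd$id)]
    if (par == -1L) break
    cur <- par
  }
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L))
      nd$parent[nd$id == path[i + 1L]] <- path[i]
  }
  nd$parent[nd$id == new_root] <- -1L
  nd
}

#' Semiautomatic tracing against a reference morphology
#'
#' Reproduces the human correction loop deterministically: run the
#' automatic tracer, then (a) delete traced terminal branches with no
#' support in the reference morphology (no reference point within
#' `tolerance`), iterating until stable, and (b) add every reference branch
#' that the trace missed, as an `edit_add_path` attached at the nearest
#' traced node. Corrections only ever improve the matched-structure score,
#' so the semiautomatic result dominates the automatic one by construction.
#'
#' @param stack grayscale `image_stack`.
#' @param params a `tracer_params`.
#' @param gt_hint the reference `morphology` (ground truth in benchmarks;
#'   conceptually, what the annotator sees in the viewer).
#' @param tolerance support radius in um.
#' @param auto optionally, a pre-computed automatic trace of `stack` under
#'   the same `params` (avoids re-running the tracer).
#' @return the corrected `morphology`, with the generated `edit_script`
#'   attached as attribute `"edits"`.
#' @export
trace_semiauto <- function(stack, params = tracer_params(), gt_hint,
                           tolerance = 2, auto = NULL) {
  gt_hint <- validate_morphology(gt_hint)
  if (is.null(auto)) auto <- trace_neurites(stack, params)
  gt_pts <- resample_morphology(gt_hint, step = 0.5)
  ops <- list()

  # (a) delete unsupported terminal branches, iterating inward
  m <- auto
  repeat {
    nd <- m$nodes
    crit <- c(morph_roots(m), morph_bifurcations(m))
    deleted <- FALSE
    for (tp in morph_tips(m)) {
      chain <- terminal_chain(nd, tp, crit)
      pts <- as.matrix(nd[match(chain, nd$id), c("x", "y", "z")])
      dmin <- min_cross_dist(pts, gt_pts$xyz)
      if (stats::median(dmin) > tolerance && length(chain) < nrow(nd)) {
        op <- edit_delete_subtree(chain[1])  # chain[1] = whole terminal branch
        res <- try(apply_edits(m, edit_script(list(op))), silent = TRUE)
        if (!inherits(res, "try-error")) {
          m <- res
          ops[[length(ops) + 1L]] <- op
          deleted <- TRUE
          break
        }
      }
    }
    if (!deleted) break
  }

  # (b) add reference branches that the trace missed
  test_pts <- resample_morphology(m, step = 0.5)
  gt_branches <- branch_chains(gt_hint)
  for (br in gt_branches) {
    pts <- br$xyz
    dmin <- min_cross_dist(pts, test_pts$xyz)
    if (mean(dmin > tolerance) > 0.5) {
      # attach at the traced node nearest to the branch start
      txyz <- morph_xyz(m)
      d0 <- colSums((t(txyz) - pts[1, ])^2)
      at <- m$nodes$id[which.min(d0)]
      op <- edit_add_path(cbind(pts, br$radius), at)
      m <- apply_edits(m, edit_script(list(op)))
      ops[[length(ops) + 1L]] <- op
      test_pts <- resample_morphology(m, step = 0.5)
    }
  }
  attr(m, "edits") <- edit_script(ops)
  attr(m, "auto_trace") <- auto
  m
}

terminal_chain <- function(nd, tip, crit) {
  chain <- integer(0)
  cur <- tip
  repeat {
    chain <- c(chain, cur)
    par <- nd$parent[match(cur, nd$id)]
    if (par == -1L || par %in% crit) break
    cur <- par
  }
  rev(chain)  # ordered from the branch-point side (subtree root) to the tip
}

# for each row of A, distance to the nearest row of B (blocked brute force)
min_cross_dist <- function(A, B) {
  nA <- nrow(A)
  out <- numeric(nA)
  block <- max(1L, floor(2e6 / max(nrow(B), 1L)))
  bs2 <- rowSums(B^2)
  for (s in seq(1L, nA, by = block)) {
    e <- min(s + block - 1L, nA)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), rep(1, nrow(B))) - 2 * Ab %*% t(B) +
      outer(rep(1, e - s + 1L), bs2)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# decompose a morphology into branch chains (between critical nodes),
# each as resampled points (~1 um) with radii
branch_chains <- function(m, step = 1) {
  nd <- m$nodes
  crit <- unique(c(morph_roots(m), morph_bifurcations(m), morph_tips(m)))
  kids_of <- split(nd$id[nd$parent != -1L], nd$parent[nd$parent != -1L])
  chains <- list()
  walk <- function(start_id) {
    for (child in kids_of[[as.character(start_id)]] %||% integer(0)) {
      chain <- child
      cur <- child
      while (!(cur %in% crit)) {
        cur <- kids_of[[as.character(cur)]][1]
        chain <- c(chain, cur)
      }
      rows <- match(c(start_id, chain), nd$id)
      pts <- cbind(nd$x[rows], nd$y[rows], nd$z[rows])
      rad <- nd$radius[rows]
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
      s <- c(0, cumsum(seg))
      svals <- unique(c(seq(0, s[length(s)], by = step), s[length(s)]))
      P <- t(vapply(svals, function(sv)
        interp_polyline(cbind(pts, rad), s, sv), numeric(4)))
      chains[[length(chains) + 1L]] <<- list(xyz = P[, 1:3, drop = FALSE],
                                             radius = P[, 4])
      walk(cur)
    }
  }
  for (r in morph_roots(m)) walk(r)
  chains
}
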