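#' Neuron morphology as a rooted tree of 3D nodes
#'
#' A `morphology` holds the node table of an SWC-style reconstruction:
#' one row per node with columns `id`, `type`, `x`, `y`, `z` (um), `radius`
#' (um) and `parent` (`-1` for a root). The table is kept topologically
#' sorted so that every parent precedes its children; ids are arbitrary
#' positive integers and are preserved verbatim, as is the SWC `type` code
#' (the type codes in use for insect neurons are not standardized, so they
#' are carried but never interpreted).
#'
#' @param nodes data.frame with columns `id, type, x, y, z, radius, parent`.
#' @param validate validate structural invariants (default `TRUE`).
#' @return An object of class `morphology`.
#' @export
morphology <- function(nodes, validate = TRUE) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(need %in% names(nodes)))
    stop("nodes must be a data.frame with columns ", paste(need, collapse = ", "))
  nodes <- nodes[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  for (cc in c("x", "y", "z", "radius")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  rownames(nodes) <- NULL
  m <- structure(list(nodes = nodes), class = "morphology")
  if (validate) validate_morphology(m)
  m
}

#' Validate a morphology
#'
#' Checks the structural invariants of the node table: unique positive ids,
#' finite coordinates, strictly positive radii, all parents present, no
#' cycles (the graph is a forest) and topological order. Out-of-order but
#' otherwise valid tables are re-sorted rather than rejected.
#'
#' @param m a `morphology`.
#' @return `m`, topologically sorted, invisibly on success; errors otherwise.
#' @export
validate_morphology <- function(m) {
  if (!inherits(m, "morphology")) stop("expected a morphology")
  nd <- m$nodes
  if (nrow(nd) == 0L) stop("morphology has no nodes")
  if (anyDuplicated(nd$id)) stop("duplicate node ids: ",
                                 paste(unique(nd$id[duplicated(nd$id)]), collapse = ", "))
  if (any(nd$id <= 0L)) stop("node ids must be positive integers")
  if (any(!is.finite(nd$x) | !is.finite(nd$y) | !is.finite(nd$z)))
    stop("non-finite node coordinates")
  if (any(!is.finite(nd$radius) | nd$radius <= 0))
    stop("all radii must be strictly positive and finite")
  nonroot <- nd$parent != -1L
  if (!any(!nonroot)) stop("morphology has no root (parent -1)")
  missing_par <- setdiff(nd$parent[nonroot], nd$id)
  if (length(missing_par))
    stop("dangling parent id(s): ", paste(missing_par, collapse = ", "))
  # cycle check + topological sort by BFS from the roots
  ord <- topo_order(nd)
  if (length(ord) != nrow(nd))
    stop("cycle detected: ", nrow(nd) - length(ord), " node(s) unreachable from any root")
  pos <- match(nd$parent, nd$id)
  already_sorted <- all(is.na(pos) | pos < seq_len(nrow(nd)))
  if (!already_sorted) {  # re-sort only when the input order is invalid
    m$nodes <- nd[ord, , drop = FALSE]
    rownames(m$nodes) <- NULL
  }
  invisible(m)
}

topo_order <- function(nd) {
  idx <- seq_len(nrow(nd))
  pos <- match(nd$parent, nd$id)  # NA for roots
  children <- split(idx, factor(pos, levels = idx))
  ord <- integer(0)
  frontier <- idx[nd$parent == -1L]
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
  }
  ord
}

#' @export
print.morphology <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("morphology: %d nodes, %d root(s), %d tip(s), %d bifurcation(s)\n",
              nrow(nd), sum(nd$parent == -1L), length(morph_tips(x)),
              length(morph_bifurcations(x))))
  cat(sprintf("  total cable length %.2f um, radius range [%.3g, %.3g] um\n",
              cable_length(x), min(nd$radius), max(nd$radius)))
  invisible(x)
}

#' Basic morphology measurements
#'
#' `cable_length` is the summed Euclidean length of all parent-child edges
#' (um). `morph_tips` and `morph_bifurcations` return node ids of degree-1
#' leaves and of nodes with 2 or more children. `morph_roots` returns root ids.
#'
#' @param m a `morphology`.
#' @export
cable_length <- function(m) {
  nd <- m$nodes
  pos <- match(nd$parent, nd$id)
  has <- !is.na(pos)
  if (!any(has)) return(0)
  dx <- nd$x[has] - nd$x[pos[has]]
  dy <- nd$y[has] - nd$y[pos[has]]
  dz <- nd$z[has] - nd$z[pos[has]]
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' @rdname cable_length
#' @export
morph_tips <- function(m) {
  nd <- m$nodes
  nd$id[!(nd$id %in% nd$parent)]
}

#' @rdname cable_length
#' @export
morph_bifurcations <- function(m) {
  nd <- m$nodes
  tab <- table(nd$parent[nd$parent != -1L])
  as.integer(names(tab)[tab >= 2L])
}

#' @rdname cable_length
#' @export
morph_roots <- function(m) m$nodes$id[m$nodes$parent == -1L]

#' Node coordinates as a matrix
#' @param m a `morphology`.
#' @return n x 3 matrix of `(x, y, z)` in um.
#' @export
morph_xyz <- function(m) as.matrix(m$nodes[, c("x", "y", "z")])

#' Read an SWC morphology file
#'
#' Parses the plain-text 7-column SWC dialect: lines are either `#` comments,
#' blank, or `id type x y z radius parent`. Forward references (a child
#' listed before its parent) are tolerated and fixed by topological
#' re-sorting; duplicate ids, dangling parents and cycles are errors.
#' Coordinates and radii are in um.
#'
#' @param path file path.
#' @return a validated `morphology`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("SWC file has no data lines: ", path)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("malformed SWC line %d (expected 7 fields, got %d): %s",
                 keep[bad[1]], length(fields[[bad[1]]]), lines[keep[bad[1]]]))
  num <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 7, byrow = TRUE)
  if (anyNA(num)) {
    row <- which(apply(is.na(num), 1, any))[1]
    stop(sprintf("non-numeric field on SWC line %d: %s", keep[row], lines[keep[row]]))
  }
  nd <- data.frame(id = num[, 1], type = num[, 2], x = num[, 3], y = num[, 4],
                   z = num[, 5], radius = num[, 6], parent = num[, 7])
  validate_morphology(morphology(nd, validate = FALSE))
}

#' Write a morphology to SWC
#'
#' Emits the 7-column whitespace format with a short provenance header;
#' `read_swc` inverts it exactly (node table round-trips field-by-field).
#'
#' @param m a valid `morphology`.
#' @param path output file path.
#' @export
write_swc <- function(m, path) {
  m <- validate_morphology(m)
  nd <- m$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC neuron morphology",
               sprintf("# written by mothatlas %s on %s",
                       as.character(utils::packageVersion("mothatlas")),
                       format(Sys.time(), "%Y-%m-%d")),
               "# id type x y z radius parent"), con)
  # %.17g preserves doubles exactly, keeping the round-trip bit-exact
  writeLines(sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                     nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent), con)
  invisible(path)
}
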