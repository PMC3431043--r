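#' Resample a morphology to a dense arc-length point chain
#'
#' Every parent-child edge is subdivided into pieces of at most `step` um;
#' each piece contributes one point at its midpoint carrying the piece
#' length as weight and the linearly interpolated diameter. This
#' length-weighted chain is the common currency of the tracing metrics.
#'
#' @param m a `morphology`.
#' @param step maximum piece length, um.
#' @return list with `xyz` (n x 3), `weight` (piece lengths, um),
#'   `diameter` (um).
#' @export
resample_morphology <- function(m, step = 0.5) {
  nd <- m$nodes
  pos <- match(nd$parent, nd$id)
  has <- which(!is.na(pos))
  if (!length(has)) {
    # single node(s): represent each as one zero-length point
    return(list(xyz = as.matrix(nd[, c("x", "y", "z")]),
                weight = rep(0, nrow(nd)), diameter = 2 * nd$radius))
  }
  P0 <- as.matrix(nd[pos[has], c("x", "y", "z")])
  P1 <- as.matrix(nd[has, c("x", "y", "z")])
  r0 <- nd$radius[pos[has]]
  r1 <- nd$radius[has]
  L <- sqrt(rowSums((P1 - P0)^2))
  nsub <- pmax(1L, ceiling(L / step))
  idx <- rep(seq_along(has), nsub)
  # midpoint parameters of the nsub pieces of each edge
  t_ <- unlist(lapply(nsub, function(k) (seq_len(k) - 0.5) / k))
  xyz <- P0[idx, , drop = FALSE] + (P1 - P0)[idx, , drop = FALSE] * t_
  list(xyz = xyz,
       weight = (L / nsub)[idx],
       diameter = 2 * (r0[idx] + (r1 - r0)[idx] * t_))
}

#' Branch-structure consistency and diameter discrepancy
#'
#' Length-weighted bidirectional point-match score of a traced morphology
#' against a reference. Both trees are resampled to arc-length chains
#' (pieces <= 0.5 um); `c_miss` is the fraction of reference cable length
#' with a test point within `tau` (1 - c_miss measures missed existing
#' branches), `c_false` the fraction of test cable length with a reference
#' point within `tau` (1 - c_false measures falsely detected branches),
#' and `consistency` their mean. Diameter discrepancy is the mean relative
#' diameter error `|d_test - d_gt| / d_gt` over matched reference points.
#' An empty or `NULL` test morphology scores consistency 0 (a null answer
#' earns no half-credit).
#'
#' @param gt reference `morphology`.
#' @param test traced `morphology`, or `NULL` for an empty extraction.
#' @param tau match tolerance, um (> 0); default 2 um, about one z-step.
#' @return a `consistency_report` list: `c_miss`, `c_false`, `consistency`,
#'   `diameter_discrepancy`, `tau`, `matched_gt_length`, `gt_length`,
#'   `test_length`.
#' @export
consistency <- function(gt, test, tau = 2) {
  if (tau <= 0) stop("tau must be > 0")
  gt <- validate_morphology(gt)
  gt_ch <- resample_morphology(gt, 0.5)
  gt_len <- sum(gt_ch$weight)
  empty <- is.null(test) || nrow(test$nodes) == 0L
  if (!empty) test <- validate_morphology(test)
  if (empty) {
    return(structure(list(c_miss = 0, c_false = 0, consistency = 0,
                          diameter_discrepancy = NA_real_, tau = tau,
                          matched_gt_length = 0, gt_length = gt_len,
                          test_length = 0),
                     class = "consistency_report"))
  }
  te_ch <- resample_morphology(test, 0.5)
  nn_gt <- nn_match(gt_ch$xyz, te_ch$xyz)     # for each gt point: index+dist in test
  nn_te <- nn_match(te_ch$xyz, gt_ch$xyz)
  gt_hit <- nn_gt$dist <= tau
  te_hit <- nn_te$dist <= tau
  c_miss <- sum(gt_ch$weight[gt_hit]) / sum(gt_ch$weight)
  c_false <- if (sum(te_ch$weight) > 0)
    sum(te_ch$weight[te_hit]) / sum(te_ch$weight) else 0
  disc <- if (any(gt_hit)) {
    d_gt <- gt_ch$diameter[gt_hit]
    d_te <- te_ch$diameter[nn_gt$index[gt_hit]]
    stats::weighted.mean(abs(d_te - d_gt) / d_gt, gt_ch$weight[gt_hit])
  } else NA_real_
  structure(list(c_miss = c_miss, c_false = c_false,
                 consistency = (c_miss + c_false) / 2,
                 diameter_discrepancy = disc, tau = tau,
                 matched_gt_length = sum(gt_ch$weight[gt_hit]),
                 gt_length = gt_len, test_length = sum(te_ch$weight)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency %.3f (miss-side %.3f, false-side %.3f) at tau = %g um\n",
              x$consistency, x$c_miss, x$c_false, x$tau))
  cat(sprintf("  diameter discrepancy %.3f; cable %0.1f / %0.1f um (gt/test)\n",
              x$diameter_discrepancy, x$gt_length, x$test_length))
  invisible(x)
}

# nearest neighbour of each row of A among rows of B (blocked brute force)
nn_match <- function(A, B) {
  nA <- nrow(A)
  index <- integer(nA)
  dist <- numeric(nA)
  bs2 <- rowSums(B^2)
  block <- max(1L, floor(2e6 / max(nrow(B), 1L)))
  for (s in seq(1L, nA, by = block)) {
    e <- min(s + block - 1L, nA)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), rep(1, nrow(B))) - 2 * Ab %*% t(B) +
      outer(rep(1, e - s + 1L), bs2)
    w <- max.col(-d2, ties.method = "first")
    index[s:e] <- w
    dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), w)], 0))
  }
  list(index = index, dist = dist)
}

#' Landmark positional variability across samples
#'
#' For each sample landmark set, the Euclidean distance of every shared
#' landmark to the base set; reported per landmark and per sample with the
#' grand mean and standard deviation. This is the statistic used to show
#' that the average brain minimizes inter-individual landmark distance.
#'
#' @param base `landmark_set` used as reference.
#' @param others list of `landmark_set` samples.
#' @return a `landmark_error_report`: `table` (sample, name, distance),
#'   `per_landmark` means, `mean`, `sd`.
#' @export
landmark_error <- function(base, others) {
  stopifnot(inherits(base, "landmark_set"), is.list(others), length(others) >= 1L)
  rows <- list()
  for (s in seq_along(others)) {
    p <- pair_landmarks(base, others[[s]], min_pairs = 1L)
    d <- sqrt(rowSums((p$src - p$dst)^2))
    rows[[s]] <- data.frame(sample = s, name = p$names, distance = d)
  }
  tb <- do.call(rbind, rows)
  if (!nrow(tb)) stop("no shared landmark names between base and samples")
  structure(list(table = tb,
                 per_landmark = tapply(tb$distance, tb$name, mean),
                 mean = mean(tb$distance),
                 sd = stats::sd(tb$distance)),
            class = "landmark_error_report")
}

#' @export
print.landmark_error_report <- function(x, ...) {
  cat(sprintf("landmark error over %d samples x %d landmarks: %.2f +/- %.2f um\n",
              length(unique(x$table$sample)), length(x$per_landmark),
              x$mean, x$sd))
  invisible(x)
}

#' Registration error at held-out distinct points
#'
#' The evaluation protocol for landmark registration: a set of fitting
#' landmarks drives the transform, while named *distinct points* (e.g.
#' CCB, RMC, LMC, RMP, LMP) held out of the fit measure the true error --
#' the Euclidean distance of each distinct point to its standard-brain
#' position before and after registration.
#'
#' @param point_names character vector of distinct-point names.
#' @param standard `landmark_set` of distinct points in the standard brain.
#' @param sample_before the same points in the unregistered sample.
#' @param sample_after the same points after registration.
#' @return data.frame with `name`, `before`, `after`, `improvement` (um).
#' @export
registration_error <- function(point_names, standard, sample_before,
                               sample_after) {
  get_pts <- function(lm, what) {
    key <- toupper(lm$name)
    miss <- setdiff(toupper(point_names), key)
    if (length(miss))
      stop("missing distinct point(s) in ", what, ": ", paste(miss, collapse = ", "))
    as.matrix(lm[match(toupper(point_names), key), c("x", "y", "z")])
  }
  S <- get_pts(standard, "standard")
  B <- get_pts(sample_before, "sample_before")
  A <- get_pts(sample_after, "sample_after")
  before <- sqrt(rowSums((B - S)^2))
  after <- sqrt(rowSums((A - S)^2))
  data.frame(name = point_names, before = before, after = after,
             improvement = before - after)
}
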