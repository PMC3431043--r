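#' Named anatomical landmark set
#'
#' A `landmark_set` is a table of named 3D reference points in physical um
#' coordinates, e.g. the five-point brain alignment scheme CCB (centre of
#' the central body), RMC/LMC (right/left mushroom-body calyx centres) and
#' RAL/LAL (right/left antennal-lobe centres). Landmarks are paired across
#' files by name (case-insensitively), never by row order.
#'
#' @param name character vector of unique, non-empty names.
#' @param x,y,z numeric coordinates in um.
#' @return An object of class `landmark_set` (a data.frame).
#' @export
landmark_set <- function(name, x, y, z) {
  name <- as.character(name)
  if (any(!nzchar(name))) stop("landmark names must be non-empty")
  if (anyDuplicated(toupper(name)))
    stop("duplicate landmark name(s): ",
         paste(unique(name[duplicated(toupper(name))]), collapse = ", "))
  xyz <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (nrow(xyz) != length(name)) stop("name and coordinates differ in length")
  if (any(!is.finite(xyz))) stop("landmark coordinates must be finite")
  structure(data.frame(name = name, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

#' Read landmarks from CSV
#'
#' Expects a header `name,x,y,z` with coordinates in um.
#'
#' @param path CSV file path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tb) <- tolower(names(tb))
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(tb)))
    stop("landmark CSV must have columns name,x,y,z; got: ",
         paste(names(tb), collapse = ","))
  if (nrow(tb) < 1L) stop("landmark CSV has no rows")
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tb[[cc]]))
    if (anyNA(v)) stop("non-numeric coordinate in column ", cc)
    tb[[cc]] <- v
  }
  landmark_set(tb$name, tb$x, tb$y, tb$z)
}

#' Write landmarks to CSV
#' @param lm a `landmark_set`.
#' @param path output path.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  utils::write.csv(as.data.frame(lm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair two landmark sets by name
#'
#' Matches names case-insensitively and returns the shared landmarks as two
#' aligned coordinate matrices.
#'
#' @param src,dst `landmark_set` objects.
#' @param min_pairs minimum number of shared names required.
#' @return list with `names`, `src` and `dst` (n x 3 matrices).
#' @export
pair_landmarks <- function(src, dst, min_pairs = 3L) {
  stopifnot(inherits(src, "landmark_set"), inherits(dst, "landmark_set"))
  key_s <- toupper(src$name)
  key_d <- toupper(dst$name)
  shared <- intersect(key_s, key_d)
  if (length(shared) < min_pairs)
    stop(sprintf("need at least %d shared landmark names, found %d",
                 min_pairs, length(shared)))
  is_ <- match(shared, key_s)
  id_ <- match(shared, key_d)
  list(names = src$name[is_],
       src = as.matrix(src[is_, c("x", "y", "z")]),
       dst = as.matrix(dst[id_, c("x", "y", "z")]))
}

landmark_xyz <- function(lm) as.matrix(lm[, c("x", "y", "z")])
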