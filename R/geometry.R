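#' Build a distance matrix from antenna center coordinates
#'
#' Computes pairwise planar Euclidean distances between antenna center points.
#' Antennas are treated as points at their reading-area centers; the vertical
#' dimension is ignored.
#'
#' @param coords A numeric matrix with two columns (x, y in meters) and one
#'   named row per location, or a named list of length-2 numeric vectors.
#' @return A symmetric numeric matrix of distances in meters with zero
#'   diagonal, dimnames set to the location ids.
#' @examples
#' distance_matrix_from_coords(list(A = c(0, 0), B = c(3, 4)))
#' @export
distance_matrix_from_coords <- function(coords) {
  coords <- as_coord_matrix(coords)
  m <- as.matrix(stats::dist(coords, method = "euclidean"))
  dimnames(m) <- list(rownames(coords), rownames(coords))
  m
}

as_coord_matrix <- function(coords) {
  if (is.list(coords) && !is.data.frame(coords)) {
    ids <- names(coords)
    if (is.null(ids) || any(ids == "")) {
      stop("all locations must be named", call. = FALSE)
    }
    bad <- ids[!vapply(coords, function(p) is.numeric(p) && length(p) == 2 && all(is.finite(p)), logical(1))]
    if (length(bad)) {
      stop("missing or invalid coordinates for location(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    coords <- do.call(rbind, coords)
    rownames(coords) <- ids
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coordinates must be two-dimensional (x, y)", call. = FALSE)
  if (is.null(rownames(coords))) stop("all locations must be named", call. = FALSE)
  if (anyNA(coords) || any(!is.finite(coords))) {
    bad <- rownames(coords)[!apply(is.finite(coords), 1, all)]
    stop("missing or invalid coordinates for location(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  storage.mode(coords) <- "double"
  coords
}

#' Validate an inter-location distance matrix
#'
#' Checks the metric properties the virtual-walking-distance computation
#' relies on: the matrix must be square with matching dimnames, symmetric,
#' zero on the diagonal, finite and nonnegative, and must satisfy the
#' triangle inequality for every ordered triple of locations. The triangle
#' inequality is what guarantees that dropping readings can never increase a
#' day's computed distance (subsampling monotonicity), so it is checked
#' exhaustively.
#'
#' Violations are reported, not thrown: an invalid matrix yields a nonempty
#' report that the caller can inspect or turn into an error.
#'
#' @param m Square numeric matrix with identical row and column names.
#' @param tol Numeric tolerance in meters used for the symmetry, diagonal and
#'   triangle checks (absorbs floating-point error; default `1e-9`).
#' @return A `data.frame` with columns `type` (one of `"asymmetry"`,
#'   `"negative"`, `"nonfinite"`, `"nonzero_diagonal"`, `"triangle"`),
#'   `i`, `j`, `k` (location ids involved; `k` is `NA` except for triangle
#'   violations) and `detail` (human-readable description). Zero rows if and
#'   only if the matrix is a valid distance matrix.
#' @examples
#' m <- distance_matrix_from_coords(list(A = c(0, 0), B = c(3, 4), C = c(6, 0)))
#' nrow(validate_distance_matrix(m)) # 0: Euclidean matrices are always valid
#' @export
validate_distance_matrix <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  viol <- list()
  add <- function(type, i, j, k = NA_character_, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      type = type, i = i, j = j, k = k, detail = detail,
      stringsAsFactors = FALSE)
  }
  n <- nrow(m)
  for (a in seq_len(n)) {
    if (!is.finite(m[a, a]) || abs(m[a, a]) > tol) {
      add("nonzero_diagonal", ids[a], ids[a],
          detail = sprintf("d(%s,%s) = %g", ids[a], ids[a], m[a, a]))
    }
  }
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (!is.finite(m[a, b])) {
      add("nonfinite", ids[a], ids[b],
          detail = sprintf("d(%s,%s) is not finite", ids[a], ids[b]))
    } else if (m[a, b] < 0) {
      add("negative", ids[a], ids[b],
          detail = sprintf("d(%s,%s) = %g < 0", ids[a], ids[b], m[a, b]))
    }
    if (a < b && is.finite(m[a, b]) && is.finite(m[b, a]) &&
        abs(m[a, b] - m[b, a]) > tol) {
      add("asymmetry", ids[a], ids[b],
          detail = sprintf("d(%s,%s) = %g but d(%s,%s) = %g",
                           ids[a], ids[b], m[a, b], ids[b], ids[a], m[b, a]))
    }
  }
  # exhaustive triangle check over all ordered triples of distinct locations
  if (all(is.finite(m))) {
    for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
      if (a == b || b == cc || a == cc) next
      if (m[a, cc] > m[a, b] + m[b, cc] + tol) {
        add("triangle", ids[a], ids[cc], ids[b],
            detail = sprintf("d(%s,%s) = %g > d(%s,%s) + d(%s,%s) = %g",
                             ids[a], ids[cc], m[a, cc], ids[a], ids[b],
                             ids[b], ids[cc], m[a, b] + m[b, cc]))
      }
    }
  }
  if (!length(viol)) {
    return(data.frame(type = character(), i = character(), j = character(),
                      k = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}
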