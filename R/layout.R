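#' Construct a pen layout
#'
#' A pen layout is the registry of antenna locations in one pen together with
#' their pairwise center-to-center distances. It can be built from planar
#' center coordinates, from an explicit distance matrix, or both. When both
#' are given the explicit matrix takes precedence (it is typically the
#' surveyed/published quantity), and a warning is emitted if it disagrees
#' with the coordinate-derived distances by more than `coord_tol` meters.
#'
#' @param coords Optional named list of `c(x, y)` meter coordinates or a
#'   two-column matrix with named rows.
#' @param distance_matrix Optional square numeric matrix of meters with
#'   identical row/column names.
#' @param coord_tol Disagreement threshold (m) between the explicit matrix
#'   and coordinate-derived distances before a consistency warning; default
#'   0.05 m.
#' @return An object of class `pen_layout`: a list with elements
#'   `locations` (character vector of ids), `coords` (matrix or `NULL`) and
#'   `dist` (the validated distance matrix).
#' @examples
#' pen_layout(coords = list(A = c(0, 0), B = c(3, 4)))
#' @export
pen_layout <- function(coords = NULL, distance_matrix = NULL,
                       coord_tol = 0.05) {
  if (is.null(coords) && is.null(distance_matrix)) {
    stop("a pen layout needs coordinates, a distance matrix, or both",
         call. = FALSE)
  }
  if (!is.null(coords)) coords <- as_coord_matrix(coords)
  if (!is.null(distance_matrix)) {
    m <- as.matrix(distance_matrix)
    if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
    if (is.null(rownames(m)) && !is.null(colnames(m))) rownames(m) <- colnames(m)
    if (is.null(colnames(m)) && !is.null(rownames(m))) colnames(m) <- rownames(m)
    if (is.null(rownames(m))) stop("distance matrix must carry location ids as dimnames", call. = FALSE)
    if (!identical(rownames(m), colnames(m))) {
      stop("distance matrix row and column ids differ", call. = FALSE)
    }
    rep <- validate_distance_matrix(m)
    if (nrow(rep)) {
      stop("invalid distance matrix: ",
           paste(utils::head(rep$detail, 3L), collapse = "; "),
           if (nrow(rep) > 3L) sprintf(" (and %d more)", nrow(rep) - 3L),
           call. = FALSE)
    }
  }
  if (!is.null(coords) && !is.null(distance_matrix)) {
    if (!setequal(rownames(coords), rownames(m))) {
      stop("coordinate and matrix location ids differ", call. = FALSE)
    }
    coords <- coords[rownames(m), , drop = FALSE]
    derived <- distance_matrix_from_coords(coords)
    dev <- max(abs(derived - m))
    if (dev > coord_tol) {
      warning(sprintf(
        "explicit distance matrix disagrees with coordinate-derived distances by up to %.3f m; using the explicit matrix",
        dev), call. = FALSE)
    }
  }
  dmat <- if (!is.null(distance_matrix)) m else distance_matrix_from_coords(coords)
  if (nrow(dmat) < 2L) stop("a pen layout needs at least 2 locations", call. = FALSE)
  structure(
    list(locations = rownames(dmat), coords = coords, dist = dmat),
    class = "pen_layout")
}

#' @export
print.pen_layout <- function(x, ...) {
  cat("<pen_layout> ", length(x$locations), " locations: ",
      paste(x$locations, collapse = ", "), "\n", sep = "")
  cat(if (is.null(x$coords)) "distances from explicit matrix\n"
      else "coordinates present\n")
  print(round(x$dist, 1))
  invisible(x)
}

#' Read a pen layout from a JSON config
#'
#' The config carries a `locations` block (id to `[x, y]` meters), a
#' `distance_matrix` block (`ids` plus an `ids`-by-`ids` `meters` array), or
#' both; precedence and consistency checking are as in [pen_layout()].
#'
#' @param path Path to a JSON layout file.
#' @param coord_tol Passed to [pen_layout()].
#' @return A `pen_layout`.
#' @seealso [table2_layout()] for the bundled five-location fixture.
#' @export
read_layout <- function(path, coord_tol = 0.05) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  coords <- NULL
  dmat <- NULL
  if (!is.null(cfg$locations) && length(cfg$locations)) {
    coords <- lapply(cfg$locations, as.numeric)
  }
  if (!is.null(cfg$distance_matrix)) {
    ids <- cfg$distance_matrix$ids
    mm <- cfg$distance_matrix$meters
    if (is.null(ids) || is.null(mm)) {
      stop("distance_matrix block needs 'ids' and 'meters'", call. = FALSE)
    }
    mm <- as.matrix(mm)
    if (nrow(mm) != length(ids) || ncol(mm) != length(ids)) {
      stop("distance matrix must be square with one row/column per id",
           call. = FALSE)
    }
    dimnames(mm) <- list(ids, ids)
    dmat <- mm
  }
  if (is.null(coords) && is.null(dmat)) {
    stop("layout config has neither 'locations' nor 'distance_matrix'",
         call. = FALSE)
  }
  pen_layout(coords = coords, distance_matrix = dmat, coord_tol = coord_tol)
}

#' The bundled five-location fattening-pen layout
#'
#' Loads the packaged layout of a conventional fattening pen instrumented
#' with UHF-RFID antennas at the trough, three nipple drinkers and a playing
#' device, with published center-to-center distances (e.g. trough to playing
#' device: 5.2 m). The coordinates in the fixture are a synthetic planar
#' embedding reconstructed from those distances (accurate to within 0.014 m);
#' the distances, not the coordinates, are authoritative.
#'
#' @return A `pen_layout` with locations `trough`, `drinker1`, `drinker2`,
#'   `drinker3`, `playing_device`.
#' @examples
#' lay <- table2_layout()
#' lay$dist["trough", "playing_device"] # 5.2
#' @export
table2_layout <- function() {
  read_layout(system.file("extdata", "table2_layout.json", package = "penwalk",
                          mustWork = TRUE))
}
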