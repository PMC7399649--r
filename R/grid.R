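#' Define a regular voxel grid
#'
#' A voxel grid is the common spatial frame for parcellations, fraction maps
#' and streamline coordinates. Voxel indices are 0-based; a world point
#' \code{p} (mm) falls in voxel \code{floor((p - origin) / voxel_size)}, so
#' voxel boxes are half-open and a point exactly on a face belongs to the
#' higher-index voxel.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric length 1 or 3, voxel edge length in mm (> 0).
#' @param origin numeric length 3, world-mm coordinate of the corner of
#'   voxel (0,0,0).
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(dims, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be three integers >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be positive")
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin)))
    stop("'origin' must be finite")
  structure(list(dims = dims, voxel_size = voxel_size, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, size %s mm, origin (%s)\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$voxel_size), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a \code{voxel_grid}.
#' @return integer, nx * ny * nz.
#' @export
n_voxels <- function(grid) prod(grid$dims)

#' Map world coordinates to 0-based voxel indices
#'
#' @param grid a \code{voxel_grid}.
#' @param points numeric matrix (n x 3) of world-mm coordinates.
#' @return integer matrix (n x 3) of 0-based voxel indices; points outside
#'   the grid yield indices outside \code{[0, dims)}.
#' @export
world_to_voxel <- function(grid, points) {
  points <- to_point_matrix(points)
  v <- sweep(sweep(points, 2L, grid$origin, "-"), 2L, grid$voxel_size, "/")
  storage.mode(v) <- "double"
  matrix(as.integer(floor(v)), ncol = 3L)
}

#' World-mm centers of 0-based voxel indices
#' @param grid a \code{voxel_grid}.
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @return numeric matrix (n x 3) of voxel-center coordinates in mm.
#' @export
voxel_centers <- function(grid, idx) {
  idx <- to_point_matrix(idx)
  sweep(sweep(idx + 0.5, 2L, grid$voxel_size, "*"), 2L, grid$origin, "+")
}

#' Linear (1-based, x-fastest raster) index of 0-based voxel triples
#' @param grid a \code{voxel_grid}.
#' @param idx integer matrix (n x 3) of 0-based voxel indices, all in-grid.
#' @return integer vector of 1-based linear indices.
#' @export
voxel_linear_index <- function(grid, idx) {
  idx <- to_point_matrix(idx)
  d <- grid$dims
  as.integer(1L + idx[, 1L] + d[1L] * (idx[, 2L] + d[2L] * idx[, 3L]))
}

#' Inverse of \code{voxel_linear_index}
#' @param grid a \code{voxel_grid}.
#' @param lin integer vector of 1-based linear indices.
#' @return integer matrix (n x 3) of 0-based voxel indices.
#' @export
voxel_from_linear <- function(grid, lin) {
  d <- grid$dims
  lin0 <- as.integer(lin) - 1L
  cbind(lin0 %% d[1L],
        (lin0 %/% d[1L]) %% d[2L],
        lin0 %/% (d[1L] * d[2L]))
}

#' Test whether 0-based voxel indices lie inside the grid
#' @param grid a \code{voxel_grid}.
#' @param idx integer matrix (n x 3).
#' @return logical vector.
#' @export
in_grid <- function(grid, idx) {
  idx <- to_point_matrix(idx)
  idx[, 1L] >= 0L & idx[, 1L] < grid$dims[1L] &
    idx[, 2L] >= 0L & idx[, 2L] < grid$dims[2L] &
    idx[, 3L] >= 0L & idx[, 3L] < grid$dims[3L]
}

to_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
  if (ncol(p) != 3L) stop("points must have 3 columns")
  p
}

#' Attach ROI labels to a voxel grid
#'
#' A parcellation assigns an integer label to every voxel: 0 is background /
#' white matter, labels 1..R are gray-matter regions of interest (ROIs).
#'
#' @param grid a \code{voxel_grid}.
#' @param labels integer array with \code{dim(labels) == grid$dims},
#'   non-negative.
#' @return An object of class \code{parcellation}.
#' @export
parcellation <- function(grid, labels) {
  if (!inherits(grid, "voxel_grid")) stop("'grid' must be a voxel_grid")
  labels <- as.array(labels)
  if (!identical(as.integer(dim(labels)), grid$dims))
    stop("label array dimensions do not match the grid")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers")
  structure(list(grid = grid, labels = labels), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  labs <- roi_labels(x)
  cat(sprintf("<parcellation> %d ROIs on a %s grid\n", length(labs),
              paste(x$grid$dims, collapse = "x")))
  invisible(x)
}

#' Sorted nonzero ROI labels of a parcellation
#' @param parc a \code{parcellation}.
#' @return increasing integer vector of ROI labels.
#' @export
roi_labels <- function(parc) {
  labs <- sort(unique(as.vector(parc$labels)))
  labs[labs != 0L]
}
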