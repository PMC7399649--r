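#' Per-voxel lengths of a streamline
#'
#' Computes the exact geometric length of a polyline inside each half-open
#' voxel box it traverses, by parametric clipping of every linear segment
#' against the integer voxel planes (3D digital differential analyzer).
#' Portions of the polyline outside the grid are clipped away; the returned
#' lengths sum to the in-grid arc length.
#'
#' @param points numeric matrix (n x 2+ rows x 3) of world-mm coordinates.
#' @param grid a \code{voxel_grid}.
#' @return list with \code{voxel} (1-based linear voxel indices) and
#'   \code{length} (mm inside each voxel); empty vectors for a degenerate
#'   (zero-length) streamline.
#' @export
segment_lengths <- function(points, grid) {
  points <- to_point_matrix(points)
  d3 <- grid$dims
  # work in voxel coordinates; lengths are measured in mm
  V <- sweep(sweep(points, 2L, grid$origin, "-"), 2L, grid$voxel_size, "/")
  acc_idx <- integer(0)
  acc_len <- numeric(0)
  for (s in seq_len(nrow(points) - 1L)) {
    a <- V[s, ]; b <- V[s + 1L, ]
    dv <- b - a
    seg_mm <- sqrt(sum((points[s + 1L, ] - points[s, ])^2))
    if (seg_mm == 0) next
    # clip [t0, t1] to the grid box [0, dims)
    t0 <- 0; t1 <- 1
    dead <- FALSE
    for (k in 1:3) {
      if (dv[k] == 0) {
        if (a[k] < 0 || a[k] >= d3[k]) { dead <- TRUE; break }
      } else {
        ta <- (0 - a[k]) / dv[k]
        tb <- (d3[k] - a[k]) / dv[k]
        t0 <- max(t0, min(ta, tb))
        t1 <- min(t1, max(ta, tb))
      }
    }
    if (dead || t1 <= t0) next
    ts <- c(t0, t1)
    for (k in 1:3) {
      if (dv[k] != 0) {
        lo <- a[k] + t0 * dv[k]; hi <- a[k] + t1 * dv[k]
        pl <- seq.int(ceiling(min(lo, hi)), floor(max(lo, hi)))
        tc <- (pl - a[k]) / dv[k]
        ts <- c(ts, tc[tc > t0 & tc < t1])
      }
    }
    ts <- sort(ts)
    dt <- diff(ts)
    keep <- dt > 0
    if (!any(keep)) next
    tm <- (ts[-length(ts)] + ts[-1L])[keep] / 2
    mid <- cbind(floor(a[1L] + tm * dv[1L]),
                 floor(a[2L] + tm * dv[2L]),
                 floor(a[3L] + tm * dv[3L]))
    # midpoints can graze the upper boundary through rounding; clamp
    mid <- pmin(pmax(mid, 0L), matrix(d3 - 1L, nrow(mid), 3L, byrow = TRUE))
    acc_idx <- c(acc_idx, voxel_linear_index(grid, mid))
    acc_len <- c(acc_len, dt[keep] * seg_mm)
  }
  if (!length(acc_idx))
    return(list(voxel = integer(0), length = numeric(0)))
  tot <- rowsum(acc_len, acc_idx)
  list(voxel = as.integer(rownames(tot)), length = as.numeric(tot))
}

#' Build the sparse streamline-to-voxel contribution matrix
#'
#' Builds the linear operator A of the forward model y = A x, mapping
#' non-negative per-compartment contributions x to the voxelwise data
#' vector y.
#'
#' In \code{"length"} mode, rows are voxels and the entry for streamline j
#' in voxel v is its arc length inside v divided by the voxel volume, so
#' that with x interpreted as cross-sectional areas (mm^2) the product A x
#' is a dimensionless volume fraction. In \code{"stickball"} mode, rows are
#' (voxel, gradient-direction) pairs and a streamline's entry is the stick
#' (zero-radius cylinder) diffusion signal oriented along its local
#' direction in that voxel; with \code{include_isotropic}, one ball
#' (isotropic) column per voxel is appended after the streamline columns,
#' in voxel raster order.
#'
#' @param tract a \code{tractogram} (non-empty).
#' @param grid a \code{voxel_grid}.
#' @param mode \code{"length"} or \code{"stickball"}.
#' @param include_isotropic append one isotropic column per voxel
#'   (default \code{FALSE} in length mode).
#' @param model_params list of stick/ball constants for
#'   \code{"stickball"} mode: \code{b} (s/mm^2), \code{d_par} and
#'   \code{d_iso} (mm^2/s), \code{directions} (n_d x 3 unit vectors).
#' @return An object of class \code{contribution_matrix} with elements
#'   \code{A} (dgCMatrix), \code{column_kinds}
#'   (\code{"streamline"}/\code{"isotropic"} per column), \code{mode},
#'   \code{grid}, and \code{n_dirs} (stickball mode).
#' @export
build_matrix <- function(tract, grid, mode = c("length", "stickball"),
                         include_isotropic = FALSE, model_params = list()) {
  stopifnot(inherits(tract, "tractogram"), inherits(grid, "voxel_grid"))
  mode <- match.arg(mode)
  ns <- length(tract$streamlines)
  if (ns == 0L) stop("empty tractogram")
  nv <- n_voxels(grid)
  per_sl <- lapply(tract$streamlines, segment_lengths, grid = grid)
  empty <- which(vapply(per_sl, function(z) length(z$voxel) == 0L, logical(1)))
  if (length(empty))
    stop("streamline(s) with no in-grid voxels (zero column): ",
         paste(empty, collapse = ", "))
  if (mode == "length") {
    voxvol <- prod(grid$voxel_size)
    i <- unlist(lapply(per_sl, `[[`, "voxel"))
    j <- rep.int(seq_len(ns), vapply(per_sl, function(z) length(z$voxel),
                                     integer(1)))
    x <- unlist(lapply(per_sl, `[[`, "length")) / voxvol
    kinds <- rep("streamline", ns)
    ncols <- ns
    if (include_isotropic) {
      i <- c(i, seq_len(nv))
      j <- c(j, ns + seq_len(nv))
      x <- c(x, rep(1, nv))
      kinds <- c(kinds, rep("isotropic", nv))
      ncols <- ns + nv
    }
    A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nv, ncols))
    out <- list(A = A, column_kinds = kinds, mode = mode, grid = grid,
                n_dirs = NULL)
  } else {
    mp <- stickball_params(model_params)
    nd <- nrow(mp$directions)
    i <- integer(0); j <- integer(0); x <- numeric(0)
    for (s in seq_len(ns)) {
      u <- voxel_directions(tract$streamlines[[s]], grid)
      for (r in seq_len(nrow(u$dir))) {
        g_dot_u <- as.numeric(mp$directions %*% u$dir[r, ])
        sig <- exp(-mp$b * mp$d_par * g_dot_u^2)
        rows <- (u$voxel[r] - 1L) * nd + seq_len(nd)
        i <- c(i, rows); j <- c(j, rep.int(s, nd)); x <- c(x, sig)
      }
    }
    kinds <- rep("streamline", ns)
    ncols <- ns
    if (include_isotropic) {
      ball <- exp(-mp$b * mp$d_iso)
      for (v in seq_len(nv)) {
        rows <- (v - 1L) * nd + seq_len(nd)
        i <- c(i, rows); j <- c(j, rep.int(ns + v, nd))
        x <- c(x, rep(ball, nd))
      }
      kinds <- c(kinds, rep("isotropic", nv))
      ncols <- ns + nv
    }
    A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nv * nd, ncols))
    out <- list(A = A, column_kinds = kinds, mode = mode, grid = grid,
                n_dirs = nd)
  }
  class(out) <- "contribution_matrix"
  out
}

stickball_params <- function(p) {
  defaults <- list(b = 3000, d_par = 1.7e-3, d_iso = 3.0e-3,
                   directions = NULL)
  p <- utils::modifyList(defaults, p)
  if (is.null(p$directions))
    p$directions <- fibonacci_directions(30L)
  p$directions <- to_point_matrix(p$directions)
  nrm <- sqrt(rowSums(p$directions^2))
  p$directions <- p$directions / nrm
  p
}

#' Quasi-uniform unit directions on the hemisphere (Fibonacci lattice)
#' @param n number of directions (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * k
  z <- k / n                         # hemisphere: z in (0, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Dominant in-voxel direction of a streamline: per traversed voxel, the
# normalized length-weighted sum of its segment direction vectors.
voxel_directions <- function(points, grid) {
  points <- to_point_matrix(points)
  vox <- integer(0)
  vecs <- NULL
  for (s in seq_len(nrow(points) - 1L)) {
    seg <- points[c(s, s + 1L), , drop = FALSE]
    sl <- segment_lengths(seg, grid)
    if (!length(sl$voxel)) next
    d <- points[s + 1L, ] - points[s, ]
    nd <- sqrt(sum(d^2))
    if (nd == 0) next
    u <- d / nd
    vox <- c(vox, sl$voxel)
    vecs <- rbind(vecs, outer(sl$length, u))
  }
  if (!length(vox)) return(list(voxel = integer(0), dir = NULL))
  uv <- sort(unique(vox))
  dir <- t(vapply(uv, function(v) {
    w <- colSums(vecs[vox == v, , drop = FALSE])
    w / sqrt(sum(w^2))
  }, numeric(3)))
  list(voxel = uv, dir = dir)
}

#' Forward prediction y = A x
#'
#' @param cm a \code{contribution_matrix}.
#' @param x non-negative coefficient vector, one entry per column of A.
#' @return numeric data vector of length \code{nrow(cm$A)}.
#' @export
predict_contributions <- function(cm, x) {
  stopifnot(inherits(cm, "contribution_matrix"))
  if (length(x) != ncol(cm$A))
    stop(sprintf("x has length %d but A has %d columns",
                 length(x), ncol(cm$A)))
  if (any(x < 0)) stop("x must be non-negative")
  as.numeric(cm$A %*% x)
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat(sprintf(
    "<contribution_matrix> %d x %d (%s mode), %d streamline + %d isotropic columns\n",
    nrow(x$A), ncol(x$A), x$mode,
    sum(x$column_kinds == "streamline"), sum(x$column_kinds == "isotropic")))
  invisible(x)
}

#' Serialize a contribution matrix in coordinate (triplet) text form
#'
#' Writes one line per stored entry: \code{row col value}, preceded by a
#' comment line with the matrix shape, for external inspection.
#'
#' @param cm a \code{contribution_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_coo <- function(cm, path) {
  stopifnot(inherits(cm, "contribution_matrix"))
  trip <- Matrix::summary(cm$A)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%%%% %d %d %d", nrow(cm$A), ncol(cm$A), nrow(trip)), con)
  writeLines(sprintf("%d %d %.17g", trip$i, trip$j, trip$x), con)
  invisible(path)
}
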