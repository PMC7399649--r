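#' Write a scalar volume (e.g. a fraction map) as NIfTI
#'
#' The affine maps 0-based voxel indices to world mm so that the center of
#' voxel (i,j,k) is \code{origin + (i+0.5)*voxel_size}, matching the
#' package's half-open voxel convention.
#'
#' @param volume 3D numeric array with \code{dim == grid$dims}.
#' @param grid the \code{voxel_grid} of the volume.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_nifti_volume <- function(volume, grid, path) {
  volume <- array(volume, grid$dims)
  im <- RNifti::asNifti(volume)
  aff <- rbind(cbind(diag(grid$voxel_size),
                     grid$origin + 0.5 * grid$voxel_size),
               c(0, 0, 0, 1))
  RNifti::sform(im) <- structure(aff, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a scalar volume written by \code{\link{write_nifti_volume}}
#'
#' Only axis-aligned affines (diagonal rotation part) are supported; the
#' package performs no resampling, so inputs must share one grid.
#'
#' @param path NIfTI file path.
#' @return list with \code{volume} (3D array) and \code{grid}
#'   (\code{voxel_grid}).
#' @export
read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  aff <- RNifti::xform(im)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4)
    stop("only axis-aligned NIfTI affines are supported: ", path)
  vs <- diag(rot)
  if (any(vs <= 0)) stop("unsupported negative/zero voxel scaling: ", path)
  origin <- aff[1:3, 4] - 0.5 * vs
  grid <- voxel_grid(dim(arr), voxel_size = vs, origin = origin)
  list(volume = arr, grid = grid)
}

#' Write a parcellation as an integer-labeled NIfTI volume
#' @param parc a \code{parcellation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  write_nifti_volume(parc$labels, parc$grid, path)
}

#' Read a parcellation from NIfTI
#' @param path NIfTI file path with integer labels.
#' @return a \code{parcellation}.
#' @export
read_parcellation <- function(path) {
  v <- read_nifti_volume(path)
  labs <- round(v$volume)
  if (max(abs(v$volume - labs)) > 1e-6)
    stop("parcellation volume has non-integer labels: ", path)
  parcellation(v$grid, labs)
}

#' Check that two voxel grids coincide
#' @param a,b \code{voxel_grid} objects.
#' @param tol coordinate tolerance in mm.
#' @return TRUE invisibly; error on mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(a$dims, b$dims) ||
      max(abs(a$voxel_size - b$voxel_size)) > tol ||
      max(abs(a$origin - b$origin)) > tol)
    stop("input volumes are not on the same grid (no resampling is performed)")
  invisible(TRUE)
}

#' Write a connectome as a dense CSV matrix with ROI labels as header
#' @param connectome a \code{connectome}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_connectome_csv <- function(connectome, path) {
  m <- as.data.frame(connectome$matrix)
  names(m) <- connectome$labels
  utils::write.csv(cbind(roi = connectome$labels, m), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a connectome edge list as CSV (roi_a, roi_b, weight)
#' @param connectome a \code{connectome}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edges_csv <- function(connectome, path) {
  utils::write.csv(connectome_edges(connectome), path, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth edge list CSV into a connectome
#' @param path CSV with columns roi_a, roi_b, weight (or fiber_count).
#' @param roi_labels_all full ROI label set.
#' @return a \code{connectome}.
#' @export
read_edges_csv <- function(path, roi_labels_all) {
  df <- utils::read.csv(path)
  if (!"weight" %in% names(df) && "fiber_count" %in% names(df))
    df$weight <- df$fiber_count
  connectome_from_edges(df[, c("roi_a", "roi_b", "weight")],
                        roi_labels_all)
}

#' Write per-streamline weights as a one-column text file
#'
#' One weight per line, ordered as the input tractogram (unassigned
#' streamlines excluded from the fit carry weight 0).
#'
#' @param weights numeric vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_weights <- function(weights, path) {
  writeLines(sprintf("%.17g", weights), path)
  invisible(path)
}

#' Serialize a solver result as JSON
#'
#' Records the effective configuration, the objective trace, per-group
#' norms and the active groups, for provenance and inspection.
#'
#' @param solution a \code{tract_solution}.
#' @param config the \code{solver_config} used.
#' @param path output path.
#' @param extra optional named list merged into the record.
#' @return \code{path}, invisibly.
#' @export
write_solution_json <- function(solution, config, path, extra = list()) {
  rec <- c(list(config = unclass(config),
                objective = solution$objective,
                residual_norm = solution$residual_norm,
                iterations = solution$iterations,
                converged = solution$converged,
                active_groups = solution$active_groups,
                group_norms = as.list(solution$group_norms),
                objective_trace = solution$objective_trace),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
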