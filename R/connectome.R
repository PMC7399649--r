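#' Assign streamline endpoints to gray-matter ROIs
#'
#' Each endpoint is mapped to the nearest labeled voxel center within
#' \code{radius} mm (Euclidean distance in world space). A streamline is
#' assigned to an unordered ROI pair only if both endpoints succeed and
#' land in two distinct ROIs; otherwise it is discarded from the
#' connectivity analysis. Ties between equidistant ROIs go to the lower
#' label.
#'
#' @param tract a \code{tractogram}.
#' @param parc a \code{parcellation} with at least one nonzero label.
#' @param radius assignment radius in mm (default 2, the usual endpoint
#'   tolerance for volumetric parcellations).
#' @return data.frame of class \code{endpoint_assignment} with columns
#'   \code{streamline}, \code{roi_a}, \code{roi_b} (NA when unassigned,
#'   \code{roi_a <= roi_b} otherwise) and \code{assigned}.
#' @export
assign_endpoints <- function(tract, parc, radius = 2) {
  stopifnot(inherits(tract, "tractogram"), inherits(parc, "parcellation"))
  if (radius < 0) stop("'radius' must be >= 0")
  lab_lin <- which(parc$labels != 0L)
  if (!length(lab_lin)) stop("parcellation has no labeled voxels")
  labs <- as.vector(parc$labels)[lab_lin]
  centers <- voxel_centers(parc$grid, voxel_from_linear(parc$grid, lab_lin))
  # order by label so that which.min resolves distance ties to the lower label
  ord <- order(labs)
  labs <- labs[ord]
  centers <- centers[ord, , drop = FALSE]
  nearest <- function(p) {
    d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
      (centers[, 3] - p[3])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= radius) labs[j] else NA_integer_
  }
  n <- length(tract$streamlines)
  roi_a <- roi_b <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- tract$streamlines[[i]]
    e1 <- nearest(s[1L, ])
    e2 <- nearest(s[nrow(s), ])
    if (!is.na(e1) && !is.na(e2) && e1 != e2) {
      roi_a[i] <- min(e1, e2)
      roi_b[i] <- max(e1, e2)
    }
  }
  out <- data.frame(streamline = seq_len(n), roi_a = roi_a, roi_b = roi_b,
                    assigned = !is.na(roi_a))
  class(out) <- c("endpoint_assignment", class(out))
  attr(out, "roi_labels") <- roi_labels(parc)
  out
}

#' Group streamlines into bundles by ROI pair
#'
#' One group per distinct unordered ROI pair; unassigned streamlines (and
#' putative self-connections, excluded at assignment time) are left out of
#' the partition and reported as exempt-free dropped columns by the caller.
#'
#' @param assignment an \code{endpoint_assignment}.
#' @param n_columns total number of matrix columns the grouping must cover
#'   (defaults to the number of streamlines; extra columns, e.g.
#'   isotropic compartments, are marked exempt).
#' @return a \code{group_structure}; group names are \code{"a-b"} pairs.
#'   Unassigned streamline columns are listed in attribute
#'   \code{"unassigned"} and marked exempt.
#' @export
group_by_pairs <- function(assignment, n_columns = nrow(assignment)) {
  stopifnot(inherits(assignment, "endpoint_assignment"))
  ok <- assignment$assigned
  if (!any(ok)) stop("no assigned streamlines to group")
  key <- paste0(assignment$roi_a[ok], "-", assignment$roi_b[ok])
  groups <- split(assignment$streamline[ok], key)
  unassigned <- assignment$streamline[!ok]
  extra <- setdiff(seq_len(n_columns), assignment$streamline)
  gs <- group_structure(groups, n_columns = n_columns,
                        exempt = c(unassigned, extra))
  attr(gs, "unassigned") <- unassigned
  gs
}

#' Build a weighted connectome from endpoint assignments
#'
#' @param assignment an \code{endpoint_assignment}.
#' @param weights per-streamline weights, required for
#'   \code{"sum_of_weights"}; must be non-negative.
#' @param weight_definition \code{"streamline_count"} (edge = number of
#'   assigned streamlines), \code{"sum_of_weights"} (edge = sum of the
#'   streamlines' solver weights), or \code{"fiber_count"} (alias of
#'   streamline_count for ground-truth fibers).
#' @param roi_labels_all optional full ROI label set (so that ROIs without
#'   any assigned streamline still appear as nodes).
#' @return object of class \code{connectome}: list with \code{labels},
#'   symmetric non-negative \code{matrix} (zero diagonal), and
#'   \code{weight_definition}. Edges with total weight below 1e-12 are set
#'   to exact zero (absent).
#' @export
build_connectome <- function(assignment,
                             weights = NULL,
                             weight_definition = c("streamline_count",
                                                   "sum_of_weights",
                                                   "fiber_count"),
                             roi_labels_all = NULL) {
  stopifnot(inherits(assignment, "endpoint_assignment"))
  weight_definition <- match.arg(weight_definition)
  labs <- roi_labels_all
  if (is.null(labs)) labs <- attr(assignment, "roi_labels")
  if (is.null(labs))
    labs <- sort(unique(c(assignment$roi_a, assignment$roi_b)))
  labs <- sort(unique(as.integer(labs)))
  labs <- labs[!is.na(labs)]
  R <- length(labs)
  if (R < 2L) stop("need at least 2 ROI labels")
  M <- matrix(0, R, R, dimnames = list(labs, labs))
  ok <- which(assignment$assigned)
  if (weight_definition == "sum_of_weights") {
    if (is.null(weights)) stop("'weights' required for sum_of_weights")
    if (length(weights) != nrow(assignment))
      stop("'weights' must have one entry per streamline")
    if (any(weights < 0)) stop("negative streamline weights")
    wv <- weights
  } else {
    wv <- rep(1, nrow(assignment))
  }
  for (i in ok) {
    a <- match(assignment$roi_a[i], labs)
    b <- match(assignment$roi_b[i], labs)
    M[a, b] <- M[a, b] + wv[i]
    M[b, a] <- M[b, a] + wv[i]
  }
  M[M < 1e-12] <- 0
  structure(list(labels = labs, matrix = M,
                 weight_definition = weight_definition),
            class = "connectome")
}

#' Construct a connectome directly from an edge list
#'
#' @param edges data.frame with columns \code{roi_a}, \code{roi_b},
#'   \code{weight}.
#' @param roi_labels_all full ROI label set.
#' @param weight_definition as in \code{\link{build_connectome}}.
#' @return a \code{connectome}.
#' @export
connectome_from_edges <- function(edges, roi_labels_all,
                                  weight_definition = "fiber_count") {
  labs <- sort(unique(as.integer(roi_labels_all)))
  R <- length(labs)
  if (R < 2L) stop("need at least 2 ROI labels")
  M <- matrix(0, R, R, dimnames = list(labs, labs))
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$roi_a[i], labs)
    b <- match(edges$roi_b[i], labs)
    if (is.na(a) || is.na(b)) stop("edge label outside ROI label set")
    if (a == b) stop("self-connections are excluded")
    M[a, b] <- M[a, b] + edges$weight[i]
    M[b, a] <- M[b, a] + edges$weight[i]
  }
  M[M < 1e-12] <- 0
  structure(list(labels = labs, matrix = M,
                 weight_definition = weight_definition),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d ROIs, %d edges (%s), density %.3f\n",
              length(x$labels), n_edges(x), x$weight_definition,
              network_density(x)))
  invisible(x)
}

upper_tri_idx <- function(connectome) which(upper.tri(connectome$matrix))

#' Number of nonzero (present) edges of a connectome
#' @param connectome a \code{connectome}.
#' @return integer count of nonzero off-diagonal edges (upper triangle).
#' @export
n_edges <- function(connectome) {
  sum(connectome$matrix[upper_tri_idx(connectome)] > 0)
}

#' Edge list of a connectome
#' @param connectome a \code{connectome}.
#' @return data.frame with \code{roi_a}, \code{roi_b}, \code{weight} for
#'   nonzero edges, \code{roi_a < roi_b}.
#' @export
connectome_edges <- function(connectome) {
  M <- connectome$matrix
  ut <- which(upper.tri(M) & M > 0, arr.ind = TRUE)
  data.frame(roi_a = connectome$labels[ut[, 1]],
             roi_b = connectome$labels[ut[, 2]],
             weight = M[ut])
}

#' Network density
#'
#' The ratio between the number of actual connections and the number of
#' possible connections, R(R-1)/2 for R nodes.
#'
#' @param connectome a \code{connectome} with >= 2 ROIs.
#' @return fraction in [0, 1].
#' @export
network_density <- function(connectome) {
  R <- length(connectome$labels)
  if (R < 2L) stop("need at least 2 ROIs")
  n_edges(connectome) / (R * (R - 1) / 2)
}
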