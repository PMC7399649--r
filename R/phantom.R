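#' Generate a digital connectivity phantom with known ground truth
#'
#' Builds a fully synthetic evaluation dataset: gray-matter ROIs placed as
#' spherical caps on a sphere inscribed in the voxel grid, smooth
#' ground-truth fiber bundles (natural cubic-spline centerlines, i.e.
#' third-order piecewise polynomials) connecting randomly chosen ROI
#' pairs, per-bundle fibers spread over the bundle cross-section, and an
#' intra-axonal signal-fraction map computed from the geometry of the
#' ground-truth fibers via the length forward operator. The map and the
#' per-fiber cross-sectional areas are rescaled together so the map peaks
#' at \code{peak_fraction}; the identity map == A(areas) is exact.
#'
#' @param n_rois number of gray-matter ROIs (>= 2).
#' @param n_bundles number of ground-truth bundles; at most
#'   \code{n_rois*(n_rois-1)/2}. Alternatively give \code{density}.
#' @param density target connection density in (0, 1];
#'   \code{n_bundles = ceiling(density * n_rois*(n_rois-1)/2)}.
#' @param grid_dims voxel grid dimensions (1 mm isotropic voxels).
#' @param seed integer seed; the phantom is a pure function of the
#'   arguments and the seed.
#' @param radius_range bundle radius range in mm, drawn uniformly
#'   (default 1.5 to 4).
#' @param fibers_per_bundle ground-truth fibers per bundle.
#' @param roi_radius ROI cap radius in mm.
#' @param peak_fraction peak value of the fraction map, <= 1.
#' @param noise_sd optional additive Gaussian noise on the fraction map
#'   (default 0: noiseless; negative values clipped at 0).
#' @return object of class \code{phantom}: \code{grid},
#'   \code{parcellation}, \code{bundles} (roi_a, roi_b, centerline,
#'   radius, fiber_count), \code{fibers} (ground-truth
#'   \code{tractogram}), \code{fiber_areas} (mm^2 per fiber),
#'   \code{fraction_map} (3D array in [0,1]), \code{true_connectome}
#'   (fiber counts), \code{roi_centers}.
#' @export
make_phantom <- function(n_rois, n_bundles = NULL, density = NULL,
                         grid_dims = c(30, 30, 30), seed = 1L,
                         radius_range = c(1.5, 4),
                         fibers_per_bundle = 30L,
                         roi_radius = 2.5,
                         peak_fraction = 0.5,
                         noise_sd = 0) {
  if (n_rois < 2) stop("'n_rois' must be >= 2")
  max_pairs <- n_rois * (n_rois - 1) / 2
  if (is.null(n_bundles)) {
    if (is.null(density)) stop("give 'n_bundles' or 'density'")
    if (density <= 0 || density > 1) stop("'density' must be in (0, 1]")
    n_bundles <- ceiling(density * max_pairs)
  }
  if (n_bundles > max_pairs)
    stop("'n_bundles' exceeds the number of ROI pairs")
  if (peak_fraction <= 0 || peak_fraction > 1)
    stop("'peak_fraction' must be in (0, 1]")
  grid <- voxel_grid(grid_dims)
  with_seed(seed, {
    parc_info <- place_rois(grid, n_rois, roi_radius)
    parc <- parc_info$parc
    centers <- parc_info$centers
    bundles <- list()
    if (n_bundles > 0) {
      pair_idx <- sample.int(max_pairs, n_bundles)
      pairs <- all_roi_pairs(n_rois)[pair_idx, , drop = FALSE]
      cgrid <- grid$origin + grid$dims * grid$voxel_size / 2
      for (k in seq_len(n_bundles)) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        cl <- bundle_centerline(centers[a, ], centers[b, ], cgrid, grid)
        bundles[[k]] <- list(
          roi_a = a, roi_b = b, centerline = cl,
          radius = stats::runif(1, radius_range[1], radius_range[2]),
          fiber_count = as.integer(fibers_per_bundle))
      }
    }
    streamlines <- list()
    areas <- numeric(0)
    meta <- NULL
    for (k in seq_along(bundles)) {
      bd <- bundles[[k]]
      fb <- bundle_fibers(bd$centerline, bd$radius, bd$fiber_count, grid,
                          offsets = "sunflower")
      streamlines <- c(streamlines, fb)
      areas <- c(areas, rep(pi * bd$radius^2 / bd$fiber_count,
                            bd$fiber_count))
      meta <- rbind(meta, data.frame(bundle = k, roi_a = bd$roi_a,
                                     roi_b = bd$roi_b)[rep(1, bd$fiber_count), ])
    }
    if (length(streamlines)) {
      fibers <- tractogram(streamlines, labels = meta)
      raw <- compute_fraction_map(fibers, grid, areas, cap = Inf)
      s <- peak_fraction / max(raw)
      fmap <- raw * s
      areas <- areas * s
      if (noise_sd > 0)
        fmap <- pmin(pmax(fmap + stats::rnorm(length(fmap), 0, noise_sd), 0), 1)
      edges <- data.frame(
        roi_a = vapply(bundles, `[[`, numeric(1), "roi_a"),
        roi_b = vapply(bundles, `[[`, numeric(1), "roi_b"),
        weight = vapply(bundles, `[[`, integer(1), "fiber_count"))
      truth <- connectome_from_edges(edges, seq_len(n_rois), "fiber_count")
    } else {
      fibers <- structure(list(streamlines = list(), labels = NULL),
                          class = "tractogram")
      fmap <- array(0, grid$dims)
      truth <- structure(list(labels = seq_len(n_rois),
                              matrix = matrix(0, n_rois, n_rois,
                                              dimnames = list(seq_len(n_rois),
                                                              seq_len(n_rois))),
                              weight_definition = "fiber_count"),
                         class = "connectome")
    }
    structure(list(grid = grid, parcellation = parc, bundles = bundles,
                   fibers = fibers, fiber_areas = areas,
                   fraction_map = array(fmap, grid$dims),
                   true_connectome = truth, roi_centers = centers,
                   seed = as.integer(seed)),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %d ROIs, %d bundles, %d fibers on a %s grid (peak fraction %.3g)\n",
    length(roi_labels(x$parcellation)), length(x$bundles),
    length(x$fibers$streamlines), paste(x$grid$dims, collapse = "x"),
    max(x$fraction_map)))
  invisible(x)
}

all_roi_pairs <- function(n_rois) {
  p <- t(utils::combn(n_rois, 2))
  colnames(p) <- c("a", "b")
  p
}

# ROIs as spherical caps centered on a sphere inscribed in the grid, laid
# out on a seeded random rotation of a Fibonacci lattice; rejection-sample
# rotations until all caps are disjoint.
place_rois <- function(grid, n_rois, roi_radius, max_attempts = 25L) {
  extent <- grid$dims * grid$voxel_size
  cgrid <- grid$origin + extent / 2
  rs <- min(extent) / 2 - roi_radius - 0.5
  if (rs <= 0) stop("grid too small for the requested ROI radius")
  base <- fibonacci_sphere(n_rois)
  for (attempt in seq_len(max_attempts)) {
    rot <- random_rotation()
    centers <- sweep(base %*% t(rot) * rs, 2L, cgrid, "+")
    dmin <- min(stats::dist(centers))
    if (dmin > 2 * roi_radius + grid$voxel_size[1]) {
      labels <- array(0L, grid$dims)
      lin <- seq_len(n_voxels(grid))
      vc <- voxel_centers(grid, voxel_from_linear(grid, lin))
      for (r in seq_len(n_rois)) {
        d2 <- (vc[, 1] - centers[r, 1])^2 + (vc[, 2] - centers[r, 2])^2 +
          (vc[, 3] - centers[r, 3])^2
        labels[lin[d2 <= roi_radius^2]] <- r
      }
      return(list(parc = parcellation(grid, labels), centers = centers))
    }
  }
  stop(sprintf(
    "infeasible geometry: could not place %d disjoint ROIs of radius %.2g mm after %d attempts",
    n_rois, roi_radius, max_attempts))
}

fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * k
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Natural cubic-spline centerline between two ROI centers, with one random
# interior control point pulled toward the grid center so bundles cross in
# the deep "white matter" of the phantom.
bundle_centerline <- function(a, b, cgrid, grid, n_samples = 60L) {
  m <- (a + b) / 2
  cp <- 0.6 * m + 0.4 * cgrid + stats::rnorm(3, sd = 1.5)
  pts <- rbind(a, cp, b)
  u <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  uu <- seq(0, u[length(u)], length.out = n_samples)
  cl <- vapply(1:3, function(k)
    stats::spline(u, pts[, k], xout = uu, method = "natural")$y,
    numeric(n_samples))
  clamp_to_grid(cl, grid)
}

clamp_to_grid <- function(points, grid, margin = 0.51) {
  lo <- grid$origin + margin * grid$voxel_size
  hi <- grid$origin + grid$dims * grid$voxel_size - margin * grid$voxel_size
  for (k in 1:3) points[, k] <- pmin(pmax(points[, k], lo[k]), hi[k])
  points
}

# Fibers of a bundle: the centerline plus a cross-sectional offset in a
# fixed perpendicular frame, tapered to zero near both endpoints so every
# fiber terminates at the ROI centers. "sunflower" offsets tile the disc
# deterministically; "uniform" draws them at random (candidate tractograms).
bundle_fibers <- function(centerline, radius, n_fibers, grid,
                          offsets = c("sunflower", "uniform"),
                          jitter_mm = 0, taper = 0.15) {
  offsets <- match.arg(offsets)
  n <- nrow(centerline)
  tvec <- centerline[n, ] - centerline[1, ]
  tvec <- tvec / sqrt(sum(tvec^2))
  ref <- if (abs(tvec[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(tvec, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(tvec, e1)
  arc <- c(0, cumsum(sqrt(rowSums(diff(centerline)^2))))
  s <- arc / max(arc)
  scale <- pmin(1, s / taper, (1 - s) / taper)
  golden <- pi * (3 - sqrt(5))
  lapply(seq_len(n_fibers), function(k) {
    if (offsets == "sunflower") {
      r <- radius * sqrt((k - 0.5) / n_fibers)
      th <- k * golden
    } else {
      r <- radius * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
    }
    off <- r * (cos(th) * e1 + sin(th) * e2)
    fb <- centerline + outer(scale, off)
    if (jitter_mm > 0) fb <- fb + smooth_jitter(n, jitter_mm) * scale
    clamp_to_grid(fb, grid)
  })
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Smooth low-frequency jitter: Gaussian displacements at 5 coarse nodes,
# spline-interpolated along the polyline.
smooth_jitter <- function(n_points, sd_mm, n_nodes = 5L) {
  u <- seq(0, 1, length.out = n_points)
  un <- seq(0, 1, length.out = n_nodes)
  vapply(1:3, function(k)
    stats::spline(un, stats::rnorm(n_nodes, 0, sd_mm), xout = u,
                  method = "natural")$y,
    numeric(n_points))
}

#' Intra-axonal signal-fraction map from streamline geometry
#'
#' Accumulates, per voxel, the streamline arc length inside the voxel
#' times the per-streamline cross-sectional area, divided by the voxel
#' volume. Values above \code{cap} are clipped with a warning.
#'
#' @param tract a \code{tractogram} whose points lie within the grid.
#' @param grid a \code{voxel_grid}.
#' @param area_per_fiber cross-sectional area in mm^2, scalar or one value
#'   per streamline.
#' @param cap maximum admissible fraction (default 1).
#' @return 3D array of per-voxel fractions.
#' @export
compute_fraction_map <- function(tract, grid, area_per_fiber, cap = 1) {
  stopifnot(inherits(tract, "tractogram"), inherits(grid, "voxel_grid"))
  areas <- rep_len(area_per_fiber, length(tract$streamlines))
  fmap <- numeric(n_voxels(grid))
  for (i in seq_along(tract$streamlines)) {
    pts <- tract$streamlines[[i]]
    if (!all(in_grid(grid, world_to_voxel(grid, pts))))
      stop(sprintf("streamline %d has points outside the grid", i))
    sl <- segment_lengths(pts, grid)
    fmap[sl$voxel] <- fmap[sl$voxel] + sl$length * areas[i]
  }
  fmap <- fmap / prod(grid$voxel_size)
  if (any(fmap > cap)) {
    warning(sprintf("%d voxel(s) exceeded the fraction cap %.3g and were clipped",
                    sum(fmap > cap), cap))
    fmap <- pmin(fmap, cap)
  }
  array(fmap, grid$dims)
}

#' Generate a candidate tractogram with controlled false positives
#'
#' Emulates the output of a tractography run on the phantom: for every
#' ground-truth bundle, jittered streamlines that follow its centerline
#' and terminate at the correct ROIs (true positives); plus false-positive
#' bundles built by splicing the centerlines of two true bundles at a
#' shared crossing voxel — the dominant mechanism by which tractography
#' produces spurious connections between regions that are not actually
#' connected.
#'
#' @param phantom a \code{phantom} with at least one bundle.
#' @param streamlines_per_true_bundle streamlines per true bundle.
#' @param n_false_bundles number of spliced false bundles; must not exceed
#'   the number of constructible unconnected ROI pairs.
#' @param streamlines_per_false_bundle streamlines per false bundle
#'   (recycled to length \code{n_false_bundles}, so false bundles can
#'   have heterogeneous cardinalities).
#' @param jitter_mm smooth per-streamline jitter amplitude in mm.
#' @param seed integer seed.
#' @return a \code{tractogram} whose \code{labels} carry
#'   \code{bundle_type} ("true"/"false"), \code{bundle_id}, \code{roi_a},
#'   \code{roi_b}.
#' @export
generate_candidate_tractogram <- function(phantom,
                                          streamlines_per_true_bundle = 15L,
                                          n_false_bundles = 0L,
                                          streamlines_per_false_bundle = 10L,
                                          jitter_mm = 0.2,
                                          seed = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  if (!length(phantom$bundles)) stop("phantom has no bundles")
  with_seed(seed + 1L, {
    streamlines <- list()
    meta <- NULL
    for (k in seq_along(phantom$bundles)) {
      bd <- phantom$bundles[[k]]
      fb <- bundle_fibers(bd$centerline, bd$radius,
                          streamlines_per_true_bundle, phantom$grid,
                          offsets = "uniform", jitter_mm = jitter_mm)
      streamlines <- c(streamlines, fb)
      meta <- rbind(meta, data.frame(
        bundle_type = "true", bundle_id = k,
        roi_a = bd$roi_a, roi_b = bd$roi_b)[rep(1, length(fb)), ])
    }
    if (n_false_bundles > 0) {
      cand <- spliced_false_candidates(phantom)
      if (nrow(cand$pairs) < n_false_bundles)
        stop(sprintf(
          "requested %d false bundles but only %d unconnected ROI pairs are reachable by splicing",
          n_false_bundles, nrow(cand$pairs)))
      pick <- sample.int(nrow(cand$pairs))[seq_len(n_false_bundles)]
      n_false <- rep_len(as.integer(streamlines_per_false_bundle),
                         n_false_bundles)
      for (j in seq_len(n_false_bundles)) {
        ci <- pick[j]
        cl <- cand$centerlines[[ci]]
        rad <- cand$radii[ci]
        fb <- bundle_fibers(cl, rad, n_false[j], phantom$grid,
                            offsets = "uniform", jitter_mm = jitter_mm)
        streamlines <- c(streamlines, fb)
        meta <- rbind(meta, data.frame(
          bundle_type = "false",
          bundle_id = length(phantom$bundles) + j,
          roi_a = cand$pairs[ci, 1],
          roi_b = cand$pairs[ci, 2])[rep(1, length(fb)), ])
      }
    }
    rownames(meta) <- NULL
    tractogram(streamlines, labels = meta)
  })
}

# Enumerate false bundles constructible by splicing two true-bundle
# centerlines at a shared crossing voxel. Returns each candidate's ROI
# pair (a < b), spliced centerline and radius.
spliced_false_candidates <- function(phantom) {
  nb <- length(phantom$bundles)
  grid <- phantom$grid
  vox_sets <- lapply(seq_len(nb), function(k) {
    sel <- which(phantom$fibers$labels$bundle == k)
    unique(unlist(lapply(phantom$fibers$streamlines[sel], function(s)
      segment_lengths(s, grid)$voxel)))
  })
  true_edges <- connectome_edges(phantom$true_connectome)
  true_key <- paste0(true_edges$roi_a, "-", true_edges$roi_b)
  pairs <- NULL
  centerlines <- list()
  radii <- numeric(0)
  seen <- character(0)
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    shared <- intersect(vox_sets[[i]], vox_sets[[j]])
    if (!length(shared)) next
    vx <- voxel_centers(grid, voxel_from_linear(grid, shared[1]))
    cli <- phantom$bundles[[i]]$centerline
    clj <- phantom$bundles[[j]]$centerline
    ki <- nearest_point(cli, vx)
    kj <- nearest_point(clj, vx)
    ends_i <- c(phantom$bundles[[i]]$roi_a, phantom$bundles[[i]]$roi_b)
    ends_j <- c(phantom$bundles[[j]]$roi_a, phantom$bundles[[j]]$roi_b)
    for (side_i in 1:2) for (side_j in 1:2) {
      ra <- ends_i[side_i]; rb <- ends_j[side_j]
      if (ra == rb) next
      key <- paste0(min(ra, rb), "-", max(ra, rb))
      if (key %in% true_key || key %in% seen) next
      part_i <- if (side_i == 1) cli[seq_len(ki), , drop = FALSE]
                else cli[nrow(cli):ki, , drop = FALSE]
      part_j <- if (side_j == 1) clj[kj:1, , drop = FALSE]
                else clj[kj:nrow(clj), , drop = FALSE]
      spliced <- resample_centerline(rbind(part_i, part_j), grid)
      seen <- c(seen, key)
      pairs <- rbind(pairs, c(min(ra, rb), max(ra, rb)))
      centerlines[[length(centerlines) + 1L]] <- spliced
      radii <- c(radii, min(phantom$bundles[[i]]$radius,
                            phantom$bundles[[j]]$radius))
    }
  }
  if (is.null(pairs)) pairs <- matrix(numeric(0), 0, 2)
  colnames(pairs) <- c("a", "b")
  list(pairs = pairs, centerlines = centerlines, radii = radii)
}

#' Number of real-negative ROI pairs reachable by the candidate generator
#'
#' The specificity denominator N: ROI pairs not connected in the ground
#' truth that the candidate-tractogram generator could connect by splicing
#' true bundles at crossings (the phantom analogue of counting the pairs
#' an exhaustive probabilistic tracking run can reach incorrectly).
#'
#' @param phantom a \code{phantom}.
#' @return integer count of constructible false ROI pairs.
#' @export
reachable_negatives <- function(phantom) {
  nrow(spliced_false_candidates(phantom)$pairs)
}

nearest_point <- function(points, target) {
  d2 <- (points[, 1] - target[1])^2 + (points[, 2] - target[2])^2 +
    (points[, 3] - target[3])^2
  which.min(d2)
}

# Smooth a spliced polyline through a coarse subsample (keeps exact
# endpoints, rounds off the splice kink the way streamline integration
# would).
resample_centerline <- function(points, grid, n_samples = 60L) {
  d <- sqrt(rowSums(diff(points)^2))
  keep <- c(TRUE, d > 1e-9)
  points <- points[keep, , drop = FALSE]
  u <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  sub <- unique(c(seq(1, nrow(points), by = 4L), nrow(points)))
  uu <- seq(0, u[length(u)], length.out = n_samples)
  cl <- vapply(1:3, function(k)
    stats::spline(u[sub], points[sub, k], xout = uu, method = "natural")$y,
    numeric(n_samples))
  clamp_to_grid(cl, grid)
}

#' Build the four-voxel stick-and-ball toy instance
#'
#' A 2 x 2 x 1 grid of 1 mm voxels with three streamlines and one
#' isotropic (ball) compartment per voxel. Fiber 1 crosses voxels 1 and 2,
#' fiber 2 crosses voxels 1 and 3, and fiber 3 crosses voxels 2, 3 and 4;
#' the noiseless signal is generated with x_true = (1, 1, 0, 0, 0, 0, 1):
#' fibers 1 and 2 carry unit contributions, fiber 3 is absent, and only
#' voxel 4 contains free (CSF-like) water. Solving NNLS on this instance
#' recovers x exactly, flagging fiber 3 as a false positive.
#'
#' @param n_dirs number of gradient directions (>= 7 so the 7 coefficients
#'   are identifiable; default 30).
#' @param b_value b-value in s/mm^2 (default 3000).
#' @param seed seed for the random rotation of the direction set.
#' @param d_par,d_iso stick / ball diffusivities in mm^2/s.
#' @return object of class \code{toy_instance}: \code{matrix} (a
#'   \code{contribution_matrix} with 7 columns), \code{signal},
#'   \code{x_true}, \code{incidence} (fiber -> linear voxel indices),
#'   \code{tract}, \code{grid}, \code{params}.
#' @export
make_toy_example <- function(n_dirs = 30L, b_value = 3000, seed = 1L,
                             d_par = 1.7e-3, d_iso = 3.0e-3) {
  if (n_dirs < 7L) stop("'n_dirs' must be >= 7 for identifiability")
  grid <- voxel_grid(c(2, 2, 1))
  f1 <- rbind(c(0.1, 0.5, 0.5), c(1.9, 0.5, 0.5))        # voxels 1, 2
  f2 <- rbind(c(0.5, 0.1, 0.5), c(0.5, 1.9, 0.5))        # voxels 1, 3
  f3 <- rbind(c(1.5, 0.1, 0.5), c(1.5, 1.5, 0.5),        # voxels 2, 4, 3
              c(0.1, 1.5, 0.5))
  tract <- tractogram(list(f1, f2, f3))
  dirs <- with_seed(seed, fibonacci_directions(n_dirs) %*% t(random_rotation()))
  params <- list(b = b_value, d_par = d_par, d_iso = d_iso,
                 directions = dirs)
  cm <- build_matrix(tract, grid, mode = "stickball",
                     include_isotropic = TRUE, model_params = params)
  x_true <- c(1, 1, 0, 0, 0, 0, 1)
  y <- predict_contributions(cm, x_true)
  structure(list(matrix = cm, signal = y, x_true = x_true,
                 incidence = list(fiber1 = c(1L, 2L),
                                  fiber2 = c(1L, 3L),
                                  fiber3 = c(2L, 3L, 4L)),
                 tract = tract, grid = grid, params = params),
            class = "toy_instance")
}
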