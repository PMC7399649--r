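# Shared fixtures, built once per test run. The reference phantom has 5
# true bundles among 10 ROIs; its candidate tractogram adds 4 spliced
# false bundles with heterogeneous cardinalities (one larger than the true
# bundles', so cardinality thresholding cannot be perfect).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

phantom_fx <- function() fixture("phantom", function()
  make_phantom(n_rois = 10, n_bundles = 5, seed = 42))

candidate_fx <- function() fixture("candidate", function()
  generate_candidate_tractogram(phantom_fx(),
                                streamlines_per_true_bundle = 15,
                                n_false_bundles = 4,
                                streamlines_per_false_bundle = c(20, 10, 8, 6),
                                jitter_mm = 0.2, seed = 42))

prep_fx <- function() fixture("prep", function()
  prepare_fit(candidate_fx(), phantom_fx()$parcellation,
              phantom_fx()$fraction_map))

lambda_grid_fx <- function() 10^seq(-4, 1, length.out = 20)

sweep_fx <- function() fixture("sweep", function() {
  p <- prep_fx()
  lambda_sweep(p$cm, p$y, p$groups, lambda_grid_fx(), solver_config())
})

true_pair_keys <- function(ph) {
  e <- connectome_edges(ph$true_connectome)
  paste0(e$roi_a, "-", e$roi_b)
}

# Small phantom for recovery-style checks (well-conditioned, fast).
small_phantom_fx <- function() fixture("small_phantom", function()
  make_phantom(n_rois = 6, n_bundles = 2, grid_dims = c(24, 24, 24),
               seed = 7, fibers_per_bundle = 8))

toy_fx <- function() fixture("toy", function() make_toy_example())

random_polyline <- function(n_pts, lo, hi) {
  matrix(runif(n_pts * 3, lo, hi), ncol = 3)
}

# Manually built endpoint assignment (bypasses a parcellation) for tests
# that need full control over the streamline -> ROI-pair mapping.
manual_assignment <- function(roi_a, roi_b, roi_labels = NULL) {
  out <- data.frame(streamline = seq_along(roi_a),
                    roi_a = as.integer(roi_a), roi_b = as.integer(roi_b),
                    assigned = !is.na(roi_a))
  class(out) <- c("endpoint_assignment", class(out))
  attr(out, "roi_labels") <- roi_labels
  out
}

# Exact proximal oracle by smooth constrained optimization (L-BFGS-B on a
# quadratic + smoothed norm), independent of the closed-form prox.
prox_qp_oracle <- function(v, t) {
  eps <- 1e-12
  f <- function(z) 0.5 * sum((z - v)^2) + t * sqrt(sum(z^2) + eps^2)
  g <- function(z) (z - v) + t * z / sqrt(sum(z^2) + eps^2)
  stats::optim(pmax(v, 0), f, g, method = "L-BFGS-B", lower = 0,
               control = list(factr = 10, maxit = 1000))$par
}
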