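test_that("phantom generation is deterministic and honors edge counts", {
  ph <- small_phantom_fx()
  ph2 <- make_phantom(n_rois = 6, n_bundles = 2, grid_dims = c(24, 24, 24),
                      seed = 7, fibers_per_bundle = 8)
  expect_identical(ph$fraction_map, ph2$fraction_map)
  expect_identical(ph$fibers$streamlines, ph2$fibers$streamlines)
  expect_equal(n_edges(ph$true_connectome), 2)
  # requesting a density fixes the bundle count: 10% of 190 pairs -> 19
  ph3 <- make_phantom(n_rois = 20, density = 0.10, seed = 3,
                      fibers_per_bundle = 4)
  expect_equal(n_edges(ph3$true_connectome), 19)
  expect_equal(network_density(ph3$true_connectome), 0.1)
  # every true bundle covers at least one voxel of the fraction map
  for (k in seq_along(ph$bundles)) {
    sel <- which(ph$fibers$labels$bundle == k)
    vox <- unlist(lapply(ph$fibers$streamlines[sel], function(s)
      segment_lengths(s, ph$grid)$voxel))
    expect_gt(sum(ph$fraction_map[unique(vox)] > 0), 0)
  }
  expect_true(all(ph$fraction_map >= 0 & ph$fraction_map <= 1))
})

test_that("empty and infeasible phantoms behave as specified", {
  ph0 <- make_phantom(n_rois = 5, n_bundles = 0, grid_dims = c(16, 16, 16),
                      seed = 1)
  expect_equal(n_edges(ph0$true_connectome), 0)
  expect_true(all(ph0$fraction_map == 0))
  expect_error(make_phantom(n_rois = 3, n_bundles = 9, seed = 1), "pairs")
  expect_error(make_phantom(n_rois = 40, n_bundles = 1,
                            grid_dims = c(10, 10, 10), seed = 1),
               "infeasible|too small")
})

test_that("fraction map equals the length operator applied to fiber areas", {
  ph <- small_phantom_fx()
  cm <- build_matrix(ph$fibers, ph$grid, mode = "length")
  pred <- predict_contributions(cm, ph$fiber_areas)
  expect_equal(pred, as.numeric(ph$fraction_map), tolerance = 1e-10)
})

test_that("compute_fraction_map accumulates length times area per voxel", {
  g <- voxel_grid(c(3, 3, 3))
  s <- rbind(c(1, 1.5, 1.5), c(2, 1.5, 1.5))   # 1 mm inside voxel (1,1,1)
  fm <- compute_fraction_map(tractogram(list(s)), g, area_per_fiber = 0.1)
  expect_equal(fm[2, 2, 2], 0.1)
  expect_equal(sum(fm > 0), 1)
  # clipping warns
  expect_warning(compute_fraction_map(tractogram(list(s)), g, 2), "clipped")
  # out-of-grid points are an error
  bad <- rbind(c(-5, 0, 0), c(1, 1, 1))
  expect_error(compute_fraction_map(tractogram(list(bad)), g, 0.1),
               "outside")
})

test_that("candidate tractograms mix labeled true and false bundles", {
  ph <- phantom_fx()
  cand <- candidate_fx()
  expect_identical(
    cand$streamlines,
    generate_candidate_tractogram(ph, 15, 4, c(20, 10, 8, 6), 0.2,
                                  seed = 42)$streamlines)
  expect_equal(sum(cand$labels$bundle_type == "true"), 5 * 15)
  expect_equal(sum(cand$labels$bundle_type == "false"), 20 + 10 + 8 + 6)
  # every labeled pair of a false bundle is absent from the ground truth
  tk <- true_pair_keys(ph)
  fk <- unique(with(cand$labels[cand$labels$bundle_type == "false", ],
                    paste0(roi_a, "-", roi_b)))
  expect_length(intersect(fk, tk), 0)
  expect_equal(length(fk), 4)
  # streamlines terminate within the assignment radius of their ROIs
  asg <- assign_endpoints(cand, ph$parcellation, radius = 2)
  expect_true(all(asg$assigned))
  expect_equal(paste0(asg$roi_a, "-", asg$roi_b),
               paste0(cand$labels$roi_a, "-", cand$labels$roi_b))
  # with no false bundles every endpoint pair is a true edge
  cand0 <- generate_candidate_tractogram(ph, 5, 0, seed = 1)
  k0 <- unique(paste0(cand0$labels$roi_a, "-", cand0$labels$roi_b))
  expect_true(all(k0 %in% tk))
  # asking for more false bundles than constructible pairs fails loudly
  expect_error(generate_candidate_tractogram(ph, 5, 10000, 5, seed = 1),
               "false bundles")
})

test_that("two crossing bundles yield four distinct endpoint pairs", {
  ph <- make_phantom(n_rois = 6, n_bundles = 2, grid_dims = c(24, 24, 24),
                     seed = 12, fibers_per_bundle = 8)
  expect_gte(reachable_negatives(ph), 2)
  cand <- generate_candidate_tractogram(ph, 5, 2, 5, seed = 2)
  pairs <- unique(paste0(cand$labels$roi_a, "-", cand$labels$roi_b))
  expect_equal(length(pairs), 4)
})

test_that("the toy instance reproduces the printed incidence and signal", {
  toy <- toy_fx()
  expect_identical(toy$incidence,
                   list(fiber1 = c(1L, 2L), fiber2 = c(1L, 3L),
                        fiber3 = c(2L, 3L, 4L)))
  expect_equal(ncol(toy$matrix$A), 7)
  expect_equal(toy$x_true, c(1, 1, 0, 0, 0, 0, 1))
  # the signal in voxel 4 is exactly the ball column of voxel 4
  nd <- toy$matrix$n_dirs
  rows4 <- (4 - 1) * nd + seq_len(nd)
  expect_equal(toy$signal[rows4], as.numeric(toy$matrix$A[rows4, 7]))
  # identifiability: full column rank with generic directions
  expect_gte(qr(as.matrix(toy$matrix$A))$rank, 7)
  expect_error(make_toy_example(n_dirs = 5), "identifiability")
  expect_identical(make_toy_example(seed = 4)$signal,
                   make_toy_example(seed = 4)$signal)
})
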