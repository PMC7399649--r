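edge_conn <- function(edges, labs) connectome_from_edges(edges, labs)

test_that("bundle classification counts valid and invalid edges", {
  labs <- 1:6
  truth <- edge_conn(data.frame(roi_a = c(1, 2, 3), roi_b = c(2, 3, 4),
                                weight = c(5, 5, 5)), labs)
  expect_equal(classify_bundles(truth, truth)[c("VB", "IB")],
               list(VB = 3L, IB = 0L))
  disj <- edge_conn(data.frame(roi_a = c(1, 5), roi_b = c(5, 6),
                               weight = 1), labs)
  expect_equal(classify_bundles(disj, truth)$VB, 0L)
  # random fixture vs brute-force enumeration
  withr::with_seed(41, {
    for (r in 1:10) {
      pairs <- t(utils::combn(6, 2))
      tr <- pairs[sample(15, 5), ]
      es <- pairs[sample(15, 7), ]
      truth_r <- edge_conn(data.frame(roi_a = tr[, 1], roi_b = tr[, 2],
                                      weight = 1), labs)
      est_r <- edge_conn(data.frame(roi_a = es[, 1], roi_b = es[, 2],
                                    weight = sample(1:9, 7, TRUE)), labs)
      key <- function(m) paste(m[, 1], m[, 2])
      vb <- sum(key(es) %in% key(tr))
      cls <- classify_bundles(est_r, truth_r)
      expect_equal(cls$VB, vb)
      expect_equal(cls$IB, 7 - vb)
      expect_equal(cls$VC + cls$IC, 1)
    }
  })
  mis <- edge_conn(data.frame(roi_a = 1, roi_b = 2, weight = 1), 1:5)
  expect_error(classify_bundles(mis, truth), "label")
})

test_that("Youden's index reproduces the printed phantom values", {
  # probabilistic tracking phantom: 27 true bundles, 594 reachable negatives
  expect_equal(round_half_away(youden(27, 20, 27, 594), 2), 0.97)
  expect_equal(round_half_away(youden(25, 120, 27, 594), 2), 0.72)
  # the corresponding printed specificities, as percentages
  expect_equal(round_half_away(100 * (1 - 20 / 594), 1), 96.6)
  expect_equal(round_half_away(100 * (1 - 441 / 594), 1), 25.8)
  # bounds attained
  expect_equal(youden(27, 0, 27, 594), 1)
  expect_equal(youden(0, 594, 27, 594), -1)
  expect_error(youden(28, 0, 27, 594), "VB")
  expect_error(youden(0, 600, 27, 594), "IB")
})

test_that("connectome error is max-normalized and scale invariant", {
  labs <- 1:4
  truth <- edge_conn(data.frame(roi_a = c(1, 2), roi_b = c(2, 3),
                                weight = c(4, 2)), labs)
  expect_equal(connectome_error(truth, truth), 0)
  scaled <- truth; scaled$matrix <- 7.3 * scaled$matrix
  expect_equal(connectome_error(scaled, truth), 0)
  # hand-computed two-edge example: truth (1,0.5), estimate (1,1) after
  # normalization, plus a spurious edge 0.25
  est <- edge_conn(data.frame(roi_a = c(1, 2, 1), roi_b = c(2, 3, 4),
                              weight = c(8, 8, 2)), labs)
  expect_equal(connectome_error(est, truth),
               sqrt((1 - 1)^2 + (0.5 - 1)^2 + 0.25^2))
  expect_equal(connectome_error(est, truth, "tp_only"),
               sqrt((0.5 - 1)^2))
  expect_lte(connectome_error(est, truth, "tp_only"),
             connectome_error(est, truth, "all"))
  # full-matrix mode doubles the squared sum on symmetric input
  expect_equal(connectome_error(est, truth, full = TRUE),
               sqrt(2) * connectome_error(est, truth))
  # all-zero estimate is left unnormalized (treated as zeros)
  zero <- edge_conn(data.frame(roi_a = 1, roi_b = 2, weight = 0), labs)
  expect_equal(connectome_error(zero, truth), sqrt(1 + 0.5^2))
})

test_that("cardinality thresholding removes low-count edges monotonically", {
  labs <- 1:5
  raw <- edge_conn(data.frame(roi_a = c(1, 1, 2, 3), roi_b = c(2, 3, 4, 5),
                              weight = c(10, 3, 1, 7)), labs)
  expect_equal(threshold_filter(raw, 0)$matrix, raw$matrix)
  expect_equal(n_edges(threshold_filter(raw, 10)), 0)
  truth <- edge_conn(data.frame(roi_a = c(1, 3), roi_b = c(2, 5),
                                weight = 1), labs)
  sweep <- threshold_sweep(raw, truth, P = 2, N = 8)
  expect_true(all(diff(sweep$VB) <= 0))
  expect_true(all(diff(sweep$IB) <= 0))
  expect_error(threshold_filter(
    build_connectome(manual_assignment(1, 2, 1:2), weights = 1,
                     weight_definition = "sum_of_weights"), 1),
    "streamline-count")
})

test_that("random removal matches its closed-form expectation", {
  labs <- 1:8
  pairs <- t(utils::combn(8, 2))
  truth <- edge_conn(data.frame(roi_a = pairs[1:6, 1], roi_b = pairs[1:6, 2],
                                weight = 1), labs)
  est <- edge_conn(data.frame(roi_a = pairs[1:15, 1], roi_b = pairs[1:15, 2],
                              weight = 1), labs)
  P <- 6; N <- 20
  base <- classify_bundles(est, truth)
  J0 <- youden(base$VB, base$IB, P, N)
  expect_equal(random_filter_score(est, truth, 0, 10, 1, P, N), J0)
  expect_equal(random_filter_score(est, truth, 1, 10, 1, P, N), 0)
  # E[J] = keep * VB/P + 1 - keep * IB/N - 1 with keep = 1 - floor(rn)/n
  rate <- 0.4
  keep <- 1 - floor(rate * 15) / 15
  expectation <- keep * base$VB / P + (1 - keep * base$IB / N) - 1
  mc <- random_filter_score(est, truth, rate, n_repeats = 1e4, seed = 9,
                            P = P, N = N)
  expect_equal(mc, expectation, tolerance = 0.02)
  # determinism given the seed
  expect_identical(mc, random_filter_score(est, truth, rate, 1e4, 9, P, N))
})

test_that("roc_sweep scores solutions and locates the best J", {
  asg <- manual_assignment(c(1, 1, 2, 2), c(2, 2, 3, 3), roi_labels = 1:3)
  truth <- edge_conn(data.frame(roi_a = 1, roi_b = 2, weight = 2), 1:3)
  sols <- list(list(x = c(1, 1, 1, 1)),     # raw: both edges
               list(x = c(1, 1, 0, 0)))     # filtered: true edge only
  roc <- roc_sweep(sols, asg, truth, P = 1, N = 2, lambdas = c(0, 1))
  expect_equal(roc$VB, c(1, 1))
  expect_equal(roc$IB, c(1, 0))
  expect_equal(roc$J, c(youden(1, 1, 1, 2), 1))
  expect_equal(attr(roc, "best"), 2L)
  expect_gte(max(roc$J), roc$J[1])
})
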