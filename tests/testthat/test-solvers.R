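test_that("group_prox handles boundary, projection and exempt cases", {
  gs <- group_structure(list(g = 1:2), 2)
  # norm equal to the threshold: group exactly zeroed
  expect_equal(group_prox(c(3, 4), gs, 5), c(0, 0))
  # zero threshold: pure projection onto the non-negative orthant
  expect_equal(group_prox(c(-1, 2), gs, 0), c(0, 2))
  # infinite threshold: group forced inactive
  expect_equal(group_prox(c(3, 4), gs, Inf), c(0, 0))
  # exempt columns are projected only
  gs2 <- group_structure(list(g = 1:2), 4, exempt = 3:4)
  expect_equal(group_prox(c(3, 4, -2, 7), gs2, 0.5),
               c(c(3, 4) * (1 - 0.5 / 5), 0, 7))
  expect_error(group_prox(c(1, 2), gs, -1), ">= 0")
})

test_that("group_prox agrees with a constrained-QP oracle", {
  withr::with_seed(21, {
    for (r in 1:30) {
      n <- sample(1:6, 1)
      v <- rnorm(n, 0, 2)
      t <- runif(1, 0, 3)
      gs <- group_structure(list(g = seq_len(n)), n)
      mine <- group_prox(v, gs, t)
      orc <- prox_qp_oracle(v, t)
      obj <- function(z) 0.5 * sum((z - v)^2) + t * sqrt(sum(z^2))
      expect_lte(obj(mine) - obj(orc), 1e-8)
      expect_equal(mine, orc, tolerance = 1e-5)
    }
  })
})

test_that("NNLS recovers noiseless solutions and matches the active-set oracle", {
  skip_if_not_installed("pracma")
  cfg <- solver_config(max_iter = 20000, tol = 1e-14)
  withr::with_seed(22, {
    for (r in 1:30) {
      A <- matrix(rnorm(8 * 5), 8, 5)
      x_true <- pmax(rnorm(5), 0)
      # noiseless recovery
      sol <- solve_nnls(A, as.numeric(A %*% x_true), cfg)
      expect_equal(sol$x, x_true, tolerance = 1e-6)
      # noisy instance: objective matches Lawson-Hanson active-set NNLS
      y <- as.numeric(A %*% x_true) + rnorm(8, 0, 0.3)
      sol2 <- solve_nnls(A, y, cfg)
      orc <- pracma::lsqnonneg(A, y)
      expect_lt(abs(sum((A %*% sol2$x - y)^2) - orc$resid.norm), 1e-6)
      expect_true(all(sol2$x >= 0))
    }
  })
  expect_equal(solve_nnls(matrix(rnorm(12), 4), numeric(4), cfg)$x,
               numeric(3))
  expect_warning(solve_nnls(matrix(0, 3, 2), c(1, 1, 1)), "zero operator")
  expect_error(solve_nnls(matrix(1, 3, 2), c(1, NA, 1)), "finite")
})

test_that("adaptive weights implement lambda * |g| / ||x_nnls(g)||", {
  gs <- group_structure(list(a = 1:4, b = 5:6), 6)
  x <- c(1, 1, 1, 1, 0, 0)
  w <- compute_adaptive_weights(x, gs, lambda = 1)$weights
  expect_equal(unname(w[1]), 1 * 4 / 2)      # |g| = 4, norm 2
  expect_equal(unname(w[2]), Inf)            # zero-norm group -> sentinel
  expect_equal(compute_adaptive_weights(x, gs, 0)$weights, c(0, 0))
  expect_error(compute_adaptive_weights(x, gs, -1), ">= 0")
  # sqrt-cardinality variant
  w2 <- compute_adaptive_weights(x, gs, 1, sqrt_cardinality = TRUE)$weights
  expect_equal(unname(w2[1]), sqrt(4) / 2)
})

test_that("group lasso at lambda 0 equals NNLS and saturates for large lambda", {
  withr::with_seed(23, {
    A <- matrix(abs(rnorm(40 * 9)), 40, 9)
    x_true <- c(rep(1, 3), rep(0, 3), rep(0.5, 3))
    y <- as.numeric(A %*% x_true) + abs(rnorm(40, 0, 0.05))
    gs <- group_structure(list(a = 1:3, b = 4:6, c = 7:9), 9)
    cfg <- solver_config(max_iter = 20000, tol = 1e-14)
    nn <- solve_nnls(A, y, cfg)
    gl0 <- solve_group_lasso(A, y, gs, solver_config(lambda = 0,
                                                     max_iter = 20000,
                                                     tol = 1e-14))
    expect_lt(abs(gl0$objective - nn$objective), 1e-8)
    # large lambda: all penalized groups inactive, residual = ||y||
    glbig <- solve_group_lasso(A, y, gs, solver_config(lambda = 1e6,
                                                       max_iter = 5000,
                                                       tol = 1e-12))
    expect_length(glbig$active_groups, 0)
    expect_equal(glbig$residual_norm, sqrt(sum(y^2)))
    # feasibility is exact and the trace is monotone
    expect_true(all(gl0$x >= 0))
    expect_true(all(diff(gl0$objective_trace) <= 1e-10))
    # KKT stationarity at convergence
    gsw <- compute_adaptive_weights(nn$x, gs, 0.01)
    gl <- solve_group_lasso(A, y, gsw, solver_config(lambda = 0.01,
                                                     max_iter = 20000,
                                                     tol = 1e-14))
    expect_lt(kkt_residual(A, y, gsw, gl$x), 1e-6)
    expect_lt(kkt_residual(A, y, NULL, nn$x), 1e-6)
  })
})

test_that("lasso is group lasso with singleton groups", {
  withr::with_seed(24, {
    A <- matrix(abs(rnorm(30 * 6)), 30, 6)
    y <- as.numeric(A %*% c(1, 0, 2, 0, 0.5, 0)) + abs(rnorm(30, 0, 0.02))
    cfg <- solver_config(lambda = 0.05, max_iter = 20000, tol = 1e-14)
    las <- solve_lasso(A, y, cfg)
    gs <- group_structure(as.list(1:6), 6)
    gl <- solve_group_lasso(A, y, gs, cfg)
    expect_lt(abs(las$objective - gl$objective), 1e-8)
    cfg0 <- solver_config(lambda = 0, max_iter = 20000, tol = 1e-14)
    expect_lt(abs(solve_lasso(A, y, cfg0)$objective -
                  solve_nnls(A, y, cfg0)$objective), 1e-8)
  })
})

test_that("lambda_sweep is warm-started, ordered and consistent", {
  withr::with_seed(25, {
    A <- matrix(abs(rnorm(30 * 6)), 30, 6)
    y <- as.numeric(A %*% c(1, 1, 0, 0, 0.5, 0.5)) + abs(rnorm(30, 0, 0.05))
    gs <- group_structure(list(a = 1:2, b = 3:4, c = 5:6), 6)
    cfg <- solver_config(max_iter = 10000, tol = 1e-12)
    expect_error(lambda_sweep(A, y, gs, numeric(0), cfg), "empty")
    expect_error(lambda_sweep(A, y, gs, c(1, 0.1), cfg), "ascending")
    # grid of one zero: the NNLS solution
    s0 <- lambda_sweep(A, y, gs, 0, cfg)
    expect_lt(abs(s0[[1]]$objective - solve_nnls(A, y, cfg)$objective), 1e-8)
    grid <- c(0, 10^seq(-3, 1, length.out = 8))
    sols <- lambda_sweep(A, y, gs, grid, cfg)
    res <- vapply(sols, `[[`, numeric(1), "residual_norm")
    obj <- vapply(sols, `[[`, numeric(1), "objective")
    expect_true(all(diff(res) >= -1e-8))
    expect_true(all(diff(obj) >= -1e-8))
    # warm starts do not change the answer: cold-start spot check
    cold <- solve_group_lasso(A, y,
                              compute_adaptive_weights(solve_nnls(A, y, cfg)$x,
                                                       gs, grid[5]),
                              cfg)
    expect_lt(abs(cold$objective - sols[[5]]$objective), 1e-7)
  })
})

test_that("small instances match a generic constrained-optimization oracle", {
  # penalized objective vs L-BFGS-B on a smoothed surrogate, <= 10 columns
  withr::with_seed(26, {
    for (r in 1:10) {
      n <- sample(3:10, 1)
      A <- matrix(rnorm(20 * n), 20, n)
      y <- rnorm(20)
      ng <- sample(1:3, 1)
      splitix <- sort(sample(rep(seq_len(ng), length.out = n)))
      gs <- group_structure(split(seq_len(n), splitix), n)
      gs$weights <- runif(ng, 0, 2)
      sol <- fista_obj <- solve_group_lasso(A, y, gs,
                                            solver_config(max_iter = 20000,
                                                          tol = 1e-14))
      eps <- 1e-10
      f <- function(x) sum((A %*% x - y)^2) +
        sum(vapply(seq_len(ng), function(k)
          gs$weights[k] * sqrt(sum(x[gs$groups[[k]]]^2) + eps^2), numeric(1)))
      o <- stats::optim(pmax(rep(0.1, n), 0), f, method = "L-BFGS-B",
                        lower = 0, control = list(factr = 10, maxit = 2000))
      expect_lt(sol$objective - o$value, 1e-6)
    }
  })
})
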