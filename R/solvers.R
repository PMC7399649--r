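#' Solver configuration
#'
#' @param lambda regularization strength, lambda >= 0.
#' @param max_iter maximum number of proximal-gradient iterations.
#' @param tol stopping tolerance on the relative objective change.
#' @param seed integer seed for any randomized component (kept for
#'   reproducibility bookkeeping; the default solver is deterministic).
#' @return list of class \code{solver_config}.
#' @export
solver_config <- function(lambda = 0, max_iter = 2000L, tol = 1e-8,
                          seed = 1L) {
  if (lambda < 0) stop("'lambda' must be >= 0")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("'max_iter' must be >= 1")
  if (!is.finite(tol) || tol <= 0) stop("'tol' must be > 0")
  structure(list(lambda = lambda, max_iter = max_iter, tol = tol,
                 seed = as.integer(seed)), class = "solver_config")
}

#' Partition of matrix columns into penalized bundles
#'
#' Groups are disjoint sets of column indices, one per anatomical bundle;
#' exempt columns (e.g. isotropic compartments) are projected to be
#' non-negative but never penalized. Every column must belong to exactly one
#' group or be exempt.
#'
#' @param groups named list of integer column-index vectors.
#' @param n_columns total number of matrix columns.
#' @param exempt integer vector of unpenalized column indices.
#' @param weights optional per-group penalty weights lambda^(g) >= 0;
#'   \code{Inf} marks a group whose coefficients are fixed to zero.
#' @return list of class \code{group_structure} with elements
#'   \code{groups}, \code{cardinalities}, \code{exempt}, \code{weights},
#'   \code{n_columns}.
#' @export
group_structure <- function(groups, n_columns, exempt = integer(0),
                            weights = NULL) {
  if (!is.list(groups)) stop("'groups' must be a list")
  groups <- lapply(groups, as.integer)
  if (is.null(names(groups)) && length(groups))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group must contain at least one column")
  all_idx <- c(unlist(groups, use.names = FALSE), as.integer(exempt))
  if (anyDuplicated(all_idx))
    stop("groups and exempt columns must be disjoint")
  if (!setequal(all_idx, seq_len(n_columns)))
    stop("union of groups and exempt columns must cover all columns")
  if (!is.null(weights)) {
    if (length(weights) != length(groups))
      stop("'weights' must have one entry per group")
    if (any(weights < 0)) stop("penalty weights must be >= 0")
  }
  structure(list(groups = groups,
                 cardinalities = vapply(groups, length, integer(1)),
                 exempt = as.integer(exempt),
                 weights = weights,
                 n_columns = as.integer(n_columns)),
            class = "group_structure")
}

#' @export
print.group_structure <- function(x, ...) {
  cat(sprintf("<group_structure> %d groups over %d columns (%d exempt)\n",
              length(x$groups), x$n_columns, length(x$exempt)))
  invisible(x)
}

#' Proximal operator of the non-negative group-L2 penalty
#'
#' For each group g with threshold t_g, the exact proximal map of
#' t_g * ||x^(g)||_2 plus the constraint x >= 0 is computed: first project
#' onto the non-negative orthant, p = max(v, 0), then apply block soft
#' thresholding, p * max(0, 1 - t_g / ||p||_2) (the whole group is zeroed
#' when ||p||_2 <= t_g). Exempt columns are only projected. A group with
#' threshold \code{Inf} is forced to zero.
#'
#' @param v numeric coefficient vector.
#' @param groups a \code{group_structure}.
#' @param thresholds per-group non-negative scalar thresholds.
#' @return numeric vector of the same length as \code{v}.
#' @export
group_prox <- function(v, groups, thresholds) {
  stopifnot(inherits(groups, "group_structure"))
  if (length(thresholds) != length(groups$groups))
    stop("'thresholds' must have one entry per group")
  if (any(thresholds < 0)) stop("'thresholds' must be >= 0")
  out <- numeric(length(v))
  if (length(groups$exempt))
    out[groups$exempt] <- pmax(v[groups$exempt], 0)
  for (k in seq_along(groups$groups)) {
    idx <- groups$groups[[k]]
    p <- pmax(v[idx], 0)
    t_g <- thresholds[k]
    if (is.infinite(t_g)) next           # stays zero
    if (t_g == 0) { out[idx] <- p; next }
    nrm <- sqrt(sum(p^2))
    if (nrm > t_g) out[idx] <- p * (1 - t_g / nrm)
  }
  out
}

#' Adaptive group-lasso penalty weights
#'
#' Sets each group's penalty to lambda * |g| / ||x_nnls^(g)||_2, where |g|
#' is the group cardinality and x_nnls the unregularized non-negative
#' least-squares solution. Groups whose NNLS norm is (numerically) zero
#' receive an \code{Inf} sentinel: the NNLS fit already deems them
#' unnecessary and their coefficients are fixed to zero in subsequent
#' solves. With \code{lambda = 0} all weights are zero.
#'
#' @param x_nnls non-negative NNLS coefficient vector.
#' @param groups a \code{group_structure}.
#' @param lambda scalar >= 0.
#' @param sqrt_cardinality use sqrt(|g|) instead of |g| in the numerator
#'   (non-default variant; the default follows the adaptive weights as
#'   commonly printed, proportional to the plain cardinality).
#' @return the \code{group_structure} with \code{weights} filled in.
#' @export
compute_adaptive_weights <- function(x_nnls, groups, lambda,
                                     sqrt_cardinality = FALSE) {
  stopifnot(inherits(groups, "group_structure"))
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (any(x_nnls < 0)) stop("'x_nnls' must be non-negative")
  card <- groups$cardinalities
  if (sqrt_cardinality) card <- sqrt(card)
  norms <- vapply(groups$groups,
                  function(idx) sqrt(sum(x_nnls[idx]^2)), numeric(1))
  if (lambda == 0) {
    w <- rep(0, length(norms))
  } else {
    w <- ifelse(norms <= 1e-12, Inf, lambda * card / norms)
  }
  groups$weights <- w
  groups
}

# Largest squared singular value of A by power iteration (deterministic
# start); underestimates are harmless because the solver backtracks.
spectral_norm_sq <- function(A, iters = 60L) {
  nc <- ncol(A)
  v <- seq_len(nc) / nc + 1
  v <- v / sqrt(sum(v^2))
  est <- 0
  for (i in seq_len(iters)) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    est_new <- nw
    v <- w / nw
    if (i > 5L && abs(est_new - est) <= 1e-12 * est_new) { est <- est_new; break }
    est <- est_new
  }
  est
}

as_operator <- function(A) {
  if (inherits(A, "contribution_matrix")) A$A else A
}

# Accelerated proximal gradient (FISTA) with adaptive restart and step
# backtracking. The objective is ||Ax - y||_2^2 + sum_g w_g ||x^(g)||_2
# subject to x >= 0; restart on objective increase makes the recorded
# trace non-increasing.
fista_solve <- function(A, y, groups, config, x0 = NULL) {
  A <- as_operator(A)
  y <- as.numeric(y)
  if (length(y) != nrow(A)) stop("length(y) must equal nrow(A)")
  if (any(!is.finite(y))) stop("'y' must be finite")
  nc <- ncol(A)
  w <- if (is.null(groups$weights)) rep(0, length(groups$groups)) else groups$weights
  # Diagonal preconditioning: rescale columns to comparable norms. Exempt
  # columns are equilibrated individually; penalized columns use one scale
  # per group (shared within the group), so the group-L2 penalty transforms
  # exactly (w_g -> w_g / d_g) and the objective value is unchanged.
  cn <- sqrt(Matrix::colSums(A^2))
  d <- rep(1, nc)
  if (length(groups$exempt)) d[groups$exempt] <- cn[groups$exempt]
  for (k in seq_along(groups$groups)) {
    idx <- groups$groups[[k]]
    d[idx] <- sqrt(mean(cn[idx]^2))
  }
  d[!is.finite(d) | d <= 0] <- 1
  A_orig <- A
  A <- A %*% Matrix::Diagonal(x = 1 / d)
  w_orig <- w
  w <- vapply(seq_along(groups$groups),
              function(k) w[k] / d[groups$groups[[k]][1L]], numeric(1))
  if (!is.null(x0)) x0 <- as.numeric(x0) * d
  penalty <- function(x) {
    if (!length(groups$groups)) return(0)
    s <- 0
    for (k in seq_along(groups$groups)) {
      if (is.infinite(w[k])) next      # group fixed to zero, no cost
      if (w[k] == 0) next
      s <- s + w[k] * sqrt(sum(x[groups$groups[[k]]]^2))
    }
    s
  }
  prox <- function(v, step) group_prox(v, groups, w * step)
  L <- 2 * spectral_norm_sq(A)
  if (L <= 0) {
    warning("zero operator: returning x = 0")
    return(finish_solution(numeric(nc), sum(y^2), sum(y^2), y, A, groups, 0L, TRUE))
  }
  step0 <- 1 / L
  x <- if (is.null(x0)) numeric(nc) else pmax(as.numeric(x0), 0)
  for (k in seq_along(groups$groups))  # enforce Inf-sentinel zeros on warm starts
    if (is.infinite(w[k])) x[groups$groups[[k]]] <- 0
  obj_of <- function(x) sum((as.numeric(A %*% x) - y)^2) + penalty(x)
  trace <- obj_of(x)
  z <- x
  tk <- 1
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    res <- backtracked_step(A, y, z, prox, step0)
    xc <- res$x
    Fc <- res$fsmooth + penalty(xc)
    if (Fc > trace[length(trace)] + 1e-12 * max(1, abs(Fc))) {
      # momentum overshoot: restart with a plain prox step from x
      tk <- 1
      res <- backtracked_step(A, y, x, prox, step0)
      xc <- res$x
      Fc <- res$fsmooth + penalty(xc)
      if (Fc > trace[length(trace)]) { xc <- x; Fc <- trace[length(trace)] }
    }
    prev <- trace[length(trace)]
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- xc + ((tk - 1) / t_new) * (xc - x)
    x <- xc
    tk <- t_new
    trace <- c(trace, Fc)
    if (abs(prev - Fc) <= config$tol * max(abs(prev), 1e-12)) {
      converged <- TRUE
      break
    }
  }
  x <- x / d                           # back to the original column scale
  r <- as.numeric(A_orig %*% x) - y
  finish_solution(x, trace, trace[length(trace)], y, A_orig, groups,
                  length(trace) - 1L, converged)
}

backtracked_step <- function(A, y, z, prox, step0) {
  rz <- as.numeric(A %*% z) - y
  fz <- sum(rz^2)
  g <- as.numeric(2 * Matrix::crossprod(A, rz))
  step <- step0
  repeat {
    xc <- prox(z - step * g, step)
    dx <- xc - z
    fx <- sum((as.numeric(A %*% xc) - y)^2)
    bound <- fz + sum(g * dx) + sum(dx^2) / (2 * step)
    if (fx <= bound + 1e-12 * max(1, abs(fz))) break
    step <- step / 2
    if (step < step0 * 2^-40)
      stop("step backtracking exhausted; objective diverged")
  }
  list(x = xc, fsmooth = fx, step = step)
}

finish_solution <- function(x, trace, obj, y, A, groups, iterations,
                            converged) {
  gnorm <- vapply(groups$groups, function(idx) sqrt(sum(x[idx]^2)),
                  numeric(1))
  active <- names(groups$groups)[gnorm > 1e-12]
  r <- as.numeric(A %*% x) - y
  structure(list(x = x,
                 objective_trace = as.numeric(trace),
                 objective = obj,
                 active_groups = active,
                 group_norms = gnorm,
                 residual_norm = sqrt(sum(r^2)),
                 iterations = iterations,
                 converged = converged),
            class = "tract_solution")
}

#' @export
print.tract_solution <- function(x, ...) {
  cat(sprintf(
    "<tract_solution> %d coefficients (%d nonzero), %d/%s groups active\n  objective %.6g, residual %.6g, %d iterations%s\n",
    length(x$x), sum(x$x > 1e-12), length(x$active_groups),
    if (length(x$group_norms)) as.character(length(x$group_norms)) else "0",
    x$objective, x$residual_norm, x$iterations,
    if (x$converged) "" else " (max_iter reached)"))
  invisible(x)
}

#' Non-negative least squares
#'
#' Minimizes ||A x - y||_2^2 over x >= 0 by accelerated projected gradient
#' (FISTA with projection onto the non-negative orthant, adaptive restart,
#' and a power-method Lipschitz estimate with step backtracking).
#'
#' @param A a \code{contribution_matrix} or a (sparse) matrix.
#' @param y data vector.
#' @param config a \code{solver_config}.
#' @return a \code{tract_solution}.
#' @export
solve_nnls <- function(A, y, config = solver_config()) {
  Am <- as_operator(A)
  gs <- group_structure(list(), n_columns = ncol(Am),
                        exempt = seq_len(ncol(Am)))
  fista_solve(Am, y, gs, config)
}

#' Adaptive group-lasso fit
#'
#' Minimizes ||A x - y||_2^2 + sum_g lambda^(g) ||x^(g)||_2 over x >= 0.
#' When the group weights are not already set, they are computed internally
#' from an initial NNLS solve via \code{\link{compute_adaptive_weights}}
#' with \code{config$lambda}. Setting \code{lambda = 0} recovers the plain
#' NNLS fit.
#'
#' @param A a \code{contribution_matrix} or a (sparse) matrix.
#' @param y data vector.
#' @param groups a \code{group_structure} (weights optional).
#' @param config a \code{solver_config}.
#' @param x0 optional warm-start coefficients.
#' @return a \code{tract_solution}.
#' @export
solve_group_lasso <- function(A, y, groups, config = solver_config(),
                              x0 = NULL) {
  stopifnot(inherits(groups, "group_structure"))
  if (is.null(groups$weights)) {
    x_nnls <- solve_nnls(A, y, config)$x
    groups <- compute_adaptive_weights(x_nnls, groups, config$lambda)
  }
  fista_solve(as_operator(A), y, groups, config, x0 = x0)
}

#' Adaptive lasso fit (singleton groups)
#'
#' The same formulation as \code{\link{solve_group_lasso}} but with every
#' streamline in its own group, i.e. sparsity is promoted at the level of
#' individual streamlines rather than anatomical bundles. Per-column
#' adaptive weights are lambda / x_nnls_i.
#'
#' @inheritParams solve_group_lasso
#' @return a \code{tract_solution}.
#' @export
solve_lasso <- function(A, y, config = solver_config(), x0 = NULL) {
  Am <- as_operator(A)
  kinds <- if (inherits(A, "contribution_matrix")) A$column_kinds
           else rep("streamline", ncol(Am))
  sl <- which(kinds == "streamline")
  gs <- group_structure(as.list(sl), n_columns = ncol(Am),
                        exempt = which(kinds != "streamline"))
  names(gs$groups) <- paste0("s", sl)
  x_nnls <- solve_nnls(Am, y, config)$x
  gs <- compute_adaptive_weights(x_nnls, gs, config$lambda)
  fista_solve(Am, y, gs, config, x0 = x0)
}

#' Solve the adaptive group lasso along a grid of lambda values
#'
#' The NNLS solution (and hence the adaptive weights' denominators) is
#' computed once; each subsequent solve is warm-started from the previous
#' lambda's solution. The grid must be sorted ascending.
#'
#' @param A a \code{contribution_matrix} or a (sparse) matrix.
#' @param y data vector.
#' @param groups a \code{group_structure} (weights are recomputed per
#'   lambda).
#' @param lambda_grid increasing vector of lambda values >= 0.
#' @param config a \code{solver_config} (its \code{lambda} is ignored).
#' @return list of \code{tract_solution}, one per lambda, with the grid as
#'   attribute \code{"lambda"}.
#' @export
lambda_sweep <- function(A, y, groups, lambda_grid,
                         config = solver_config()) {
  if (!length(lambda_grid)) stop("'lambda_grid' is empty")
  if (is.unsorted(lambda_grid, strictly = FALSE))
    stop("'lambda_grid' must be sorted ascending")
  if (any(lambda_grid < 0)) stop("lambda values must be >= 0")
  Am <- as_operator(A)
  x_nnls <- solve_nnls(Am, y, config)$x
  out <- vector("list", length(lambda_grid))
  x0 <- x_nnls
  for (k in seq_along(lambda_grid)) {
    gk <- compute_adaptive_weights(x_nnls, groups, lambda_grid[k])
    out[[k]] <- fista_solve(Am, y, gk, config, x0 = x0)
    x0 <- out[[k]]$x
  }
  attr(out, "lambda") <- lambda_grid
  out
}

#' Karush-Kuhn-Tucker stationarity residual of a fitted solution
#'
#' For diagnostics: the maximum absolute violation of the first-order
#' optimality conditions of the non-negative (group-)penalized least
#' squares problem, normalized by the gradient scale. Near zero at an
#' exact minimizer.
#'
#' @param A a \code{contribution_matrix} or matrix.
#' @param y data vector.
#' @param groups a \code{group_structure} with weights set (or NULL for
#'   plain NNLS).
#' @param x coefficient vector.
#' @return non-negative scalar.
#' @export
kkt_residual <- function(A, y, groups = NULL, x) {
  Am <- as_operator(A)
  g <- as.numeric(2 * Matrix::crossprod(Am, as.numeric(Am %*% x) - y))
  scale <- max(1, max(abs(g)))
  viol <- 0
  check_exempt <- function(idx) {
    if (!length(idx)) return(0)
    act <- idx[x[idx] > 1e-12]
    inact <- idx[x[idx] <= 1e-12]
    max(0,
        if (length(act)) max(abs(g[act])) else 0,
        if (length(inact)) max(pmax(-g[inact], 0)) else 0)
  }
  if (is.null(groups))
    return(check_exempt(seq_along(x)) / scale)
  viol <- check_exempt(groups$exempt)
  w <- groups$weights
  for (k in seq_along(groups$groups)) {
    idx <- groups$groups[[k]]
    nrm <- sqrt(sum(x[idx]^2))
    if (is.infinite(w[k])) next
    if (nrm > 1e-12) {
      sub <- g[idx] + w[k] * x[idx] / nrm
      act <- x[idx] > 1e-12
      viol <- max(viol,
                  if (any(act)) max(abs(sub[act])) else 0,
                  if (any(!act)) max(pmax(-sub[!act], 0)) else 0)
    } else {
      # inactive group: need ||min(g,0)^(g)|| <= w_g
      slack <- sqrt(sum(pmin(g[idx], 0)^2)) - w[k]
      viol <- max(viol, slack)
    }
  }
  viol / scale
}
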