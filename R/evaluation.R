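#' Classify estimated bundles against ground truth
#'
#' Valid bundles (VB) are estimated edges present in the ground-truth
#' connectome; invalid bundles (IB) are estimated edges absent from it.
#' When the estimated connectome carries streamline counts, the valid /
#' invalid connection ratios VC / IC (fractions of streamlines landing on
#' true / false edges) are computed as well.
#'
#' @param estimated a \code{connectome}.
#' @param truth the ground-truth \code{connectome}; same ROI label set.
#' @return list with \code{VB}, \code{IB}, \code{VC}, \code{IC} (the
#'   ratios are NA unless \code{estimated} uses streamline counts).
#' @export
classify_bundles <- function(estimated, truth) {
  check_same_labels(estimated, truth)
  ut <- upper_tri_idx(truth)
  est <- estimated$matrix[ut] > 0
  tru <- truth$matrix[ut] > 0
  VB <- sum(est & tru)
  IB <- sum(est & !tru)
  VC <- IC <- NA_real_
  if (estimated$weight_definition %in% c("streamline_count", "fiber_count")) {
    tot <- sum(estimated$matrix[ut])
    if (tot > 0) {
      VC <- sum(estimated$matrix[ut][tru]) / tot
      IC <- sum(estimated$matrix[ut][!tru]) / tot
    }
  }
  list(VB = VB, IB = IB, VC = VC, IC = IC)
}

check_same_labels <- function(a, b) {
  if (!identical(a$labels, b$labels))
    stop("connectomes have different ROI label sets")
  invisible(TRUE)
}

#' Youden's index J
#'
#' J = sensitivity + specificity - 1, with sensitivity = VB / P (P =
#' number of real-positive bundles) and specificity = 1 - IB / N (N =
#' number of real-negative ROI pairs reachable by tractography).
#'
#' @param VB,IB valid / invalid bundle counts.
#' @param P number of real positives, >= 1.
#' @param N number of real negatives, >= 1.
#' @return J in [-1, 1].
#' @export
youden <- function(VB, IB, P, N) {
  if (P < 1 || N < 1) stop("P and N must be >= 1")
  if (VB < 0 || VB > P) stop("VB must be in [0, P]")
  if (IB < 0 || IB > N) stop("IB must be in [0, N]")
  VB / P + (1 - IB / N) - 1
}

#' Round half away from zero at a fixed number of decimals
#'
#' Matches the rounding convention of printed tables (0.965 -> 0.97),
#' unlike base R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalized connectome error
#'
#' Both connectomes are first normalized to their own maximum entry; the
#' error is the square root of the sum of squared entry differences, over
#' all edges (\code{mode = "all"}) or restricted to the true-positive edge
#' positions (\code{mode = "tp_only"}). By default the sum runs over the
#' upper triangle only (each unordered pair counted once); \code{full =
#' TRUE} sums over the whole symmetric matrix instead (a factor sqrt(2)
#' larger).
#'
#' @param estimated a \code{connectome}.
#' @param truth ground-truth \code{connectome} (non-empty).
#' @param mode \code{"all"} or \code{"tp_only"}.
#' @param full sum over the full matrix rather than the upper triangle.
#' @return non-negative scalar (epsilon or epsilon_TP).
#' @export
connectome_error <- function(estimated, truth, mode = c("all", "tp_only"),
                             full = FALSE) {
  mode <- match.arg(mode)
  check_same_labels(estimated, truth)
  Mt <- truth$matrix
  Me <- estimated$matrix
  if (max(Mt) <= 0) stop("ground-truth connectome is empty")
  Mt <- Mt / max(Mt)
  if (max(Me) > 0) Me <- Me / max(Me)   # an all-zero estimate stays zero
  d2 <- (Mt - Me)^2
  idx <- if (full) which(row(Mt) != col(Mt)) else upper_tri_idx(truth)
  if (mode == "tp_only") idx <- idx[Mt[idx] > 0]
  sqrt(sum(d2[idx]))
}

#' Remove low-cardinality edges from a streamline-count connectome
#'
#' The common clinical heuristic: progressively drop connections made of
#' few streamlines. Edges with count <= k are removed.
#'
#' @param connectome a \code{connectome} with streamline counts.
#' @param k non-negative integer threshold.
#' @return the thresholded \code{connectome}.
#' @export
threshold_filter <- function(connectome, k) {
  if (!connectome$weight_definition %in% c("streamline_count", "fiber_count"))
    stop("threshold_filter needs a streamline-count connectome")
  if (k < 0) stop("'k' must be >= 0")
  connectome$matrix[connectome$matrix <= k] <- 0
  connectome
}

#' Mean Youden's index under random bundle removal
#'
#' Baseline: remove floor(rate * n_edges) bundles of the estimated
#' connectome uniformly at random and score the remainder against ground
#' truth; repeat and average.
#'
#' @param estimated a \code{connectome}.
#' @param truth ground-truth \code{connectome}.
#' @param removal_rate fraction of bundles to remove, in [0, 1].
#' @param n_repeats number of random repetitions (>= 1).
#' @param seed integer seed (results are deterministic given the seed).
#' @param P,N positives / negatives for \code{\link{youden}}.
#' @return mean J across repeats.
#' @export
random_filter_score <- function(estimated, truth, removal_rate,
                                n_repeats = 100L, seed = 1L, P, N) {
  if (removal_rate < 0 || removal_rate > 1)
    stop("'removal_rate' must be in [0, 1]")
  if (n_repeats < 1) stop("'n_repeats' must be >= 1")
  check_same_labels(estimated, truth)
  ut <- upper_tri_idx(truth)
  present <- ut[estimated$matrix[ut] > 0]
  n_remove <- floor(removal_rate * length(present))
  tru <- truth$matrix[ut] > 0
  names(tru) <- ut
  js <- with_seed(seed, vapply(seq_len(n_repeats), function(r) {
    keep <- present
    if (n_remove > 0)
      keep <- setdiff(present, sample(present, n_remove))
    is_tp <- truth$matrix[keep] > 0
    youden(VB = sum(is_tp), IB = sum(!is_tp), P = P, N = N)
  }, numeric(1)))
  mean(js)
}

#' Full evaluation report of an estimated connectome
#'
#' @param estimated a \code{connectome}.
#' @param truth ground-truth \code{connectome}.
#' @param P,N positives / negatives (default: P = number of true edges; N
#'   must be supplied by the caller from the reachable-negative count).
#' @return list of class \code{evaluation_report}: VB, IB, VC, IC,
#'   sensitivity, specificity, youden_J, epsilon, epsilon_TP,
#'   network_density, P, N.
#' @export
evaluation_report <- function(estimated, truth, P = n_edges(truth), N) {
  cls <- classify_bundles(estimated, truth)
  J <- youden(cls$VB, cls$IB, P, N)
  structure(list(
    VB = cls$VB, IB = cls$IB, VC = cls$VC, IC = cls$IC,
    sensitivity = cls$VB / P,
    specificity = 1 - cls$IB / N,
    youden_J = J,
    epsilon = connectome_error(estimated, truth, "all"),
    epsilon_TP = connectome_error(estimated, truth, "tp_only"),
    network_density = network_density(estimated),
    P = P, N = N), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> VB %d/%d, IB %d/%d | sens %.3f spec %.3f J %.3f | eps %.3f eps_TP %.3f\n",
    x$VB, x$P, x$IB, x$N, x$sensitivity, x$specificity, x$youden_J,
    x$epsilon, x$epsilon_TP))
  invisible(x)
}

#' Sweep the cardinality threshold and score each filtered connectome
#'
#' @param raw a streamline-count \code{connectome} (unfiltered).
#' @param truth ground-truth \code{connectome}.
#' @param P,N positives / negatives for \code{\link{youden}}.
#' @param k_grid thresholds to test (default 0 .. max edge count).
#' @return data.frame with \code{k}, \code{VB}, \code{IB}, \code{J};
#'   attribute \code{"best"} is the row index of the maximum J.
#' @export
threshold_sweep <- function(raw, truth, P, N,
                            k_grid = 0:max(raw$matrix)) {
  rows <- lapply(k_grid, function(k) {
    cls <- classify_bundles(threshold_filter(raw, k), truth)
    data.frame(k = k, VB = cls$VB, IB = cls$IB,
               J = youden(cls$VB, cls$IB, P, N))
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- which.max(out$J)
  out
}

#' Score a list of solutions along a regularization path
#'
#' For each solution, builds the sum-of-weights connectome of the
#' surviving streamlines, classifies its bundles against ground truth and
#' computes Youden's J (receiver-operating-characteristic style sweep over
#' the regularization strength).
#'
#' @param solutions list of \code{tract_solution} (e.g. from
#'   \code{\link{lambda_sweep}}); streamline weights are taken from the
#'   first \code{nrow(assignment)} coefficients.
#' @param assignment an \code{endpoint_assignment} for the fitted
#'   tractogram.
#' @param truth ground-truth \code{connectome}.
#' @param P,N positives / negatives for \code{\link{youden}}.
#' @param lambdas optional per-solution parameter values (defaults to the
#'   \code{"lambda"} attribute of \code{solutions}).
#' @return data.frame with columns \code{lambda}, \code{VB}, \code{IB},
#'   \code{J}, \code{n_active_bundles}; the row index of the maximum J is
#'   attached as attribute \code{"best"}.
#' @export
roc_sweep <- function(solutions, assignment, truth, P, N, lambdas = NULL) {
  if (!length(solutions)) stop("'solutions' is empty")
  if (is.null(lambdas)) lambdas <- attr(solutions, "lambda")
  if (is.null(lambdas)) lambdas <- seq_along(solutions)
  rows <- lapply(seq_along(solutions), function(k) {
    w <- solutions[[k]]$x[seq_len(nrow(assignment))]
    est <- build_connectome(assignment, weights = w,
                            weight_definition = "sum_of_weights",
                            roi_labels_all = truth$labels)
    cls <- classify_bundles(est, truth)
    data.frame(lambda = lambdas[k], VB = cls$VB, IB = cls$IB,
               J = youden(cls$VB, cls$IB, P, N),
               n_active_bundles = n_edges(est))
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- which.max(out$J)
  out
}

# Evaluate a seeded expression without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
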