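# Fuzzy c-means machinery: squared distances, the membership update with its
# degenerate zero-distance branch, the objective J, the fitness transform
# f = 1/(J+1), and a chunked (map/reduce-style) objective evaluation.

# tolerance below which a squared distance is treated as exactly zero, so
# near-coincident points route through the degenerate branch instead of
# overflowing the reciprocal-ratio update
.D2_EPS <- 1e-12

as_feature_matrix <- function(X) {
  if (inherits(X, "labeled_dataset")) X$features else as.matrix(X)
}

#' Squared Euclidean distances from cluster centers to data points
#'
#' @param X a [labeled_dataset()] or n x p numeric matrix.
#' @param V c x p matrix of cluster centers.
#' @return c x n matrix \code{D2} with \code{D2[i, k]} the squared Euclidean
#'   distance from data point \code{k} to center \code{i}.
#' @examples
#' squared_distances(rbind(c(0, 0)), rbind(c(3, 4)))  # 25
#' @export
squared_distances <- function(X, V) {
  X <- as_feature_matrix(X)
  V <- as.matrix(V)
  if (ncol(X) != ncol(V))
    stop("dimensionality mismatch: data has ", ncol(X),
         " features, centers have ", ncol(V))
  # |x - v|^2 = |x|^2 - 2 v.x + |v|^2, clamped at 0 against cancellation
  cross <- V %*% t(X)
  D2 <- -2 * cross + outer(rowSums(V^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(V)), rowSums(X^2))
  D2[D2 < 0] <- 0
  D2
}

#' Fuzzy membership update
#'
#' Computes the c x n membership matrix U from squared distances. For a data
#' point with all distances positive, \code{u[i, k] =
#' 1 / sum_j (d2[i, k] / d2[j, k])^(1/(m-1))}; for a point coinciding with one
#' or more centers, all membership mass goes to the coincident centers (split
#' uniformly when several centers coincide) and every other membership is 0.
#' Every column of the result sums to 1.
#'
#' @param D2 c x n matrix of squared distances, as from
#'   [squared_distances()].
#' @param m fuzzifier, \code{m > 1}.
#' @return c x n membership matrix.
#' @examples
#' membership_update(cbind(c(1, 3)), m = 2)  # 0.75, 0.25
#' @export
membership_update <- function(D2, m = 2) {
  if (m <= 1) stop("fuzzifier m must be > 1")
  D2 <- as.matrix(D2)
  c_ <- nrow(D2)
  U <- matrix(0, c_, ncol(D2))
  zero <- D2 <= .D2_EPS
  degenerate <- colSums(zero) > 0L
  if (any(!degenerate)) {
    # u_ik = w_ik / sum_j w_jk with w_ik = (d2_ik / min_j d2_jk)^(-1/(m-1));
    # dividing by the column minimum leaves the ratios unchanged but keeps
    # every w in (0, 1], so no overflow even for m close to 1
    A <- D2[, !degenerate, drop = FALSE]
    A <- sweep(A, 2L, apply(A, 2L, min), "/")
    W <- A^(-1 / (m - 1))
    U[, !degenerate] <- sweep(W, 2L, colSums(W), "/")
  }
  if (any(degenerate)) {
    Z <- zero[, degenerate, drop = FALSE]
    U[, degenerate] <- sweep(Z * 1, 2L, colSums(Z), "/")
  }
  U
}

#' Fuzzy c-means objective
#'
#' \code{J = sum_k sum_i u[i,k]^m * D2[i,k]}: the membership-weighted total
#' squared scatter the evolutionary search minimizes. Smaller is better.
#'
#' @param U c x n membership matrix.
#' @param D2 c x n squared-distance matrix.
#' @param m fuzzifier, \code{m > 1}.
#' @return scalar J >= 0.
#' @export
fcm_objective <- function(U, D2, m = 2) {
  if (m <= 1) stop("fuzzifier m must be > 1")
  U <- as.matrix(U); D2 <- as.matrix(D2)
  if (!all(dim(U) == dim(D2)))
    stop("U and D2 must have identical dimensions")
  sum(U^m * D2)
}

#' Fitness transform
#'
#' Maps the objective to \code{f = 1/(J+1)}, a strictly decreasing bijection
#' from \code{[0, Inf)} onto \code{(0, 1]}, so fitness-proportionate selection
#' can maximize it.
#'
#' @param J nonnegative objective value (vectorized).
#' @return fitness in (0, 1].
#' @export
fcm_fitness <- function(J) {
  if (any(J < 0)) stop("objective J must be nonnegative")
  1 / (J + 1)
}

#' Score a cluster-center chromosome on a dataset
#'
#' The per-individual evaluation of the evolutionary loop: decode the flat
#' gene vector into c centers, compute squared distances, the membership
#' update, the objective J, and the fitness f = 1/(J+1).
#'
#' @param a numeric chromosome of length \code{c * p}.
#' @param X a [labeled_dataset()] or numeric matrix.
#' @param c number of clusters encoded in \code{a}.
#' @param m fuzzifier.
#' @return list with \code{U} (c x n), \code{J}, \code{f}, \code{V} (decoded
#'   centers).
#' @export
evaluate_chromosome <- function(a, X, c, m = 2) {
  X <- as_feature_matrix(X)
  V <- decode_chromosome(a, c, ncol(X))
  D2 <- squared_distances(X, V)
  U <- membership_update(D2, m)
  J <- fcm_objective(U, D2, m)
  list(U = U, J = J, f = fcm_fitness(J), V = V)
}

#' Chunked evaluation of the fuzzy c-means objective
#'
#' Splits the data rows into contiguous chunks, computes each chunk's partial
#' objective independently (the "map" step) and sums the partials (the
#' "reduce" step). Because the membership update is column-separable, the
#' result equals the monolithic objective up to summation order.
#'
#' @param X a [labeled_dataset()] or numeric matrix.
#' @param V c x p matrix of cluster centers.
#' @param m fuzzifier.
#' @param chunk_size rows per chunk, >= 1.
#' @return scalar J.
#' @export
partitioned_objective <- function(X, V, m = 2, chunk_size) {
  X <- as_feature_matrix(X)
  if (chunk_size < 1) stop("chunk_size must be >= 1")
  starts <- seq(1L, nrow(X), by = as.integer(chunk_size))
  partial <- vapply(starts, function(s) {
    rows <- s:min(s + chunk_size - 1L, nrow(X))
    D2 <- squared_distances(X[rows, , drop = FALSE], V)
    fcm_objective(membership_update(D2, m), D2, m)
  }, numeric(1))
  sum(partial)
}

#' Fuzzy c-means by alternating optimization
#'
#' The classic descent baseline the evolutionary algorithm is compared
#' against: alternate the membership update and the weighted-mean center
#' update \code{v_i = sum_k u_ik^m x_k / sum_k u_ik^m} until the objective
#' decreases by less than \code{tol} or \code{max_iter} is reached. The J
#' trajectory is non-increasing. If a cluster loses all effective mass its
#' center is re-seeded from a random data point (recorded in the result).
#'
#' @param X a [labeled_dataset()] or numeric matrix.
#' @param V_init c x p matrix of starting centers, or an integer c to draw
#'   that many initial centers uniformly within the per-feature data range.
#' @param m fuzzifier.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on |J_t - J_{t-1}|.
#' @param seed optional seed (used for random init / re-seeding).
#' @return list with \code{V}, \code{U}, \code{J} (final), \code{J_history},
#'   \code{iterations}, \code{reseeded} (count of re-seeded centers).
#' @export
fcm_refine <- function(X, V_init, m = 2, max_iter = 100L, tol = 1e-8,
                       seed = NULL) {
  X <- as_feature_matrix(X)
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (length(V_init) == 1L && is.numeric(V_init)) {
    c_ <- as.integer(V_init)
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
    V <- matrix(stats::runif(c_ * ncol(X), rep(lo, each = c_),
                             rep(hi, each = c_)), c_, ncol(X))
  } else {
    V <- as.matrix(V_init)
  }
  reseeded <- 0L
  J_history <- numeric(0)
  U <- NULL
  for (it in seq_len(max_iter)) {
    D2 <- squared_distances(X, V)
    U <- membership_update(D2, m)
    J <- fcm_objective(U, D2, m)
    J_history <- c(J_history, J)
    if (it > 1L && abs(J_history[it - 1L] - J) < tol) break
    Um <- U^m
    mass <- rowSums(Um)
    dead <- mass <= 0
    if (any(dead)) {
      V[dead, ] <- X[sample.int(nrow(X), sum(dead)), , drop = FALSE]
      reseeded <- reseeded + sum(dead)
      mass[dead] <- NA  # keep live rows' update below
    }
    V_new <- (Um %*% X) / mass
    V[!dead, ] <- V_new[!dead, , drop = FALSE]
  }
  list(V = V, U = U, J = J_history[length(J_history)],
       J_history = J_history, iterations = length(J_history),
       reseeded = reseeded)
}
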