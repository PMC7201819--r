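# External cluster validation against reference class labels: contingency
# tables, per-(class, cluster) precision/recall/F, the class-size-weighted
# clustering F-measure, and majority-mapping accuracy.

#' Class-by-cluster contingency table
#'
#' \code{n_ij}: the number of samples with reference class i assigned to
#' cluster j. Row and column order follow first appearance of each value.
#'
#' @param labels reference class labels.
#' @param clusters cluster assignments of the same length.
#' @return An object of class \code{cluster_contingency}: list with
#'   \code{n_ij} (K x C matrix), \code{n_i} (class sizes), \code{n_j}
#'   (cluster sizes), \code{n} (total).
#' @export
contingency <- function(labels, clusters) {
  if (length(labels) != length(clusters))
    stop("labels and clusters must have equal length")
  if (length(labels) == 0L) stop("empty label vectors")
  li <- match(labels, unique(labels))
  cj <- match(clusters, unique(clusters))
  n_ij <- unclass(table(factor(li, levels = seq_len(max(li))),
                        factor(cj, levels = seq_len(max(cj)))))
  dimnames(n_ij) <- list(as.character(unique(labels)),
                         as.character(unique(clusters)))
  structure(list(n_ij = n_ij, n_i = rowSums(n_ij), n_j = colSums(n_ij),
                 n = length(labels)),
            class = "cluster_contingency")
}

#' Precision, recall and F for one (class, cluster) pair
#'
#' Recall \code{r = n_ij / n_i}, precision \code{p = n_ij / n_j}, and their
#' harmonic mean \code{F = 2 r p / (r + p)} (0 when the pair is disjoint).
#'
#' @param n_ij samples shared by class i and cluster j.
#' @param n_i class size, > 0.
#' @param n_j cluster size, > 0.
#' @return list with \code{r}, \code{p}, \code{F}.
#' @export
pair_f <- function(n_ij, n_i, n_j) {
  if (n_i <= 0 || n_j <= 0) stop("class and cluster sizes must be positive")
  r <- n_ij / n_i
  p <- n_ij / n_j
  F <- if (r + p == 0) 0 else 2 * r * p / (r + p)
  list(r = r, p = p, F = F)
}

#' Clustering F-measure
#'
#' The class-size-weighted sum of each class's best pairwise F over clusters:
#' \code{F = sum_i (n_i / n) * max_j F(i, j)}. Equals 1 exactly when the
#' clustering reproduces the reference partition (up to cluster relabeling);
#' its upper bound is 1, and larger is better.
#'
#' @param cont a \code{cluster_contingency} from [contingency()].
#' @return scalar F in (0, 1].
#' @export
f_measure <- function(cont) {
  stopifnot(inherits(cont, "cluster_contingency"))
  live <- cont$n_j > 0  # empty clusters contribute nothing
  best <- vapply(seq_along(cont$n_i), function(i) {
    max(vapply(which(live), function(j)
      pair_f(cont$n_ij[i, j], cont$n_i[i], cont$n_j[j])$F, numeric(1)))
  }, numeric(1))
  sum(cont$n_i / cont$n * best)
}

#' Majority-mapping accuracy
#'
#' Maps every cluster to its most frequent reference class and reports the
#' fraction of samples mapped correctly: \code{sum_j max_i n_ij / n}.
#'
#' @param cont a \code{cluster_contingency} from [contingency()].
#' @return accuracy fraction in (0, 1].
#' @export
majority_accuracy <- function(cont) {
  stopifnot(inherits(cont, "cluster_contingency"))
  sum(apply(cont$n_ij, 2L, max)) / cont$n
}

#' Evaluate a clustering against reference labels
#'
#' Convenience wrapper computing the contingency table, F-measure and
#' majority-mapping accuracy in one call.
#'
#' @param labels reference class labels.
#' @param clusters cluster assignments.
#' @return list with \code{F}, \code{accuracy}, \code{contingency}.
#' @examples
#' evaluate_clustering(c("A", "A", "B", "B"), c(1, 1, 1, 2))
#' @export
evaluate_clustering <- function(labels, clusters) {
  cont <- contingency(labels, clusters)
  list(F = f_measure(cont), accuracy = majority_accuracy(cont),
       contingency = cont)
}
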