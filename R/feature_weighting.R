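# Relief feature weighting: score each feature by how well it separates a
# sampled instance from its nearest other-class neighbor (nearest miss)
# relative to its nearest same-class neighbor (nearest hit), average the
# weights over repeated runs, and prune low-weight features.

#' Relief feature weights
#'
#' Classic Relief on min-max-scaled features: for each of \code{n_samples}
#' sampled instances R, find the nearest hit (same class, excluding R) and
#' the nearest miss (closest instance of any other class) by Euclidean
#' distance over all features, then accumulate per feature d
#' \code{w_d <- w_d + diff(d, R, miss) - diff(d, R, hit)}, where diff is the
#' absolute difference of scaled values. Weights are normalized by
#' \code{n_samples}, so each lies in [-1, 1]. A feature carrying no class
#' information scores near 0; a separating feature scores positive.
#'
#' @param ds a [labeled_dataset()] with labels covering >= 2 classes, each
#'   class with >= 2 members.
#' @param n_samples number of instances to sample; sampling is without
#'   replacement when \code{n_samples <= n}, with replacement otherwise.
#' @param seed optional integer seed.
#' @return numeric vector of p weights (named by feature).
#' @export
relief_weights <- function(ds, n_samples = ds$n, seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(ds$labels)) stop("Relief requires class labels")
  if (length(unique(ds$labels)) < 2L)
    stop("Relief requires at least two classes")
  tab <- table(ds$labels)
  if (any(tab < 2L))
    stop("every class needs at least two members (for a nearest hit)")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  Xs <- min_max_scale(ds)$dataset$features
  n <- nrow(Xs)
  idx <- sample.int(n, n_samples, replace = n_samples > n)
  w <- numeric(ncol(Xs))
  for (r in idx) {
    d2 <- rowSums(sweep(Xs, 2L, Xs[r, ], "-")^2)
    same <- ds$labels == ds$labels[r]
    hit_pool <- which(same); hit_pool <- hit_pool[hit_pool != r]
    miss_pool <- which(!same)
    hit <- hit_pool[which.min(d2[hit_pool])]
    miss <- miss_pool[which.min(d2[miss_pool])]
    w <- w + abs(Xs[r, ] - Xs[miss, ]) - abs(Xs[r, ] - Xs[hit, ])
  }
  stats::setNames(w / n_samples, colnames(Xs))
}

#' Averaged Relief weights over repeated runs
#'
#' The random choice of sampled instances makes single-run Relief weights
#' noisy, so the procedure is repeated (20 times by default) with derived
#' seeds \code{base_seed + r} and the per-feature weights averaged.
#'
#' @param ds a [labeled_dataset()] with labels.
#' @param n_samples instances sampled per run.
#' @param repeats number of runs to average (default 20).
#' @param base_seed integer; run r uses seed \code{base_seed + r - 1}.
#' @return An object of class \code{weight_report}: list with \code{weights}
#'   (length-p mean weights), \code{per_run_weights} (repeats x p),
#'   \code{repeats}, and empty pruning fields filled by
#'   [select_features()].
#' @export
averaged_weights <- function(ds, n_samples = ds$n, repeats = 20L,
                             base_seed = 1L) {
  stopifnot(repeats >= 1)
  per_run <- t(vapply(seq_len(repeats),
                      function(r) relief_weights(ds, n_samples,
                                                 seed = base_seed + r - 1L),
                      numeric(ds$p)))
  structure(list(weights = colMeans(per_run), per_run_weights = per_run,
                 repeats = as.integer(repeats), removed = integer(0),
                 threshold_rule = NULL),
            class = "weight_report")
}

#' @export
print.weight_report <- function(x, ...) {
  cat(sprintf("Relief weight report (%d runs averaged):\n", x$repeats))
  print(round(x$weights, 4))
  if (length(x$removed))
    cat("removed features:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Prune features by weight
#'
#' Either removes every feature whose averaged weight falls below a
#' threshold, or removes the k features with the smallest weights (ties
#' broken by removing the lower index first).
#'
#' @param report a \code{weight_report} from [averaged_weights()].
#' @param rule \code{"threshold"} or \code{"bottom_k"}.
#' @param t weight threshold (features with \code{w < t} are removed).
#' @param k number of smallest-weight features to remove, \code{k < p}.
#' @return the report with \code{kept} and \code{removed} (1-based feature
#'   indices) and \code{threshold_rule} filled in.
#' @export
select_features <- function(report, rule = c("threshold", "bottom_k"),
                            t = NULL, k = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(report, "weight_report"))
  p <- length(report$weights)
  if (rule == "threshold") {
    if (is.null(t)) stop("threshold rule needs t")
    removed <- which(report$weights < t)
  } else {
    if (is.null(k)) stop("bottom_k rule needs k")
    if (k >= p) stop("k must be smaller than the number of features")
    removed <- sort(order(report$weights, seq_len(p))[seq_len(k)])
  }
  report$removed <- removed
  report$kept <- setdiff(seq_len(p), removed)
  report$threshold_rule <- if (rule == "threshold")
    list(rule = "threshold", t = t) else list(rule = "bottom_k", k = k)
  report
}
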