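#' Labeled numeric dataset
#'
#' Container for an \code{n x p} numeric feature matrix with optional integer
#' class labels, the shared currency of every other function in the package.
#' Labels, when present, are remapped to contiguous integers \code{0..K-1} in
#' first-appearance order so that contingency tables are stable across runs.
#'
#' @param features numeric matrix (or coercible data frame), one row per
#'   sample, one column per feature.
#' @param labels optional vector of class labels (any atomic type), length
#'   equal to \code{nrow(features)}.
#' @param feature_names optional character vector of column names; defaults to
#'   existing column names or \code{V1..Vp}.
#' @return An object of class \code{labeled_dataset}: a list with elements
#'   \code{features} (numeric matrix), \code{labels} (integer vector or
#'   \code{NULL}), \code{label_levels} (original label values, in
#'   first-appearance order, or \code{NULL}), \code{n}, \code{p}.
#' @examples
#' ds <- labeled_dataset(matrix(1:6, 3, 2), labels = c("a", "a", "b"))
#' ds$n; ds$p; ds$labels
#' @export
labeled_dataset <- function(features, labels = NULL, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1L || ncol(features) < 1L)
    stop("dataset must have at least one row and one column")
  if (anyNA(features))
    stop("features contain missing values; apply a missing-value policy first")
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names))
      feature_names <- paste0("V", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  label_levels <- NULL
  if (!is.null(labels)) {
    if (length(labels) != nrow(features))
      stop("labels must have one entry per row")
    label_levels <- unique(labels)
    labels <- match(labels, label_levels) - 1L
  }
  structure(
    list(features = features, labels = labels, label_levels = label_levels,
         feature_names = feature_names,
         n = nrow(features), p = ncol(features)),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: n = %d samples, p = %d features%s\n",
              x$n, x$p,
              if (is.null(x$labels)) ", unlabeled"
              else sprintf(", %d classes", length(x$label_levels))))
  invisible(x)
}

#' Read a delimited numeric table as a labeled dataset
#'
#' Reads a UCI-style delimited text file: an optional ID column, numeric
#' feature columns, and an optional class-label column. The missing-value
#' marker is \code{"?"} (the Breast Cancer Wisconsin convention); cells that
#' are neither numeric nor \code{"?"} raise an error naming the offending
#' row and column.
#'
#' @param path file to read.
#' @param label_column column holding class labels: name, 1-based index, or
#'   \code{NULL} (no labels).
#' @param id_column column holding sample IDs, dropped from the features:
#'   name, 1-based index, or \code{NULL}.
#' @param missing_policy what to do with rows containing \code{"?"}:
#'   \code{"drop_row"} (default) removes them, \code{"mean_impute"} replaces
#'   each missing cell by its feature's mean over observed values.
#' @param sep field separator, default comma.
#' @param header does the file carry a header line? Default \code{FALSE}
#'   (UCI data files usually do not).
#' @return A [labeled_dataset()].
#' @export
load_table <- function(path, label_column = NULL, id_column = NULL,
                       missing_policy = c("drop_row", "mean_impute"),
                       sep = ",", header = FALSE) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  resolve_col <- function(col, what) {
    if (is.null(col)) return(NULL)
    if (is.numeric(col)) {
      col <- as.integer(col)
      if (col < 1L || col > ncol(raw))
        stop(what, " column index out of range: ", col)
      return(col)
    }
    idx <- match(col, names(raw))
    if (is.na(idx)) stop(what, " column not found: ", col)
    idx
  }
  id_idx <- resolve_col(id_column, "id")
  lab_idx <- resolve_col(label_column, "label")
  labels <- if (!is.null(lab_idx)) raw[[lab_idx]] else NULL
  drop <- c(id_idx, lab_idx)
  feat <- if (length(drop)) raw[, -drop, drop = FALSE] else raw
  if (ncol(feat) < 1L) stop("no feature columns remain")

  mat <- matrix(NA_real_, nrow(feat), ncol(feat),
                dimnames = list(NULL, names(feat)))
  for (j in seq_len(ncol(feat))) {
    cell <- feat[[j]]
    is_missing <- cell == "?"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is_missing)
    if (length(bad))
      stop(sprintf("cell at row %d, column '%s' is not numeric: '%s'",
                   bad[1L], names(feat)[j], cell[bad[1L]]))
    mat[, j] <- num
  }

  if (anyNA(mat)) {
    if (missing_policy == "drop_row") {
      keep <- !apply(is.na(mat), 1L, any)
      if (!any(keep)) stop("all rows dropped by missing-value policy")
      mat <- mat[keep, , drop = FALSE]
      if (!is.null(labels)) labels <- labels[keep]
    } else {
      for (j in seq_len(ncol(mat))) {
        miss <- is.na(mat[, j])
        if (any(miss)) mat[miss, j] <- mean(mat[!miss, j])
      }
    }
  }
  labeled_dataset(mat, labels = labels)
}

#' Write a labeled dataset back to delimited text
#'
#' Inverse of [load_table()]: features (full precision) plus an optional
#' trailing label column, so pipeline stages compose through plain CSV files.
#'
#' @param ds a [labeled_dataset()].
#' @param path output file.
#' @param sep field separator.
#' @param header write a header line? Default \code{TRUE}.
#' @param labels include the label column (named \code{class}) when present?
#' @return \code{path}, invisibly.
#' @export
write_table <- function(ds, path, sep = ",", header = TRUE, labels = TRUE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- as.data.frame(ds$features)
  if (labels && !is.null(ds$labels)) df$class <- ds$label_levels[ds$labels + 1L]
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' Min-max scale every feature to [0, 1]
#'
#' Maps each feature linearly onto \code{[0, 1]}; constant features map to 0.
#' The per-feature \code{(min, max)} pair is returned so cluster prototypes
#' found in scaled space can be mapped back to data units with
#' [unscale_prototypes()]. Commensurate feature ranges are a precondition for
#' both Euclidean distances and Relief weights to be meaningful.
#'
#' @param ds a [labeled_dataset()].
#' @return A list: \code{dataset} (scaled [labeled_dataset()]), \code{mins},
#'   \code{maxs} (length-p numeric vectors).
#' @examples
#' ds <- labeled_dataset(cbind(a = c(1, 2, 3)))
#' min_max_scale(ds)$dataset$features[, 1]  # 0, 0.5, 1
#' @export
min_max_scale <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  mins <- apply(ds$features, 2L, min)
  maxs <- apply(ds$features, 2L, max)
  rng <- maxs - mins
  scaled <- sweep(ds$features, 2L, mins, "-")
  pos <- rng > 0
  scaled[, pos] <- sweep(scaled[, pos, drop = FALSE], 2L, rng[pos], "/")
  scaled[, !pos] <- 0
  out <- ds
  out$features <- scaled
  list(dataset = out, mins = mins, maxs = maxs)
}

#' Map scaled-space prototypes back to data units
#'
#' @param V c x p matrix of cluster centers in min-max scaled coordinates.
#' @param mins,maxs per-feature minima and maxima from [min_max_scale()].
#' @return c x p matrix in the original units (constant features restored to
#'   their constant value).
#' @export
unscale_prototypes <- function(V, mins, maxs) {
  V <- as.matrix(V)
  stopifnot(ncol(V) == length(mins), length(mins) == length(maxs))
  sweep(sweep(V, 2L, maxs - mins, "*"), 2L, mins, "+")
}

#' Specification of a labeled Gaussian-mixture generator
#'
#' Describes the synthetic data every test and demo runs on: \code{c_true}
#' isotropic Gaussian components at given means with per-cluster spreads and
#' mixing weights, optionally padded with pure-noise uniform features that
#' carry no class information (used to exercise feature weighting).
#'
#' @param means c x p numeric matrix of component means.
#' @param spreads per-cluster standard deviations (scalar recycled), all > 0
#'   (0 is allowed as the exact zero-noise limit).
#' @param weights mixing proportions, must sum to 1 (default uniform).
#' @param noise_features number of appended uniform[0,1] features independent
#'   of the labels.
#' @return An object of class \code{mixture_spec}.
#' @export
mixture_spec <- function(means, spreads = 1, weights = NULL,
                         noise_features = 0L) {
  means <- as.matrix(means)
  c_true <- nrow(means)
  spreads <- rep_len(as.numeric(spreads), c_true)
  if (any(spreads < 0)) stop("spreads must be non-negative")
  if (is.null(weights)) weights <- rep(1 / c_true, c_true)
  if (length(weights) != c_true) stop("one weight per component required")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  structure(list(c_true = c_true, p = ncol(means), means = means,
                 spreads = spreads, weights = weights,
                 noise_features = as.integer(noise_features)),
            class = "mixture_spec")
}

#' Draw a labeled sample from a Gaussian mixture
#'
#' Component assignments are drawn from \code{weights} (every component is
#' guaranteed at least one sample when \code{n >= c_true}), then each sample
#' from an isotropic Gaussian at its component mean. Labels record the
#' generating component (0-based). Identical seeds give identical output.
#'
#' @param spec a [mixture_spec()].
#' @param n number of samples, \code{n >= c_true}.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return A [labeled_dataset()] with attribute \code{"truth"}: a list of the
#'   generating means, spreads, weights and indices of noise features.
#' @export
generate_mixture <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (n < spec$c_true) stop("n must be at least the number of components")
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(spec$c_true, n, replace = TRUE, prob = spec$weights)
  # guarantee every component appears so labels always span c_true classes;
  # reassign only samples of components that have duplicates to spare
  for (k in setdiff(seq_len(spec$c_true), unique(comp))) {
    counts <- tabulate(comp, spec$c_true)
    spare <- which(comp %in% which(counts > 1L))
    comp[spare[sample.int(length(spare), 1L)]] <- k
  }
  X <- spec$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(n * spec$p), n, spec$p) * spec$spreads[comp]
  if (spec$noise_features > 0L)
    X <- cbind(X, matrix(stats::runif(n * spec$noise_features),
                         n, spec$noise_features))
  colnames(X) <- c(paste0("V", seq_len(spec$p)),
                   if (spec$noise_features > 0L)
                     paste0("noise", seq_len(spec$noise_features)))
  ds <- labeled_dataset(X)
  # labels are the generating component directly (0-based), not remapped by
  # first appearance, so truth$means[k + 1, ] corresponds to label k
  ds$labels <- comp - 1L
  ds$label_levels <- seq_len(spec$c_true) - 1L
  attr(ds, "truth") <- list(
    means = spec$means, spreads = spec$spreads, weights = spec$weights,
    noise_features = if (spec$noise_features > 0L)
      spec$p + seq_len(spec$noise_features) else integer(0))
  ds
}
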