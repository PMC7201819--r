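# Independent oracles the implementation is checked against. These stay
# deliberately naive (explicit loops, no shared code paths with R/).

# double-loop fuzzy c-means objective: J = sum_k sum_i u_ik^m d2_ik
naive_objective <- function(U, D2, m) {
  J <- 0
  for (k in seq_len(ncol(U)))
    for (i in seq_len(nrow(U)))
      J <- J + U[i, k]^m * D2[i, k]
  J
}

# all-pairs clustering F-measure from raw label vectors
naive_f_measure <- function(labels, clusters) {
  classes <- unique(labels)
  cls <- unique(clusters)
  n <- length(labels)
  total <- 0
  for (i in classes) {
    n_i <- sum(labels == i)
    best <- 0
    for (j in cls) {
      n_j <- sum(clusters == j)
      n_ij <- sum(labels == i & clusters == j)
      r <- n_ij / n_i
      p <- n_ij / n_j
      F <- if (r + p == 0) 0 else 2 * r * p / (r + p)
      best <- max(best, F)
    }
    total <- total + n_i / n * best
  }
  total
}

# random contingency-shaped label pair
random_labelings <- function(n, K, C) {
  list(labels = sample.int(K, n, replace = TRUE),
       clusters = sample.int(C, n, replace = TRUE))
}

# small 3-component 2-D mixture used across suites
toy_mixture_spec <- function(spreads = 0.2, noise_features = 0L)
  mixture_spec(rbind(c(0, 0), c(5, 5), c(0, 5)), spreads = spreads,
               noise_features = noise_features)

# write a Wisconsin-shaped file: id + 9 feature columns + class, "?" allowed
write_wisconsin_fixture <- function(path, n = 6L, missing_at = NULL) {
  set.seed(7)
  id <- 1000 + seq_len(n)
  feats <- matrix(sample(1:10, n * 9L, replace = TRUE), n, 9L)
  class <- rep(c(2, 4), length.out = n)
  rows <- cbind(id, feats, class)
  lines <- apply(rows, 1L, paste, collapse = ",")
  if (!is.null(missing_at)) {
    parts <- strsplit(lines[missing_at[1L]], ",")[[1L]]
    parts[missing_at[2L]] <- "?"
    lines[missing_at[1L]] <- paste(parts, collapse = ",")
  }
  writeLines(lines, path)
  path
}
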