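# Shared fixtures and independent reference implementations.

# A small cohort for fast unit tests: planted effects scaled down with the
# region count, but the same generative structure as the full generator.
tiny_cohort <- function(n_regions = 8, n_mci = 4, n_nmci = 6,
                        n_timepoints = 30, seed = 1, ...) {
  generate_cohort(synthetic_config(
    n_mci = n_mci, n_nmci = n_nmci, n_regions = n_regions,
    n_timepoints = n_timepoints, seed = seed, ...
  ))
}

tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, hidden_dim = 4L, gat_layers = 1L,
                   mlp_hidden = 8L, epochs = 15L, folds = 3L)
  do.call(run_config, utils::modifyList(defaults, args))
}

# Naive reference GAT layer: explicit loops straight from the update rules
# (score, mask, softmax over the neighborhood, weighted aggregation).
# Deliberately independent of the package implementation.
naive_gat_layer <- function(H, A, W, a, leaky = 0.2, activation = "relu") {
  n <- nrow(H)
  f_out <- nrow(W)
  lrelu <- function(x) if (x > 0) x else leaky * x
  out <- matrix(0, n, f_out)
  for (i in seq_len(n)) {
    nbrs <- union(i, which(A[i, ] > 0))
    scores <- numeric(length(nbrs))
    for (k in seq_along(nbrs)) {
      j <- nbrs[k]
      scores[k] <- lrelu(sum(a * c(W %*% H[i, ], W %*% H[j, ])))
    }
    w <- exp(scores - max(scores))
    w <- w / sum(w)
    zi <- numeric(f_out)
    for (k in seq_along(nbrs)) {
      zi <- zi + w[k] * drop(W %*% H[nbrs[k], ])
    }
    out[i, ] <- if (activation == "relu") pmax(zi, 0) else zi
  }
  out
}

# Projected-gradient reference for the non-negative elastic net, run on the
# same standardized problem the package solves internally.
pg_elastic_net <- function(X, y, l1, l2, iters = 50000, step = NULL) {
  sds <- apply(X, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  X <- scale(X, center = TRUE, scale = sds)
  y <- y - mean(y)
  n <- nrow(X)
  if (is.null(step)) {
    lip <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                     only.values = TRUE)$values) + l2
    step <- 1 / lip
  }
  beta <- numeric(ncol(X))
  for (it in seq_len(iters)) {
    grad <- -crossprod(X, y - X %*% beta) / n + l2 * beta
    beta <- pmax(0, beta - step * (drop(grad) + l1))
  }
  beta
}

pg_objective <- function(X, y, beta, l1, l2) {
  sds <- apply(X, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  Xs <- scale(X, center = TRUE, scale = sds)
  yc <- y - mean(y)
  sum((yc - Xs %*% beta)^2) / (2 * nrow(Xs)) + l1 * sum(beta) +
    l2 / 2 * sum(beta^2)
}

# Apply one permutation consistently to every block of a subject record.
permute_subject <- function(s, perm) {
  subject_record(
    subject_id = s$subject_id,
    time_series = s$time_series[perm, , drop = FALSE],
    fiber_counts = s$fiber_counts[perm, perm],
    roi_volumes = s$roi_volumes[perm],
    demographics = s$demographics,
    label = s$label
  )
}
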