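#' 2-D t-SNE embedding of learned representations
#'
#' An exact-gradient t-SNE (no tree approximation; cohort sizes here are
#' tens of subjects): Gaussian input affinities with per-point precision
#' found by binary search to match `perplexity`, Student-t output
#' affinities, early exaggeration, and momentum gradient descent.
#' Deterministic given `seed`.
#'
#' @param features Numeric n x d matrix (e.g. [model_embeddings()]).
#' @param seed Integer seed for the initial layout.
#' @param perplexity Effective neighbor count; must be < n.
#' @param iters Gradient iterations.
#' @param eta Learning rate.
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed_2d <- function(features, seed = 1L, perplexity = 10, iters = 500L,
                     eta = 10) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 points to embed", call. = FALSE)
  if (perplexity >= n) {
    stop("perplexity (", perplexity, ") must be smaller than the number of ",
         "points (", n, ")", call. = FALSE)
  }
  D2 <- as.matrix(stats::dist(X))^2
  P <- conditional_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5
    for (it in seq_len(iters)) {
      ex <- if (it <= 100) 4 else 1            # early exaggeration
      if (it == 251) momentum <- 0.8
      Dy <- as.matrix(stats::dist(Y))^2
      Wq <- 1 / (1 + Dy); diag(Wq) <- 0
      Q <- pmax(Wq / sum(Wq), 1e-12)
      Lmat <- (ex * P - Q) * Wq
      grad <- 4 * (diag(rowSums(Lmat)) - Lmat) %*% Y
      inc <- momentum * inc - eta * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

# Row-conditional Gaussian affinities with per-point bandwidth matched to
# log2(perplexity) entropy by binary search.
conditional_affinities <- function(D2, perplexity, tol = 1e-5,
                                   max_iter = 60L) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; p <- w } else {
        p <- w / sw
        h <- -sum(ifelse(p > 0, p * log(p), 0))   # Shannon entropy
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}
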