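#' Graph-attention layer parameters
#'
#' One masked graph-attention layer: a shared linear map `W` (f_out x f_in),
#' an attention vector `a` (length 2 f_out) scoring concatenated transformed
#' endpoint features, and the LeakyReLU slope (0.2 as is standard).
#'
#' @param f_in,f_out Input/output feature widths.
#' @param leaky_alpha Negative-slope of the LeakyReLU on raw scores.
#' @param init `"glorot"` (draws from the current RNG stream) or `"zero"`.
#' @return List with `W`, `a`, `leaky_alpha`.
#' @export
gat_layer_params <- function(f_in, f_out, leaky_alpha = 0.2,
                             init = c("glorot", "zero")) {
  init <- match.arg(init)
  stopifnot(leaky_alpha > 0, leaky_alpha < 1)
  a <- if (init == "zero") numeric(2 * f_out) else {
    lim <- sqrt(6 / (2 * f_out + 1))
    stats::runif(2 * f_out, -lim, lim)
  }
  list(W = init_mat(f_out, f_in, init), a = a, leaky_alpha = leaky_alpha)
}

#' Channel stack: a sequence of graph-attention layers
#'
#' @param n_in Input feature width (number of regions for the first layer).
#' @param hidden Output width of every layer.
#' @param depth Number of layers (the grid-searched range is 1..5).
#' @inheritParams gat_layer_params
#' @return List of class `brainfuse_stack`.
#' @export
channel_stack <- function(n_in, hidden, depth, init = c("glorot", "zero")) {
  init <- match.arg(init)
  stopifnot(depth >= 1)
  dims <- c(n_in, rep(hidden, depth))
  layers <- lapply(seq_len(depth), function(l) {
    gat_layer_params(dims[l], dims[l + 1], init = init)
  })
  structure(list(layers = layers), class = "brainfuse_stack")
}

#' Raw pairwise attention scores
#'
#' `e_ij = LeakyReLU(a^T [W r_i || W r_j])` for every ordered pair of
#' regions, before any masking.
#'
#' @param node_features n x f_in matrix, one row per region.
#' @param params From [gat_layer_params()].
#' @return n x n matrix of scores.
#' @export
attention_scores <- function(node_features, params) {
  S <- node_features %*% t(params$W)           # n x f_out
  f_out <- nrow(params$W)
  if (length(params$a) != 2 * f_out) {
    stop("attention vector length ", length(params$a), " != 2 x f_out (",
         2 * f_out, ")", call. = FALSE)
  }
  f <- drop(S %*% params$a[seq_len(f_out)])
  g <- drop(S %*% params$a[f_out + seq_len(f_out)])
  leaky_relu(outer(f, rep(1, length(g))) + outer(rep(1, length(f)), g),
             params$leaky_alpha)
}

leaky_relu <- function(x, alpha) pmax(x, 0) + alpha * pmin(x, 0)

#' Neighborhoods implied by an adjacency matrix
#'
#' An edge survives only where the adjacency entry is strictly positive;
#' self-loops are always inserted so no region is orphaned (the structural
#' diagonal is zero by construction).
#'
#' @param adjacency n x n matrix.
#' @return Logical n x n neighborhood matrix.
#' @export
attention_mask <- function(adjacency) {
  M <- adjacency > 0
  diag(M) <- TRUE
  M
}

#' Apply the graph mask to raw scores
#'
#' Scores on non-edges (adjacency <= 0, off the diagonal) are zeroed and
#' excluded from the softmax neighborhoods.
#'
#' @param e Raw score matrix from [attention_scores()].
#' @param adjacency Matching adjacency matrix.
#' @return Masked score matrix.
#' @export
mask_scores <- function(e, adjacency) {
  if (!all(dim(e) == dim(adjacency))) {
    stop("score and adjacency shapes differ", call. = FALSE)
  }
  e * attention_mask(adjacency)
}

#' Softmax-normalize masked scores over each neighborhood
#'
#' @param e Score matrix.
#' @param mask Logical neighborhood matrix (from [attention_mask()]).
#' @return Row-stochastic attention matrix: rows sum to 1 over the
#'   neighborhood, zero elsewhere.
#' @export
normalize_attention <- function(e, mask) {
  if (any(rowSums(mask) == 0)) {
    stop("internal error: empty neighborhood despite self-loops", call. = FALSE)
  }
  em <- e
  em[!mask] <- -Inf
  mx <- em[cbind(seq_len(nrow(em)), max.col(em, "first"))]
  ex <- exp(em - mx)                           # overflow-safe; exp(-Inf) = 0
  ex / rowSums(ex)
}

# Full forward pass of one layer, keeping every intermediate needed by the
# analytic backward pass. `notmask` is the precomputed complement of the
# neighborhood matrix (hot loop: avoids reallocating it per call).
gat_forward_cache <- function(H, mask, notmask, params, activation = "relu") {
  S <- tcrossprod(H, params$W)                 # H %*% t(W)
  f_out <- nrow(params$W)
  a1 <- params$a[seq_len(f_out)]
  a2 <- params$a[f_out + seq_len(f_out)]
  f <- drop(S %*% a1)
  g <- drop(S %*% a2)
  Eraw <- outer(f, g, `+`)
  Eact <- leaky_relu(Eraw, params$leaky_alpha)
  em <- Eact
  em[notmask] <- -Inf
  mx <- em[cbind(seq_along(f), max.col(em, "first"))]
  ex <- exp(em - mx)
  alpha <- ex / rowSums(ex)
  P <- alpha %*% S
  out <- if (activation == "relu") pmax(P, 0) else P
  list(H = H, S = S, Eraw = Eraw, alpha = alpha, P = P, out = out,
       activation = activation)
}

# Backward pass matching gat_forward_cache. Returns parameter gradients and
# the gradient w.r.t. the layer input. Off-neighborhood entries need no
# explicit masking: alpha is zero there, so dEact already vanishes.
gat_backward <- function(cache, params, dOut) {
  f_out <- nrow(params$W)
  a1 <- params$a[seq_len(f_out)]
  a2 <- params$a[f_out + seq_len(f_out)]
  dP <- if (cache$activation == "relu") dOut * (cache$P > 0) else dOut
  dalpha <- tcrossprod(dP, cache$S)
  dS <- crossprod(cache$alpha, dP)
  # softmax backward per masked row
  rs <- rowSums(cache$alpha * dalpha)
  dEact <- cache$alpha * (dalpha - rs)
  al <- params$leaky_alpha
  dEraw <- dEact * (al + (1 - al) * (cache$Eraw > 0))
  df <- rowSums(dEraw)
  dg <- colSums(dEraw)
  dS <- dS + outer(df, a1) + outer(dg, a2)
  da <- c(drop(crossprod(cache$S, df)), drop(crossprod(cache$S, dg)))
  list(dW = crossprod(dS, cache$H), da = da, dH = dS %*% params$W)
}

#' One graph-attention layer forward pass
#'
#' Scores every masked pair, softmax-normalizes over neighborhoods and
#' aggregates transformed neighbor features:
#' `z_i = sigma(sum_j alpha_ij W r_j)`.
#'
#' @param node_features n x f_in matrix.
#' @param adjacency n x n adjacency whose positive support defines edges.
#' @param params From [gat_layer_params()].
#' @param activation `"relu"` (hidden layers) or `"identity"` (final layer,
#'   so the fusion stage sees signed features).
#' @return n x f_out matrix of updated region features.
#' @export
gat_layer_forward <- function(node_features, adjacency, params,
                              activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  M <- attention_mask(adjacency)
  gat_forward_cache(node_features, M, !M, params, activation)$out
}

# Forward a whole stack; the last layer uses the identity activation.
# `mask` may be an adjacency matrix or a precomputed list(mask, notmask).
stack_forward <- function(H, mask, stack) {
  if (!is.list(mask)) {
    M <- attention_mask(mask)
    mask <- list(mask = M, notmask = !M)
  }
  L <- length(stack$layers)
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    act <- if (l == L) "identity" else "relu"
    caches[[l]] <- gat_forward_cache(H, mask$mask, mask$notmask,
                                     stack$layers[[l]], act)
    H <- caches[[l]]$out
  }
  list(out = H, caches = caches)
}

stack_backward <- function(caches, stack, dOut) {
  L <- length(stack$layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    g <- gat_backward(caches[[l]], stack$layers[[l]], dOut)
    grads[[l]] <- list(dW = g$dW, da = g$da)
    dOut <- g$dH
  }
  list(grads = grads, dH = dOut)
}

#' Run both channels of the multichannel graph-attention extractor
#'
#' The two networks share node features; each channel has its own layer
#' stack and is masked by its own adjacency (Pearson support for the
#' functional channel, fiber-count support for the structural one).
#'
#' @param networks Output of [build_networks()].
#' @param stack_f,stack_s [channel_stack()]s for the two channels.
#' @return List with embeddings `Z_F` and `Z_S` (n x hidden).
#' @export
multichannel_forward <- function(networks, stack_f, stack_s) {
  H <- networks$functional$node_features
  list(Z_F = stack_forward(H, networks$functional$adjacency, stack_f)$out,
       Z_S = stack_forward(H, networks$structural$adjacency, stack_s)$out)
}
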