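#' Run configuration
#'
#' All tunable knobs of the fusion model in one place. Every source of
#' randomness (initialization, fold shuffling) flows from `seed`.
#'
#' @param seed Integer seed.
#' @param hidden_dim Width of the graph-attention embeddings (per region).
#' @param gat_layers Depth of each channel stack (the searched range is
#'   1..5).
#' @param learning_rate Adam learning rate.
#' @param epochs Full-batch training epochs.
#' @param folds Cross-validation folds.
#' @param node_feature_mode How the per-region context vector becomes node
#'   features; see [build_networks()].
#' @param attention_heads Attention heads per layer (the model's equations
#'   are single-head; kept configurable).
#' @param mlp_hidden Integer vector of MLP hidden widths.
#' @param fusion_hidden Width of the channel-attention scorer (defaults to
#'   `hidden_dim`).
#' @param weight_decay L2 penalty added to the gradient (the standard
#'   graph-attention training recipe; essential against memorization at
#'   cohort sizes of a few dozen subjects).
#' @return List of class `brainfuse_config`.
#' @export
run_config <- function(seed = 1L, hidden_dim = 8L, gat_layers = 1L,
                       learning_rate = 3e-3, epochs = 150L, folds = 5L,
                       node_feature_mode = c("diag", "broadcast", "conn_row"),
                       attention_heads = 1L, mlp_hidden = 16L,
                       fusion_hidden = hidden_dim, weight_decay = 5e-3) {
  node_feature_mode <- match.arg(node_feature_mode)
  stopifnot(folds >= 2, gat_layers >= 1, gat_layers <= 5, learning_rate >= 0,
            epochs >= 0, hidden_dim >= 1, attention_heads >= 1,
            weight_decay >= 0)
  structure(list(seed = as.integer(seed), hidden_dim = as.integer(hidden_dim),
                 gat_layers = as.integer(gat_layers),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 folds = as.integer(folds), node_feature_mode = node_feature_mode,
                 attention_heads = as.integer(attention_heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 fusion_hidden = as.integer(fusion_hidden),
                 weight_decay = weight_decay),
            class = "brainfuse_config")
}

#' Channel-attention fusion parameters
#'
#' Scorer `delta_ci = q^T tanh(W_att z_ci + b_att)` shared across both
#' channels; a per-region two-way softmax over the channel scores yields
#' the fusion weights.
#'
#' @param h Scorer hidden width.
#' @param f Embedding width.
#' @inheritParams gat_layer_params
#' @return List with `W_att` (h x f), `b_att` (h), `q` (h).
#' @export
fusion_params <- function(h, f, init = c("glorot", "zero")) {
  init <- match.arg(init)
  q <- if (init == "zero") numeric(h) else {
    lim <- sqrt(6 / (h + 1)); stats::runif(h, -lim, lim)
  }
  list(W_att = init_mat(h, f, init), b_att = init_vec(h, f, init), q = q)
}

mlp_params <- function(dims, init = "glorot") {
  lapply(seq_len(length(dims) - 1), function(l) {
    list(W = init_mat(dims[l + 1], dims[l], init),
         b = init_vec(dims[l + 1], dims[l], init))
  })
}

#' Initialize an untrained fusion model
#'
#' Draws all parameters from the current RNG stream ([train_model()] seeds
#' it from the config).
#'
#' @param n Number of regions.
#' @param config A [run_config()].
#' @param p Number of demographic variables.
#' @param init Parameter initialization scheme.
#' @return List of class `brainfuse_model`.
#' @export
init_fusion_model <- function(n, config = run_config(), p = 9L,
                              init = c("glorot", "zero")) {
  init <- match.arg(init)
  f <- config$hidden_dim
  structure(list(
    context = context_params(n, p, init = init),
    stack_f = channel_stack(n, f, config$gat_layers, init = init),
    stack_s = channel_stack(n, f, config$gat_layers, init = init),
    fusion = fusion_params(config$fusion_hidden, f, init = init),
    mlp = mlp_params(c(n * f, config$mlp_hidden, 2L), init = init),
    config = config, n = n, p = p, encoding = NULL
  ), class = "brainfuse_model")
}

#' Per-region channel-attention weights
#'
#' @param Z_F,Z_S Channel embeddings (n x f).
#' @param params From [fusion_params()].
#' @return List with vectors `w_f`, `w_s` (elementwise in (0,1), summing to
#'   1) and the raw scores `delta_f`, `delta_s`.
#' @export
channel_attention <- function(Z_F, Z_S, params) {
  if (!all(dim(Z_F) == dim(Z_S))) stop("embedding shapes differ", call. = FALSE)
  score <- function(Z) {
    U <- Z %*% t(params$W_att)
    U <- sweep(U, 2, params$b_att, `+`)
    drop(tanh(U) %*% params$q)
  }
  d_f <- score(Z_F); d_s <- score(Z_S)
  w_f <- 1 / (1 + exp(d_s - d_f))              # two-way softmax, stable
  list(w_f = w_f, w_s = 1 - w_f, delta_f = d_f, delta_s = d_s)
}

#' Convex-combine channel embeddings with fusion weights
#'
#' Row i of the result is `w_f[i] * Z_F[i, ] + w_s[i] * Z_S[i, ]`.
#'
#' @param Z_F,Z_S Channel embeddings.
#' @param weights From [channel_attention()] (or any list with `w_f`,
#'   `w_s`).
#' @return Fused n x f embedding.
#' @export
fuse_embeddings <- function(Z_F, Z_S, weights) {
  if (!all(dim(Z_F) == dim(Z_S))) stop("embedding shapes differ", call. = FALSE)
  Z_F * weights$w_f + Z_S * weights$w_s
}

#' MLP classifier forward pass
#'
#' Flattens the fused embedding row-major (region-major), applies affine
#' layers with ReLU between them, and softmaxes the two output logits.
#'
#' @param Z Fused n x f embedding (or an already-flattened vector).
#' @param layers List of `(W, b)` layers, e.g. from a trained model's
#'   `$mlp`.
#' @return Length-2 probability vector `(p_nmci, p_mci)`.
#' @export
mlp_forward <- function(Z, layers) {
  x <- if (is.matrix(Z)) as.vector(t(Z)) else as.numeric(Z)
  L <- length(layers)
  for (l in seq_len(L)) {
    if (length(x) != ncol(layers[[l]]$W)) {
      stop("MLP layer ", l, " expects input of length ", ncol(layers[[l]]$W),
           ", got ", length(x), call. = FALSE)
    }
    x <- drop(layers[[l]]$W %*% x) + layers[[l]]$b
    if (l < L) x <- pmax(x, 0)
  }
  softmax2(x)
}

softmax2 <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

# ---- end-to-end forward/backward ------------------------------------------

# Fixed (non-learnable) per-subject blocks, computed once before training.
# `ablation` is a character subset of c("fmri", "dti", "t1", "demographics")
# naming modality paths to disable: dropped connectivity channels fall back
# to a fully-connected mask, dropped vector inputs are zeroed.
# `abs_correlation` rectifies the functional adjacency before masking for
# users who prefer not to discard anticorrelated edges.
prepare_subject <- function(subject, enc, ablation = NULL,
                            abs_correlation = FALSE) {
  n <- nrow(subject$time_series)
  C <- functional_connectivity(subject$time_series)
  if (abs_correlation) C <- abs(C)
  D <- subject$fiber_counts
  E <- encode_demographics(subject$demographics, enc)
  Tv <- encode_volumes(subject$roi_volumes, enc)
  if (!is.null(ablation)) {
    bad <- setdiff(ablation, c("fmri", "dti", "t1", "demographics"))
    if (length(bad)) stop("unknown ablation: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if ("fmri" %in% ablation) C <- matrix(1, n, n)
    if ("dti" %in% ablation) { D <- matrix(1, n, n); diag(D) <- 0 }
    if ("t1" %in% ablation) Tv <- Tv * 0
    if ("demographics" %in% ablation) E <- E * 0
  }
  MC <- attention_mask(C)
  MD <- attention_mask(D)
  list(C = C, D = D, E = E, Tv = Tv,
       mask_c = list(mask = MC, notmask = !MC),
       mask_d = list(mask = MD, notmask = !MD),
       label = subject$label, subject_id = subject$subject_id)
}

model_forward <- function(model, pre) {
  ctx <- model$context
  Fv <- drop(ctx$w1 %*% pre$E) + ctx$b1 + pre$Tv
  R <- drop(ctx$w2 %*% Fv) + ctx$b2
  H0 <- node_features_from_context(R, pre$C, model$config$node_feature_mode)
  sf <- stack_forward(H0, pre$mask_c, model$stack_f)
  ss <- stack_forward(H0, pre$mask_d, model$stack_s)
  Z_F <- sf$out; Z_S <- ss$out
  fu <- model$fusion
  U_F <- tcrossprod(Z_F, fu$W_att)
  U_S <- tcrossprod(Z_S, fu$W_att)
  U_F <- U_F + rep(fu$b_att, each = nrow(U_F))
  U_S <- U_S + rep(fu$b_att, each = nrow(U_S))
  T_F <- tanh(U_F); T_S <- tanh(U_S)
  d_f <- drop(T_F %*% fu$q); d_s <- drop(T_S %*% fu$q)
  w_f <- 1 / (1 + exp(d_s - d_f)); w_s <- 1 - w_f
  Z <- Z_F * w_f + Z_S * w_s
  x <- as.vector(t(Z))
  L <- length(model$mlp)
  xs <- vector("list", L)                      # layer inputs
  for (l in seq_len(L)) {
    xs[[l]] <- x
    x <- drop(model$mlp[[l]]$W %*% x) + model$mlp[[l]]$b
    if (l < L) x <- pmax(x, 0)
  }
  probs <- softmax2(x)
  list(probs = probs, logits = x, xs = xs, Z = Z, Z_F = Z_F, Z_S = Z_S,
       w_f = w_f, w_s = w_s, T_F = T_F, T_S = T_S, sf = sf, ss = ss,
       Fv = Fv, R = R, H0 = H0)
}

model_backward <- function(model, pre, fwd, label) {
  y <- c(1 - label, label)
  dlogits <- fwd$probs - y
  L <- length(model$mlp)
  g_mlp <- vector("list", L)
  d <- dlogits
  for (l in rev(seq_len(L))) {
    x_in <- fwd$xs[[l]]
    g_mlp[[l]] <- list(W = outer(d, x_in), b = d)
    dx <- drop(crossprod(model$mlp[[l]]$W, d))
    if (l > 1) d <- dx * (fwd$xs[[l]] > 0) else d_in <- dx
  }
  n <- model$n; f <- model$config$hidden_dim
  dZ <- matrix(d_in, n, f, byrow = TRUE)
  # fusion backward
  fu <- model$fusion
  dZ_F <- dZ * fwd$w_f
  dZ_S <- dZ * fwd$w_s
  dw_f <- rowSums(dZ * fwd$Z_F)
  dw_s <- rowSums(dZ * fwd$Z_S)
  dd_f <- fwd$w_f * fwd$w_s * (dw_f - dw_s)    # pair softmax backward
  dd_s <- -dd_f
  dT_F <- outer(dd_f, fu$q); dT_S <- outer(dd_s, fu$q)
  dU_F <- dT_F * (1 - fwd$T_F^2); dU_S <- dT_S * (1 - fwd$T_S^2)
  g_fu <- list(
    W_att = crossprod(dU_F, fwd$Z_F) + crossprod(dU_S, fwd$Z_S),
    b_att = colSums(dU_F) + colSums(dU_S),
    q = drop(crossprod(fwd$T_F, dd_f) + crossprod(fwd$T_S, dd_s))
  )
  dZ_F <- dZ_F + dU_F %*% fu$W_att
  dZ_S <- dZ_S + dU_S %*% fu$W_att
  bf <- stack_backward(fwd$sf$caches, model$stack_f, dZ_F)
  bs <- stack_backward(fwd$ss$caches, model$stack_s, dZ_S)
  dH0 <- bf$dH + bs$dH
  dR <- switch(model$config$node_feature_mode,
    diag = diag(dH0),
    broadcast = colSums(dH0),
    conn_row = colSums(dH0 * pre$C)
  )
  ctx <- model$context
  dFv <- drop(crossprod(ctx$w2, dR))
  g_ctx <- list(w1 = outer(dFv, pre$E), b1 = dFv,
                w2 = outer(dR, fwd$Fv), b2 = dR)
  list(context = g_ctx,
       stack_f = list(layers = bf$grads), stack_s = list(layers = bs$grads),
       fusion = g_fu, mlp = g_mlp)
}

# ---- nested-list (pytree) arithmetic and Adam -----------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(x[[i]], y[[i]], f)
    out
  } else f(x, y)
}

# extract only the learnable leaves of a model, in a fixed layout that
# matches model_backward's gradient tree
model_params <- function(model) {
  list(context = model$context,
       stack_f = list(layers = lapply(model$stack_f$layers,
                                      function(l) list(dW = l$W, da = l$a))),
       stack_s = list(layers = lapply(model$stack_s$layers,
                                      function(l) list(dW = l$W, da = l$a))),
       fusion = model$fusion, mlp = model$mlp)
}

model_set_params <- function(model, params) {
  model$context <- params$context
  for (l in seq_along(model$stack_f$layers)) {
    model$stack_f$layers[[l]]$W <- params$stack_f$layers[[l]]$dW
    model$stack_f$layers[[l]]$a <- drop(params$stack_f$layers[[l]]$da)
  }
  for (l in seq_along(model$stack_s$layers)) {
    model$stack_s$layers[[l]]$W <- params$stack_s$layers[[l]]$dW
    model$stack_s$layers[[l]]$a <- drop(params$stack_s$layers[[l]]$da)
  }
  model$fusion <- params$fusion
  model$mlp <- params$mlp
  model
}

# Parameters and gradients share one tree layout, so the optimizer works on
# flat vectors (cheap accumulation in the hot loop) and the tree is rebuilt
# once per epoch.
unflatten_tree <- function(flat, skeleton) {
  i <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    len <- length(s)
    v <- flat[(i + 1L):(i + len)]
    i <<- i + len
    if (!is.null(dim(s))) dim(v) <- dim(s)
    v
  }
  rec(skeleton)
}

adam_init <- function(n_par) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L)
}

adam_step <- function(pflat, gflat, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gflat
  state$v <- beta2 * state$v + (1 - beta2) * gflat^2
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  pflat <- pflat - lr * (state$m / bc1) / (sqrt(state$v / bc2) + eps)
  list(pflat = pflat, state = state)
}

# ---- training --------------------------------------------------------------

#' Train the fusion model on a labeled cohort
#'
#' Full-batch Adam on the mean cross-entropy of the cohort, with analytic
#' gradients through the MLP, channel-attention fusion, both
#' graph-attention stacks and the context encoder. Deterministic given
#' `config$seed`.
#'
#' @param x A labeled `brainfuse_cohort` (both classes present).
#' @param config A [run_config()].
#' @param encoding Optional pre-fitted [fit_encoding()]; fitted on `x`
#'   otherwise. Pass the training-fold encoding during cross-validation.
#' @param ablation Optional character vector of modality paths to disable
#'   (subset of `"fmri"`, `"dti"`, `"t1"`, `"demographics"`): dropped
#'   connectivity channels fall back to a fully-connected attention mask,
#'   dropped vector inputs are zeroed. The trained model remembers the
#'   ablation and applies it at prediction time.
#' @return The trained `brainfuse_model`; `$loss_trace` holds the per-epoch
#'   mean cross-entropy, `$encoding` the encoding used.
#' @export
train_model <- function(x, config = run_config(), encoding = NULL,
                        ablation = NULL) {
  stopifnot(inherits(x, "brainfuse_cohort"))
  labs <- cohort_labels(x)
  if (anyNA(labs)) stop("all training subjects must be labeled", call. = FALSE)
  if (length(unique(labs)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (is.null(encoding)) encoding <- fit_encoding(x)
  pres <- lapply(x$subjects, prepare_subject, enc = encoding,
                 ablation = ablation)
  n <- n_regions(x$atlas)
  with_seed(config$seed, {
    model <- init_fusion_model(n, config)
    model$encoding <- encoding
    model$ablation <- ablation
    skeleton <- model_params(model)
    pflat <- unlist(skeleton, use.names = FALSE)
    state <- adam_init(length(pflat))
    trace <- numeric(config$epochs)
    k <- length(pres)
    for (epoch in seq_len(config$epochs)) {
      gtotal <- numeric(length(pflat))
      loss <- 0
      for (pre in pres) {
        fwd <- model_forward(model, pre)
        loss <- loss - log(max(fwd$probs[pre$label + 1L], 1e-12))
        g <- model_backward(model, pre, fwd, pre$label)
        gtotal <- gtotal + unlist(g, use.names = FALSE)
      }
      loss <- loss / k
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      trace[epoch] <- loss
      st <- adam_step(pflat, gtotal / k + config$weight_decay * pflat,
                      state, config$learning_rate)
      pflat <- st$pflat
      state <- st$state
      model <- model_set_params(model, unflatten_tree(pflat, skeleton))
    }
    model$loss_trace <- trace
    model
  })
}

#' Predict MCI probability for subjects
#'
#' @param object A trained `brainfuse_model`.
#' @param newdata A `brainfuse_cohort` or single `brainfuse_subject`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `prob_mci`, `pred` (1 iff
#'   `prob_mci >= 0.5`; exact ties go to the positive class, the
#'   screening-appropriate choice).
#' @export
predict.brainfuse_model <- function(object, newdata, ...) {
  subjects <- if (inherits(newdata, "brainfuse_subject")) list(newdata)
              else newdata$subjects
  purrr::map_dfr(subjects, function(s) {
    pre <- prepare_subject(s, object$encoding, object$ablation)
    fwd <- model_forward(object, pre)
    p <- fwd$probs[2]
    tibble::tibble(subject_id = s$subject_id, prob_mci = p,
                   pred = as.integer(p >= 0.5))
  })
}

#' Fused pre-classifier embeddings for subjects
#'
#' Returns the per-subject fused embedding `Z` (the representation fed to
#' the classifier), flattened region-major — the input to saliency and
#' 2-D embedding analyses.
#'
#' @param model A trained `brainfuse_model`.
#' @param x A `brainfuse_cohort`.
#' @return Matrix (subjects x (n regions * hidden_dim)).
#' @export
model_embeddings <- function(model, x) {
  out <- t(vapply(x$subjects, function(s) {
    pre <- prepare_subject(s, model$encoding, model$ablation)
    as.vector(t(model_forward(model, pre)$Z))
  }, numeric(model$n * model$config$hidden_dim)))
  rownames(out) <- cohort_ids(x)
  out
}

#' @export
print.brainfuse_model <- function(x, ...) {
  np <- sum(unlist(tree_map(model_params(x), length)))
  cat("<brainfuse_model> ", x$n, " regions, hidden ", x$config$hidden_dim,
      ", ", x$config$gat_layers, " GAT layer(s)/channel, ",
      format(np, big.mark = ","), " parameters",
      if (length(x$loss_trace)) paste0("; final loss ",
                                       signif(utils::tail(x$loss_trace, 1), 4)),
      "\n", sep = "")
  invisible(x)
}
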