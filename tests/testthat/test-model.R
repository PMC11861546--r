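test_that("channel attention is a per-region two-way softmax", {
  set.seed(21)
  Z <- matrix(rnorm(12), 4, 3)
  params <- fusion_params(3, 3)
  w <- channel_attention(Z, Z, params)
  expect_equal(w$w_f, rep(0.5, 4))             # identical channels
  expect_equal(w$w_f + w$w_s, rep(1, 4), tolerance = 1e-12)

  params0 <- fusion_params(3, 3, init = "zero")
  Z2 <- matrix(rnorm(12), 4, 3)
  w0 <- channel_attention(Z, Z2, params0)
  expect_equal(w0$w_f, rep(0.5, 4))            # zero scorer

  # delta_F = ln 3, delta_S = 0 -> w_F = 0.75 (closed form)
  expect_equal(1 / (1 + exp(0 - log(3))), 0.75)
  expect_error(channel_attention(Z, matrix(0, 2, 3), params), "differ")
})

test_that("fusion weights stay in (0,1) and sum to one on random inputs", {
  set.seed(22)
  for (rep in 1:20) {
    Z_F <- matrix(rnorm(40), 8, 5)
    Z_S <- matrix(rnorm(40), 8, 5)
    w <- channel_attention(Z_F, Z_S, fusion_params(5, 5))
    expect_equal(w$w_f + w$w_s, rep(1, 8), tolerance = 1e-12)
    expect_true(all(w$w_f > 0 & w$w_f < 1))
  }
})

test_that("fused embeddings are the advertised convex combination", {
  Z_F <- matrix(2, 1, 1); Z_S <- matrix(4, 1, 1)
  expect_equal(fuse_embeddings(Z_F, Z_S, list(w_f = 0.75, w_s = 0.25)),
               matrix(2.5, 1, 1))
  expect_equal(fuse_embeddings(Z_F, Z_S, list(w_f = 1, w_s = 0)), Z_F)
  set.seed(23)
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
  expect_equal(fuse_embeddings(A, B, list(w_f = rep(0.5, 4), w_s = rep(0.5, 4))),
               (A + B) / 2)
})

test_that("the MLP head produces calibrated softmax probabilities", {
  layers <- list(list(W = matrix(0, 2, 4), b = c(0, 0)))
  expect_equal(mlp_forward(matrix(1, 2, 2), layers), c(0.5, 0.5))
  layers <- list(list(W = diag(2), b = c(0, 0)))
  expect_equal(mlp_forward(c(log(3), 0), layers), c(0.75, 0.25))
  # dead hidden path: output depends only on the output bias
  layers <- list(list(W = matrix(-1, 3, 2), b = rep(-1, 3)),
                 list(W = matrix(rnorm(6), 2, 3), b = c(log(9), 0)))
  expect_equal(mlp_forward(c(5, 5), layers), c(0.9, 0.1))
  expect_error(mlp_forward(c(1, 2, 3), list(list(W = diag(2), b = c(0, 0)))),
               "length 2")
})

test_that("analytic gradients match finite differences end to end", {
  co <- tiny_cohort(seed = 33)
  enc <- fit_encoding(co)
  cfg <- tiny_config(hidden_dim = 5L, gat_layers = 2L, mlp_hidden = 6L)
  set.seed(44)
  model <- init_fusion_model(8, cfg)
  model$encoding <- enc
  pres <- lapply(co$subjects[1:4], brainfuse:::prepare_subject, enc = enc)

  loss_fn <- function(m) {
    sum(vapply(pres, function(pre) {
      -log(brainfuse:::model_forward(m, pre)$probs[pre$label + 1])
    }, numeric(1)))
  }
  grads <- NULL
  for (pre in pres) {
    fwd <- brainfuse:::model_forward(model, pre)
    g <- brainfuse:::model_backward(model, pre, fwd, pre$label)
    grads <- if (is.null(grads)) g else brainfuse:::tree_map2(grads, g, `+`)
  }
  skeleton <- brainfuse:::model_params(model)
  pflat <- unlist(skeleton, use.names = FALSE)
  gflat <- unlist(grads, use.names = FALSE)
  eps <- 1e-6
  set.seed(55)
  for (idx in sample(length(pflat), 20)) {
    bump <- function(delta) {
      p2 <- pflat; p2[idx] <- p2[idx] + delta
      brainfuse:::model_set_params(model,
                                   brainfuse:::unflatten_tree(p2, skeleton))
    }
    num <- (loss_fn(bump(eps)) - loss_fn(bump(-eps))) / (2 * eps)
    expect_equal(gflat[idx], num,
                 tolerance = max(1e-4, 1e-4 * abs(num)))
  }
})

test_that("training is deterministic given a seed and inert at zero learning rate", {
  co <- tiny_cohort(seed = 40)
  cfg <- tiny_config(seed = 9, epochs = 5L)
  m1 <- train_model(co, cfg)
  m2 <- train_model(co, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(brainfuse:::model_params(m1), brainfuse:::model_params(m2))

  cfg0 <- tiny_config(seed = 9, epochs = 5L, learning_rate = 0,
                      weight_decay = 0)
  m0 <- train_model(co, cfg0)
  expect_equal(max(abs(diff(m0$loss_trace))), 0, tolerance = 1e-12)
  set.seed(cfg0$seed)
  expect_equal(unlist(brainfuse:::model_params(m0), use.names = FALSE),
               unlist(brainfuse:::model_params(
                 train_model(co, tiny_config(seed = 9, epochs = 0L))),
                 use.names = FALSE))
})

test_that("training refuses single-class cohorts", {
  co <- tiny_cohort(seed = 41)
  idx <- which(brainfuse:::cohort_labels(co) == 0)
  solo <- brainfuse:::cohort_subset(co, idx)
  expect_error(train_model(solo, tiny_config()), "single class")
})

test_that("loss decreases over early epochs at the default learning rate", {
  co <- tiny_cohort(seed = 42, n_regions = 10, n_mci = 5, n_nmci = 7)
  cfg <- tiny_config(seed = 3, epochs = 10L, weight_decay = 0)
  m <- train_model(co, cfg)
  expect_true(all(diff(m$loss_trace) <= 1e-8))
})

test_that("a separable synthetic cohort is fit to high training accuracy", {
  co <- generate_cohort(synthetic_config(
    n_mci = 5, n_nmci = 7, n_regions = 10, n_timepoints = 40,
    functional_edges = rbind(c(1, 5)), delta_c = 0.6,
    structural_edges = rbind(c(2, 6)), delta_s = 30,
    atrophy_regions = c(3, 8), atrophy = 0.2, seed = 50
  ))
  m <- train_model(co, tiny_config(seed = 1, epochs = 60L))
  p <- predict(m, co)
  acc <- mean(p$pred == brainfuse:::cohort_labels(co))
  expect_gte(acc, 0.95)
})

test_that("prediction applies the documented tie rule and probability range", {
  co <- tiny_cohort(seed = 43)
  cfg <- tiny_config(epochs = 0L)
  m <- train_model(co, cfg)
  # untrained model with zeroed output layer gives exactly 0.5 -> class 1
  pars <- brainfuse:::model_params(m)
  pars$mlp[[length(pars$mlp)]]$W[] <- 0
  pars$mlp[[length(pars$mlp)]]$b[] <- 0
  m <- brainfuse:::model_set_params(m, pars)
  p <- predict(m, co$subjects[[1]])
  expect_equal(p$prob_mci, 0.5)
  expect_equal(p$pred, 1L)
})

test_that("swapping class labels and output rows mirrors the probabilities", {
  co <- tiny_cohort(seed = 44)
  m <- train_model(co, tiny_config(seed = 5, epochs = 3L))
  p1 <- predict(m, co)
  pars <- brainfuse:::model_params(m)
  L <- length(pars$mlp)
  pars$mlp[[L]]$W <- pars$mlp[[L]]$W[2:1, , drop = FALSE]
  pars$mlp[[L]]$b <- pars$mlp[[L]]$b[2:1]
  m2 <- brainfuse:::model_set_params(m, pars)
  p2 <- predict(m2, co)
  expect_equal(p2$prob_mci, 1 - p1$prob_mci, tolerance = 1e-12)
})

test_that("a subject-and-model permutation leaves predictions unchanged", {
  co <- tiny_cohort(seed = 45)
  cfg <- tiny_config(seed = 6, epochs = 8L)
  m <- train_model(co, cfg)
  perm <- sample(8)
  co_p <- cohort(region_atlas(co$atlas$name[perm]),
                 lapply(co$subjects, permute_subject, perm = perm))
  # retraining on permuted data with permutation-matched init is equivalent
  # to permuting the trained model's region-indexed parameters
  pars <- brainfuse:::model_params(m)
  pars$context$w1 <- pars$context$w1[perm, , drop = FALSE]
  pars$context$b1 <- pars$context$b1[perm]
  pars$context$w2 <- pars$context$w2[perm, perm]
  pars$context$b2 <- pars$context$b2[perm]
  for (ch in c("stack_f", "stack_s")) {
    pars[[ch]]$layers[[1]]$dW <- pars[[ch]]$layers[[1]]$dW[, perm, drop = FALSE]
  }
  # MLP input is region-major: permute its first-layer column blocks
  f <- m$config$hidden_dim
  colblocks <- as.vector(vapply(perm, function(r) (r - 1) * f + seq_len(f),
                                numeric(f)))
  pars$mlp[[1]]$W <- pars$mlp[[1]]$W[, colblocks, drop = FALSE]
  m_p <- brainfuse:::model_set_params(m, pars)
  m_p$n <- 8
  m_p$encoding$vol_mean <- m$encoding$vol_mean[perm]
  m_p$encoding$vol_sd <- m$encoding$vol_sd[perm]
  expect_equal(predict(m_p, co_p)$prob_mci, predict(m, co)$prob_mci,
               tolerance = 1e-8)
})

test_that("grid search is exhaustive with documented tie-breaking", {
  co <- tiny_cohort(seed = 46, n_mci = 5, n_nmci = 7)
  cfg <- tiny_config(seed = 2, epochs = 3L, folds = 2L)
  gs <- grid_search(co, lr_grid = c(1e-3, 10), depth_grid = c(1, 2),
                    config = cfg)
  expect_equal(nrow(gs$table), 4)
  best_acc <- max(gs$table$acc)
  expect_equal(
    gs$table$acc[gs$table$learning_rate == gs$best_lr &
                   gs$table$gat_layers == gs$best_depth],
    best_acc
  )
  # an absurd learning rate can never beat the best grid point
  expect_lte(gs$table$acc[gs$table$learning_rate == 10 &
                            gs$table$gat_layers == gs$best_depth][1], best_acc)
  gs1 <- grid_search(co, 1e-3, 1L, config = cfg)
  expect_equal(gs1$best_lr, 1e-3)
  expect_equal(gs1$best_depth, 1L)
})
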