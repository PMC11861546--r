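test_that("single standardized feature has the closed-form solution", {
  set.seed(81)
  for (rep in 1:10) {
    x <- rnorm(25); y <- rnorm(25, 0.5 * x)
    xs <- as.vector(scale(x)); yc <- y - mean(y)
    n <- 25
    l1 <- 0.05
    expected <- max(0, sum(xs * yc) / n - l1) / (sum(xs^2) / n)
    beta <- nonneg_elastic_net(matrix(x), y, lambda_l1 = l1, lambda_l2 = 0)
    expect_equal(as.numeric(beta), expected, tolerance = 1e-8)
  }
})

test_that("large l1 shrinks everything to zero; anticorrelation pins at zero", {
  set.seed(82)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  l1_max <- max(abs(crossprod(scale(X), y - mean(y)))) / 20
  beta <- nonneg_elastic_net(X, y, lambda_l1 = l1_max * 1.01, lambda_l2 = 0)
  expect_equal(as.numeric(beta), c(0, 0, 0))

  x <- rnorm(30)
  y2 <- -x + rnorm(30, sd = 0.1)               # strongly anticorrelated
  b <- nonneg_elastic_net(matrix(x), y2, lambda_l1 = 0.01, lambda_l2 = 0.01)
  expect_equal(as.numeric(b), 0)
})

test_that("coordinate descent matches a projected-gradient oracle", {
  set.seed(83)
  for (rep in 1:5) {
    X <- matrix(rnorm(200), 20, 10)
    y <- rbinom(20, 1, 0.5)
    l1 <- 0.02; l2 <- 0.01
    ours <- nonneg_elastic_net(X, y, l1, l2, tol = 1e-10)
    ref <- pg_elastic_net(X, y, l1, l2)
    expect_equal(pg_objective(X, y, ours, l1, l2),
                 pg_objective(X, y, ref, l1, l2), tolerance = 1e-6)
    expect_true(all(ours >= 0))
  }
})

test_that("the elastic-net objective never increases across sweeps", {
  set.seed(84)
  X <- matrix(rnorm(300), 30, 10)
  y <- rbinom(30, 1, 0.4)
  l1 <- 0.02; l2 <- 0.01
  objs <- vapply(1:8, function(k) {
    b <- suppressWarnings(
      nonneg_elastic_net(X, y, l1, l2, max_iter = k, tol = 0))
    pg_objective(X, y, b, l1, l2)
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("increasing l1 never grows the coefficient l1-norm", {
  set.seed(85)
  X <- matrix(rnorm(400), 40, 10)
  y <- rbinom(40, 1, 0.5)
  norms <- vapply(c(0.001, 0.005, 0.02, 0.08, 0.3), function(l1) {
    sum(nonneg_elastic_net(X, y, l1, 0.01))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("region weights recover a planted embedding signal", {
  set.seed(86)
  atlas <- region_atlas(sprintf("R%02d", 1:10))
  n <- 40; f <- 3
  labels <- rep(c(0, 1), each = 20)
  emb <- matrix(rnorm(n * 10 * f), n)
  # plant signal in the embedding blocks of regions 3 and 7
  for (r in c(3, 7)) {
    cols <- (r - 1) * f + seq_len(f)
    emb[, cols] <- emb[, cols] + 2 * labels
  }
  tbl <- region_weights(emb, labels, atlas, top_k = 10)
  expect_true(all(c("R03", "R07") %in% tbl$name[1:5]))
  expect_true(all(diff(tbl$weight) <= 0))
  expect_identical(tbl$rank, seq_len(nrow(tbl)))
})

test_that("null embeddings give no dominant region", {
  set.seed(87)
  atlas <- region_atlas(sprintf("R%02d", 1:10))
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    emb <- matrix(rnorm(30 * 30), 30)
    labels <- rep(c(0, 1), 15)
    tbl <- suppressWarnings(
      region_weights(emb, labels, atlas, top_k = 10,
                     lambda_l1 = 0.05, lambda_l2 = 0.05))
    if (nrow(tbl) > 1 && tbl$weight[1] > 5 * stats::median(tbl$weight)) {
      hits <- hits + 1
    }
  }
  expect_lte(hits, 6)                           # no systematic dominance
})

test_that("all-zero coefficients yield an empty ranking with a warning", {
  atlas <- region_atlas(c("A", "B"))
  emb <- matrix(rnorm(20), 10, 2)
  labels <- rep(c(0, 1), 5)
  expect_warning(tbl <- region_weights(emb, labels, atlas, lambda_l1 = 10),
                 "zero")
  expect_equal(nrow(tbl), 0)
})

test_that("SAC ranks a planted fiber-count shift first at its magnitude", {
  co <- generate_cohort(synthetic_config(
    n_mci = 15, n_nmci = 15, n_regions = 12, n_timepoints = 20,
    structural_edges = rbind(c(2, 9)), delta_s = 25, seed = 88
  ))
  tbl <- sac_edges(co, "structural", top_k = 5)
  expect_equal(tbl$region_a[1], co$atlas$name[2])
  expect_equal(tbl$region_b[1], co$atlas$name[9])
  expect_equal(tbl$weight[1], 25, tolerance = 0.25 * 25)

  # symmetric under swapping group labels
  swapped <- cohort(co$atlas, lapply(co$subjects, function(s) {
    subject_record(s$subject_id, s$time_series, s$fiber_counts,
                   s$roi_volumes, s$demographics, 1L - s$label)
  }))
  expect_equal(sac_edges(swapped, "structural", top_k = 5)$weight,
               tbl$weight)
})

test_that("identical group means give all-zero SAC weights", {
  co <- tiny_cohort(seed = 89, n_mci = 3, n_nmci = 3)
  # give every subject the same fiber matrix
  D <- co$subjects[[1]]$fiber_counts
  same <- cohort(co$atlas, lapply(co$subjects, function(s) {
    subject_record(s$subject_id, s$time_series, D, s$roi_volumes,
                   s$demographics, s$label)
  }))
  expect_true(all(sac_edges(same, "structural")$weight == 0))
})

test_that("null SAC weights shrink with group size", {
  max_w <- vapply(c(20, 80), function(n) {
    mean(vapply(1:4, function(seed) {
      co <- generate_cohort(synthetic_config(
        n_mci = n / 2, n_nmci = n / 2, n_regions = 10, n_timepoints = 10,
        seed = 100 + seed
      ))
      max(sac_edges(co, "structural", top_k = 1)$weight)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max_w[2], max_w[1])
})

test_that("saliency reports mirror the published table layouts", {
  atlas <- synthetic_atlas(seed = 1)
  regions <- tibble::tibble(rank = 1:20, region_id = 1:20,
                            name = atlas$name[1:20],
                            weight = seq(2.0813, 0.26, length.out = 20))
  edges <- tibble::tibble(rank = 1:10, region_a = atlas$name[1:10],
                          region_b = atlas$name[11:20], weight = 91:82)
  dir <- withr::local_tempdir()
  paths <- report_saliency(regions, edges, atlas, dir)
  rtab <- read.csv(file.path(dir, "regions.csv"), check.names = FALSE)
  expect_equal(names(rtab), c("No", "Brain region", "Weight"))
  expect_equal(nrow(rtab), 20)
  expect_equal(rtab$Weight[1], 2.0813)
  etab <- read.csv(file.path(dir, "edges.csv"))
  expect_equal(nrow(etab), 10)
  expect_match(etab$Connection[1], "—")
  expect_true(file.exists(file.path(dir, "saliency.node")))

  empty <- report_saliency(regions[0, ], edges[0, ], atlas,
                           file.path(dir, "empty"))
  expect_equal(nrow(read.csv(file.path(dir, "empty", "regions.csv"))), 0)
})
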