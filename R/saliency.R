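#' Non-negative elastic net by cyclic coordinate descent
#'
#' Minimizes `(1/2n) ||y - X b||^2 + l1 ||b||_1 + (l2/2) ||b||^2` subject to
#' `b >= 0`, by cyclic coordinate descent with non-negative
#' soft-thresholding. Columns are standardized internally (and `y`
#' centered), so coefficients are comparable importance weights;
#' anti-correlated features are pinned at zero by the constraint.
#'
#' @param features Numeric n x p matrix.
#' @param labels Numeric response (0/1 group labels here).
#' @param lambda_l1,lambda_l2 Penalty weights (both >= 0).
#' @param max_iter Maximum coordinate sweeps.
#' @param tol Convergence: largest coefficient change in a sweep.
#' @return Numeric vector of p non-negative coefficients (standardized
#'   scale), with attribute `converged`.
#' @export
nonneg_elastic_net <- function(features, labels, lambda_l1 = 0.01,
                               lambda_l2 = 0.01, max_iter = 1000L,
                               tol = 1e-7) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  n <- nrow(X)
  if (n < 2 || length(y) != n) {
    stop("need >= 2 rows and matching labels", call. = FALSE)
  }
  stopifnot(lambda_l1 >= 0, lambda_l2 >= 0)
  sds <- apply(X, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  X <- scale(X, center = TRUE, scale = sds)
  y <- y - mean(y)
  p <- ncol(X)
  beta <- numeric(p)
  xss <- colSums(X^2) / n
  r <- y                                       # residual for beta = 0
  converged <- FALSE
  for (sweep_i in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xss[j] == 0) next
      rho <- sum(X[, j] * r) / n + beta[j] * xss[j]
      bj <- max(0, rho - lambda_l1) / (xss[j] + lambda_l2)
      if (bj != beta[j]) {
        r <- r - X[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("coordinate descent did not converge in ", max_iter,
            " sweeps (last max change ", format(delta), ")", call. = FALSE)
  }
  attr(beta, "converged") <- converged
  beta
}

# objective used by tests and the monotonicity property
elastic_net_objective <- function(X, y, beta, lambda_l1, lambda_l2) {
  n <- nrow(X)
  sum((y - X %*% beta)^2) / (2 * n) + lambda_l1 * sum(beta) +
    lambda_l2 / 2 * sum(beta^2)
}

#' Discriminative region weights from pre-classifier embeddings
#'
#' Regresses group labels on the per-subject fused embeddings with a
#' non-negative elastic net and sums the coefficient mass of each region's
#' embedding coordinates. Regions with zero total weight are dropped; the
#' remaining regions are ranked by weight.
#'
#' @param embeddings Subjects x (n regions * hidden) matrix, region-major
#'   (as returned by [model_embeddings()]).
#' @param labels 0/1 group labels.
#' @param atlas The region atlas.
#' @param top_k Rows to keep (default 20).
#' @param lambda_l1,lambda_l2,max_iter,tol Passed to
#'   [nonneg_elastic_net()].
#' @return Tibble with `rank`, `region_id`, `name`, `weight`, sorted by
#'   descending weight.
#' @export
region_weights <- function(embeddings, labels, atlas, top_k = 20,
                           lambda_l1 = 0.01, lambda_l2 = 0.01,
                           max_iter = 1000L, tol = 1e-7) {
  n <- n_regions(atlas)
  p <- ncol(embeddings)
  if (p %% n != 0) {
    stop("embedding width ", p, " is not a multiple of the region count ", n,
         call. = FALSE)
  }
  f <- p %/% n
  beta <- nonneg_elastic_net(embeddings, labels, lambda_l1, lambda_l2,
                             max_iter, tol)
  region <- rep(seq_len(n), each = f)
  w <- vapply(seq_len(n), function(i) sum(beta[region == i]), numeric(1))
  tbl <- tibble::tibble(region_id = seq_len(n), name = atlas$name, weight = w)
  tbl <- dplyr::filter(tbl, .data$weight > 0)
  if (nrow(tbl) == 0) {
    warning("all elastic-net coefficients are zero; empty region ranking",
            call. = FALSE)
    return(tibble::tibble(rank = integer(), region_id = integer(),
                          name = character(), weight = numeric()))
  }
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$weight))
  tbl <- utils::head(tbl, top_k)
  dplyr::mutate(tbl, rank = dplyr::row_number(), .before = 1)
}

#' Group-difference connectivity (SAC) edge ranking
#'
#' For every undirected region pair, the absolute difference between the
#' MCI and NMCI group means of the chosen channel's connectivity (raw fiber
#' counts by default, Pearson correlation for the functional channel).
#' Symmetric under swapping the group labels.
#'
#' @param x A labeled `brainfuse_cohort`.
#' @param channel `"structural"` (default) or `"functional"`.
#' @param top_k Edges to keep (default 10).
#' @return Tibble with `rank`, `region_a`, `region_b` (canonical order,
#'   a < b by region id), `weight`, sorted by descending weight.
#' @export
sac_edges <- function(x, channel = c("structural", "functional"),
                      top_k = 10) {
  channel <- match.arg(channel)
  stopifnot(inherits(x, "brainfuse_cohort"))
  labs <- cohort_labels(x)
  if (anyNA(labs) || !all(c(0, 1) %in% labs)) {
    stop("both groups must be present and labeled", call. = FALSE)
  }
  get_adj <- function(s) {
    if (channel == "structural") s$fiber_counts
    else functional_connectivity(s$time_series)
  }
  mean_adj <- function(group) {
    ms <- lapply(x$subjects[labs == group], get_adj)
    Reduce(`+`, ms) / length(ms)
  }
  diff <- abs(mean_adj(1) - mean_adj(0))
  n <- nrow(diff)
  ut <- which(upper.tri(diff), arr.ind = TRUE)
  tbl <- tibble::tibble(
    region_a = x$atlas$name[ut[, 1]], region_b = x$atlas$name[ut[, 2]],
    id_a = ut[, 1], id_b = ut[, 2], weight = diff[ut]
  )
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$weight), .data$id_a, .data$id_b)
  tbl <- utils::head(tbl, top_k)
  dplyr::mutate(tbl[, c("region_a", "region_b", "weight")],
                rank = dplyr::row_number(), .before = 1)
}

#' Write saliency tables and BrainNet Viewer files
#'
#' `regions.csv` mirrors the (No, Brain region, Weight) layout of published
#' region-saliency tables; `edges.csv` prints connections as
#' `RegionA—RegionB`. If the atlas carries MNI coordinates, matching
#' `saliency.node` / `saliency.edge` files are written too.
#'
#' @param regions Tibble from [region_weights()].
#' @param edges Tibble from [sac_edges()].
#' @param atlas The region atlas.
#' @param out_dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
report_saliency <- function(regions, edges, atlas, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rcsv <- file.path(out_dir, "regions.csv")
  ecsv <- file.path(out_dir, "edges.csv")
  rtab <- data.frame(No = regions$rank, Brain.region = regions$name,
                     Weight = round(regions$weight, 4), check.names = FALSE)
  names(rtab)[2] <- "Brain region"
  utils::write.csv(rtab, rcsv, row.names = FALSE, quote = FALSE)
  etab <- data.frame(NO = edges$rank,
                     Connection = if (nrow(edges))
                       paste0(edges$region_a, "—", edges$region_b)
                     else character(),
                     Weight = round(edges$weight, 4))
  utils::write.csv(etab, ecsv, row.names = FALSE, quote = FALSE)
  paths <- c(rcsv, ecsv)
  if (has_mni(atlas)) {
    bn <- write_brainnet_files(regions, edges, atlas,
                               file.path(out_dir, "saliency"))
    paths <- c(paths, unname(bn))
  }
  invisible(paths)
}
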