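#' Configuration of the synthetic multimodal cohort
#'
#' The generator emulates the data model of a steno-occlusive-disease MCI
#' study: regional BOLD series (n_regions x n_timepoints) from a
#' group-specific multivariate normal whose correlation follows a sparse
#' latent-factor block structure; symmetric Poisson fiber-count matrices on
#' a shared sparse backbone; log-normal regional gray-matter volumes; and
#' demographics sampled to mimic a typical baseline table (age ~ N(60, 8),
#' education ~ N(9, 4) truncated at 0, binary rates near the published
#' cohort proportions, no group differences by default).
#'
#' Group effects are planted in the MCI group only: a correlation shift
#' `delta_c` on `functional_edges`, a fiber-count mean shift `delta_s` on
#' `structural_edges` (placed off the shared backbone, so the edge exists
#' only in MCI — count shifts on an existing edge would be invisible to a
#' mask-based attention model), and a fractional volume reduction
#' `atrophy` in `atrophy_regions`.
#'
#' @param n_mci,n_nmci Group sizes (defaults 11 and 29).
#' @param n_regions,n_timepoints Block dimensions (defaults 90 and 240).
#' @param functional_edges 2-column matrix of region pairs for the
#'   correlation shift.
#' @param delta_c Correlation shift in (-0.8, 0.8).
#' @param structural_edges 2-column matrix of region pairs for the
#'   fiber-count shift.
#' @param delta_s Fiber-count mean shift (counts).
#' @param atrophy_regions Integer vector of region ids.
#' @param atrophy Fractional volume reduction in \[0, 1).
#' @param base_fiber_mean Mean fiber count on backbone edges.
#' @param fiber_density Fraction of region pairs on the backbone.
#' @param vol_sdlog Between-subject log-SD of regional volumes.
#' @param n_factors Latent factors behind the base correlation structure.
#' @param seed Integer seed.
#' @return List of class `brainfuse_synth_config`.
#' @export
synthetic_config <- function(n_mci = 11L, n_nmci = 29L, n_regions = 90L,
                             n_timepoints = 240L,
                             functional_edges = NULL, delta_c = 0,
                             structural_edges = NULL, delta_s = 0,
                             atrophy_regions = integer(), atrophy = 0,
                             base_fiber_mean = 40, fiber_density = 0.3,
                             vol_sdlog = 0.12, n_factors = 5L, seed = 1L) {
  as_pairs <- function(x) {
    if (is.null(x)) return(matrix(integer(), 0, 2))
    x <- matrix(as.integer(x), ncol = 2)
    if (any(x[, 1] == x[, 2]) || any(x < 1) || any(x > n_regions)) {
      stop("edge pairs must be distinct regions in 1..", n_regions,
           call. = FALSE)
    }
    cbind(pmin(x[, 1], x[, 2]), pmax(x[, 1], x[, 2]))
  }
  stopifnot(abs(delta_c) <= 0.8, atrophy >= 0, atrophy < 1,
            n_timepoints >= 3, n_regions >= 2)
  structure(list(
    n_mci = as.integer(n_mci), n_nmci = as.integer(n_nmci),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    functional_edges = as_pairs(functional_edges), delta_c = delta_c,
    structural_edges = as_pairs(structural_edges), delta_s = delta_s,
    atrophy_regions = as.integer(atrophy_regions), atrophy = atrophy,
    base_fiber_mean = base_fiber_mean, fiber_density = fiber_density,
    vol_sdlog = vol_sdlog, n_factors = as.integer(n_factors),
    seed = as.integer(seed)
  ), class = "brainfuse_synth_config")
}

#' @rdname synthetic_config
#' @param preset `"null"` (no group effects), `"weak"` (half-strength) or
#'   `"strong"` (delta_c 0.5 on 4 functional edges, delta_s 30 on 4
#'   structural edges, 15% atrophy in 4 regions).
#' @export
preset_config <- function(preset = c("null", "weak", "strong"), seed = 1L,
                          ...) {
  preset <- match.arg(preset)
  f_edges <- rbind(c(3, 7), c(10, 20), c(30, 40), c(50, 60))
  s_edges <- rbind(c(5, 9), c(15, 25), c(35, 45), c(55, 65))
  regions <- c(2, 12, 22, 32)
  args <- switch(preset,
    null = list(),
    weak = list(functional_edges = f_edges, delta_c = 0.25,
                structural_edges = s_edges, delta_s = 15,
                atrophy_regions = regions, atrophy = 0.075),
    strong = list(functional_edges = f_edges, delta_c = 0.5,
                  structural_edges = s_edges, delta_s = 30,
                  atrophy_regions = regions, atrophy = 0.15)
  )
  do.call(synthetic_config, c(args, list(seed = seed), list(...)))
}

#' Generate a synthetic multimodal cohort
#'
#' Deterministic given `config$seed`. NMCI subjects come first in the
#' cohort, then MCI.
#'
#' @param config A [synthetic_config()] or [preset_config()].
#' @param atlas Optional atlas; defaults to [aal90_atlas()] for 90 regions
#'   or an anonymous atlas otherwise.
#' @return A labeled `brainfuse_cohort`.
#' @export
generate_cohort <- function(config, atlas = NULL) {
  stopifnot(inherits(config, "brainfuse_synth_config"))
  n <- config$n_regions
  if (is.null(atlas)) {
    atlas <- if (n == 90) aal90_atlas()
             else region_atlas(sprintf("Region_%03d", seq_len(n)))
  }
  stopifnot(n_regions(atlas) == n)
  with_seed(config$seed, {
    base_cor <- factor_correlation(n, config$n_factors)
    cor_nmci <- base_cor
    cor_mci <- plant_correlation(base_cor, config$functional_edges,
                                 config$delta_c)
    chol_nmci <- chol(ensure_pd(cor_nmci))
    chol_mci <- chol(ensure_pd(cor_mci))
    # shared structural backbone; planted structural edges forced off it
    backbone <- matrix(stats::runif(n * n) < config$fiber_density, n, n)
    backbone[lower.tri(backbone, diag = TRUE)] <- FALSE
    if (nrow(config$structural_edges)) {
      backbone[config$structural_edges] <- FALSE
    }
    fiber_mean_nmci <- ifelse(backbone, config$base_fiber_mean, 0)
    fiber_mean_mci <- fiber_mean_nmci
    if (nrow(config$structural_edges)) {
      fiber_mean_mci[config$structural_edges] <-
        fiber_mean_mci[config$structural_edges] + config$delta_s
    }
    # per-region baseline volumes (mm^3), shared across subjects
    v0 <- exp(stats::rnorm(n, log(8000), 0.5))
    atrophy_mult <- rep(1, n)
    atrophy_mult[config$atrophy_regions] <- 1 - config$atrophy
    gen_subject <- function(id, label) {
      chol_g <- if (label == 1) chol_mci else chol_nmci
      X <- t(chol_g) %*% matrix(stats::rnorm(n * config$n_timepoints),
                                n, config$n_timepoints)
      mu <- if (label == 1) fiber_mean_mci else fiber_mean_nmci
      Du <- matrix(0, n, n)
      pos <- which(mu > 0)
      Du[pos] <- stats::rpois(length(pos), mu[pos])
      D <- Du + t(Du)
      vols <- v0 * exp(stats::rnorm(n, 0, config$vol_sdlog))
      if (label == 1) vols <- vols * atrophy_mult
      demo <- list(
        age = round(stats::rnorm(1, 60, 8), 1),
        sex = stats::rbinom(1, 1, 0.55),
        education_years = round(max(0, stats::rnorm(1, 9, 4)), 1),
        hypertension = stats::rbinom(1, 1, 0.80),
        diabetes = stats::rbinom(1, 1, 0.40),
        hyperlipidemia = stats::rbinom(1, 1, 0.50),
        smoker = stats::rbinom(1, 1, 0.20),
        drinker = stats::rbinom(1, 1, 0.225),
        stenosis_side_right = stats::rbinom(1, 1, 0.50)
      )
      subject_record(id, X, D, vols, demo, label)
    }
    subjects <- c(
      lapply(seq_len(config$n_nmci),
             function(i) gen_subject(sprintf("nmci%02d", i), 0L)),
      lapply(seq_len(config$n_mci),
             function(i) gen_subject(sprintf("mci%02d", i), 1L))
    )
    cohort(atlas, subjects)
  })
}

# Sparse latent-factor correlation: each region loads mainly on one of k
# factors, giving realistic positive block structure.
factor_correlation <- function(n, k) {
  block <- sample(rep_len(seq_len(k), n))
  L <- matrix(0, n, k)
  L[cbind(seq_len(n), block)] <- stats::runif(n, 0.5, 0.8)
  cross <- sample(seq_len(k), n, replace = TRUE)
  L[cbind(seq_len(n), cross)] <- L[cbind(seq_len(n), cross)] +
    stats::runif(n, 0, 0.2)
  S <- L %*% t(L)
  psi <- pmax(1 - diag(S), 0.15)
  stats::cov2cor(S + diag(psi))
}

plant_correlation <- function(base, edges, delta) {
  if (!nrow(edges) || delta == 0) return(base)
  out <- base
  target <- pmin(pmax(base[edges] + delta, -0.95), 0.95)
  out[edges] <- target
  out[edges[, c(2, 1), drop = FALSE]] <- target
  out
}

# Positive-definiteness guard. Planting correlations entrywise can push the
# target slightly indefinite; eigenvalue clipping (nearest-PSD projection,
# rescaled to unit diagonal) repairs it with far less distortion of the
# planted entries than uniform diagonal jitter. A small jitter floor is
# still added afterwards if clipping alone leaves the matrix numerically
# singular; an irreparable target is an error.
ensure_pd <- function(S, floor_ev = 1e-6) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) > 1e-10) return(S)
  message("correlation target indefinite (min eigenvalue ",
          signif(min(ev$values), 3), "); clipping spectrum")
  vals <- pmax(ev$values, floor_ev)
  S2 <- stats::cov2cor(ev$vectors %*% (vals * t(ev$vectors)))
  S2 <- (S2 + t(S2)) / 2
  if (min(eigen(S2, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    S2 <- stats::cov2cor(S2 + diag(1e-6, nrow(S2)))
  }
  if (min(eigen(S2, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("correlation target not positive definite after spectral repair; ",
         "reduce the planted correlation shift", call. = FALSE)
  }
  S2
}
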