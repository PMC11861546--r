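#' Fit the demographic / volume encoding on a training set
#'
#' Continuous variables (age, education years) are z-scored with mean/sd
#' estimated on the training subjects only; binary variables pass through as
#' 0/1. Regional gray-matter volumes are likewise z-scored per region with
#' training-set statistics so they live on the same scale as the encoded
#' demographics they are summed with. Fitting on training folds only keeps
#' cross-validation leakage-free.
#'
#' @param x A `brainfuse_cohort`.
#' @param idx Integer indices of the training subjects (default: all).
#' @return An encoding object (class `brainfuse_encoding`).
#' @export
fit_encoding <- function(x, idx = seq_along(x$subjects)) {
  stopifnot(inherits(x, "brainfuse_cohort"))
  demo <- cohort_demographics(x)[idx, ]
  sd0 <- function(v) { s <- stats::sd(v); if (!is.finite(s) || s == 0) 1 else s }
  vols <- vapply(x$subjects[idx], function(s) s$roi_volumes,
                 numeric(n_regions(x$atlas)))
  vol_sd <- apply(vols, 1, sd0)
  structure(
    list(
      age_mean = mean(demo$age), age_sd = sd0(demo$age),
      edu_mean = mean(demo$education_years), edu_sd = sd0(demo$education_years),
      vol_mean = rowMeans(vols), vol_sd = vol_sd
    ),
    class = "brainfuse_encoding"
  )
}

#' Encode one subject's demographics as the model's 9-vector
#'
#' @param raw Named list with the fields of [demographic_fields()].
#' @param enc A `brainfuse_encoding` from [fit_encoding()].
#' @return Numeric vector of length 9 in canonical field order.
#' @export
encode_demographics <- function(raw, enc) {
  stopifnot(inherits(enc, "brainfuse_encoding"))
  raw <- as.list(raw)
  missing <- setdiff(demographic_fields(), names(raw))
  if (length(missing)) {
    stop("missing demographic field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bin <- function(field) {
    v <- raw[[field]]
    if (is.logical(v)) v <- as.integer(v)
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v) || !v %in% c(0, 1)) {
      stop("demographic field '", field, "' must be binary 0/1", call. = FALSE)
    }
    v
  }
  out <- c(
    age = (as.numeric(raw$age) - enc$age_mean) / enc$age_sd,
    sex = bin("sex"),
    education_years = (as.numeric(raw$education_years) - enc$edu_mean) / enc$edu_sd,
    hypertension = bin("hypertension"),
    diabetes = bin("diabetes"),
    hyperlipidemia = bin("hyperlipidemia"),
    smoker = bin("smoker"),
    drinker = bin("drinker"),
    stenosis_side_right = bin("stenosis_side_right")
  )
  unname(out)
}

encode_volumes <- function(vols, enc) {
  (vols - enc$vol_mean) / enc$vol_sd
}

#' Context-encoder parameters
#'
#' The learnable parameters of the two linear maps that project the
#' demographic 9-vector onto the regions and mix it with the (encoded)
#' regional volumes: `E' = w1 E + b1`, `F = E' + T`, `R = w2 F + b2`.
#'
#' @param n Number of regions.
#' @param p Number of demographic variables (9).
#' @param init `"zero"` or `"glorot"` (uniform Glorot; draws from the
#'   current RNG stream).
#' @return List with `w1` (n x p), `b1` (n), `w2` (n x n), `b2` (n).
#' @export
context_params <- function(n, p = 9L, init = c("glorot", "zero")) {
  init <- match.arg(init)
  list(w1 = init_mat(n, p, init), b1 = init_vec(n, p, init),
       w2 = init_mat(n, n, init), b2 = init_vec(n, n, init))
}

init_mat <- function(nout, nin, init) {
  if (init == "zero") return(matrix(0, nout, nin))
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

# biases drawn uniform within 1/sqrt(fan_in), as torch's linear layers do;
# a zero bias vector leaves degenerate inputs (e.g. ablated modalities) on
# an exact saddle of the full-batch loss
init_vec <- function(nout, nin, init) {
  if (init == "zero") return(numeric(nout))
  lim <- 1 / sqrt(nin)
  stats::runif(nout, -lim, lim)
}

#' Project demographic and volumetric context onto the regions
#'
#' Computes `R = w2 (w1 E + b1 + T) + b2`, the per-region context score that
#' becomes the node feature of both brain-network channels. Linear in `E`
#' and `T` for fixed parameters.
#'
#' @param E Encoded demographic vector (length p).
#' @param T_vec Encoded regional volume vector (length n).
#' @param params From [context_params()].
#' @return Numeric vector `R` of length n.
#' @export
project_context <- function(E, T_vec, params) {
  if (length(E) != ncol(params$w1) || length(T_vec) != nrow(params$w1)) {
    stop("dimension mismatch: E has length ", length(E), ", T has length ",
         length(T_vec), ", w1 is ", nrow(params$w1), " x ", ncol(params$w1),
         call. = FALSE)
  }
  Fv <- drop(params$w1 %*% E) + params$b1 + T_vec
  drop(params$w2 %*% Fv) + params$b2
}

#' Pearson functional connectivity
#'
#' Correlation of every pair of regional BOLD time series,
#' `c_ij = Cov(x_i, x_j) / (sd(x_i) sd(x_j))`.
#'
#' @param X Numeric n x m matrix, one row per region, m >= 3 time points.
#' @return Symmetric n x n matrix with unit diagonal, entries in \[-1, 1\].
#' @export
functional_connectivity <- function(X) {
  X <- as.matrix(X)
  v <- apply(X, 1, stats::var)
  if (any(v == 0)) {
    stop("constant BOLD signal (zero variance) in region(s) ",
         paste(which(v == 0), collapse = ", "), call. = FALSE)
  }
  C <- stats::cor(t(X))
  diag(C) <- 1
  unname(C)
}

#' Build the functional and structural networks for one subject
#'
#' The functional channel pairs the shared node features with the Pearson
#' connectivity matrix `C`; the structural channel pairs them with the raw
#' fiber-count matrix `D`. Attention masking downstream keeps an edge only
#' where the adjacency entry is strictly positive, so `D`'s magnitudes (and
#' `C`'s, beyond sign) affect the model only through that support.
#'
#' Node-feature modes resolve how a length-n context vector `R` becomes an
#' n x n node-feature matrix: `diag` (node i's feature is `R[i]` on its own
#' one-hot axis; the default), `broadcast` (every node gets the full `R`),
#' `conn_row` (node i gets `R` weighted elementwise by row i of `C`).
#'
#' @param subject A `brainfuse_subject`.
#' @param params [context_params()] for the atlas size.
#' @param enc A `brainfuse_encoding`.
#' @param mode Node-feature mode.
#' @return List with elements `functional` and `structural`, each a
#'   `brainfuse_network` (fields `channel`, `node_features`, `adjacency`,
#'   `mask`), plus the shared context vector `R`.
#' @export
build_networks <- function(subject, params, enc,
                           mode = c("diag", "broadcast", "conn_row")) {
  mode <- match.arg(mode)
  stopifnot(inherits(subject, "brainfuse_subject"))
  C <- functional_connectivity(subject$time_series)
  D <- subject$fiber_counts
  E <- encode_demographics(subject$demographics, enc)
  Tv <- encode_volumes(subject$roi_volumes, enc)
  R <- project_context(E, Tv, params)
  H0 <- node_features_from_context(R, C, mode)
  mk <- function(channel, adjacency) {
    structure(list(channel = channel, node_features = H0,
                   adjacency = adjacency, mask = adjacency > 0),
              class = "brainfuse_network")
  }
  list(functional = mk("functional", C), structural = mk("structural", D),
       R = R, E = E, T_enc = Tv)
}

node_features_from_context <- function(R, C, mode) {
  n <- length(R)
  switch(mode,
    diag = diag(R, n),
    broadcast = matrix(R, n, n, byrow = TRUE),
    conn_row = sweep(C, 2, R, `*`)
  )
}
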