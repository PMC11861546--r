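#' Region atlases
#'
#' A region atlas is a tibble with one row per brain region: a contiguous
#' 1-based `region_id`, a unique `name`, and optional MNI centroid
#' coordinates `mni_x`, `mni_y`, `mni_z` (millimetres) used only for
#' BrainNet Viewer exports. Region indexing is 1-based in all files and
#' messages; internal matrix code uses ordinary R indexing.
#'
#' @param names Character vector of unique region names.
#' @param mni Optional numeric matrix (length(names) x 3) of MNI centroids.
#' @return A tibble of class `brainfuse_atlas` with columns `region_id`,
#'   `name`, `mni_x`, `mni_y`, `mni_z`.
#' @examples
#' region_atlas(c("Precentral_L", "Precentral_R"))
#' @export
region_atlas <- function(names, mni = NULL) {
  names <- as.character(names)
  if (length(names) < 2) stop("an atlas needs at least 2 regions", call. = FALSE)
  if (anyDuplicated(names)) {
    stop("region names must be unique; duplicated: ",
         paste(unique(names[duplicated(names)]), collapse = ", "), call. = FALSE)
  }
  n <- length(names)
  if (is.null(mni)) {
    mni <- matrix(NA_real_, n, 3)
  } else {
    mni <- as.matrix(mni)
    if (!all(dim(mni) == c(n, 3))) {
      stop("mni must be a ", n, " x 3 matrix", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    region_id = seq_len(n), name = names,
    mni_x = mni[, 1], mni_y = mni[, 2], mni_z = mni[, 3]
  )
  class(out) <- c("brainfuse_atlas", class(out))
  out
}

#' @rdname region_atlas
#' @details `aal90_atlas()` returns the 90 cerebral regions of the AAL
#'   parcellation (cerebellar regions 91-116 excluded), in the standard
#'   odd-left / even-right order. Coordinates are left `NA`; attach your own
#'   centroids if you need brain-map export.
#' @export
aal90_atlas <- function() {
  region_atlas(aal90_names())
}

#' @rdname region_atlas
#' @param seed Integer seed for the synthetic coordinates.
#' @details `synthetic_atlas()` is `aal90_atlas()` plus *synthetic* MNI-like
#'   coordinates (mirrored left/right, drawn once from a fixed seed). They
#'   are placeholders for exercising `.node`/`.edge` export, not anatomical
#'   locations.
#' @export
synthetic_atlas <- function(seed = 1L) {
  nm <- aal90_names()
  with_seed(seed, {
    half <- length(nm) / 2
    base <- cbind(stats::runif(half, 10, 60), stats::runif(half, -90, 60),
                  stats::runif(half, -40, 70))
    xyz <- matrix(0, length(nm), 3)
    xyz[seq(1, length(nm), 2), ] <- cbind(-base[, 1], base[, 2:3]) # _L
    xyz[seq(2, length(nm), 2), ] <- base                           # _R
    region_atlas(nm, round(xyz, 1))
  })
}

# Standard AAL labels for the 90 cerebral regions, odd = left, even = right.
aal90_names <- function() {
  stems <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(rbind(paste0(stems, "_L"), paste0(stems, "_R")))
}

#' @export
print.brainfuse_atlas <- function(x, ...) {
  cat("<brainfuse_atlas> ", nrow(x), " regions",
      if (all(is.na(x$mni_x))) " (no MNI coordinates)" else "", "\n", sep = "")
  NextMethod()
}

n_regions <- function(atlas) nrow(atlas)

has_mni <- function(atlas) !anyNA(atlas[, c("mni_x", "mni_y", "mni_z")])

# Evaluate `code` under a temporary RNG state seeded from `seed`, restoring
# the caller's RNG stream afterwards. All stochastic entry points route their
# seed through this, so results are deterministic-given-seed without
# clobbering the user's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
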