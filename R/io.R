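#' Read a numeric matrix from a TSV/CSV file
#'
#' Matrix files carry no header row. The delimiter is autodetected from the
#' first line (tab preferred, comma otherwise).
#'
#' @param path File path.
#' @param expected_shape Optional integer pair `c(rows, cols)`; a mismatch
#'   is an error naming the file and both shapes.
#' @return A numeric matrix.
#' @export
read_matrix <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow(raw), ncol(raw)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in ", path, " at row ", bad[1], ", column ", bad[2],
         " (value '", as.matrix(raw)[bad[1], bad[2]], "')", call. = FALSE)
  }
  if (!is.null(expected_shape) && !all(dim(m) == expected_shape)) {
    stop("dimension mismatch in ", path, ": got ", nrow(m), " x ", ncol(m),
         ", expected ", expected_shape[1], " x ", expected_shape[2],
         call. = FALSE)
  }
  m
}

#' @rdname read_matrix
#' @param x Numeric matrix to write.
#' @param sep Field separator, tab by default.
#' @export
write_matrix <- function(x, path, sep = "\t") {
  x <- as.matrix(x)
  writeLines(apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep)),
             path)
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
}

#' Load a cohort from a manifest
#'
#' The manifest is a headered CSV with columns `subject_id`, `label`
#' (0/1/empty) and relative paths `time_series`, `fiber_counts`,
#' `roi_volumes`; a `demographics.csv` (headered, keyed by `subject_id`,
#' one column per field of [demographic_fields()]) must sit next to it.
#' Subject order in the returned cohort equals manifest order.
#'
#' @param manifest Path to the manifest CSV.
#' @param atlas A [region_atlas()]; defaults to [aal90_atlas()].
#' @return A `brainfuse_cohort`.
#' @export
read_cohort <- function(manifest, atlas = aal90_atlas()) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  dir <- dirname(manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("subject_id", "label", "time_series", "fiber_counts", "roi_volumes")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  demo_path <- file.path(dir, "demographics.csv")
  if (!file.exists(demo_path)) {
    stop("demographics.csv not found next to manifest at ", demo_path,
         call. = FALSE)
  }
  demo <- utils::read.csv(demo_path, stringsAsFactors = FALSE)
  n <- n_regions(atlas)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    id <- row$subject_id
    for (block in c("time_series", "fiber_counts", "roi_volumes")) {
      p <- row[[block]]
      if (is.na(p) || !nzchar(p) || !file.exists(file.path(dir, p))) {
        stop("subject ", id, ": missing ", block, " file",
             if (!is.na(p) && nzchar(p)) paste0(" at ", file.path(dir, p)),
             call. = FALSE)
      }
    }
    lab <- row$label
    lab <- if (is.na(lab) || !nzchar(lab)) NA_integer_ else {
      if (!lab %in% c("0", "1")) {
        stop("subject ", id, ": label must be 0, 1 or empty, got '", lab, "'",
             call. = FALSE)
      }
      as.integer(lab)
    }
    d <- demo[demo$subject_id == id, , drop = FALSE]
    if (nrow(d) != 1) {
      stop("subject ", id, ": expected exactly one demographics row, found ",
           nrow(d), call. = FALSE)
    }
    ts <- read_matrix(file.path(dir, row$time_series))
    if (nrow(ts) != n) {
      stop("subject ", id, ": time series has ", nrow(ts),
           " regions, atlas has ", n, call. = FALSE)
    }
    subject_record(
      subject_id = id,
      time_series = ts,
      fiber_counts = read_matrix(file.path(dir, row$fiber_counts),
                                 expected_shape = c(n, n)),
      roi_volumes = drop(read_matrix(file.path(dir, row$roi_volumes),
                                     expected_shape = c(n, 1))),
      demographics = as.list(d[demographic_fields()]),
      label = lab
    )
  })
  cohort(atlas, subjects)
}

#' Write a cohort to a directory readable by [read_cohort()]
#'
#' Writes per-subject `*_ts.tsv`, `*_fibers.tsv`, `*_volumes.tsv`, a
#' `demographics.csv` and a `manifest.csv`.
#'
#' @param x A `brainfuse_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(x, out_dir) {
  stopifnot(inherits(x, "brainfuse_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(x$subjects, function(s) {
    id <- s$subject_id
    ts <- paste0(id, "_ts.tsv")
    fb <- paste0(id, "_fibers.tsv")
    vol <- paste0(id, "_volumes.tsv")
    write_matrix(s$time_series, file.path(out_dir, ts))
    write_matrix(s$fiber_counts, file.path(out_dir, fb))
    write_matrix(matrix(s$roi_volumes, ncol = 1), file.path(out_dir, vol))
    tibble::tibble(subject_id = id,
                   label = if (is.na(s$label)) "" else as.character(s$label),
                   time_series = ts, fiber_counts = fb, roi_volumes = vol)
  })
  demo <- cohort_demographics(x)[, c("subject_id", demographic_fields())]
  utils::write.csv(demo, file.path(out_dir, "demographics.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(rows, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Export saliency tables as BrainNet Viewer node/edge files
#'
#' Writes `<prefix>.node` (one row per atlas region: `x y z color size
#' label`, whitespace-separated; regions outside the table get color 1 and
#' size 0) and `<prefix>.edge` (full N x N symmetric weighted adjacency,
#' zero off the selected edges).
#'
#' @param regions Tibble with columns `name` and `weight` (e.g. from
#'   [region_weights()]); may have zero rows.
#' @param edges Tibble with columns `region_a`, `region_b`, `weight`; may
#'   have zero rows.
#' @param atlas Atlas with MNI coordinates.
#' @param prefix Output path prefix.
#' @return Character vector `c(node, edge)` of the two paths, invisibly.
#' @export
write_brainnet_files <- function(regions, edges, atlas, prefix) {
  stopifnot(inherits(atlas, "brainfuse_atlas"))
  if (!has_mni(atlas)) {
    stop("atlas has no MNI coordinates; supply an atlas with mni_x/mni_y/",
         "mni_z to export brain maps", call. = FALSE)
  }
  n <- n_regions(atlas)
  size <- stats::setNames(rep(0, n), atlas$name)
  color <- rep(1, n)
  if (nrow(regions)) {
    idx <- match(regions$name, atlas$name)
    if (anyNA(idx)) {
      stop("region name(s) not in atlas: ",
           paste(regions$name[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    size[idx] <- regions$weight
    color[idx] <- 2
  }
  node_path <- paste0(prefix, ".node")
  node <- data.frame(atlas$mni_x, atlas$mni_y, atlas$mni_z, color,
                     unname(size), atlas$name)
  utils::write.table(node, node_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  adj <- matrix(0, n, n)
  if (nrow(edges)) {
    ia <- match(edges$region_a, atlas$name)
    ib <- match(edges$region_b, atlas$name)
    if (anyNA(ia) || anyNA(ib)) {
      stop("edge region name(s) not in atlas", call. = FALSE)
    }
    adj[cbind(ia, ib)] <- edges$weight
    adj[cbind(ib, ia)] <- edges$weight
  }
  edge_path <- paste0(prefix, ".edge")
  write_matrix(adj, edge_path)
  invisible(c(node = node_path, edge = edge_path))
}
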