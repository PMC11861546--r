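#' Grid search over learning rate and stack depth
#'
#' Exhaustive cross-validated accuracy for every grid point; ties are
#' broken toward smaller depth, then smaller learning rate.
#'
#' @param x A labeled `brainfuse_cohort`.
#' @param lr_grid Numeric vector of learning rates (the published searched
#'   range is 1e-6 .. 10).
#' @param depth_grid Integer vector of stack depths (searched range 1..5).
#' @param config Base [run_config()]; `learning_rate` and `gat_layers` are
#'   overridden per grid point.
#' @return List with `best_lr`, `best_depth` and `table` (tibble of
#'   `learning_rate`, `gat_layers`, `acc`, `auc`).
#' @export
grid_search <- function(x, lr_grid, depth_grid, config = run_config()) {
  stopifnot(length(lr_grid) >= 1, length(depth_grid) >= 1)
  grid <- expand.grid(learning_rate = sort(lr_grid),
                      gat_layers = sort(depth_grid))
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$learning_rate <- grid$learning_rate[i]
    cfg$gat_layers <- as.integer(grid$gat_layers[i])
    cv <- cross_validate(x, cfg)
    tibble::tibble(learning_rate = cfg$learning_rate,
                   gat_layers = cfg$gat_layers,
                   acc = cv$mean$acc, auc = cv$mean$auc)
  })
  ord <- order(-rows$acc, rows$gat_layers, rows$learning_rate)
  best <- rows[ord[1], ]
  list(best_lr = best$learning_rate, best_depth = best$gat_layers,
       table = rows)
}

#' Run the full multimodal experiment
#'
#' Wires every stage together: obtain a cohort (synthetic preset or an
#' on-disk manifest), cross-validate the fusion model, compute the
#' baseline-table group statistics, rank discriminative regions
#' (non-negative elastic net on pooled out-of-fold embeddings) and edges
#' (group-difference connectivity), embed the out-of-fold representations
#' in 2-D, and write everything under `out_dir`. One seed (in `config`)
#' governs the whole run, so reports are bit-identical across re-runs.
#'
#' @param config A [run_config()].
#' @param preset Synthetic preset name (see [preset_config()]), ignored
#'   when `cohort` is given.
#' @param cohort A `brainfuse_cohort` or a manifest path.
#' @param out_dir Output directory; `NULL` skips all file output.
#' @param ablation Optional ablation passed through to training; see
#'   [train_model()].
#' @param top_regions,top_edges Saliency table sizes.
#' @return An `ExperimentReport`-style list (class
#'   `brainfuse_experiment`): `config`, `cv`, `stats`, `regions`, `edges`,
#'   `embedding`, `files`.
#' @export
run_experiment <- function(config = run_config(), preset = "strong",
                           cohort = NULL, out_dir = NULL, ablation = NULL,
                           top_regions = 20, top_edges = 10) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(preset_config(preset, seed = config$seed))
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  stopifnot(inherits(cohort, "brainfuse_cohort"))
  cv <- cross_validate(cohort, config, ablation = ablation)
  stats <- cohort_summary(cohort)
  regions <- region_weights(cv$embeddings, cv$predictions$label,
                            cohort$atlas, top_k = top_regions)
  edges <- sac_edges(cohort, "structural", top_k = top_edges)
  emb <- embed_2d(cv$embeddings, seed = config$seed,
                  perplexity = min(10, floor(nrow(cv$embeddings) / 3)))
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_experiment(out_dir, config, cv, stats, regions, edges,
                              emb, cohort)
  }
  structure(list(config = config, cv = cv, stats = stats, regions = regions,
                 edges = edges, embedding = emb, files = files),
            class = "brainfuse_experiment")
}

write_experiment <- function(out_dir, config, cv, stats, regions, edges,
                             emb, cohort) {
  fp <- function(x) file.path(out_dir, x)
  utils::write.csv(cv$roc, fp("roc_points.csv"), row.names = FALSE)
  utils::write.csv(cv$predictions, fp("per_subject_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(stats, fp("group_statistics.csv"), row.names = FALSE)
  tsne <- data.frame(subject_id = cv$predictions$subject_id,
                     label = cv$predictions$label,
                     dim1 = emb[, 1], dim2 = emb[, 2])
  utils::write.csv(tsne, fp("tsne.csv"), row.names = FALSE)
  sal <- report_saliency(regions, edges, cohort$atlas, out_dir)
  report <- list(
    config = unclass(config),
    cv = list(folds = cv$folds, mean = cv$mean, pooled_auc = cv$pooled_auc),
    group_statistics = stats,
    top_regions = regions,
    top_edges = edges,
    files = basename(c(fp("roc_points.csv"), fp("per_subject_predictions.csv"),
                       fp("group_statistics.csv"), fp("tsne.csv"), sal))
  )
  jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(fp("report.json"), fp("roc_points.csv"), fp("per_subject_predictions.csv"),
    fp("group_statistics.csv"), fp("tsne.csv"), sal)
}

#' @export
print.brainfuse_experiment <- function(x, ...) {
  cat("<brainfuse_experiment>\n")
  print(x$cv)
  cat("  top region: ", if (nrow(x$regions)) x$regions$name[1] else "(none)",
      "; top edge: ",
      if (nrow(x$edges)) paste0(x$edges$region_a[1], "—", x$edges$region_b[1])
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Training-loss trace plot
#' @param model A trained `brainfuse_model`.
#' @return A ggplot.
#' @export
plot_loss <- function(model) {
  df <- tibble::tibble(epoch = seq_along(model$loss_trace),
                       loss = model$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Mean cross-entropy") +
    ggplot2::theme_minimal()
}

#' Region-saliency bar chart
#' @param regions Tibble from [region_weights()].
#' @return A ggplot.
#' @export
plot_saliency <- function(regions) {
  ggplot2::ggplot(regions,
                  ggplot2::aes(x = stats::reorder(.data$name, .data$weight),
                               y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Elastic-net weight") +
    ggplot2::theme_minimal()
}

#' 2-D embedding scatter plot
#' @param emb n x 2 matrix from [embed_2d()].
#' @param labels 0/1 group labels.
#' @return A ggplot.
#' @export
plot_embedding <- function(emb, labels) {
  df <- tibble::tibble(dim1 = emb[, 1], dim2 = emb[, 2],
                       group = factor(labels, 0:1, c("NMCI", "MCI")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
    ggplot2::theme_minimal()
}
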