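#' Stratified k-fold assignment
#'
#' Splits subjects into k mutually exclusive folds with per-fold class
#' counts within one of perfect stratification and total fold sizes as
#' equal as possible. Deterministic given `seed`.
#'
#' @param labels Integer vector of 0/1 class labels.
#' @param k Number of folds (2 <= k <= length(labels)).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in 1..k, one per subject.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")",
                  call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  with_seed(seed, {
    fold_perm <- sample.int(k)
    assign <- integer(n)
    classes <- sort(unique(labels))
    for (ci in seq_along(classes)) {
      idx <- sample(which(labels == classes[ci]))
      nc <- length(idx)
      base <- nc %/% k
      rem <- nc %% k
      counts <- rep(base, k)
      if (rem > 0) {
        # hand remainders to opposite ends of a shared fold permutation so
        # the two classes' extras land on different folds where possible
        extras <- if (ci %% 2 == 1) fold_perm[seq_len(rem)]
                  else fold_perm[k + 1 - seq_len(rem)]
        counts[extras] <- counts[extras] + 1
      }
      assign[idx] <- rep(seq_len(k), counts)
    }
    assign
  })
}

#' Confusion-matrix metric panel
#'
#' Thresholds probabilities at `threshold` (ties to positive) and reports
#' the standard panel as percentages: accuracy, precision, recall,
#' F-measure, sensitivity and specificity. Recall equals sensitivity by
#' definition with MCI as the positive class; both are reported because the
#' field's result tables list both. Degenerate conventions: with zero
#' predicted positives precision is 0, and F1 is 0 whenever
#' precision + recall is 0.
#'
#' @param y_true 0/1 labels.
#' @param y_prob Probabilities of the positive class.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble with `acc`, `pre`, `rec`, `f1`, `sen`, `spe`
#'   (percent).
#' @export
confusion_metrics <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop("labels and probabilities differ in length", call. = FALSE)
  }
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  div <- function(a, b) if (b == 0) 0 else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(
    acc = 100 * (tp + tn) / length(y_true),
    pre = 100 * precision,
    rec = 100 * recall,
    f1 = 100 * f1,
    sen = 100 * recall,
    spe = 100 * div(tn, tn + fp)
  )
}

#' ROC curve and AUC
#'
#' AUC is the normalized Mann-Whitney U statistic (tied scores count 1/2),
#' which equals the trapezoidal area under the tie-grouped ROC curve.
#'
#' @param y_true 0/1 labels (both classes required).
#' @param y_prob Scores for the positive class.
#' @return List with `roc` (tibble of `threshold`, `fpr`, `tpr`, monotone
#'   nondecreasing) and `auc` (fraction in \[0, 1\]).
#' @export
roc_auc <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes are required for ROC analysis", call. = FALSE)
  }
  r <- rank(y_prob)                            # midranks handle ties
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(y_prob), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(threshold = t,
                   fpr = sum(y_prob >= t & y_true == 0) / n0,
                   tpr = sum(y_prob >= t & y_true == 1) / n1)
  })
  roc <- dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0), pts)
  list(roc = roc, auc = auc)
}

#' Stratified cross-validated evaluation of the fusion model
#'
#' Trains one model per fold from scratch on the training folds (the
#' demographic/volume encoding is refit on the training subjects of each
#' fold, so no test statistics leak) and evaluates on the held-out fold.
#'
#' @param x A labeled `brainfuse_cohort`.
#' @param config A [run_config()] (`folds`, `seed` and all model knobs).
#' @param ablation Optional ablation spec passed to [train_model()].
#' @return Object of class `brainfuse_cv`: `$folds` (per-fold metric
#'   panel), `$mean` (arithmetic mean of the fold panels), `$roc` (pooled
#'   out-of-fold ROC points), `$pooled_auc`, `$predictions` (per-subject
#'   out-of-fold probabilities) and `$embeddings` (pooled out-of-fold
#'   pre-classifier embeddings, rows aligned with `$predictions` — the
#'   leakage-free input for saliency and 2-D embedding analyses).
#' @export
cross_validate <- function(x, config = run_config(), ablation = NULL) {
  stopifnot(inherits(x, "brainfuse_cohort"))
  labs <- cohort_labels(x)
  if (anyNA(labs)) stop("cross-validation needs a fully labeled cohort",
                        call. = FALSE)
  fold <- stratified_kfold(labs, config$folds, config$seed)
  preds <- vector("list", config$folds)
  panels <- vector("list", config$folds)
  embeds <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(labs[tr])) < 2) {
      stop("training split for fold ", f, " is single-class", call. = FALSE)
    }
    train <- cohort(x$atlas, x$subjects[tr])
    enc <- fit_encoding(train)
    cfg <- config
    cfg$seed <- config$seed + f               # fresh init per fold
    model <- train_model(train, cfg, encoding = enc, ablation = ablation)
    test <- cohort_subset(x, te)
    p <- predict(model, test)
    p$fold <- f
    p$label <- labs[te]
    preds[[f]] <- p
    embeds[[f]] <- model_embeddings(model, test)
    panel <- confusion_metrics(p$label, p$prob_mci)
    panel$auc <- if (length(unique(p$label)) == 2) {
      roc_auc(p$label, p$prob_mci)$auc
    } else NA_real_
    panel$fold <- f
    panels[[f]] <- panel
  }
  folds_tbl <- dplyr::bind_rows(panels)[, c("fold", "acc", "pre", "rec",
                                            "f1", "sen", "spe", "auc")]
  mean_tbl <- dplyr::summarise(folds_tbl,
                               dplyr::across(-"fold", ~mean(.x, na.rm = TRUE)))
  pred_tbl <- dplyr::bind_rows(preds)
  pooled <- roc_auc(pred_tbl$label, pred_tbl$prob_mci)
  structure(list(folds = folds_tbl, mean = mean_tbl, roc = pooled$roc,
                 pooled_auc = pooled$auc, predictions = pred_tbl,
                 embeddings = do.call(rbind, embeds), config = config),
            class = "brainfuse_cv")
}

# subset preserving cohort class without the >=2-per-class check (test
# folds may be small)
cohort_subset <- function(x, idx) {
  structure(list(atlas = x$atlas, subjects = x$subjects[idx]),
            class = "brainfuse_cohort")
}

#' @export
print.brainfuse_cv <- function(x, ...) {
  m <- x$mean
  cat("<brainfuse_cv> ", nrow(x$folds), "-fold cross-validation\n",
      sprintf("  mean ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  F1 %.2f%%  AUC %.4f (pooled %.4f)\n",
              m$acc, m$sen, m$spe, m$f1, m$auc, x$pooled_auc), sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold metrics of a cross-validation run
#' @param x A `brainfuse_cv`.
#' @param ... Unused.
#' @return Tibble, one row per fold.
#' @export
tidy.brainfuse_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation run
#' @param x A `brainfuse_cv`.
#' @param ... Unused.
#' @return One-row tibble: mean panel plus pooled AUC.
#' @export
glance.brainfuse_cv <- function(x, ...) {
  dplyr::mutate(x$mean, pooled_auc = x$pooled_auc)
}

#' ROC curve of pooled out-of-fold predictions
#' @param object A `brainfuse_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.brainfuse_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("Pooled ROC (AUC = %.4f)", object$pooled_auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
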