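#' Two-group comparison of one cohort variable
#'
#' Reproduces standard statistical-package reporting for a two-group
#' baseline table. Binary variables: a 2x2 chi-square statistic — Pearson
#' `sum((O-E)^2/E)` when every expected count is at least 5, otherwise the
#' Yates-corrected `sum(max(|O-E|-0.5, 0)^2/E)` (floored at zero) — with a
#' two-sided p-value from Fisher's exact test. Continuous variables: Welch
#' (unequal-variance) t test when both groups look normal (Shapiro-Wilk
#' p > 0.05), otherwise a Mann-Whitney U test reported as a tie-corrected
#' normal-approximation Z.
#'
#' @param values Per-subject values (binary 0/1 or continuous).
#' @param labels Per-subject group labels (two groups).
#' @param variable Variable name carried into the output.
#' @param test `"auto"` applies the rule above; or force one of
#'   `"chi2_fisher"`, `"t_welch"`, `"mann_whitney"`.
#' @return One-row tibble: `variable`, `test` (one of `chi2_pearson`,
#'   `chi2_yates`, `t_welch`, `mann_whitney`), `statistic`, `p_value`.
#' @export
group_compare <- function(values, labels, variable = "x",
                          test = c("auto", "chi2_fisher", "t_welch",
                                   "mann_whitney")) {
  test <- match.arg(test)
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  v1 <- values[labels == groups[1]]
  v2 <- values[labels == groups[2]]
  is_binary <- all(values %in% c(0, 1))
  if (test == "auto") {
    test <- if (is_binary) "chi2_fisher" else {
      normal <- tryCatch(
        stats::shapiro.test(v1)$p.value > 0.05 &&
          stats::shapiro.test(v2)$p.value > 0.05,
        error = function(e) FALSE)
      if (normal) "t_welch" else "mann_whitney"
    }
  }
  out <- switch(test,
    chi2_fisher = {
      if (!is_binary) stop("chi-square comparison requires a binary 0/1 ",
                           "variable (only 2x2 tables are supported)",
                           call. = FALSE)
      O <- rbind(c(sum(v1 == 1), sum(v1 == 0)),
                 c(sum(v2 == 1), sum(v2 == 0)))
      cs <- chisq_2x2(O)
      p <- stats::fisher.test(O)$p.value
      tibble::tibble(test = cs$branch, statistic = cs$statistic, p_value = p)
    },
    t_welch = {
      tt <- stats::t.test(v1, v2, var.equal = FALSE)
      tibble::tibble(test = "t_welch", statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    },
    mann_whitney = {
      mw <- mann_whitney_z(v1, v2)
      tibble::tibble(test = "mann_whitney", statistic = mw$z,
                     p_value = mw$p_value)
    })
  dplyr::bind_cols(tibble::tibble(variable = variable), out)
}

# Pearson chi-square when all expected counts >= 5, else Yates with the
# correction floored at zero.
chisq_2x2 <- function(O) {
  if (!all(dim(O) == c(2, 2))) stop("2x2 table required", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (all(E >= 5)) {
    list(statistic = sum((O - E)^2 / E), branch = "chi2_pearson")
  } else {
    list(statistic = sum(pmax(abs(O - E) - 0.5, 0)^2 / E),
         branch = "chi2_yates")
  }
}

# Mann-Whitney U as a tie-corrected normal-approximation Z (the form SPSS
# prints); sign follows group 1 minus group 2 mean rank.
mann_whitney_z <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2); n <- n1 + n2
  r <- rank(c(v1, v2))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(v1, v2))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
  z <- (u1 - mu) / sigma
  list(u = u1, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Welch t statistic from group summaries
#'
#' The unequal-variance t computed from means, standard deviations and
#' group sizes only — the form needed to check a printed baseline table
#' without raw data.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `statistic`, `df` (Welch-Satterthwaite) and `p_value`.
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Baseline-table comparison of cohort demographics
#'
#' A Table-1-style summary: per-group descriptive statistics and the
#' [group_compare()] test for each of the nine demographic variables.
#' Statistics are rounded to 3 decimals, as baseline tables print them.
#'
#' @param x A labeled `brainfuse_cohort`.
#' @return Tibble with `variable`, `nmci`, `mci` (formatted summaries),
#'   `test`, `statistic`, `p_value`.
#' @export
cohort_summary <- function(x) {
  demo <- cohort_demographics(x)
  if (anyNA(demo$label)) stop("cohort must be fully labeled", call. = FALSE)
  g0 <- demo[demo$label == 0, ]; g1 <- demo[demo$label == 1, ]
  summarise_var <- function(field) {
    v <- demo[[field]]
    if (all(v %in% c(0, 1))) {
      fmt <- function(g) sprintf("%d (%.2f%%)", sum(g[[field]] == 1),
                                 100 * mean(g[[field]] == 1))
    } else {
      fmt <- function(g) sprintf("%.2f ± %.2f", mean(g[[field]]),
                                 stats::sd(g[[field]]))
    }
    cmp <- group_compare(v, demo$label, variable = field)
    tibble::tibble(variable = field, nmci = fmt(g0), mci = fmt(g1),
                   test = cmp$test, statistic = round(cmp$statistic, 3),
                   p_value = round(cmp$p_value, 3))
  }
  purrr::map_dfr(demographic_fields(), summarise_var)
}
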