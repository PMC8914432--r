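#' Rank genes by a group-wise F statistic
#'
#' Per-gene one-way ANOVA of expression across the radiosensitivity groups,
#' vectorised over genes. The p-value uses the F distribution with
#' `(g - 1, n - g)` degrees of freedom. Genes are returned sorted by
#' ascending p-value, ties broken by descending F, then by gene id. Genes
#' with zero within-group variance and zero between-group variance have an
#' undefined F; they are flagged `degenerate` and ranked last.
#'
#' With `moderated = TRUE` the per-gene residual variance is shrunk toward
#' the grand mean of the gene-wise variances with a fixed prior of 4 degrees
#' of freedom (empirical-Bayes style), which stabilises the ranking when
#' within-group variances are noisy; the denominator df becomes
#' `n - g + 4`.
#'
#' @param expr Numeric matrix, genes x samples, with gene row names.
#' @param groups Factor (or coercible) of length `ncol(expr)`; at least two
#'   groups with at least two samples each.
#' @param moderated Use the variance-shrunk F (default `FALSE`, plain ANOVA).
#'
#' @return Tibble `gene, f_statistic, p_value, degenerate, rank`, sorted.
#' @examples
#' sim <- simulate_expression(expression_design(n_genes = 100, seed = 1))
#' rank_genes(sim$expr, sim$labels$group)
#' @export
rank_genes <- function(expr, groups, moderated = FALSE) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (anyNA(expr)) rlang::abort("`expr` must not contain missing values.")
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(expr)) {
    rlang::abort("`groups` must have one label per column of `expr`.")
  }
  counts <- table(groups)
  if (length(counts) < 2) rlang::abort("At least two groups are required.")
  if (any(counts < 2)) {
    rlang::abort(paste0("Every group needs >= 2 samples; too small: ",
                        paste(names(counts)[counts < 2], collapse = ", ")))
  }
  g <- length(counts)
  n <- ncol(expr)
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("gene%04d", seq_len(nrow(expr)))
  }

  # group means via indicator algebra: one matrix product per statistic
  ind <- stats::model.matrix(~ groups - 1)
  nk <- colSums(ind)
  gmeans <- expr %*% ind %*% diag(1 / nk, g) # genes x groups
  grand <- rowMeans(expr)
  ss_between <- as.vector((gmeans - grand)^2 %*% nk)
  ss_total <- rowSums((expr - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)

  ms_between <- ss_between / (g - 1)
  s2 <- ss_within / (n - g)
  if (moderated) {
    d0 <- 4
    s2_prior <- mean(s2[s2 > 0])
    s2 <- (d0 * s2_prior + (n - g) * s2) / (d0 + n - g)
    df2 <- n - g + d0
  } else {
    df2 <- n - g
  }
  f <- ms_between / s2
  degenerate <- !is.finite(f)
  p <- stats::pf(f, g - 1, df2, lower.tail = FALSE)
  p[degenerate] <- NA_real_
  f[degenerate] <- NA_real_

  tibble::tibble(gene = rownames(expr), f_statistic = f, p_value = p,
                 degenerate = degenerate) |>
    dplyr::arrange(.data$degenerate, .data$p_value,
                   dplyr::desc(.data$f_statistic), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
}

stratified_folds <- function(groups, folds) {
  n <- length(groups)
  if (folds > n) rlang::abort("`folds` must not exceed the number of samples.")
  fold <- integer(n)
  for (lev in levels(groups)) {
    idx <- sample(which(groups == lev))
    fold[idx] <- rep_len(sample(folds), length(idx))
  }
  fold
}

svm_fold_predict <- function(expr, groups, genes, train, test, cost) {
  x_train <- t(expr[genes, train, drop = FALSE])
  x_test <- t(expr[genes, test, drop = FALSE])
  fit <- e1071::svm(x = x_train, y = droplevels(groups[train]),
                    kernel = "linear", cost = cost, scale = FALSE)
  as.character(stats::predict(fit, x_test))
}

balanced_accuracy <- function(truth, pred) {
  mean(vapply(levels(truth), function(lev) {
    idx <- truth == lev
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == lev)
  }, numeric(1)), na.rm = TRUE)
}

#' Evaluate incrementally growing gene panels by cross-validated SVM accuracy
#'
#' For each panel size, trains a linear support-vector machine (C = 1 by
#' default) on the top-ranked genes and measures accuracy by repeated
#' stratified k-fold cross-validation: predictions are pooled over the folds
#' of each repeat, and the per-repeat accuracies are averaged. Balanced
#' accuracy (mean per-class recall) is reported alongside, which matters for
#' imbalanced designs such as 3 resistant lines vs. 35 others.
#'
#' `selection` controls where feature ranking happens: `"inside_cv"`
#' (default) re-ranks genes within each training fold, so the held-out
#' samples never influence feature selection and null data scores at chance;
#' `"outside_cv"` ranks once on all samples, the optimistic single-ranking
#' procedure often seen in practice.
#'
#' @inheritParams rank_genes
#' @param sizes Integer vector of panel sizes (e.g. `4:500`), each `<=`
#'   the gene count.
#' @param folds Number of CV folds (default 10).
#' @param repeats Number of CV repeats (default 10).
#' @param selection `"inside_cv"` or `"outside_cv"`.
#' @param cost SVM cost parameter.
#' @param seed Optional integer seed controlling fold assignment.
#'
#' @return Tibble (class `panel_evaluation`) with one row per panel size:
#'   `panel_size, mean_accuracy, balanced_accuracy, genes` (list-column: the
#'   all-data top-k panel) and `repeat_accuracies` (list-column).
#' @export
evaluate_panels <- function(expr, groups, sizes, folds = 10, repeats = 10,
                            selection = c("inside_cv", "outside_cv"),
                            moderated = FALSE, cost = 1, seed = NULL) {
  selection <- match.arg(selection)
  groups <- droplevels(as.factor(groups))
  n <- ncol(expr)
  if (n < folds) rlang::abort("Need at least as many samples as folds.")
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1) || any(sizes > nrow(expr))) {
    rlang::abort("Panel sizes must lie between 1 and the number of genes.")
  }
  if (any(table(groups) < folds)) {
    rlang::warn("Some class has fewer members than folds; its samples appear in only a subset of test folds.")
  }
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("gene%04d", seq_len(nrow(expr)))
  }

  global_ranking <- rank_genes(expr, groups, moderated = moderated)

  run <- function() {
    acc <- matrix(NA_real_, nrow = repeats, ncol = length(sizes))
    bacc <- matrix(NA_real_, nrow = repeats, ncol = length(sizes))
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(groups, folds)
      pred <- matrix(NA_character_, nrow = n, ncol = length(sizes))
      for (f in seq_len(folds)) {
        test <- which(fold == f)
        train <- which(fold != f)
        if (length(test) == 0) next
        ranking <- if (selection == "inside_cv") {
          rank_genes(expr[, train, drop = FALSE], groups[train],
                     moderated = moderated)
        } else {
          global_ranking
        }
        for (k in seq_along(sizes)) {
          genes <- ranking$gene[seq_len(sizes[k])]
          pred[test, k] <- svm_fold_predict(expr, groups, genes, train, test,
                                            cost)
        }
      }
      for (k in seq_along(sizes)) {
        acc[r, k] <- mean(pred[, k] == as.character(groups), na.rm = TRUE)
        bacc[r, k] <- balanced_accuracy(groups, pred[, k])
      }
    }
    list(acc = acc, bacc = bacc)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  out <- tibble::tibble(
    panel_size = sizes,
    mean_accuracy = colMeans(res$acc),
    balanced_accuracy = colMeans(res$bacc),
    genes = purrr::map(sizes, ~ global_ranking$gene[seq_len(.x)]),
    repeat_accuracies = purrr::map(seq_along(sizes), ~ res$acc[, .x])
  )
  class(out) <- c("panel_evaluation", class(out))
  out
}

#' Pick the best-performing gene panel
#'
#' Returns the evaluation row with the highest mean cross-validated
#' accuracy; ties go to the smallest panel (parsimony).
#'
#' @param evaluations An [evaluate_panels()] result.
#'
#' @return A one-row tibble.
#' @export
select_signature <- function(evaluations) {
  if (nrow(evaluations) == 0) rlang::abort("`evaluations` must be non-empty.")
  evaluations |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy), .data$panel_size) |>
    dplyr::slice(1)
}

#' Binary resistant-vs-rest labels for expression samples
#'
#' Collapses four-cohort S/MS/MR/R labels to `other`/`resistant` so the same
#' ranking + SVM pipeline runs in binary mode (where the two-group F
#' statistic equals the squared two-sample t statistic). For imbalanced
#' designs, judge performance by balanced accuracy: plain accuracy on a
#' 3-vs-35 null sits at the majority-class rate, not at 0.5.
#'
#' @param groups Factor of S/MS/MR/R labels.
#'
#' @return Factor `other < resistant` with `"R"` mapped to `"resistant"`.
#' @export
resistant_labels <- function(groups) {
  groups <- as.factor(groups)
  factor(ifelse(groups == "R", "resistant", "other"),
         levels = c("other", "resistant"))
}
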