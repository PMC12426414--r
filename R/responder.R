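#' Responder labelling from UPDRS-III change
#'
#' A subject is a responder when the UPDRS-III motor score after treatment
#' improves by at least 30 percent of baseline, or decreases by more than 5
#' points: responder iff `(t0 - t10) / t0 >= 0.30` OR `(t0 - t10) > 5`
#' (improvement is a decrease; the 30% bound is inclusive, the 5-point bound
#' strict).
#'
#' @param updrs_t0 Baseline UPDRS-III total (> 0).
#' @param updrs_t10 Post-treatment UPDRS-III total; `NA` leaves the subject
#'   unlabelled (`NA` returned).
#' @return `"responder"`, `"non-responder"`, or `NA_character_`.
#' @export
#' @examples
#' label_responder(20, 13)  # responder: 35% and 7 points
#' label_responder(20, 15)  # non-responder: 25% and exactly 5 points
#' label_responder(10, 7)   # responder: exactly 30%
label_responder <- function(updrs_t0, updrs_t10) {
  if (is.na(updrs_t10)) return(NA_character_)
  abort_if(is.na(updrs_t0) || updrs_t0 <= 0,
           "baseline UPDRS-III must be positive (improvement rate undefined)",
           class = "tmsreact_undefined_ratio")
  change <- updrs_t0 - updrs_t10
  if (change / updrs_t0 >= 0.30 || change > 5) "responder" else "non-responder"
}

#' Baseline EEG feature vector for responder prediction
#'
#' The two-dimensional feature used to predict iTBS response: the
#' region-averaged frontal delta relative power and the F2-F7 delta-band
#' PLI, both from the baseline resting recording. Feature standardisation is
#' deliberately NOT applied here - inside cross-validation it must use
#' training-fold statistics only (see [fold_zscore()]).
#'
#' @param spectral A `spectral_summary` of the baseline resting EEG.
#' @param pli A `pli_matrix` for the delta band.
#' @param frontal_cluster Cluster name for the frontal average.
#' @param pair Channel pair for the PLI feature.
#' @return A one-row tibble: `frontal_delta_relpow`, `f2f7_delta_pli`.
#' @export
extract_features <- function(spectral, pli, frontal_cluster = "frontal",
                             pair = c("F2", "F7")) {
  tibble(
    frontal_delta_relpow = region_average(spectral, frontal_cluster,
                                          band = "delta"),
    f2f7_delta_pli = pair_pli(pli, pair[1], pair[2])
  )
}

#' Z-score features using training-fold statistics
#'
#' Centres and scales every column of `train` and `test` by the mean and SD
#' of the training rows only, preventing information leakage across folds.
#' A constant training column (SD 0) is mapped to all zeros with a warning.
#'
#' @param train,test Numeric matrices (rows = subjects).
#' @return A list with scaled `train` and `test`.
#' @export
fold_zscore <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  if (any(sdv == 0)) {
    warn("constant feature column in training fold; z-scored to zeros")
    sdv[sdv == 0] <- Inf
  }
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sdv, "/"))
}

stratified_folds <- function(labels, k, max_attempts = 100L) {
  for (attempt in seq_len(max_attempts)) {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[fold == f])) == length(unique(labels))
    }, logical(1)))
    if (ok) return(fold)
  }
  abort("could not draw stratified folds with both classes in every fold",
        class = "tmsreact_pipeline_error")
}

svm_scores <- function(xtr, ytr, xte, cost) {
  fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  pred <- stats::predict(fit, xte, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # e1071 orients decision values toward the first label in the colname pair
  first <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1]][1]
  if (first != "responder") dv <- -dv
  list(pred = as.character(pred), score = dv)
}

balanced_accuracy <- function(truth, pred) {
  sens <- mean(pred[truth == "responder"] == "responder")
  spec <- mean(pred[truth == "non-responder"] == "non-responder")
  (sens + spec) / 2
}

#' Nested cross-validated linear-SVM responder classifier
#'
#' Linear support vector machine with 5-fold nested cross-validation: the
#' outer loop yields held-out decision scores and class predictions; the
#' inner loop (run on each outer-training set) selects the margin penalty C
#' from a log-spaced grid by inner-fold balanced accuracy. Feature z-scoring
#' uses training-fold statistics only, at both levels. The whole procedure
#' is repeated `repetitions` times with freshly drawn stratified outer
#' folds, and balanced accuracy / AUC are averaged across repetitions.
#'
#' @param features Data frame or matrix of numeric features (rows =
#'   subjects).
#' @param labels Responder labels: `"responder"` / `"non-responder"` (or a
#'   logical vector, `TRUE` = responder).
#' @param outer_folds,inner_folds Fold counts (default 5 and 5).
#' @param repetitions Number of outer-partition re-draws averaged (default
#'   1000).
#' @param cost_grid Candidate C values (default `10^(-3:3)`).
#' @param seed Integer seed; the full procedure is a pure function of its
#'   arguments.
#'
#' @return An object of class `responder_clf`: list with `balanced_accuracy`
#'   and `auc` (means over repetitions), `per_rep` (tibble of per-repetition
#'   metrics), `roc` (the [roc_report()] of the pooled out-of-fold scores),
#'   `sensitivity` / `specificity` at the Youden point, `cost_trace`
#'   (selected C counts), and the settings.
#' @export
nested_cv_classify <- function(features, labels, outer_folds = 5L,
                               inner_folds = 5L, repetitions = 1000L,
                               cost_grid = 10^seq(-3, 3), seed = 1) {
  x <- as.matrix(features)
  abort_if(!is.numeric(x) || anyNA(x), "features must be numeric and complete")
  if (is.logical(labels)) {
    labels <- ifelse(labels, "responder", "non-responder")
  }
  abort_if(!all(labels %in% c("responder", "non-responder")),
           "labels must be 'responder' / 'non-responder'")
  abort_if(min(table(labels)) < 2L, "need at least 2 subjects per class")
  y <- factor(labels, levels = c("non-responder", "responder"))
  n <- nrow(x)

  with_seed(seed, {
    per_rep <- vector("list", repetitions)
    all_scores <- vector("list", repetitions)
    cost_pick <- numeric(0)

    for (r in seq_len(repetitions)) {
      fold <- stratified_folds(labels, outer_folds)
      scores <- numeric(n)
      preds <- character(n)
      for (f in seq_len(outer_folds)) {
        tr <- fold != f
        best <- tune_cost(x[tr, , drop = FALSE], labels[tr], inner_folds,
                          cost_grid)
        cost_pick <- c(cost_pick, best)
        sc <- fold_zscore(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
        out <- svm_scores(sc$train, y[tr], sc$test, best)
        scores[!tr] <- out$score
        preds[!tr] <- out$pred
      }
      per_rep[[r]] <- tibble(
        rep = r,
        balanced_accuracy = balanced_accuracy(labels, preds),
        auc = auc_midrank(scores, labels == "responder")
      )
      all_scores[[r]] <- scores
    }

    per_rep <- dplyr::bind_rows(per_rep)
    pooled <- roc_report(unlist(all_scores), rep(labels == "responder",
                                                 repetitions))
    structure(list(
      balanced_accuracy = mean(per_rep$balanced_accuracy),
      auc = mean(per_rep$auc),
      per_rep = per_rep,
      roc = pooled,
      sensitivity = pooled$sensitivity,
      specificity = pooled$specificity,
      cost_trace = table(cost_pick),
      settings = list(outer_folds = outer_folds, inner_folds = inner_folds,
                      repetitions = repetitions, cost_grid = cost_grid,
                      seed = seed),
      n = n
    ), class = "responder_clf")
  })
}

tune_cost <- function(xtr, labels, inner_folds, cost_grid) {
  k <- min(inner_folds, min(table(labels)))
  fold <- stratified_folds(labels, k)
  ytr <- factor(labels, levels = c("non-responder", "responder"))
  ba <- vapply(cost_grid, function(cost) {
    preds <- character(length(labels))
    for (f in seq_len(k)) {
      inner <- fold != f
      sc <- fold_zscore(xtr[inner, , drop = FALSE],
                        xtr[!inner, , drop = FALSE])
      preds[!inner] <- svm_scores(sc$train, ytr[inner], sc$test, cost)$pred
    }
    balanced_accuracy(labels, preds)
  }, numeric(1))
  cost_grid[which.max(ba)]   # ties resolve to the smallest C
}

#' @export
print.responder_clf <- function(x, ...) {
  cat("<responder_clf> linear SVM, ", x$settings$outer_folds, "x",
      x$settings$inner_folds, " nested CV, ", x$settings$repetitions,
      " repetition(s), n = ", x$n, "\n", sep = "")
  cat(sprintf("  balanced accuracy %.3f | AUC %.3f | sens %.3f | spec %.3f\n",
              x$balanced_accuracy, x$auc, x$sensitivity, x$specificity))
  invisible(x)
}

# Midrank (Mann-Whitney) AUC; ties share rank, so constant scores give 0.5.
auc_midrank <- function(scores, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  abort_if(n1 == 0 || n0 == 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve, AUC, and Youden operating point
#'
#' AUC is the midrank (Mann-Whitney) statistic, equal to the trapezoid area
#' under the empirical ROC with tied scores handled by midranks. The
#' operating point maximises Youden's J = sensitivity + specificity - 1;
#' ties resolve to the higher sensitivity.
#'
#' @param scores Numeric decision scores (larger = more responder-like).
#' @param labels Logical (`TRUE` = positive/responder) or
#'   `"responder"`/`"non-responder"` labels.
#' @return An object of class `roc_curve`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
#' @examples
#' roc_report(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))$auc
roc_report <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "responder"
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  abort_if(n1 == 0 || n0 == 0, "both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) sum(scores >= th & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & !labels) / n0, numeric(1))
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.max(tpr[best])]
  structure(list(points = tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc_midrank(scores, labels),
                 threshold = thr[best],
                 sensitivity = tpr[best],
                 specificity = 1 - fpr[best]),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f; Youden point: sens %.3f, spec %.3f\n",
              x$auc, x$sensitivity, x$specificity))
  invisible(x)
}

#' Between-class feature comparisons
#'
#' Two-sample comparison of each feature between responders and
#' non-responders (or any two-level grouping): Shapiro-Wilk at alpha = 0.05
#' on each group gates an independent t-test (both normal) versus a
#' Mann-Whitney U test; p-values are adjusted across features by
#' Benjamini-Hochberg FDR. Features with zero variance in both groups are
#' skipped with a note.
#'
#' @param data Data frame with one row per subject.
#' @param features Character vector of feature column names.
#' @param group_col Two-level grouping column (default `"responder"`).
#' @return A tibble: `feature`, `test`, `statistic`, `p`, `p_adj`,
#'   `mean_a`, `mean_b`, `note`.
#' @export
group_difference_tests <- function(data,
                                   features = c("frontal_delta_relpow",
                                                "f2f7_delta_pli"),
                                   group_col = "responder") {
  g <- data[[group_col]]
  lv <- sort(unique(as.character(g)))
  abort_if(length(lv) != 2L, "grouping column must have exactly two levels")
  abort_if(min(table(g)) < 2L, "need at least 2 subjects per group")
  rows <- purrr::map(features, function(f) {
    a <- data[[f]][g == lv[1]]
    b <- data[[f]][g == lv[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble(feature = f, test = NA_character_,
                    statistic = NA_real_, p = NA_real_,
                    mean_a = mean(a), mean_b = mean(b),
                    note = "zero variance in both groups; test skipped"))
    }
    normal <- is_normalish(a) && is_normalish(b)
    if (normal) {
      tt <- stats::t.test(a, b)
      tibble(feature = f, test = "t", statistic = unname(tt$statistic),
             p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
             note = NA_character_)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      tibble(feature = f, test = "mann-whitney",
             statistic = unname(wt$statistic), p = wt$p.value,
             mean_a = mean(a), mean_b = mean(b), note = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("feature", "test", "statistic", "p", "p_adj",
          "mean_a", "mean_b", "note")]
}

# Shapiro-Wilk normality gate at alpha = 0.05; degenerate samples count as
# non-normal.
is_normalish <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3L || length(x) < 3L) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}
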