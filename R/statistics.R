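#' One-way fixed-effects ANOVA for a feature across groups
#'
#' Classical equal-variance one-way ANOVA (the screening test applied to
#' every (structure, feature) pair before pairwise comparison). A fully
#' constant response is degenerate and returns `NA` statistics with
#' `degenerate = TRUE`.
#'
#' @param values numeric vector.
#' @param groups factor or character vector of group labels.
#' @return list: `F`, `p`, `df_between`, `df_within`, `degenerate`.
#' @export
anova_per_feature <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (any(table(groups) < 2)) stop_pdtex("need >= 2 values per group")
  if (length(unique(values)) < 2) {
    return(list(F = NA_real_, p = NA_real_, df_between = nlevels(groups) - 1,
                df_within = length(values) - nlevels(groups), degenerate = TRUE))
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df_between = unname(ft$parameter[1]), df_within = unname(ft$parameter[2]),
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin, named wrapper around `stats::p.adjust(..., method = "BH")` so the
#' correction used across the package is explicit and swappable.
#'
#' @param p numeric vector of raw p-values.
#' @return vector of BH-adjusted q-values.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Pairwise Welch tests with FDR correction
#'
#' Welch (unequal-variance) t tests for every pair of groups, with
#' Benjamini-Hochberg correction across the pairs and a significance flag at
#' `q < alpha`. Pairs with fewer than 2 observations in a group are skipped
#' with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha FDR significance threshold (default 0.02).
#' @return data frame: group1, group2, t, p, q, significant.
#' @export
pairwise_tests_fdr <- function(values, groups, alpha = 0.02) {
  groups <- factor(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- values[groups == pr[1] & !is.na(values)]
    b <- values[groups == pr[2] & !is.na(values)]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("pair %s vs %s skipped: fewer than 2 observations",
                      pr[1], pr[2]), call. = FALSE)
      return(NULL)
    }
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) {
      return(data.frame(group1 = pr[1], group2 = pr[2], t = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(group1 = pr[1], group2 = pr[2], t = unname(tt$statistic),
               p = unname(tt$p.value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q <- fdr_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < alpha
  out
}

# Stratified fold assignment: shuffles within each class, then deals folds
# round-robin so class proportions are balanced across folds. Classes smaller
# than k cannot populate every fold, so tiny samples fall back to a plain
# shuffled round-robin that keeps all k folds non-empty.
stratified_folds <- function(y, k) {
  if (min(table(y)) < k) {
    return(sample(rep_len(seq_len(k), length(y))))
  }
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' LASSO selection of texture features over three groups
#'
#' Multinomial logistic LASSO on z-scored columns; the penalty is chosen by
#' stratified k-fold cross-validation at the 1-SE rule, and every feature
#' with a nonzero coefficient in any class equation is reported as selected.
#' Deterministic for a fixed `seed` (only fold assignment is random).
#' Constant columns carry no information and are dropped with a warning.
#' Collinear informative columns make the selected set non-unique: at least
#' one member of a duplicated pair is retained, but which one is arbitrary.
#'
#' @param x numeric matrix or data frame, subjects x features, with column
#'   names.
#' @param y group labels (3 classes).
#' @param seed integer seed for fold assignment.
#' @param nfolds folds for cross-validation (default 5).
#' @param lambda `"lambda.1se"` (default) or `"lambda.min"`.
#' @return character vector of selected feature names (possibly empty), with
#'   the fitted `cv.glmnet` object as attribute `"fit"`.
#' @export
lasso_select <- function(x, y, seed = 1L, nfolds = 5L, lambda = "lambda.1se") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(y)
  if (nrow(x) <= 5) stop_pdtex("need more than 5 subjects for LASSO selection")
  if (min(table(y)) < 3) {
    warning("fewer than 3 subjects in a class: cross-validated LASSO is not ",
            "estimable, skipping selection", call. = FALSE)
    return(character(0))
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    drop <- colnames(x)[sds == 0 | is.na(sds)]
    warning(sprintf("dropping constant column(s): %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    x <- x[, !(colnames(x) %in% drop), drop = FALSE]
  }
  if (ncol(x) == 0) return(character(0))
  xs <- scale(x)
  set.seed(seed)
  foldid <- stratified_folds(y, nfolds)
  # glmnet warns when path tail lambdas (far below the CV optimum) do not
  # converge; those solutions never enter the 1-SE choice, so muffle them
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(xs, y, family = "multinomial", foldid = foldid,
                      standardize = FALSE, type.measure = "deviance"),
    warning = function(w) {
      if (grepl("from glmnet C\\+\\+ code", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(cv, s = lambda)
  nz <- Reduce(`|`, lapply(co, function(m) as.vector(m[-1, 1]) != 0))
  sel <- colnames(x)[nz]
  attr(sel, "fit") <- cv
  sel
}

#' ROC evaluation of a feature for early- versus late-stage discrimination
#'
#' AUC by the Mann-Whitney pair-count convention (ties count one half), with
#' a fixed orientation: AUC is the probability that a case (second level /
#' `positive`) scores higher than a control. No direction flipping is
#' applied, so AUC below 0.5 is reported as computed. Specificity and
#' sensitivity are taken at the threshold maximizing Youden's J.
#'
#' @param values numeric marker values.
#' @param labels two-class labels.
#' @param positive label of the positive class (default `"latePD"` when
#'   present, else the second factor level).
#' @return list: `auc`, `specificity`, `sensitivity`, `threshold`, `n_pos`,
#'   `n_neg`.
#' @export
roc_evaluate <- function(values, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop_pdtex("labels must have exactly 2 classes")
  if (is.null(positive)) {
    positive <- if ("latePD" %in% levels(labels)) "latePD" else levels(labels)[2]
  }
  negative <- setdiff(levels(labels), positive)
  if (!all(table(labels) > 0)) stop_pdtex("both classes must be present")
  r <- pROC::roc(response = labels, predictor = values,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "specificity", "sensitivity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]  # ties in J: take the first optimum
  list(auc = as.numeric(r$auc),
       specificity = best$specificity, sensitivity = best$sensitivity,
       threshold = best$threshold,
       n_pos = sum(labels == positive), n_neg = sum(labels == negative))
}

#' Spearman correlations of features with clinical scores, FDR-corrected
#'
#' Spearman's rank correlation (average ranks for ties) of each feature
#' column against each clinical score, with pairwise deletion of missing
#' values and Benjamini-Hochberg correction across the whole
#' (feature x score) family passed in. Constant vectors give an undefined
#' (`NA`) correlation.
#'
#' @param features data frame of feature columns.
#' @param scores data frame of clinical score columns (same row order).
#' @param alpha significance threshold on q (default 0.05).
#' @return data frame: feature, score, n, rho, p, q, significant.
#' @export
spearman_fdr <- function(features, scores, alpha = 0.05) {
  rows <- list()
  for (f in names(features)) {
    for (s in names(scores)) {
      x <- features[[f]]; y <- scores[[s]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 5) stop_pdtex("fewer than 5 complete pairs for %s vs %s", f, s)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                               method = "spearman",
                                               exact = FALSE))
        rho <- unname(ct$estimate); p <- unname(ct$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(feature = f, score = s, n = n,
                                              rho = rho, p = p,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < alpha
  out
}
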