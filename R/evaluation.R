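# Confusion-matrix metrics, ROC/AUC with max-MCC cutoff selection, k-fold
# cross-validation at entry level, cutoff screening, Welch comparison of
# classifier families, and precision-at-coverage readout.

#' Confusion counts from predictions and truth
#'
#' @param predicted logical/0-1 predicted positives (IFR = positive).
#' @param truth logical/0-1 true labels.
#' @return list with `TP`, `TN`, `FP`, `FN` (doubles, to keep large
#'   products exact enough for MCC).
#' @export
confusion_counts <- function(predicted, truth) {
  p <- as.logical(predicted); t_ <- as.logical(truth)
  list(TP = sum(p & t_) + 0, TN = sum(!p & !t_) + 0,
       FP = sum(p & !t_) + 0, FN = sum(!p & t_) + 0)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any factor of the denominator vanishes. Ranges over `[-1, 1]`;
#' zero for a random classifier.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN`.
#' @return MCC value.
#' @export
#' @examples
#' mcc(list(TP = 50, TN = 50, FP = 0, FN = 0))  # 1
mcc <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Accuracy, precision, sensitivity and MCC from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`. An undefined ratio (zero denominator) is reported as `NA`,
#' not as 0.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN`.
#' @return tibble with `accuracy`, `precision`, `sensitivity`, `mcc`.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  tibble::tibble(
    accuracy = if (total > 0) (tp + tn) / total else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    mcc = mcc(counts)
  )
}

#' ROC curve, AUC and maximum-MCC cutoff
#'
#' Sweeps every distinct score as a decision threshold (ties grouped), and
#' reports the ROC points with per-threshold precision and MCC, the
#' trapezoidal AUC (which equals the Mann-Whitney concordant-pair
#' statistic, counting ties as half), and the threshold maximizing MCC.
#'
#' @param scores numeric posterior scores (higher = more interface-like).
#' @param labels binary truth (1 = interface).
#' @return An `ifr_roc` object: `points` (tibble `cutoff`, `fpr`, `tpr`,
#'   `precision`, `mcc`), `auc`, `max_mcc`, `max_mcc_cutoff`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("undefined AUC: both classes must be present")
  }
  n_pos <- sum(labels == 1) + 0
  n_neg <- sum(labels == 0) + 0
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))       # tie groups of equal score
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(which(diff(grp) != 0), length(s))  # last index of each group
  tp <- tp[last]; fp <- fp[last]
  cut <- s[last]
  tpr <- tp / n_pos; fpr <- fp / n_neg
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  fn <- n_pos - tp; tn <- n_neg - fp
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mccs <- ifelse(den == 0, 0, (tp * tn - fp * fn) / sqrt(den))
  pts <- tibble::tibble(cutoff = c(Inf, cut), fpr = c(0, fpr),
                        tpr = c(0, tpr), precision = c(NA_real_, prec),
                        mcc = c(0, mccs))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  imax <- which.max(pts$mcc)
  structure(
    list(points = pts, auc = auc, max_mcc = pts$mcc[imax],
         max_mcc_cutoff = pts$cutoff[imax], n_pos = n_pos, n_neg = n_neg),
    class = "ifr_roc"
  )
}

#' @export
print.ifr_roc <- function(x, ...) {
  cat(sprintf("<ifr_roc> AUC %.4f, max MCC %.4f at cutoff %.4g (%d pos / %d neg)\n",
              x$auc, x$max_mcc, x$max_mcc_cutoff, x$n_pos, x$n_neg))
  invisible(x)
}

#' Entry-level k-fold assignment
#'
#' Shuffles the entry ids with a seeded generator and deals them
#' round-robin into `k` folds, so fold sizes differ by at most one and no
#' residue of an entry ever crosses folds.
#'
#' @param ids entry (PDB) identifiers.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return tibble with `id` and `fold` (0-based).
#' @export
kfold_split <- function(ids, k = 10, seed = 1) {
  if (length(ids) < k) stop("fewer entries than folds")
  shuffled <- withr::with_seed(seed, sample(ids))
  tibble::tibble(id = shuffled,
                 fold = rep_len(seq_len(k) - 1L, length(ids)))
}

#' Metrics across decision cutoffs
#'
#' Confusion metrics at each posterior cutoff (default 0.1 to 0.9 in steps
#' of 0.1): as the cutoff rises fewer residues are called interface, so
#' sensitivity can only fall while precision tends to grow.
#'
#' @param scores posterior scores.
#' @param labels binary truth.
#' @param cutoffs cutoff grid.
#' @return An `ifr_cutoff_screen` tibble: `cutoff`, `TP`, `TN`, `FP`,
#'   `FN`, `accuracy`, `precision`, `sensitivity`, `mcc`.
#' @export
cutoff_screen <- function(scores, labels, cutoffs = seq(0.1, 0.9, by = 0.1)) {
  rows <- lapply(cutoffs, function(ct) {
    cc <- confusion_counts(scores >= ct, labels)
    dplyr::bind_cols(tibble::tibble(cutoff = ct, TP = cc$TP, TN = cc$TN,
                                    FP = cc$FP, FN = cc$FN),
                     confusion_metrics(cc))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ifr_cutoff_screen", class(out))
  out
}

#' Welch's two-sample comparison of classifier families
#'
#' Unequal-variance two-sided t-test (Welch-Satterthwaite degrees of
#' freedom), typically applied to per-fold AUC samples of two classifier
#' families. Two degenerate constant samples with equal means give p = 1.
#'
#' @param a,b numeric metric samples (length at least 2 each).
#' @return tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 samples per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(t = if (equal) 0 else Inf,
                          df = NA_real_,
                          p_value = if (equal) 1 else 0,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Precision at requested interface coverage levels
#'
#' For each requested sensitivity (coverage) level, selects the ROC
#' threshold achieving the smallest sensitivity at or above the level and
#' reports its precision.
#'
#' @param roc an `ifr_roc`.
#' @param coverage_levels sensitivities to query, in `[0, 1]`.
#' @return tibble with `coverage`, `attained` (logical), `sensitivity`,
#'   `precision`, `cutoff`.
#' @export
precision_at_coverage <- function(roc, coverage_levels) {
  pts <- roc$points
  rows <- lapply(coverage_levels, function(lv) {
    cand <- pts[!is.na(pts$precision) & pts$tpr >= lv, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(tibble::tibble(coverage = lv, attained = FALSE,
                            sensitivity = NA_real_, precision = NA_real_,
                            cutoff = NA_real_))
    }
    best <- cand[order(cand$tpr, -cand$cutoff), ][1, ]
    tibble::tibble(coverage = lv, attained = TRUE,
                   sensitivity = best$tpr, precision = best$precision,
                   cutoff = best$cutoff)
  })
  dplyr::bind_rows(rows)
}

#' Cross-validate datamart classifiers
#'
#' Row-level k-fold cross-validation over a set of per-type datamarts: in
#' every fold the correlation pruning, PCA and LDA are fitted on the
#' training rows only; the retained component count per type is frozen
#' from the first fold. Reports per-fold AUC/max-MCC for every type, for
#' the aggregated per-type classifier (pooling each type's held-out
#' posteriors) and for the type-unspecific classifier trained on the
#' pooled datamarts.
#'
#' @param marts named list of `ifr_datamart` objects with a common feature
#'   set (required for the unspecific classifier).
#' @param config an [ifr_config()] (`k_folds`, `cor_threshold`,
#'   `variance_target`, `seed`).
#' @return tibble with `fold`, `classifier` (a type name, `"aggregated"`
#'   or `"unspecific"`), `auc`, `max_mcc`, `n_test`.
#' @export
crossval_marts <- function(marts, config = ifr_config()) {
  k <- config$k_folds
  folds <- lapply(marts, function(m) {
    fa <- kfold_split(seq_along(m$y), k, config$seed)
    fa$fold[match(seq_along(m$y), fa$id)]
  })
  common <- Reduce(intersect, lapply(marts, function(m) names(m$x)))
  k_frozen <- list()
  res <- list()
  for (f in seq_len(k) - 1L) {
    pooled_scores <- c(); pooled_labels <- c()
    tr_x_all <- list(); tr_y_all <- list()
    te_x_all <- list(); te_y_all <- list()
    for (tp in names(marts)) {
      m <- marts[[tp]]
      te <- folds[[tp]] == f
      if (length(unique(m$y[!te])) < 2 || !any(te)) next
      pruned <- drop_correlated(m$x[!te, , drop = FALSE], config$cor_threshold)
      pca <- fit_pca(pruned$data, config$variance_target,
                     k_override = k_frozen[[tp]])
      if (is.null(k_frozen[[tp]])) k_frozen[[tp]] <- pca$k
      lda <- fit_lda(project(pca, pruned$data), m$y[!te])
      p <- posterior(lda, project(pca, m$x[te, names(pruned$data), drop = FALSE]))
      if (length(unique(m$y[te])) == 2) {
        r <- roc_auc(p, m$y[te])
        res[[length(res) + 1]] <- tibble::tibble(
          fold = f, classifier = tp, auc = r$auc, max_mcc = r$max_mcc,
          n_test = sum(te))
      }
      pooled_scores <- c(pooled_scores, p)
      pooled_labels <- c(pooled_labels, m$y[te])
      tr_x_all[[tp]] <- m$x[!te, common, drop = FALSE]
      tr_y_all[[tp]] <- m$y[!te]
      te_x_all[[tp]] <- m$x[te, common, drop = FALSE]
      te_y_all[[tp]] <- m$y[te]
    }
    if (length(unique(pooled_labels)) == 2) {
      r <- roc_auc(pooled_scores, pooled_labels)
      res[[length(res) + 1]] <- tibble::tibble(
        fold = f, classifier = "aggregated", auc = r$auc,
        max_mcc = r$max_mcc, n_test = length(pooled_labels))
    }
    tr_x <- dplyr::bind_rows(tr_x_all); tr_y <- unlist(tr_y_all)
    te_x <- dplyr::bind_rows(te_x_all); te_y <- unlist(te_y_all)
    if (length(unique(tr_y)) == 2 && length(unique(te_y)) == 2) {
      pruned <- drop_correlated(tr_x, config$cor_threshold)
      pca <- fit_pca(pruned$data, config$variance_target,
                     k_override = k_frozen[["..unspecific"]])
      if (is.null(k_frozen[["..unspecific"]])) k_frozen[["..unspecific"]] <- pca$k
      lda <- fit_lda(project(pca, pruned$data), tr_y)
      p <- posterior(lda, project(pca, te_x[, names(pruned$data), drop = FALSE]))
      r <- roc_auc(p, te_y)
      res[[length(res) + 1]] <- tibble::tibble(
        fold = f, classifier = "unspecific", auc = r$auc,
        max_mcc = r$max_mcc, n_test = length(te_y))
    }
  }
  dplyr::bind_rows(res)
}
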