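# Datamart assembly, correlation pruning at |r| > 0.85, and
# correlation-matrix PCA retaining 95% of training variance.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (at least 2) with nonzero
#'   variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(x, y)
}

#' Prune linearly correlated feature columns
#'
#' Iteratively removes the column participating in the most pairs with
#' `|r|` above the threshold (ties broken by larger mean absolute
#' correlation, then by column order) until no pair exceeds the threshold.
#'
#' @param x numeric data frame / tibble of feature columns.
#' @param threshold absolute-correlation threshold (default 0.85).
#' @return list with `data` (the reduced tibble) and `removed` (tibble:
#'   `column`, `n_high`, `mean_abs_r`, in removal order).
#' @export
#' @examples
#' d <- tibble::tibble(a = rnorm(50))
#' d$b <- d$a
#' drop_correlated(d)$removed$column
drop_correlated <- function(x, threshold = 0.85) {
  x <- tibble::as_tibble(x)
  removed <- tibble::tibble(column = character(), n_high = integer(),
                            mean_abs_r = double())
  repeat {
    if (ncol(x) < 2) break
    r <- abs(stats::cor(as.matrix(x)))
    r[is.na(r)] <- 0
    diag(r) <- 0
    n_high <- colSums(r > threshold)
    if (max(n_high) == 0) break
    mean_r <- rowMeans(r)
    worst <- which(n_high == max(n_high))
    worst <- worst[order(-mean_r[worst])][1]
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      column = names(x)[worst], n_high = as.integer(max(n_high)),
      mean_abs_r = unname(mean_r[worst])))
    x <- x[, -worst, drop = FALSE]
  }
  list(data = x, removed = removed)
}

#' Fit a correlation-matrix PCA with a variance-retention rule
#'
#' Columns are standardized by their training means and standard
#' deviations; the eigendecomposition of the training correlation matrix
#' defines the components, and `k` is the smallest number of leading
#' components whose cumulative eigenvalue fraction reaches
#' `variance_target`.
#'
#' @param x numeric tibble/data frame (training rows only).
#' @param variance_target cumulative variance fraction to retain (default
#'   0.95).
#' @param k_override fix the retained component count (used to freeze `k`
#'   across cross-validation folds).
#' @return An `ifr_pca` object: `columns`, `means`, `sds`, `rotation`
#'   (eigenvectors), `eigenvalues`, `k`, `cum_var` (cumulative fraction at
#'   `k`).
#' @export
fit_pca <- function(x, variance_target = 0.95, k_override = NULL) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  if (any(sd_ == 0)) stop("zero-variance column(s): ",
                          paste(colnames(x)[sd_ == 0], collapse = ", "))
  z <- scale(x, center = mu, scale = sd_)
  C <- stats::cor(x)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (any(e$values < -1e-8) || any(ev < 1e-12)) {
    warning("rank-deficient correlation matrix; zero eigenvalues retained")
  }
  frac <- cumsum(ev) / sum(ev)
  k <- if (!is.null(k_override)) as.integer(k_override)
       else which(frac >= variance_target)[1]
  structure(
    list(columns = colnames(x), means = mu, sds = sd_,
         rotation = e$vectors, eigenvalues = ev, k = k,
         cum_var = frac[k], variance_target = variance_target),
    class = "ifr_pca"
  )
}

#' @export
print.ifr_pca <- function(x, ...) {
  cat(sprintf("<ifr_pca> %d columns -> %d components (%.1f%% of variance)\n",
              length(x$columns), x$k, 100 * x$cum_var))
  invisible(x)
}

#' Project rows onto fitted principal components
#'
#' Standardizes rows by the training means and standard deviations and
#' multiplies into the training eigenvectors; the fit is never updated on
#' new rows.
#'
#' @param projection an `ifr_pca` fit.
#' @param rows tibble/data frame containing at least the fitted columns.
#' @return matrix of scores with `k` columns (`PC1`..`PCk`).
#' @export
project <- function(projection, rows) {
  missing_cols <- setdiff(projection$columns, colnames(rows))
  extra <- setdiff(colnames(rows), projection$columns)
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")) else "")
  }
  x <- as.matrix(rows[, projection$columns, drop = FALSE])
  z <- scale(x, center = projection$means, scale = projection$sds)
  s <- z %*% projection$rotation[, seq_len(projection$k), drop = FALSE]
  colnames(s) <- paste0("PC", seq_len(projection$k))
  s
}

#' Assemble per-amino-acid-type datamarts
#'
#' Splits a labeled descriptor table into one training matrix per
#' amino-acid type: surface residues only (interface-forming = positive
#' class, free-surface = negative; buried residues excluded), descriptor
#' columns that are entirely missing or constant for that type dropped,
#' remaining rows with any missing value dropped. Types with fewer than
#' two residues per class are skipped with a message in the log.
#'
#' @param desc descriptor tibble (with `cls` labels and any unused-energy /
#'   neighbor-average columns already appended).
#' @param min_per_class minimum residues per class (default 2).
#' @return list with `marts` (named list of `ifr_datamart`: `type`, `x`
#'   feature tibble, `y` integer labels, `row_uid`) and `log` (tibble of
#'   per-type row/column drops).
#' @export
build_datamarts <- function(desc, min_per_class = 2) {
  surf <- desc[desc$cls %in% c("IFR", "FSR"), , drop = FALSE]
  feat_cols <- setdiff(names(surf), LOCATOR_COLS)
  marts <- list()
  log <- tibble::tibble(res_type = character(), n_rows = integer(),
                        n_dropped_rows = integer(), n_dropped_cols = integer(),
                        kept = logical())
  for (tp in sort(unique(surf$res_type))) {
    sub <- surf[surf$res_type == tp, , drop = FALSE]
    x <- sub[, feat_cols, drop = FALSE]
    # first drop columns that are missing or constant for this type,
    # then rows that still have missing values
    all_na_or_const <- vapply(x, function(v) {
      all(is.na(v)) || length(unique(v[!is.na(v)])) <= 1
    }, TRUE)
    x <- x[, !all_na_or_const, drop = FALSE]
    cc <- stats::complete.cases(x)
    y <- as.integer(sub$cls == "IFR")[cc]
    xk <- x[cc, , drop = FALSE]
    kept <- sum(y == 1) >= min_per_class && sum(y == 0) >= min_per_class
    log <- dplyr::bind_rows(log, tibble::tibble(
      res_type = tp, n_rows = sum(cc),
      n_dropped_rows = as.integer(sum(!cc)),
      n_dropped_cols = as.integer(sum(all_na_or_const)), kept = kept))
    if (!kept) next
    marts[[tp]] <- new_datamart(tp, xk, y, sub$res_uid[cc])
  }
  list(marts = marts, log = log)
}

new_datamart <- function(type, x, y, row_uid = NULL) {
  structure(list(type = type, x = tibble::as_tibble(x), y = as.integer(y),
                 row_uid = row_uid),
            class = "ifr_datamart")
}

#' @export
print.ifr_datamart <- function(x, ...) {
  cat(sprintf("<ifr_datamart> %s: %d rows (%d IFR / %d FSR), %d features\n",
              x$type, length(x$y), sum(x$y == 1), sum(x$y == 0), ncol(x$x)))
  invisible(x)
}
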