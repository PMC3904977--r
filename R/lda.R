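# Two-class linear discriminant analysis with Gaussian class-conditional
# densities and pooled covariance (the pooling is what makes the decision
# boundary linear), plus the per-amino-acid-type classifier bundle.

#' Fit a two-class linear discriminant model
#'
#' Maximum-likelihood Gaussian LDA: class means are per-class averages, the
#' covariance is pooled within-class, priors are the training class
#' frequencies. A numerically singular pooled covariance is
#' ridge-regularized on the diagonal (1e-6) with a warning.
#'
#' @param x numeric matrix (rows = observations, e.g. PC scores).
#' @param y binary labels (1 = positive/interface class).
#' @return An `ifr_lda` object: `mu0`, `mu1`, `sigma`, `priors`, the
#'   discriminant direction `w = sigma^-1 (mu1 - mu0)`, and `n`.
#' @export
fit_lda <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training requires both classes present")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  x1 <- x[y == 1, , drop = FALSE]
  x0 <- x[y == 0, , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  s1 <- if (n1 > 1) stats::cov(x1) else matrix(0, ncol(x), ncol(x))
  s0 <- if (n0 > 1) stats::cov(x0) else matrix(0, ncol(x), ncol(x))
  sigma <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2)
  w <- tryCatch(solve(sigma, mu1 - mu0), error = function(e) {
    warning("singular pooled covariance; applying diagonal ridge 1e-6")
    solve(sigma + diag(1e-6, ncol(x)), mu1 - mu0)
  })
  structure(
    list(mu0 = mu0, mu1 = mu1, sigma = sigma,
         priors = c(p0 = n0 / (n0 + n1), p1 = n1 / (n0 + n1)),
         w = w, n = c(n0 = n0, n1 = n1)),
    class = "ifr_lda"
  )
}

#' @export
print.ifr_lda <- function(x, ...) {
  cat(sprintf("<ifr_lda> %d features, n = %d IFR / %d FSR, priors %.2f/%.2f\n",
              length(x$w), x$n["n1"], x$n["n0"], x$priors["p1"], x$priors["p0"]))
  invisible(x)
}

#' Posterior probability of the positive (interface) class
#'
#' Gaussian class-conditional likelihoods times the class priors,
#' normalized. With pooled covariance the log-odds are linear in `x`, so
#' the posterior is a logistic function of the discriminant score.
#'
#' @param model an `ifr_lda` fit.
#' @param x numeric matrix (or vector) of observations in model space.
#' @return numeric vector of `P(IFR | x)` in `[0, 1]`.
#' @export
posterior <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model$w)) {
    stop(sprintf("dimension mismatch: model has %d features, x has %d",
                 length(model$w), ncol(x)))
  }
  mid <- (model$mu0 + model$mu1) / 2
  score <- sweep(x, 2, mid) %*% model$w +
    log(model$priors["p1"] / model$priors["p0"])
  stats::plogis(as.numeric(score))
}

#' Fit the per-amino-acid-type classifier bundle from datamarts
#'
#' For each datamart: correlated columns are pruned at `cor_threshold`, a
#' correlation-matrix PCA retaining `variance_target` of the training
#' variance is fitted, and an LDA model is trained on the component
#' scores. The bundle keeps, per type, the retained column list, the PCA
#' projection and the LDA model, together with the decision cutoff and the
#' contact-energy maxima of the training corpus (when supplied).
#'
#' @param marts named list of `ifr_datamart` objects (from
#'   [build_datamarts()] or [make_gaussian_mart()]).
#' @param config an [ifr_config()].
#' @param max_table training-corpus contact-energy maxima
#'   ([contact_energy_maxima()]); carried for prediction-time unused
#'   energies.
#' @param k_override named integer vector fixing the per-type retained
#'   component counts (cross-validation freezes these from the first
#'   fold).
#' @return An `ifr_bundle` object.
#' @export
fit_ifr_bundle <- function(marts, config = ifr_config(), max_table = NULL,
                           k_override = NULL) {
  models <- list()
  for (tp in names(marts)) {
    m <- marts[[tp]]
    pruned <- drop_correlated(m$x, config$cor_threshold)
    pca <- fit_pca(pruned$data, config$variance_target,
                   k_override = k_override[[tp]])
    scores <- project(pca, pruned$data)
    lda <- fit_lda(scores, m$y)
    models[[tp]] <- list(columns = names(pruned$data),
                         removed = pruned$removed$column,
                         pca = pca, lda = lda)
  }
  structure(
    list(models = models, cutoff = config$decision_cutoff,
         max_table = max_table, config = unclass(config),
         seed = config$seed),
    class = "ifr_bundle"
  )
}

#' @export
print.ifr_bundle <- function(x, ...) {
  ks <- vapply(x$models, function(m) m$pca$k, 0L)
  cat(sprintf("<ifr_bundle> %d type-specific model(s) [%s], cutoff %.2f\n",
              length(x$models), paste(names(x$models), collapse = ","),
              x$cutoff))
  cat("  retained components per type: ",
      paste(sprintf("%s=%d", names(ks), ks), collapse = " "), "\n")
  invisible(x)
}

#' Score rows of a labeled descriptor table with a bundle
#'
#' Routes each surface residue to its amino-acid-type model and returns
#' interface posteriors; types without a model are reported unpredicted.
#'
#' @param bundle an `ifr_bundle`.
#' @param desc descriptor tibble with `res_type` and the feature columns
#'   the bundle was trained on.
#' @return tibble `res_uid`, `res_type`, `p_ifr`, `predicted_cls`.
#' @keywords internal
score_descriptors <- function(bundle, desc) {
  out <- tibble::tibble(res_uid = desc$res_uid, res_type = desc$res_type,
                        p_ifr = NA_real_, predicted_cls = NA_character_)
  for (tp in unique(desc$res_type)) {
    mdl <- bundle$models[[tp]]
    rows <- which(desc$res_type == tp)
    if (is.null(mdl)) next
    x <- desc[rows, mdl$columns, drop = FALSE]
    cc <- stats::complete.cases(x)
    if (!any(cc)) next
    sc <- project(mdl$pca, x[cc, , drop = FALSE])
    p <- posterior(mdl$lda, sc)
    out$p_ifr[rows[cc]] <- p
    out$predicted_cls[rows[cc]] <- ifelse(p >= bundle$cutoff, "IFR", "FSR")
  }
  out
}

#' Predict interface residues of a structure
#'
#' End-to-end application of a fitted bundle: label accessibility, compute
#' the descriptor suite, add unused contact energies from the bundle's
#' training-corpus maxima, append weighted neighbor averages, and score
#' each surface residue with its amino-acid-type model. Buried residues
#' are reported without a prediction, as are residue types lacking a
#' model.
#'
#' @param bundle an `ifr_bundle`.
#' @param complex a `complex_structure`.
#' @param cutoff posterior decision cutoff; defaults to the bundle's.
#' @param config an [ifr_config()]; defaults to the bundle's training
#'   configuration.
#' @return tibble: `pdb_id`, `chain`, `res_seq`, `ins`, `res_type`,
#'   `cls` (surface labeling), `p_ifr`, `predicted_cls` (`"IFR"`/`"FSR"`,
#'   `NA` when unpredicted), `cutoff`.
#' @export
predict_structure <- function(bundle, complex, cutoff = NULL, config = NULL) {
  if (is.null(config)) config <- do.call(ifr_config, bundle$config)
  if (is.null(cutoff)) cutoff <- bundle$cutoff
  labels <- label_residues(complex, config)
  desc <- compute_descriptors(complex, labels, config)
  if (!is.null(bundle$max_table)) {
    un <- unused_contact_energy(desc, bundle$max_table)
    desc <- dplyr::left_join(desc, un, by = "res_uid")
  }
  desc <- wna_augment(desc, config)
  b <- bundle
  b$cutoff <- cutoff
  sc <- score_descriptors(b, desc[desc$cls %in% c("IFR", "FSR"), , drop = FALSE])
  out <- labels[, c("chain", "res_seq", "ins", "res_type", "cls")]
  out$pdb_id <- complex$pdb_id
  key <- paste(out$chain, out$res_seq, out$ins, sep = "_")
  out$p_ifr <- sc$p_ifr[match(key, sc$res_uid)]
  out$predicted_cls <- sc$predicted_cls[match(key, sc$res_uid)]
  out$cutoff <- cutoff
  out[, c("pdb_id", "chain", "res_seq", "ins", "res_type", "cls",
          "p_ifr", "predicted_cls", "cutoff")]
}

#' Aggregate per-type prediction tables into one
#'
#' Concatenates the disjoint per-amino-acid-type outputs into a single
#' table ordered by chain and residue number; scores are never
#' recalibrated across types.
#'
#' @param per_type list of prediction tibbles (one per amino-acid type).
#' @return single tibble ordered by `chain`, `res_seq`, `ins`.
#' @export
aggregate_predictions <- function(per_type) {
  out <- dplyr::bind_rows(per_type)
  key <- paste(out$pdb_id %||% "", out$chain, out$res_seq, out$ins)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate residue(s) across per-type predictions")
  }
  dplyr::arrange(out, .data$chain, .data$res_seq, .data$ins)
}

#' Persist a classifier bundle as JSON
#'
#' Exact reload: means, covariances, priors, projections, column lists,
#' maxima table and cutoff are written with full precision.
#'
#' @param bundle an `ifr_bundle`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  ser <- list(
    format = "ifr_bundle",
    version = 1L,
    cutoff = bundle$cutoff,
    seed = bundle$seed,
    config = bundle$config,
    max_table = bundle$max_table,
    models = lapply(bundle$models, function(m) list(
      columns = m$columns,
      removed = m$removed,
      pca = list(columns = m$pca$columns, means = m$pca$means,
                 sds = m$pca$sds, rotation = m$pca$rotation,
                 eigenvalues = m$pca$eigenvalues, k = m$pca$k,
                 cum_var = m$pca$cum_var,
                 variance_target = m$pca$variance_target),
      lda = list(mu0 = m$lda$mu0, mu1 = m$lda$mu1, sigma = m$lda$sigma,
                 priors = m$lda$priors, w = m$lda$w, n = m$lda$n)
    ))
  )
  json <- jsonlite::toJSON(ser, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a classifier bundle written by [write_bundle()]
#'
#' @param path JSON file.
#' @return an `ifr_bundle`.
#' @export
read_bundle <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(s$format, "ifr_bundle") || !identical(as.integer(s$version), 1L)) {
    stop("not a compatible classifier bundle file: ", path)
  }
  models <- lapply(s$models, function(m) {
    pca <- structure(list(
      columns = m$pca$columns,
      means = stats::setNames(unlist(m$pca$means), m$pca$columns),
      sds = stats::setNames(unlist(m$pca$sds), m$pca$columns),
      rotation = as.matrix(m$pca$rotation),
      eigenvalues = as.numeric(m$pca$eigenvalues),
      k = as.integer(m$pca$k), cum_var = m$pca$cum_var,
      variance_target = m$pca$variance_target), class = "ifr_pca")
    lda <- structure(list(
      mu0 = as.numeric(unlist(m$lda$mu0)), mu1 = as.numeric(unlist(m$lda$mu1)),
      sigma = as.matrix(m$lda$sigma),
      priors = stats::setNames(unlist(m$lda$priors), c("p0", "p1")),
      w = as.numeric(unlist(m$lda$w)),
      n = stats::setNames(as.integer(unlist(m$lda$n)), c("n0", "n1"))),
      class = "ifr_lda")
    list(columns = m$columns, removed = m$removed, pca = pca, lda = lda)
  })
  structure(list(models = models, cutoff = s$cutoff,
                 max_table = if (!is.null(s$max_table)) tibble::as_tibble(s$max_table),
                 config = s$config, seed = s$seed),
            class = "ifr_bundle")
}
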