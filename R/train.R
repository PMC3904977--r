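# End-to-end training: structures -> labels -> descriptor suite ->
# unused energies (training-corpus maxima) -> neighbor averages ->
# per-type datamarts -> pruning/PCA/LDA, with entry-level cross-validation.

prepare_entry <- function(complex, config) {
  labels <- label_residues(complex, config)
  desc <- compute_descriptors(complex, labels, config)
  desc$pdb_id <- complex$pdb_id
  desc
}

finish_descriptors <- function(desc, max_table, config) {
  un <- unused_contact_energy(desc, max_table)
  desc <- dplyr::left_join(desc, un, by = "res_uid")
  wna_augment(desc, config)
}

#' Train a classifier bundle on a corpus of complexes
#'
#' Full training path: each structure is surface-labeled and converted to
#' the descriptor table; contact-energy maxima over the whole corpus
#' define the unused energies; weighted neighbor averages are appended;
#' per-amino-acid-type datamarts are assembled, pruned at the correlation
#' threshold, projected onto principal components retaining the variance
#' target, and a linear discriminant model is fitted per type. Types
#' lacking both classes are omitted with a warning.
#'
#' @param corpus list of `complex_structure` objects (or a directory of
#'   PDB files).
#' @param config an [ifr_config()].
#' @return an `ifr_bundle` (with the corpus maxima table attached) plus a
#'   `mart_log` attribute describing per-type row/column drops.
#' @export
train_ifr <- function(corpus, config = ifr_config()) {
  if (is.character(corpus) && length(corpus) == 1 && dir.exists(corpus)) {
    corpus <- lapply(list.files(corpus, pattern = "\\.pdb$", full.names = TRUE),
                     parse_pdb)
  }
  descs <- lapply(corpus, prepare_entry, config = config)
  all_desc <- dplyr::bind_rows(descs)
  all_desc$res_uid <- paste(all_desc$pdb_id, all_desc$res_uid, sep = ":")
  max_table <- contact_energy_maxima(all_desc)
  finished <- dplyr::bind_rows(lapply(descs, function(d) {
    d2 <- finish_descriptors(d, max_table, config)
    d2$res_uid <- paste(d2$pdb_id, d2$res_uid, sep = ":")
    d2
  }))
  finished$pdb_id <- NULL
  dm <- build_datamarts(finished)
  absent <- dm$log$res_type[!dm$log$kept]
  if (length(absent) > 0) {
    warning("type(s) without both classes omitted: ",
            paste(absent, collapse = ", "))
  }
  bundle <- fit_ifr_bundle(dm$marts, config, max_table = max_table)
  attr(bundle, "mart_log") <- dm$log
  bundle
}

#' Entry-level cross-validation of the full training path
#'
#' Splits the corpus into `k_folds` folds by PDB entry (never by residue).
#' Within every fold the contact-energy maxima, correlation pruning, PCA
#' and LDA are all fitted on the training entries only; retained component
#' counts are frozen from the first fold. Held-out residues are scored
#' with their type models and pooled into an aggregated per-fold
#' AUC/max-MCC.
#'
#' @param corpus list of `complex_structure` objects.
#' @param config an [ifr_config()].
#' @return tibble with `fold`, `classifier` (`"aggregated"` or a type),
#'   `auc`, `max_mcc`, `n_test`; fitted-parameter fingerprints per fold are
#'   attached as attribute `fingerprints`.
#' @export
cross_validate_ifr <- function(corpus, config = ifr_config()) {
  ids <- vapply(corpus, function(e) e$pdb_id, "")
  if (anyDuplicated(ids)) stop("corpus entries must have unique pdb ids")
  fa <- kfold_split(ids, config$k_folds, config$seed)
  descs <- lapply(corpus, prepare_entry, config = config)
  names(descs) <- ids
  k_frozen <- NULL
  out <- list()
  fingerprints <- list()
  for (f in sort(unique(fa$fold))) {
    test_ids <- fa$id[fa$fold == f]
    train_ids <- setdiff(ids, test_ids)
    tr_raw <- dplyr::bind_rows(descs[train_ids])
    max_table <- contact_energy_maxima(tr_raw)
    fin <- function(id_set) {
      d <- dplyr::bind_rows(lapply(descs[id_set], function(d) {
        d2 <- finish_descriptors(d, max_table, config)
        d2$res_uid <- paste(d2$pdb_id, d2$res_uid, sep = ":")
        d2
      }))
      d$pdb_id <- NULL
      d
    }
    tr <- fin(train_ids)
    te <- fin(test_ids)
    dm <- build_datamarts(tr)
    bundle <- fit_ifr_bundle(dm$marts, config, max_table = max_table,
                             k_override = k_frozen)
    if (is.null(k_frozen)) {
      k_frozen <- lapply(bundle$models, function(m) m$pca$k)
    }
    fingerprints[[as.character(f)]] <- list(
      max_table = max_table,
      pca_means = lapply(bundle$models, function(m) unname(m$pca$means)))
    te_surf <- te[te$cls %in% c("IFR", "FSR"), , drop = FALSE]
    sc <- score_descriptors(bundle, te_surf)
    truth <- as.integer(te_surf$cls == "IFR")
    ok <- !is.na(sc$p_ifr)
    if (length(unique(truth[ok])) == 2) {
      r <- roc_auc(sc$p_ifr[ok], truth[ok])
      out[[length(out) + 1]] <- tibble::tibble(
        fold = f, classifier = "aggregated", auc = r$auc,
        max_mcc = r$max_mcc, n_test = sum(ok))
    }
    for (tp in unique(te_surf$res_type)) {
      sel <- ok & te_surf$res_type == tp
      if (length(unique(truth[sel])) == 2) {
        r <- roc_auc(sc$p_ifr[sel], truth[sel])
        out[[length(out) + 1]] <- tibble::tibble(
          fold = f, classifier = tp, auc = r$auc, max_mcc = r$max_mcc,
          n_test = sum(sel))
      }
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "fingerprints") <- fingerprints
  res
}
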