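# Interface labeling by accessibility change upon complexation, interface
# areas and size classes, the sequential dataset filter chain, and greedy
# sequence-redundancy reduction.

#' Label residues as interface-forming, free-surface or buried
#'
#' Computes each residue's solvent accessibility twice: with its chain in
#' isolation and within the full complex. A residue losing more than
#' `delta_area` of accessible area upon complexation is an interface-forming
#' residue (IFR); otherwise it is a free-surface residue (FSR) when its
#' relative accessibility (isolation area over the type-specific theoretical
#' maximum) reaches `exposure_min`, and buried below that. A single-chain
#' structure has no IFRs by construction.
#'
#' @param complex a `complex_structure`.
#' @param config an [ifr_config()] (uses `probe_radius`, `n_points`,
#'   `delta_area`, `exposure_min`).
#' @return tibble with one row per residue: locators, `res_type`,
#'   `acc_isolation`, `acc_complex` (square angstrom), `relative_acc`, `cls`
#'   in `{"IFR","FSR","BURIED"}`, and the CA coordinates used by downstream
#'   spatial descriptors.
#' @export
#' @examples
#' cx <- parse_pdb(make_toy_complex(toy_complex_spec(n_residues = 5))$text)
#' table(label_residues(cx, ifr_config(n_points = 120))$cls)
label_residues <- function(complex, config = ifr_config()) {
  at <- complex$atoms
  res <- residues(complex)
  iso <- dplyr::bind_rows(lapply(unique(at$chain), function(ch) {
    residue_sasa(at[at$chain == ch, ], config$probe_radius, config$n_points)
  }))
  names(iso)[names(iso) == "area"] <- "acc_isolation"
  cpx <- residue_sasa(at, config$probe_radius, config$n_points)
  names(cpx)[names(cpx) == "area"] <- "acc_complex"
  lab <- res |>
    dplyr::left_join(iso, by = c("chain", "res_seq", "ins")) |>
    dplyr::left_join(cpx, by = c("chain", "res_seq", "ins")) |>
    dplyr::mutate(
      relative_acc = .data$acc_isolation / unname(MAX_ASA[.data$res_type]),
      cls = dplyr::case_when(
        .data$acc_isolation - .data$acc_complex > config$delta_area ~ "IFR",
        .data$relative_acc >= config$exposure_min ~ "FSR",
        TRUE ~ "BURIED"
      )
    )
  lab[, c("chain", "res_seq", "ins", "res_type", "res_uid", "seq_index",
          "acc_isolation", "acc_complex", "relative_acc", "cls",
          "ca_x", "ca_y", "ca_z")]
}

#' Interface area of a chain
#'
#' Buried area: the summed per-residue accessibility lost upon
#' complexation (clipped at zero per residue).
#'
#' @param labels output of [label_residues()].
#' @param chain_id chain identifier.
#' @return area in square angstrom.
#' @export
interface_area <- function(labels, chain_id) {
  sub <- labels[labels$chain == chain_id, ]
  if (nrow(sub) == 0) stop("unknown chain_id: ", chain_id)
  sum(pmax(sub$acc_isolation - sub$acc_complex, 0))
}

#' Interface size class
#'
#' Interfaces up to 800 square angstrom are "small", between 800 and 3000
#' "medium", larger than 3000 "large".
#'
#' @param area interface area(s) in square angstrom; must be non-negative.
#' @return character vector in `{"SMALL","MEDIUM","LARGE"}`.
#' @export
#' @examples
#' size_class(c(0, 800, 1500, 3500))
size_class <- function(area) {
  if (any(area < 0)) stop("interface area must be non-negative")
  dplyr::case_when(area <= 800 ~ "SMALL", area <= 3000 ~ "MEDIUM",
                   TRUE ~ "LARGE")
}

#' Per-chain interface summary
#'
#' @param labels output of [label_residues()].
#' @return tibble with `chain`, `interface_area`, `size_class`, `n_ifr`.
#' @export
interface_summary <- function(labels) {
  labels |>
    dplyr::group_by(chain_id = .data$chain) |>
    dplyr::summarise(
      interface_area = sum(pmax(.data$acc_isolation - .data$acc_complex, 0)),
      n_ifr = sum(.data$cls == "IFR"),
      .groups = "drop"
    ) |>
    dplyr::mutate(size_class = size_class(.data$interface_area))
}

#' Sequential dataset filter chain
#'
#' Applies, in order: crystallographic resolution at most `max_resolution`;
#' no non-protein polymer chains; consistent oligomeric state (metadata
#' flag); at least two chains; every chain at least `min_chain_length`
#' residues; interface area at least `min_interface_area` (largest per-chain
#' buried area); not a sequence fragment (metadata flag). Each rejected
#' entry is attributed to the first filter it fails.
#'
#' @param entries list of `complex_structure` objects.
#' @param config an [ifr_config()] supplying `max_resolution`,
#'   `min_chain_length`, `min_interface_area` and the accessibility
#'   parameters.
#' @return list with `kept` (the surviving entries) and `log` (tibble:
#'   `pdb_id`, `kept`, `rejected_by`).
#' @export
filter_dataset <- function(entries, config = ifr_config()) {
  log <- tibble::tibble(pdb_id = vapply(entries, function(e) e$pdb_id, ""),
                        kept = TRUE, rejected_by = NA_character_)
  kept <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    res <- residues(e)
    chain_len <- table(res$chain)
    reject <- NULL
    if (is.na(e$resolution) || e$resolution > config$max_resolution) {
      reject <- "resolution"
    } else if (length(e$nonprotein_chains) > 0) {
      reject <- "non_protein_chains"
    } else if (!isTRUE(e$oligomeric_state_consistent)) {
      reject <- "oligomeric_state"
    } else if (length(chain_len) < 2) {
      reject <- "n_chains"
    } else if (min(chain_len) < config$min_chain_length) {
      reject <- "chain_length"
    } else {
      labs <- label_residues(e, config)
      areas <- vapply(names(chain_len), function(ch) interface_area(labs, ch), 0)
      if (max(areas) < config$min_interface_area) reject <- "interface_area"
      else if (isTRUE(e$is_fragment)) reject <- "fragment"
    }
    if (is.null(reject)) {
      kept[[length(kept) + 1]] <- e
    } else {
      log$kept[i] <- FALSE
      log$rejected_by[i] <- reject
    }
  }
  list(kept = kept, log = log)
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, gap opening 10,
#' gap extension 0.5); identity is matches over alignment length.
#'
#' @param a,b amino-acid sequences (one-letter strings).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  letters20 <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]], unname(AA1)))
  m <- diag(1, length(letters20))
  dimnames(m) <- list(letters20, letters20)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = m,
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Greedy sequence-redundancy reduction
#'
#' Chains are sorted by length (descending) and greedily clustered: a chain
#' joins an existing cluster when its global-alignment identity to the
#' cluster representative exceeds `identity_cutoff`, otherwise it founds a
#' new cluster. Cluster representatives (the longest member) are returned;
#' no two representatives exceed the cutoff.
#'
#' @param chains tibble with columns `chain_id` and `sequence`, or a named
#'   character vector of sequences.
#' @param identity_cutoff identity fraction above which chains are redundant
#'   (default 0.30).
#' @return tibble of representatives with `chain_id`, `sequence`, `cluster`
#'   (1-based), plus a `members` list-column of clustered chain ids.
#' @export
redundancy_reduce <- function(chains, identity_cutoff = 0.30) {
  if (is.character(chains)) {
    chains <- tibble::tibble(chain_id = names(chains) %||% as.character(seq_along(chains)),
                             sequence = unname(chains))
  }
  chains <- chains[nchar(chains$sequence) > 0 | {
    if (any(nchar(chains$sequence) == 0)) warning("skipping chains with empty sequence")
    FALSE
  }, ]
  ord <- order(-nchar(chains$sequence))
  chains <- chains[ord, ]
  reps <- integer()      # row indices of representatives
  cluster_of <- integer(nrow(chains))
  members <- list()
  for (i in seq_len(nrow(chains))) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(chains$sequence[i], chains$sequence[reps[k]]) >
            identity_cutoff) {
        cluster_of[i] <- k
        members[[k]] <- c(members[[k]], chains$chain_id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      cluster_of[i] <- length(reps)
      members[[length(reps)]] <- chains$chain_id[i]
    }
  }
  tibble::tibble(
    chain_id = chains$chain_id[reps],
    sequence = chains$sequence[reps],
    cluster = seq_along(reps),
    members = members
  )
}
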