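# Typed residue-residue contact detection and contact energies.
#
# The energy table (kcal/mol): hydrophobic 0.6, aromatic stacking 1.5,
# hydrogen bond 2.6 (all direct and water-mediated subtypes), charged pair
# (salt bridge) 10.0, cysteine bridge 85.0. Geometric criteria are
# config-exposed; see ifr_config(). Charged, aromatic and disulfide
# contacts are recorded once per residue pair (group-level interactions);
# hydrogen bonds and hydrophobic contacts once per qualifying atom pair.
# Residues adjacent in sequence are never contact partners (covalent
# neighborhood).

res_uid_of <- function(tb) paste(tb$chain, tb$res_seq, tb$ins, sep = "_")

#' Detect typed residue contacts in a complex
#'
#' Scans the structure for hydrophobic (apolar carbon pairs), aromatic
#' (ring-centroid), hydrogen-bond (N/O donor-acceptor pairs, subtyped
#' main-chain/side-chain and water-mediated via one or two bridging
#' waters), charged attractive/repulsive (side-chain charged groups) and
#' disulfide contacts. Atom pairs belonging to two charged side-chain
#' groups are classified as charged contacts, not hydrogen bonds.
#'
#' @param complex a `complex_structure` (waters are used for the
#'   water-mediated hydrogen-bond subtypes).
#' @param config an [ifr_config()] supplying the distance cutoffs.
#' @param intra_only if `TRUE`, only contacts within a chain are reported
#'   (the "internal" contact set used for descriptor computation).
#' @return tibble with one row per contact: `uid1`, `uid2` (residue ids),
#'   `chain1`, `chain2`, `seq_sep` (|sequence separation|, `NA` across
#'   chains), `contact_type`, `energy` (kcal/mol), `distance` (angstrom),
#'   and the contact midpoint `mx`, `my`, `mz`.
#' @export
detect_contacts <- function(complex, config = ifr_config(), intra_only = FALSE) {
  at <- complex$atoms
  at$uid <- res_uid_of(at)
  res <- residues(complex)
  seq_idx <- stats::setNames(res$seq_index, res$res_uid)
  chain_of <- stats::setNames(res$chain, res$res_uid)

  empty <- tibble::tibble(uid1 = character(), uid2 = character(),
                          chain1 = character(), chain2 = character(),
                          seq_sep = integer(), contact_type = character(),
                          energy = double(), distance = double(),
                          mx = double(), my = double(), mz = double())
  recs <- list(empty)

  pair_ok <- function(u1, u2) {
    if (u1 == u2) return(FALSE)
    if (chain_of[u1] == chain_of[u2] &&
          abs(seq_idx[u1] - seq_idx[u2]) <= 1L) return(FALSE)
    if (intra_only && chain_of[u1] != chain_of[u2]) return(FALSE)
    TRUE
  }
  add <- function(u1, u2, type, d, mid) {
    if (u1 > u2) { tmp <- u1; u1 <- u2; u2 <- tmp }
    sep <- if (chain_of[u1] == chain_of[u2])
      abs(seq_idx[u1] - seq_idx[u2]) else NA_integer_
    tibble::tibble(uid1 = u1, uid2 = u2,
                   chain1 = unname(chain_of[u1]), chain2 = unname(chain_of[u2]),
                   seq_sep = as.integer(sep), contact_type = type,
                   energy = unname(CONTACT_ENERGY[type]), distance = d,
                   mx = mid[1], my = mid[2], mz = mid[3])
  }
  xyz <- function(rows) as.matrix(at[rows, c("x", "y", "z")])

  # charged-group membership per atom (for hydrogen-bond exclusion)
  in_charged <- rep(FALSE, nrow(at))
  for (tp in names(CHARGED_GROUPS)) {
    g <- CHARGED_GROUPS[[tp]]
    in_charged[at$res_type == tp & at$atom %in% g$atoms] <- TRUE
  }

  # ---- disulfide: SG-SG
  sg <- which(at$res_type == "CYS" & at$atom == "SG")
  if (length(sg) >= 2) {
    for (a in seq_along(sg)) for (b in seq_along(sg)) {
      if (a >= b) next
      i <- sg[a]; j <- sg[b]
      if (!pair_ok(at$uid[i], at$uid[j])) next
      d <- sqrt(sum((xyz(i) - xyz(j))^2))
      if (d <= config$disulfide_cut) {
        recs[[length(recs) + 1]] <- add(at$uid[i], at$uid[j], "DISULFIDE", d,
                                        (xyz(i) + xyz(j)) / 2)
      }
    }
  }

  # ---- charged groups: one record per residue pair, min atom distance
  grp <- list()
  for (tp in names(CHARGED_GROUPS)) {
    g <- CHARGED_GROUPS[[tp]]
    rows <- which(at$res_type == tp & at$atom %in% g$atoms)
    for (u in unique(at$uid[rows])) {
      grp[[length(grp) + 1]] <- list(uid = u, rows = rows[at$uid[rows] == u],
                                     sign = g$sign)
    }
  }
  if (length(grp) >= 2) {
    for (a in seq_along(grp)) for (b in seq_along(grp)) {
      if (a >= b) next
      ga <- grp[[a]]; gb <- grp[[b]]
      if (!pair_ok(ga$uid, gb$uid)) next
      pa <- xyz(ga$rows); pb <- xyz(gb$rows)
      dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
                    Vectorize(function(i, j) sqrt(sum((pa[i, ] - pb[j, ])^2))))
      d <- min(dmat)
      if (d <= config$charged_cut) {
        w <- which(dmat == d, arr.ind = TRUE)[1, ]
        type <- if (ga$sign * gb$sign < 0) "CHARGED_ATTRACTIVE" else "CHARGED_REPULSIVE"
        recs[[length(recs) + 1]] <- add(ga$uid, gb$uid, type, d,
                                        (pa[w[1], ] + pb[w[2], ]) / 2)
      }
    }
  }

  # ---- aromatic: ring-centroid pairs
  rings <- list()
  for (tp in names(AROMATIC_RING)) {
    rows <- which(at$res_type == tp & at$atom %in% AROMATIC_RING[[tp]])
    for (u in unique(at$uid[rows])) {
      rr <- rows[at$uid[rows] == u]
      if (length(rr) >= 3) {
        rings[[length(rings) + 1]] <- list(uid = u, c = colMeans(xyz(rr)))
      }
    }
  }
  if (length(rings) >= 2) {
    for (a in seq_along(rings)) for (b in seq_along(rings)) {
      if (a >= b) next
      ra <- rings[[a]]; rb <- rings[[b]]
      if (!pair_ok(ra$uid, rb$uid)) next
      d <- sqrt(sum((ra$c - rb$c)^2))
      if (d <= config$aromatic_cut) {
        recs[[length(recs) + 1]] <- add(ra$uid, rb$uid, "AROMATIC", d,
                                        (ra$c + rb$c) / 2)
      }
    }
  }

  # ---- hydrophobic: apolar carbon pairs
  apolar <- rep(FALSE, nrow(at))
  for (tp in names(APOLAR_CARBONS)) {
    apolar[at$res_type == tp & at$atom %in% APOLAR_CARBONS[[tp]]] <- TRUE
  }
  ap <- which(apolar)
  if (length(ap) >= 2) {
    p <- xyz(ap)
    dd <- as.matrix(stats::dist(p))
    hit <- which(dd <= config$hydrophobic_cut & upper.tri(dd), arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- ap[hit[r, 1]]; j <- ap[hit[r, 2]]
      if (!pair_ok(at$uid[i], at$uid[j])) next
      recs[[length(recs) + 1]] <- add(at$uid[i], at$uid[j], "HYDROPHOBIC",
                                      dd[hit[r, 1], hit[r, 2]],
                                      (xyz(i) + xyz(j)) / 2)
    }
  }

  # ---- hydrogen bonds: N/O - N/O atom pairs (excluding charged-charged)
  no <- which(at$element %in% c("N", "O"))
  hb_pairs <- NULL
  if (length(no) >= 2) {
    p <- xyz(no)
    dd <- as.matrix(stats::dist(p))
    hit <- which(dd <= config$hbond_cut & upper.tri(dd), arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- no[hit[r, 1]]; j <- no[hit[r, 2]]
      if (in_charged[i] && in_charged[j]) next
      if (!pair_ok(at$uid[i], at$uid[j])) next
      cls_i <- if (at$atom[i] %in% MAIN_CHAIN_ATOMS) "M" else "S"
      cls_j <- if (at$atom[j] %in% MAIN_CHAIN_ATOMS) "M" else "S"
      type <- if (cls_i == "M" && cls_j == "M") "HB_MM"
              else if (cls_i == "S" && cls_j == "S") "HB_SS" else "HB_MS"
      recs[[length(recs) + 1]] <- add(at$uid[i], at$uid[j], type,
                                      dd[hit[r, 1], hit[r, 2]],
                                      (xyz(i) + xyz(j)) / 2)
    }
  }

  # ---- water-mediated hydrogen bonds
  wat <- complex$waters
  if (nrow(wat) > 0 && length(no) > 0) {
    wxyz <- as.matrix(wat[, c("x", "y", "z")])
    p <- xyz(no)
    # protein polar atoms H-bonded to each water
    partners <- lapply(seq_len(nrow(wat)), function(w) {
      d <- sqrt(colSums((t(p) - wxyz[w, ])^2))
      no[d <= config$hbond_cut]
    })
    hb_type_w <- function(i, j, n_w) {
      cls_i <- if (at$atom[i] %in% MAIN_CHAIN_ATOMS) "M" else "S"
      cls_j <- if (at$atom[j] %in% MAIN_CHAIN_ATOMS) "M" else "S"
      cl <- sort(c(cls_i, cls_j))            # "M" before "S"
      bridge <- paste(rep("W", n_w), collapse = "")
      paste0("HB_", cl[1], bridge, cl[2])    # e.g. HB_MWS, HB_SWWS
    }
    seen <- character()
    for (w in seq_along(partners)) {
      pr <- partners[[w]]
      if (length(pr) >= 2) {
        for (a in seq_along(pr)) for (b in seq_along(pr)) {
          if (a >= b) next
          i <- pr[a]; j <- pr[b]
          if (!pair_ok(at$uid[i], at$uid[j])) next
          key <- paste(min(at$uid[i], at$uid[j]), max(at$uid[i], at$uid[j]), "W", w)
          if (key %in% seen) next
          seen <- c(seen, key)
          recs[[length(recs) + 1]] <- add(at$uid[i], at$uid[j],
                                          hb_type_w(i, j, 1L),
                                          sqrt(sum((xyz(i) - xyz(j))^2)),
                                          (xyz(i) + xyz(j)) / 2)
        }
      }
    }
    if (nrow(wat) >= 2) {
      wdd <- as.matrix(stats::dist(wxyz))
      wpair <- which(wdd <= config$hbond_cut & upper.tri(wdd), arr.ind = TRUE)
      for (r in seq_len(nrow(wpair))) {
        p1 <- partners[[wpair[r, 1]]]
        p2 <- partners[[wpair[r, 2]]]
        for (i in p1) for (j in p2) {
          if (at$uid[i] == at$uid[j]) next
          if (!pair_ok(at$uid[i], at$uid[j])) next
          key <- paste(min(at$uid[i], at$uid[j]), max(at$uid[i], at$uid[j]),
                       "WW", wpair[r, 1], wpair[r, 2])
          if (key %in% seen) next
          seen <- c(seen, key)
          recs[[length(recs) + 1]] <- add(at$uid[i], at$uid[j],
                                          hb_type_w(i, j, 2L),
                                          sqrt(sum((xyz(i) - xyz(j))^2)),
                                          (xyz(i) + xyz(j)) / 2)
        }
      }
    }
  }

  out <- dplyr::bind_rows(recs)
  dplyr::arrange(out, .data$uid1, .data$uid2, .data$contact_type)
}

#' Per-residue contact energy sums
#'
#' Sums the energies of all contacts incident to each residue, per contact
#' type and in total.
#'
#' @param contacts output of [detect_contacts()].
#' @param res_uids residue ids to report (rows with no contacts get zeros);
#'   defaults to the residues appearing in `contacts`.
#' @return tibble with `res_uid`, one `Energy_<type>` column per contact
#'   type, and `Energy_Total` (kcal/mol).
#' @export
contact_energy <- function(contacts, res_uids = NULL) {
  if (is.null(res_uids)) res_uids <- sort(unique(c(contacts$uid1, contacts$uid2)))
  long <- dplyr::bind_rows(
    contacts[, c("uid1", "contact_type", "energy")] |> dplyr::rename(res_uid = "uid1"),
    contacts[, c("uid2", "contact_type", "energy")] |> dplyr::rename(res_uid = "uid2")
  )
  out <- tibble::tibble(res_uid = res_uids)
  for (tp in CONTACT_TYPES) {
    s <- long |>
      dplyr::filter(.data$contact_type == tp) |>
      dplyr::group_by(.data$res_uid) |>
      dplyr::summarise(v = sum(.data$energy), .groups = "drop")
    out[[paste0("Energy_", tp)]] <- s$v[match(res_uids, s$res_uid)]
  }
  out[is.na(out)] <- 0
  out$Energy_Total <- rowSums(out[, paste0("Energy_", CONTACT_TYPES)])
  out
}

#' Corpus maxima of contact energies per amino-acid type
#'
#' Scans a training corpus' per-residue energies for the maximum realized
#' contact energy of each amino-acid type (per contact type and total).
#' These maxima define the unused contact energies and are persisted with a
#' fitted classifier bundle.
#'
#' @param energies tibble combining [contact_energy()] outputs with a
#'   `res_type` column.
#' @return tibble with `res_type` and the per-column maxima.
#' @export
contact_energy_maxima <- function(energies) {
  cols <- grep("^Energy_", names(energies), value = TRUE)
  energies |>
    dplyr::group_by(.data$res_type) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), max), .groups = "drop")
}

#' Unused contact energies
#'
#' The gap between an amino-acid type's corpus maximum contact energy and a
#' residue's realized energy (its unexploited binding potential), floored
#' at zero, per contact type and total.
#'
#' @param energies [contact_energy()] output with a `res_type` column.
#' @param max_table [contact_energy_maxima()] of the training corpus.
#' @return tibble with `res_uid` and `Unused_<type>` / `Unused_Total`
#'   columns (kcal/mol, all non-negative).
#' @export
unused_contact_energy <- function(energies, max_table) {
  missing_types <- setdiff(unique(energies$res_type), max_table$res_type)
  if (length(missing_types) > 0) {
    stop("amino acid type(s) absent from maxima table: ",
         paste(missing_types, collapse = ", "))
  }
  cols <- grep("^Energy_", names(energies), value = TRUE)
  idx <- match(energies$res_type, max_table$res_type)
  out <- tibble::tibble(res_uid = energies$res_uid)
  for (cl in cols) {
    out[[sub("^Energy_", "Unused_", cl)]] <-
      pmax(max_table[[cl]][idx] - energies[[cl]], 0)
  }
  out
}
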