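# Per-residue descriptor suite: cross-link/cross-presence order, local
# density and sponge, hydrophobicity, screened-Coulomb electrostatic
# potential, contact energy density, and the weighted neighbor averages.
#
# Contact-derived descriptors use intra-chain ("internal") contacts only,
# and the electrostatic potential sums a chain's own charged groups, so the
# full suite is computable for an unbound chain. Density and sponge probe
# spheres see all protein atoms of the structure.

sphere_volume <- function(r) 4 / 3 * pi * r^3

#' Cross-link order (CLO)
#'
#' Number of distinct contact partners of a residue separated by at least
#' `min_seq_sep` positions in the same chain.
#'
#' @param contacts intra-chain contacts from
#'   `detect_contacts(..., intra_only = TRUE)`.
#' @param res_uids residues to report.
#' @param min_seq_sep minimum sequence separation (default 30).
#' @return tibble with `res_uid` and `CLO`.
#' @export
clo <- function(contacts, res_uids, min_seq_sep = 30L) {
  far <- contacts[!is.na(contacts$seq_sep) & contacts$seq_sep >= min_seq_sep, ]
  long <- dplyr::bind_rows(
    tibble::tibble(res_uid = far$uid1, partner = far$uid2),
    tibble::tibble(res_uid = far$uid2, partner = far$uid1)
  )
  cnt <- long |>
    dplyr::distinct() |>
    dplyr::count(.data$res_uid, name = "CLO")
  out <- tibble::tibble(res_uid = res_uids)
  out$CLO <- cnt$CLO[match(res_uids, cnt$res_uid)]
  out$CLO[is.na(out$CLO)] <- 0L
  out
}

#' Cross-presence order (CPO)
#'
#' Number of residues of the same chain whose anchor atom lies within
#' `radius` of this residue's anchor and that are at least `min_seq_sep`
#' positions away in sequence. The anchor is CA, CB or the last heavy atom.
#'
#' @param complex a `complex_structure`.
#' @param anchor one of `"CA"`, `"CB"`, `"LHA"`.
#' @param radius probe sphere radius in angstrom (default 8).
#' @inheritParams clo
#' @return tibble with `res_uid` and `CPO` (`NA` where the anchor atom is
#'   missing, e.g. CB for glycine).
#' @export
cpo <- function(complex, anchor = c("CA", "CB", "LHA"), radius = 8,
                min_seq_sep = 30L) {
  anchor <- match.arg(anchor)
  pos <- anchor_positions(complex, anchor)
  res <- residues(complex)
  out <- tibble::tibble(res_uid = res$res_uid, CPO = NA_integer_)
  for (ch in unique(res$chain)) {
    in_ch <- res$chain == ch
    p <- pos[in_ch, , drop = FALSE]
    si <- res$seq_index[in_ch]
    ok <- stats::complete.cases(p)
    idx <- which(in_ch)
    for (a in seq_along(idx)) {
      if (!ok[a]) next
      d <- sqrt(colSums((t(p) - p[a, ])^2))
      out$CPO[idx[a]] <- sum(ok & d <= radius & abs(si - si[a]) >= min_seq_sep,
                             na.rm = TRUE)
    }
  }
  out
}

anchor_positions <- function(complex, anchor) {
  at <- complex$atoms
  res <- residues(complex)
  nm <- switch(anchor,
               CA = rep("CA", nrow(res)),
               CB = rep("CB", nrow(res)),
               LHA = unname(LHA_ATOM[res$res_type]))
  key_at <- paste(at$chain, at$res_seq, at$ins, at$atom)
  key_want <- paste(res$chain, res$res_seq, res$ins, nm)
  i <- match(key_want, key_at)
  cbind(x = at$x[i], y = at$y[i], z = at$z[i])
}

#' Local mass density
#'
#' Total atomic mass (all protein chains, waters excluded) inside a probe
#' sphere centered on the residue anchor, divided by the sphere volume.
#' Atoms count wholly when their center lies in the sphere.
#'
#' @param complex a `complex_structure`.
#' @param anchor `"CA"` or `"LHA"`.
#' @param radius sphere radius in angstrom (3 to 7 in the standard suite).
#' @return tibble with `res_uid` and `density` in Da per cubic angstrom
#'   (`NA` where the anchor is missing).
#' @export
density_descriptor <- function(complex, anchor = c("CA", "LHA"), radius = 5) {
  anchor <- match.arg(anchor)
  pos <- anchor_positions(complex, anchor)
  at <- complex$atoms
  axyz <- t(as.matrix(at[, c("x", "y", "z")]))
  v <- sphere_volume(radius)
  vals <- vapply(seq_len(nrow(pos)), function(i) {
    if (anyNA(pos[i, ])) return(NA_real_)
    d2 <- colSums((axyz - pos[i, ])^2)
    sum(at$mass[d2 <= radius^2]) / v
  }, 0)
  tibble::tibble(res_uid = residues(complex)$res_uid, density = vals)
}

#' Local emptiness (sponge)
#'
#' Fraction of a probe sphere's volume not occupied by the van der Waals
#' volumes of the enclosed atoms (center-point inclusion), clipped to
#' `[0, 1]`.
#'
#' @inheritParams density_descriptor
#' @return tibble with `res_uid` and `sponge` in `[0, 1]`.
#' @export
sponge_descriptor <- function(complex, anchor = c("CA", "LHA"), radius = 5) {
  anchor <- match.arg(anchor)
  pos <- anchor_positions(complex, anchor)
  at <- complex$atoms
  axyz <- t(as.matrix(at[, c("x", "y", "z")]))
  v <- sphere_volume(radius)
  vol_atom <- sphere_volume(at$vdw)
  vals <- vapply(seq_len(nrow(pos)), function(i) {
    if (anyNA(pos[i, ])) return(NA_real_)
    d2 <- colSums((axyz - pos[i, ])^2)
    max(v - sum(vol_atom[d2 <= radius^2]), 0) / v
  }, 0)
  tibble::tibble(res_uid = residues(complex)$res_uid, sponge = vals)
}

#' Accessibility-weighted hydrophobicity
#'
#' The Radzicka hydrophobicity of a residue's type multiplied by its
#' relative accessibility, so buried residues score zero.
#'
#' @param res_type amino-acid three-letter codes.
#' @param relative_acc relative accessibility in `[0, ~1]`.
#' @return numeric vector (dimensionless).
#' @export
hydrophobicity <- function(res_type, relative_acc) {
  unname(RADZICKA_HYDROPHOBICITY[res_type]) * relative_acc
}

chain_charges <- function(at_chain) {
  # side-chain groups at their member-atom centroid, plus +-1 termini
  ch <- list()
  uid <- res_uid_of(at_chain)
  for (tp in names(CHARGED_GROUPS)) {
    g <- CHARGED_GROUPS[[tp]]
    rows <- which(at_chain$res_type == tp & at_chain$atom %in% g$atoms)
    for (u in unique(uid[rows])) {
      rr <- rows[uid[rows] == u]
      ch[[length(ch) + 1]] <- c(colMeans(at_chain[rr, c("x", "y", "z")]), q = g$sign)
    }
  }
  ord <- order(at_chain$res_seq, at_chain$ins)
  first_res <- uid[ord[1]]
  last_res <- uid[ord[length(ord)]]
  nrow_ <- which(uid == first_res & at_chain$atom == "N")
  if (length(nrow_) > 0) {
    ch[[length(ch) + 1]] <- c(unlist(at_chain[nrow_[1], c("x", "y", "z")]), q = 1)
  }
  orow <- which(uid == last_res & at_chain$atom %in% c("O", "OXT"))
  if (length(orow) > 0) {
    ch[[length(ch) + 1]] <- c(colMeans(at_chain[orow, c("x", "y", "z")]), q = -1)
  }
  if (length(ch) == 0) return(matrix(numeric(), ncol = 4))
  do.call(rbind, ch)
}

screened_potential <- function(point, charges, lambda, eps) {
  if (nrow(charges) == 0) return(0)
  d <- sqrt((charges[, 1] - point[1])^2 + (charges[, 2] - point[2])^2 +
              (charges[, 3] - point[3])^2)
  keep <- d > 1e-9
  sum(charges[keep, 4] * exp(-d[keep] / lambda) / (eps * d[keep]))
}

#' Screened-Coulomb electrostatic potential
#'
#' Debye-screened Coulomb potential of the chain's formal charges
#' (side-chain groups of ASP/GLU at -1, LYS/ARG/HIS at +1, and the chain
#' termini at +-1), evaluated at the CA, the last heavy atom, averaged over
#' a residue's heavy atoms, and at its most solvent-exposed atom. Serves as
#' a pluggable stand-in for a Poisson-Boltzmann solver behind the same
#' descriptor interface.
#'
#' @param complex a `complex_structure`.
#' @param config an [ifr_config()] (uses `ep_lambda`, `ep_epsilon`, and the
#'   accessibility parameters for the surface anchor).
#' @return tibble with `res_uid`, `EP@Ca`, `EP@LHA`, `EP@Avg`, `EP@Surf`
#'   (dimensionless potential units).
#' @export
electrostatic_potential <- function(complex, config = ifr_config()) {
  at <- complex$atoms
  uid <- res_uid_of(at)
  res <- residues(complex)
  out <- tibble::tibble(res_uid = res$res_uid,
                        `EP@Ca` = NA_real_, `EP@LHA` = NA_real_,
                        `EP@Avg` = NA_real_, `EP@Surf` = NA_real_)
  ca <- anchor_positions(complex, "CA")
  lha <- anchor_positions(complex, "LHA")
  for (ch in unique(res$chain)) {
    rows <- which(at$chain == ch)
    charges <- chain_charges(at[rows, ])
    area <- sasa(at[rows, ], config$probe_radius, config$n_points)
    ridx <- which(res$chain == ch)
    for (i in ridx) {
      arow <- rows[uid[rows] == res$res_uid[i]]
      if (!anyNA(ca[i, ])) {
        out$`EP@Ca`[i] <- screened_potential(ca[i, ], charges,
                                             config$ep_lambda, config$ep_epsilon)
      }
      if (!anyNA(lha[i, ])) {
        out$`EP@LHA`[i] <- screened_potential(lha[i, ], charges,
                                              config$ep_lambda, config$ep_epsilon)
      }
      if (length(arow) > 0) {
        pts <- as.matrix(at[arow, c("x", "y", "z")])
        vals <- apply(pts, 1, screened_potential, charges = charges,
                      lambda = config$ep_lambda, eps = config$ep_epsilon)
        out$`EP@Avg`[i] <- mean(vals)
        out$`EP@Surf`[i] <- vals[which.max(area[match(arow, rows)])]
      }
    }
  }
  out
}

#' Contact energy density (CED)
#'
#' Energies of intra-chain contacts whose midpoint lies within a probe
#' sphere around the residue anchor, divided by the sphere volume.
#'
#' @param complex a `complex_structure`.
#' @param contacts intra-chain contact records.
#' @param anchor `"CA"` or `"LHA"`.
#' @param radius sphere radius in angstrom.
#' @return tibble with `res_uid` and `ced` (kcal/mol per cubic angstrom).
#' @export
ced <- function(complex, contacts, anchor = c("CA", "LHA"), radius = 5) {
  anchor <- match.arg(anchor)
  pos <- anchor_positions(complex, anchor)
  v <- sphere_volume(radius)
  vals <- vapply(seq_len(nrow(pos)), function(i) {
    if (anyNA(pos[i, ])) return(NA_real_)
    if (nrow(contacts) == 0) return(0)
    d2 <- (contacts$mx - pos[i, 1])^2 + (contacts$my - pos[i, 2])^2 +
      (contacts$mz - pos[i, 3])^2
    sum(contacts$energy[d2 <= radius^2]) / v
  }, 0)
  tibble::tibble(res_uid = residues(complex)$res_uid, ced = vals)
}

#' Weighted neighbor average of a per-residue descriptor
#'
#' Averages a descriptor over the residues within `cutoff` of each residue
#' (excluding the residue itself), weighting neighbors by inverse distance
#' (`mode = "DIST"`) or by their relative accessibility (`mode = "SURF"`).
#' With no neighbors, all-zero weights, or no neighbor carrying a value,
#' the residue's own value is returned.
#'
#' @param values numeric descriptor vector (may contain `NA`).
#' @param positions n-by-3 matrix of residue anchor (CA) coordinates.
#' @param mode `"DIST"` or `"SURF"`.
#' @param cutoff neighbor distance cutoff in angstrom (default 15).
#' @param relative_acc neighbor weights for `mode = "SURF"`.
#' @return numeric vector of weighted neighbor means.
#' @export
wna <- function(values, positions, mode = c("DIST", "SURF"), cutoff = 15,
                relative_acc = NULL) {
  mode <- match.arg(mode)
  if (cutoff < 0) stop("cutoff must be non-negative")
  if (mode == "SURF" && is.null(relative_acc)) {
    stop("relative_acc is required for SURF mode")
  }
  n <- length(values)
  pos <- as.matrix(positions)
  out <- values
  for (i in seq_len(n)) {
    if (anyNA(pos[i, ])) { out[i] <- NA_real_; next }
    d <- sqrt(colSums((t(pos) - pos[i, ])^2))
    nb <- which(d <= cutoff & seq_len(n) != i & !is.na(values) &
                  !is.na(d) & d > 0)
    if (length(nb) == 0) next
    w <- if (mode == "DIST") 1 / d[nb] else relative_acc[nb]
    if (all(is.na(w)) || sum(w, na.rm = TRUE) <= 0) next
    ok <- !is.na(w)
    out[i] <- sum(w[ok] * values[nb[ok]]) / sum(w[ok])
  }
  out
}

#' Compute the full per-residue descriptor table
#'
#' Runs every descriptor of the suite over a structure: hydrophobicity,
#' electrostatic potential at four anchors, contact energy density at
#' CA/LHA for radii 3-7, cross-link order, cross-presence order at three
#' anchors, backbone and side-chain dihedrals, density and sponge at CA/LHA
#' for radii 3-7, and the per-type and total contact energies. Unused
#' contact energies are added separately (they need corpus maxima; see
#' [unused_contact_energy()]), and weighted neighbor averages via
#' [wna_augment()].
#'
#' @param complex a `complex_structure`.
#' @param labels output of [label_residues()] for the same structure.
#' @param config an [ifr_config()].
#' @return A wide tibble, one row per residue: locator columns (`res_uid`,
#'   `chain`, `res_seq`, `ins`, `res_type`, `cls`, `relative_acc`, CA
#'   coordinates) followed by one column per descriptor; `NA` marks values
#'   whose defining atoms are missing or inapplicable.
#' @export
compute_descriptors <- function(complex, labels = NULL, config = ifr_config()) {
  if (is.null(labels)) labels <- label_residues(complex, config)
  res <- residues(complex)
  desc <- labels[, c("res_uid", "chain", "res_seq", "ins", "res_type", "cls",
                     "relative_acc", "ca_x", "ca_y", "ca_z")]

  desc$Hydrophobicity <- hydrophobicity(desc$res_type, desc$relative_acc)

  epd <- electrostatic_potential(complex, config)
  desc <- dplyr::left_join(desc, epd, by = "res_uid")

  contacts <- detect_contacts(complex, config, intra_only = TRUE)
  for (anc in c("Ca", "LHA")) {
    for (r in 3:7) {
      cc <- ced(complex, contacts, anchor = toupper(sub("Ca", "CA", anc)), radius = r)
      desc[[sprintf("CED@%s_INT_%d", anc, r)]] <- cc$ced[match(desc$res_uid, cc$res_uid)]
    }
  }

  cl <- clo(contacts, desc$res_uid, config$min_seq_sep)
  desc$CLO <- cl$CLO[match(desc$res_uid, cl$res_uid)]
  for (anc in c("Ca", "Cb", "LHA")) {
    cp <- cpo(complex, anchor = c(Ca = "CA", Cb = "CB", LHA = "LHA")[anc],
              radius = config$cpo_radius, min_seq_sep = config$min_seq_sep)
    desc[[paste0("CPO@", anc)]] <- cp$CPO[match(desc$res_uid, cp$res_uid)]
  }

  pp <- phi_psi(complex)
  pp$res_uid <- paste(pp$chain, pp$res_seq, pp$ins, sep = "_")
  desc$PHI <- pp$phi[match(desc$res_uid, pp$res_uid)]
  desc$PSI <- pp$psi[match(desc$res_uid, pp$res_uid)]
  chis <- chi_angles(complex)
  chis$res_uid <- paste(chis$chain, chis$res_seq, chis$ins, sep = "_")
  for (k in 1:4) {
    desc[[paste0("CHI", k)]] <- chis[[paste0("chi", k)]][match(desc$res_uid, chis$res_uid)]
  }

  for (anc in c("Ca", "LHA")) {
    a <- c(Ca = "CA", LHA = "LHA")[anc]
    for (r in 3:7) {
      dd <- density_descriptor(complex, anchor = a, radius = r)
      desc[[sprintf("Density@%s_%d", anc, r)]] <- dd$density[match(desc$res_uid, dd$res_uid)]
      ss <- sponge_descriptor(complex, anchor = a, radius = r)
      desc[[sprintf("Sponge@%s_%d", anc, r)]] <- ss$sponge[match(desc$res_uid, ss$res_uid)]
    }
  }

  en <- contact_energy(contacts, res_uids = desc$res_uid)
  desc <- dplyr::left_join(desc, en, by = "res_uid")
  desc
}

#' Locator (non-descriptor) columns of a descriptor table
#' @keywords internal
LOCATOR_COLS <- c("res_uid", "chain", "res_seq", "ins", "res_type", "cls",
                  "relative_acc", "ca_x", "ca_y", "ca_z")

#' Append weighted neighbor averages to a descriptor table
#'
#' Adds `<column>_WNADist` and `<column>_WNASurf` for every descriptor
#' column (or the subset in `cols`), using CA-CA neighbor distances and the
#' residues' relative accessibility.
#'
#' @param desc descriptor tibble from [compute_descriptors()] (optionally
#'   already carrying unused-energy columns).
#' @param config an [ifr_config()] (uses `wna_cutoff`).
#' @param cols columns to average; defaults to all descriptor columns.
#' @return `desc` with the neighbor-average columns appended.
#' @export
wna_augment <- function(desc, config = ifr_config(), cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(desc), c(LOCATOR_COLS, "pdb_id",
                                   grep("_WNA", names(desc), value = TRUE)))
    cols <- cols[vapply(desc[cols], is.numeric, TRUE)]
  }
  pos <- as.matrix(desc[, c("ca_x", "ca_y", "ca_z")])
  for (cl in cols) {
    desc[[paste0(cl, "_WNADist")]] <-
      wna(desc[[cl]], pos, "DIST", config$wna_cutoff)
    desc[[paste0(cl, "_WNASurf")]] <-
      wna(desc[[cl]], pos, "SURF", config$wna_cutoff, desc$relative_acc)
  }
  desc
}
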