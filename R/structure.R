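# Typed atomic model of a multi-chain complex, built on bio3d's PDB reader,
# plus the geometric primitives (torsions, backbone/side-chain dihedrals)
# the descriptor suite needs.

new_complex_structure <- function(pdb_id, resolution, atoms, waters,
                                  nonprotein_chains = character(),
                                  oligomeric_state_consistent = TRUE,
                                  is_fragment = FALSE) {
  structure(
    list(
      pdb_id = pdb_id,
      resolution = resolution,
      atoms = atoms,
      waters = waters,
      nonprotein_chains = nonprotein_chains,
      oligomeric_state_consistent = oligomeric_state_consistent,
      is_fragment = is_fragment
    ),
    class = "complex_structure"
  )
}

#' Parse a PDB-format structure into a typed atomic model
#'
#' Reads fixed-column PDB text (ATOM/HETATM/TER records) into a
#' `complex_structure`: a tibble of protein atoms split by chain, water
#' molecules routed to a separate table, alternate locations resolved to the
#' highest-occupancy conformer, selenomethionine (MSE) mapped to MET, and
#' non-protein polymer chains (nucleic acids) set aside and flagged.
#'
#' @param x PDB-format text (single string or character vector of lines) or a
#'   path to a PDB file.
#' @param pdb_id identifier stored with the structure; defaults to the file
#'   basename or `"UNKN"`.
#' @param oligomeric_state_consistent,is_fragment metadata flags normally
#'   supplied from a curation sidecar table; they are carried, not computed.
#' @return A `complex_structure` with elements `atoms` (tibble: one row per
#'   protein atom with chain, residue number, insertion code, residue type,
#'   atom name, element, coordinates, mass, van der Waals radius) and
#'   `waters` (same layout for water oxygens), plus `pdb_id`, `resolution`,
#'   and the metadata flags.
#' @export
#' @examples
#' pdb <- make_toy_complex(toy_complex_spec(n_residues = 4))
#' cx <- parse_pdb(pdb$text)
#' nrow(cx$atoms)
parse_pdb <- function(x, pdb_id = NULL,
                      oligomeric_state_consistent = TRUE,
                      is_fragment = FALSE) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (is.null(pdb_id)) pdb_id <- sub("\\.pdb$", "", basename(x))
  } else {
    lines <- unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(pdb_id)) pdb_id <- "UNKN"
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty structure: no ATOM records found")

  # validate coordinate fields before handing to the reader, so a malformed
  # line is reported with its line number
  for (i in which(is_atom)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[i], fld[1], fld[2])))
      if (is.na(v)) {
        stop(sprintf("malformed coordinate field at line %d: '%s'",
                     i, lines[i]))
      }
    }
  }

  resolution <- NA_real_
  m <- regmatches(lines, regexpr("RESOLUTION\\.?\\s+([0-9.]+)", lines))
  if (length(m) > 0) {
    resolution <- suppressWarnings(as.numeric(sub(".*?([0-9.]+)\\s*$", "\\1", m[1])))
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1

  # alternate locations: keep highest occupancy, ties -> first encountered
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
  keep <- rep(TRUE, nrow(at))
  dupgrp <- key[duplicated(key)]
  for (k in unique(dupgrp)) {
    idx <- which(key == k)
    best <- idx[which.max(at$o[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]

  at$resid[at$resid == "MSE"] <- "MET"
  at$elety[at$elety == "SE" & at$resid == "MET"] <- "SD"

  is_water <- at$resid %in% c("HOH", "WAT", "DOD")
  is_aa <- at$resid %in% AA3
  elem <- infer_element(at$elety)
  elem[is_water] <- "O"

  tb <- tibble::tibble(
    chain = at$chain,
    res_seq = as.integer(at$resno),
    ins = at$insert,
    res_type = at$resid,
    atom = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    mass = unname(ELEMENT_MASS[elem]),
    vdw = unname(ELEMENT_VDW[elem]),
    occupancy = at$o
  )
  tb <- dplyr::filter(tb, .data$element != "H")

  waters <- dplyr::filter(tb, tb$res_type %in% c("HOH", "WAT", "DOD"))
  protein <- dplyr::filter(tb, tb$res_type %in% AA3)

  # chains containing polymer residues that are not amino acids or waters
  other <- dplyr::filter(tb, !tb$res_type %in% c(AA3, "HOH", "WAT", "DOD"))
  nonprotein_chains <- setdiff(unique(other$chain), unique(protein$chain))

  if (nrow(protein) == 0) stop("empty structure: no protein atoms found")
  protein <- dplyr::arrange(protein, .data$chain, .data$res_seq, .data$ins)
  new_complex_structure(pdb_id, resolution, protein, waters,
                        nonprotein_chains,
                        oligomeric_state_consistent, is_fragment)
}

#' @export
print.complex_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<complex_structure> %s: %d chain(s) [%s], %d residues, %d atoms, %d waters\n",
              x$pdb_id, length(ch), paste(ch, collapse = ","),
              nrow(residues(x)), nrow(x$atoms), nrow(x$waters)))
  if (!is.na(x$resolution)) cat(sprintf("  resolution: %.2f A\n", x$resolution))
  invisible(x)
}

#' Per-residue summary of a complex structure
#'
#' @param complex a `complex_structure`.
#' @return A tibble with one row per residue: `chain`, `res_seq`, `ins`,
#'   `res_type`, `seq_index` (0-based position within the chain), a residue
#'   id `res_uid`, and the coordinates of the CA and last-heavy-atom (LHA)
#'   anchors where present.
#' @export
residues <- function(complex) {
  at <- complex$atoms
  r <- at |>
    dplyr::group_by(.data$chain, .data$res_seq, .data$ins, .data$res_type) |>
    dplyr::summarise(n_atoms = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$res_seq, .data$ins) |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(seq_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(res_uid = paste(.data$chain, .data$res_seq, .data$ins, sep = "_"))
  anchor <- function(nm_map) {
    want <- unname(nm_map[at$res_type])
    hit <- at[at$atom == want, c("chain", "res_seq", "ins", "x", "y", "z")]
    hit
  }
  ca <- at[at$atom == "CA", c("chain", "res_seq", "ins", "x", "y", "z")]
  names(ca)[4:6] <- c("ca_x", "ca_y", "ca_z")
  lha <- anchor(LHA_ATOM)
  names(lha)[4:6] <- c("lha_x", "lha_y", "lha_z")
  r |>
    dplyr::left_join(ca, by = c("chain", "res_seq", "ins")) |>
    dplyr::left_join(lha, by = c("chain", "res_seq", "ins"))
}

#' One-letter sequence of a chain
#' @param complex a `complex_structure`.
#' @param chain_id chain identifier.
#' @return single string.
#' @export
chain_sequence <- function(complex, chain_id) {
  r <- residues(complex)
  r <- r[r$chain == chain_id, ]
  if (nrow(r) == 0) stop("unknown chain: ", chain_id)
  paste(AA1[r$res_type], collapse = "")
}

#' Write a complex structure as PDB-format text
#'
#' Fixed-column formatter for ATOM/HETATM records (the inverse of
#' [parse_pdb()] up to coordinate rounding at 3 decimals).
#'
#' @param complex a `complex_structure`.
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return PDB text (single string), invisibly when written to file.
#' @export
write_pdb <- function(complex, file = NULL) {
  fmt <- function(tb, rectype) {
    if (nrow(tb) == 0) return(character())
    nm <- ifelse(nchar(tb$atom) < 4, paste0(" ", tb$atom), tb$atom)
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rectype, seq_len(nrow(tb)), nm, "", tb$res_type, tb$chain,
            tb$res_seq, tb$ins, tb$x, tb$y, tb$z, 1, 0, tb$element)
  }
  lines <- character()
  if (!is.na(complex$resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %8.2f ANGSTROMS.", complex$resolution))
  }
  lines <- c(lines, fmt(complex$atoms, "ATOM"), fmt(complex$waters, "HETATM"), "END")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Signed torsion angle of four points
#'
#' Standard signed dihedral about the p2-p3 axis, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees; `NA` for degenerate (collinear) geometry.
#' @export
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)) # cis -> 0
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2n[3] - n1[3] * b2n[2],
          n1[3] * b2n[1] - n1[1] * b2n[3],
          n1[1] * b2n[2] - n1[2] * b2n[1])
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

atom_xyz <- function(atoms, chain, res_seq, ins, name) {
  i <- which(atoms$chain == chain & atoms$res_seq == res_seq &
               atoms$ins == ins & atoms$atom == name)
  if (length(i) == 0) return(NULL)
  c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
}

#' Backbone phi/psi dihedrals
#'
#' Phi of residue i is the C(i-1)-N-CA-C torsion, psi the N-CA-C-N(i+1)
#' torsion; either is `NA` at chain termini or when a backbone atom is
#' missing.
#'
#' @param complex a `complex_structure`.
#' @return A tibble with `chain`, `res_seq`, `ins`, `phi`, `psi` in degrees.
#' @export
phi_psi <- function(complex) {
  at <- complex$atoms
  r <- residues(complex)
  out <- r[, c("chain", "res_seq", "ins")]
  out$phi <- NA_real_
  out$psi <- NA_real_
  for (ch in unique(r$chain)) {
    idx <- which(r$chain == ch)
    for (j in seq_along(idx)) {
      i <- idx[j]
      n_  <- atom_xyz(at, ch, r$res_seq[i], r$ins[i], "N")
      ca_ <- atom_xyz(at, ch, r$res_seq[i], r$ins[i], "CA")
      c_  <- atom_xyz(at, ch, r$res_seq[i], r$ins[i], "C")
      if (is.null(n_) || is.null(ca_) || is.null(c_)) next
      if (j > 1) {
        ip <- idx[j - 1]
        cprev <- atom_xyz(at, ch, r$res_seq[ip], r$ins[ip], "C")
        if (!is.null(cprev)) out$phi[i] <- dihedral(cprev, n_, ca_, c_)
      }
      if (j < length(idx)) {
        inx <- idx[j + 1]
        nnext <- atom_xyz(at, ch, r$res_seq[inx], r$ins[inx], "N")
        if (!is.null(nnext)) out$psi[i] <- dihedral(n_, ca_, c_, nnext)
      }
    }
  }
  tibble::as_tibble(out)
}

#' Side-chain chi dihedrals
#'
#' CHI1..CHI4 from the standard side-chain tetrads for each residue type;
#' glycine and alanine have none, and a missing side-chain atom leaves that
#' chi and all deeper chis `NA`.
#'
#' @param complex a `complex_structure`.
#' @return tibble with `chain`, `res_seq`, `ins`, `chi1`..`chi4` (degrees).
#' @export
chi_angles <- function(complex) {
  at <- complex$atoms
  r <- residues(complex)
  out <- r[, c("chain", "res_seq", "ins", "res_type")]
  for (k in 1:4) out[[paste0("chi", k)]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    tet <- CHI_ATOMS[[out$res_type[i]]]
    if (is.null(tet)) next
    for (k in seq_along(tet)) {
      pts <- lapply(tet[[k]], function(nm)
        atom_xyz(at, out$chain[i], out$res_seq[i], out$ins[i], nm))
      if (any(vapply(pts, is.null, logical(1)))) break
      out[[paste0("chi", k)]][i] <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
  }
  out$res_type <- NULL
  tibble::as_tibble(out)
}
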