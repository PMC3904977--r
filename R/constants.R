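# Embedded constant data: element properties, amino-acid reference tables,
# dihedral atom tetrads, contact energies. All distances in angstrom, masses
# in Da, energies in kcal/mol.

#' @keywords internal
ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  SE = 78.971, P = 30.974
)

#' @keywords internal
ELEMENT_VDW <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  SE = 1.90, P = 1.80
)

#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' @keywords internal
AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

# Last heavy atom of each side chain; ties in symmetric termini broken by
# lowest atom-name ordinal. Glycine has no side chain, so CA stands in;
# alanine's side chain ends at CB.
#' @keywords internal
LHA_ATOM <- c(
  ALA = "CB", ARG = "NH1", ASN = "OD1", ASP = "OD1", CYS = "SG",
  GLN = "OE1", GLU = "OE1", GLY = "CA", HIS = "NE2", ILE = "CD1",
  LEU = "CD1", LYS = "NZ", MET = "CE", PHE = "CZ", PRO = "CD",
  SER = "OG", THR = "OG1", TRP = "CH2", TYR = "OH", VAL = "CG1"
)

# Water-to-cyclohexane transfer free energies (Radzicka & Wolfenden 1988
# scale). Proline was not measured on that scale; 0.0 by convention.
#' @keywords internal
RADZICKA_HYDROPHOBICITY <- c(
  ALA = 1.81, ARG = -14.92, ASN = -6.64, ASP = -8.72, CYS = 1.28,
  GLN = -5.54, GLU = -6.81, GLY = 0.94, HIS = -4.66, ILE = 4.92,
  LEU = 4.92, LYS = -5.55, MET = 2.35, PHE = 2.98, PRO = 0.00,
  SER = -3.40, THR = -2.57, TRP = 2.33, TYR = -0.14, VAL = 4.04
)

# Theoretical maximum accessible surface area per residue type (Tien et al.
# 2013, extended tripeptide reference), used to normalize relative
# accessibility.
#' @keywords internal
MAX_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174
)

# Contact energies by interaction type. All hydrogen-bond subtypes
# (direct and water-mediated) carry the hydrogen-bond energy.
#' @keywords internal
CONTACT_ENERGY <- c(
  HYDROPHOBIC = 0.6, AROMATIC = 1.5,
  HB_MM = 2.6, HB_MS = 2.6, HB_SS = 2.6,
  HB_MWM = 2.6, HB_MWS = 2.6, HB_SWS = 2.6,
  HB_MWWM = 2.6, HB_MWWS = 2.6, HB_SWWS = 2.6,
  CHARGED_ATTRACTIVE = 10.0, CHARGED_REPULSIVE = 10.0,
  DISULFIDE = 85.0
)

#' @keywords internal
CONTACT_TYPES <- names(CONTACT_ENERGY)

# Side-chain charged groups: member atoms and formal sign.
#' @keywords internal
CHARGED_GROUPS <- list(
  ASP = list(atoms = c("OD1", "OD2"), sign = -1L),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1L),
  LYS = list(atoms = "NZ", sign = +1L),
  ARG = list(atoms = c("NE", "NH1", "NH2"), sign = +1L),
  HIS = list(atoms = c("ND1", "NE2"), sign = +1L)
)

# Aromatic ring atoms (for centroid-based stacking contacts).
#' @keywords internal
AROMATIC_RING <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# Side-chain carbons treated as apolar for hydrophobic contacts (carbons not
# bonded to N/O/S and aromatic ring carbons).
#' @keywords internal
APOLAR_CARBONS <- list(
  ALA = "CB", ARG = c("CB", "CG"), ASN = "CB", ASP = "CB",
  CYS = "CB", GLN = c("CB", "CG"), GLU = c("CB", "CG"), GLY = character(),
  HIS = "CB", ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"), LYS = c("CB", "CG", "CD"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"), SER = "CB", THR = "CG2",
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2")
)

# Chi-angle atom tetrads per residue type, in order CHI1..CHI4. Each entry
# is a character vector of 4 atom names.
#' @keywords internal
CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

#' @keywords internal
MAIN_CHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Infer element symbol from a PDB atom name
#' @keywords internal
infer_element <- function(atom_name, residue_type = NULL) {
  nm <- toupper(trimws(atom_name))
  first <- substr(nm, 1, 1)
  out <- ifelse(grepl("^SE", nm), "SE",
         ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, "C"))
  out
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their default values:
#' probe radius 1.4 A and 960 sampling points for accessibility, the
#' contact geometric cutoffs, the 15 A neighbor-average cutoff, the 0.85
#' correlation-pruning threshold, the 95% PCA variance target, 10
#' cross-validation folds and the 0.50 decision cutoff.
#'
#' @param ... named overrides of any default.
#' @return A named list of parameters (class `ifr_config`).
#' @export
#' @examples
#' cfg <- ifr_config(n_points = 240)
#' cfg$probe_radius
ifr_config <- function(...) {
  cfg <- list(
    probe_radius = 1.4,
    n_points = 960,
    delta_area = 0.1,          # A^2 accessibility loss that marks an IFR
    exposure_min = 0.05,       # relative accessibility defining the surface
    hydrophobic_cut = 3.9,
    aromatic_cut = 5.0,
    hbond_cut = 3.2,
    charged_cut = 6.0,
    disulfide_cut = 2.5,
    wna_cutoff = 15.0,
    cpo_radius = 8.0,
    min_seq_sep = 30L,
    cor_threshold = 0.85,
    variance_target = 0.95,
    k_folds = 10L,
    decision_cutoff = 0.50,
    ep_lambda = 8.0,           # screening length, A
    ep_epsilon = 80,           # dielectric
    max_resolution = 3.0,
    min_chain_length = 50L,
    min_interface_area = 200,
    identity_cutoff = 0.30,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "ifr_config")
}
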