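# Seed-deterministic synthetic test inputs: toy two-chain complexes on an
# idealized extended backbone with designed contacts/contact patches, and
# labeled Gaussian feature sets with known Bayes-optimal AUC. Fixtures are
# geometric test vectors, not realistic folds; ground truth is emitted
# alongside so tests never re-derive it from the code under test.

# CB -> last-heavy-atom extension lengths (angstrom) for the single
# pseudo-atom side-chain representation
SC_EXT <- c(
  ALA = 0, ARG = 5.7, ASN = 2.4, ASP = 2.4, CYS = 1.8, GLN = 3.6,
  GLU = 3.6, HIS = 3.2, ILE = 2.6, LEU = 2.5, LYS = 5.0, MET = 3.6,
  PHE = 3.4, PRO = 1.5, SER = 1.4, THR = 1.4, TRP = 4.4, TYR = 4.8,
  VAL = 1.5
)

# linear (unbranched) full side chains available for chi-angle fixtures
SIDE_CHAIN_LINEAR <- list(
  SER = "OG", CYS = "SG", LYS = c("CG", "CD", "CE", "NZ"),
  MET = c("CG", "SD", "CE"), GLU = c("CG", "CD", "OE1")
)

#' Specification of a synthetic two-chain toy complex
#'
#' @param n_residues residues in chain A.
#' @param seq_a,seq_b three-letter residue sequences (recycled);
#'   defaults: poly-ALA chain A of `n_residues`, chain B of `len_b`.
#' @param len_b residues in chain B (ignored when `seq_b` given).
#' @param chain_sep z-separation of the two CA planes in angstrom.
#' @param patch_start 0-based chain-A residue index over which chain B
#'   residue 0 is aligned.
#' @param contacts list of planted contacts, each
#'   `list(i =, j =, type =, distance =)` with `i`/`j` 0-based residue
#'   indices in chains A/B; the first one rigidly places chain B so its
#'   contact atoms sit exactly `distance` apart (vertically).
#' @param full_side_chains build full linear side chains where available
#'   (SER, CYS, LYS, MET, GLU) instead of the single pseudo-atom.
#' @param waters optional matrix/data frame of water oxygen coordinates.
#' @param resolution nominal crystallographic resolution written to the
#'   header.
#' @param pdb_id identifier.
#' @param seed stored with the spec (the builder itself is deterministic).
#' @return a `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_residues = 8, seq_a = NULL, seq_b = NULL,
                             len_b = 4, chain_sep = 8.5, patch_start = NULL,
                             contacts = list(), full_side_chains = FALSE,
                             waters = NULL, resolution = 2.0,
                             pdb_id = "TOY1", seed = 1L) {
  if (is.null(seq_a)) seq_a <- rep("ALA", n_residues)
  if (is.null(seq_b)) seq_b <- rep("ALA", len_b)
  stopifnot(all(seq_a %in% AA3), all(seq_b %in% AA3))
  if (is.null(patch_start)) {
    patch_start <- max(0L, floor((length(seq_a) - length(seq_b)) / 2))
  }
  structure(list(seq_a = seq_a, seq_b = seq_b, chain_sep = chain_sep,
                 patch_start = patch_start, contacts = contacts,
                 full_side_chains = full_side_chains, waters = waters,
                 resolution = resolution, pdb_id = pdb_id, seed = seed),
            class = "toy_complex_spec")
}

# idealized residue on an extended template; sz = +1 (side chains up) or -1
build_residue <- function(res_type, i, sz, z0, full = FALSE) {
  s <- 3.8 * i
  atoms <- list(
    N = c(s, 0, z0),
    CA = c(s + 1.3, 0.9, z0),
    C = c(s + 2.5, 0, z0),
    O = c(s + 2.5, -1.23, z0 + 0.1 * sz)
  )
  ca <- atoms$CA
  if (res_type != "GLY") {
    atoms$CB <- ca + c(0, 0, sz * 1.55)
    lin <- SIDE_CHAIN_LINEAR[[res_type]]
    if (full && !is.null(lin)) {
      prev <- atoms$CB
      for (j in seq_along(lin)) {
        prev <- prev + c(0.45 * cos(1.9 * j), 0.45 * sin(1.9 * j), sz * 1.25)
        atoms[[lin[j]]] <- prev
      }
    } else if (res_type != "ALA") {
      atoms[[LHA_ATOM[[res_type]]]] <- atoms$CB + c(0, 0, sz * SC_EXT[[res_type]])
    }
  }
  tibble::tibble(atom = names(atoms),
                 x = vapply(atoms, `[`, 0, 1),
                 y = vapply(atoms, `[`, 0, 2),
                 z = vapply(atoms, `[`, 0, 3),
                 res_type = res_type)
}

contact_atom_for <- function(type, res_type) {
  switch(type,
         DISULFIDE = "SG",
         CHARGED_ATTRACTIVE = LHA_ATOM[[res_type]],
         CHARGED_REPULSIVE = LHA_ATOM[[res_type]],
         HYDROPHOBIC = LHA_ATOM[[res_type]],
         LHA_ATOM[[res_type]])
}

#' Build a toy two-chain complex with known ground truth
#'
#' Chain A lies on an extended template along x with side chains pointing
#' +z; chain B mirrors it above at `chain_sep`, aligned over the residue
#' patch starting at `patch_start`. A planted contact rigidly shifts chain
#' B so the two designated atoms sit exactly at the requested distance.
#' Atom clashes below 1.0 angstrom abort generation.
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `text` (PDB-format string), and `truth`: the planted
#'   `contacts` (with residue uids), `patch_a_uids` (chain-A residues under
#'   chain B) and `chain_b_uids`.
#' @export
#' @examples
#' fx <- make_toy_complex(toy_complex_spec(
#'   seq_a = "LYS", seq_b = "ASP", chain_sep = 12,
#'   contacts = list(list(i = 0, j = 0, type = "CHARGED_ATTRACTIVE",
#'                        distance = 3.0))))
#' cx <- parse_pdb(fx$text)
make_toy_complex <- function(spec) {
  a_list <- lapply(seq_along(spec$seq_a) - 1L, function(i) {
    r <- build_residue(spec$seq_a[i + 1], i, +1, 0, spec$full_side_chains)
    r$chain <- "A"; r$res_seq <- i + 1L
    r
  })
  b_list <- lapply(seq_along(spec$seq_b) - 1L, function(j) {
    r <- build_residue(spec$seq_b[j + 1], spec$patch_start + j, -1,
                       spec$chain_sep, spec$full_side_chains)
    r$chain <- "B"; r$res_seq <- j + 1L
    r
  })
  a <- dplyr::bind_rows(a_list)
  b <- dplyr::bind_rows(b_list)

  if (length(spec$contacts) > 0) {
    c1 <- spec$contacts[[1]]
    ta <- spec$seq_a[c1$i + 1]; tb <- spec$seq_b[c1$j + 1]
    an <- contact_atom_for(c1$type, ta); bn <- contact_atom_for(c1$type, tb)
    pa <- a[a$res_seq == c1$i + 1L & a$atom == an, c("x", "y", "z")]
    pb <- b[b$res_seq == c1$j + 1L & b$atom == bn, c("x", "y", "z")]
    if (nrow(pa) == 0 || nrow(pb) == 0) {
      stop("planted contact atoms not present in the template")
    }
    target <- unlist(pa) + c(0, 0, c1$distance)
    shift <- target - unlist(pb)
    b$x <- b$x + shift[1]; b$y <- b$y + shift[2]; b$z <- b$z + shift[3]
    # remaining planted contacts must be consistent with the rigid placement
    for (ck in spec$contacts[-1]) {
      ta2 <- spec$seq_a[ck$i + 1]; tb2 <- spec$seq_b[ck$j + 1]
      pa2 <- unlist(a[a$res_seq == ck$i + 1L &
                        a$atom == contact_atom_for(ck$type, ta2), c("x", "y", "z")])
      pb2 <- unlist(b[b$res_seq == ck$j + 1L &
                        b$atom == contact_atom_for(ck$type, tb2), c("x", "y", "z")])
      d <- sqrt(sum((pa2 - pb2)^2))
      if (abs(d - ck$distance) > 0.5) {
        stop(sprintf("infeasible geometry: planted contact %d lands at %.2f A",
                     which(vapply(spec$contacts, identical, TRUE, ck)), d))
      }
    }
  }

  all_at <- dplyr::bind_rows(a, b)
  da <- as.matrix(a[, c("x", "y", "z")])
  db <- as.matrix(b[, c("x", "y", "z")])
  ab_d2 <- outer(rowSums(da^2), rep(1, nrow(db))) +
    outer(rep(1, nrow(da)), rowSums(db^2)) - 2 * da %*% t(db)
  if (min(ab_d2) < 1.0^2) stop("infeasible geometry: overlapping hard spheres")

  lines <- sprintf("REMARK   2 RESOLUTION. %8.2f ANGSTROMS.", spec$resolution)
  serial <- 0L
  for (r in seq_len(nrow(all_at))) {
    serial <- serial + 1L
    nm <- all_at$atom[r]
    nm4 <- if (nchar(nm) < 4) paste0(" ", nm) else nm
    lines <- c(lines, sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      "ATOM", serial, nm4, "", all_at$res_type[r], all_at$chain[r],
      all_at$res_seq[r], "", all_at$x[r], all_at$y[r], all_at$z[r], 1, 0,
      infer_element(nm)))
  }
  if (!is.null(spec$waters)) {
    w <- as.matrix(spec$waters)
    for (r in seq_len(nrow(w))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        "HETATM", serial, " O", "", "HOH", "W", r, "",
        w[r, 1], w[r, 2], w[r, 3], 1, 0, "O"))
    }
  }
  lines <- c(lines, "END")

  truth_contacts <- dplyr::bind_rows(lapply(spec$contacts, function(ck) {
    tibble::tibble(uid1 = paste("A", ck$i + 1L, "", sep = "_"),
                   uid2 = paste("B", ck$j + 1L, "", sep = "_"),
                   contact_type = ck$type, distance = ck$distance)
  }))
  patch_idx <- spec$patch_start + seq_along(spec$seq_b) - 1L
  patch_idx <- patch_idx[patch_idx >= 0 & patch_idx < length(spec$seq_a)]
  list(
    text = paste(lines, collapse = "\n"),
    truth = list(
      contacts = truth_contacts,
      patch_a_uids = paste("A", patch_idx + 1L, "", sep = "_"),
      chain_b_uids = paste("B", seq_along(spec$seq_b), "", sep = "_")
    )
  )
}

#' Seed-deterministic corpus of toy complexes
#'
#' Generates varied two-chain complexes with random sequences (drawn from
#' residue types of comparable side-chain reach, so the contact patch
#' actually occludes) for end-to-end training exercises.
#'
#' @param n_entries number of complexes.
#' @param n_residues chain-A length.
#' @param len_b chain-B length.
#' @param seed RNG seed.
#' @return list of `complex_structure` objects.
#' @export
make_toy_corpus <- function(n_entries = 10, n_residues = 10, len_b = 4,
                            seed = 1L) {
  alphabet <- c("ALA", "SER", "THR", "VAL", "CYS", "LEU", "ASP", "ASN")
  withr::with_seed(seed, {
    lapply(seq_len(n_entries), function(e) {
      seq_a <- sample(alphabet, n_residues, replace = TRUE)
      seq_b <- sample(alphabet, len_b, replace = TRUE)
      ext_a <- 1.55 + max(SC_EXT[seq_a])
      ext_b <- 1.55 + max(SC_EXT[seq_b])
      sp <- toy_complex_spec(
        seq_a = seq_a, seq_b = seq_b,
        chain_sep = ext_a + ext_b + 3.0,
        patch_start = sample(0:(n_residues - len_b), 1),
        pdb_id = sprintf("TY%02d", e), seed = seed)
      parse_pdb(make_toy_complex(sp)$text, pdb_id = sp$pdb_id)
    })
  })
}

#' Specification of a labeled Gaussian feature set
#'
#' @param n_per_class observations per class.
#' @param n_features feature count.
#' @param delta class mean separation in pooled-SD units (Euclidean norm
#'   of the mean difference under identity covariance); the Bayes-optimal
#'   AUC is `pnorm(delta / sqrt(2))`.
#' @param covariance `"identity"` or `"planted"` (appends a duplicated
#'   column, a near-duplicate and two linear combinations to exercise
#'   correlation pruning and PCA).
#' @param type amino-acid type tag for the resulting datamart.
#' @param seed RNG seed.
#' @return a `gaussian_mart_spec` list.
#' @export
gaussian_mart_spec <- function(n_per_class = 200, n_features = 10, delta = 2,
                               covariance = c("identity", "planted"),
                               type = "ALA", seed = 1L) {
  covariance <- match.arg(covariance)
  stopifnot(delta >= 0, n_per_class >= 2, n_features >= 2)
  structure(list(n_per_class = n_per_class, n_features = n_features,
                 delta = delta, covariance = covariance, type = type,
                 seed = seed),
            class = "gaussian_mart_spec")
}

#' Generate a labeled Gaussian datamart with known Bayes AUC
#'
#' Two multivariate Gaussian classes with identity covariance and mean
#' difference `delta` along the first feature; the analytic Bayes AUC
#' `pnorm(delta / sqrt(2))` is attached as attribute `bayes_auc`. The
#' `"planted"` covariance mode appends linearly dependent columns.
#'
#' @param spec a [gaussian_mart_spec()].
#' @param direction optional unit vector for the mean difference (defaults
#'   to the first feature axis).
#' @return an `ifr_datamart` with attribute `bayes_auc`.
#' @export
make_gaussian_mart <- function(spec, direction = NULL) {
  withr::with_seed(spec$seed, {
    n <- spec$n_per_class
    p <- spec$n_features
    if (is.null(direction)) direction <- c(1, rep(0, p - 1))
    direction <- direction / sqrt(sum(direction^2))
    x0 <- matrix(stats::rnorm(n * p), n, p)
    x1 <- matrix(stats::rnorm(n * p), n, p) +
      matrix(spec$delta * direction, n, p, byrow = TRUE)
    x <- rbind(x0, x1)
    colnames(x) <- sprintf("feat_%02d", seq_len(p))
    x <- tibble::as_tibble(x)
    if (spec$covariance == "planted") {
      x$feat_dup <- x$feat_02
      x$feat_near <- x$feat_03 + stats::rnorm(2 * n, sd = 0.05)
      x$feat_lin1 <- 0.6 * x$feat_04 + 0.4 * x$feat_05
      x$feat_lin2 <- x$feat_06 - x$feat_07
    }
    y <- rep(c(0L, 1L), each = n)
    m <- new_datamart(spec$type, x, y)
    attr(m, "bayes_auc") <- stats::pnorm(spec$delta / sqrt(2))
    m
  })
}

#' Per-type Gaussian datamarts with type-specific signal directions
#'
#' Each amino-acid type receives the same separation `delta` but along a
#' different, alternating-sign feature axis, so the type-specific
#' classifiers see clean signal while a pooled (type-unspecific)
#' classifier sees the directions cancel.
#'
#' @param types amino-acid types to simulate.
#' @inheritParams gaussian_mart_spec
#' @return named list of `ifr_datamart` objects.
#' @export
make_typed_gaussian_marts <- function(types = c("ALA", "ASP", "LYS", "SER"),
                                      n_per_class = 150, n_features = 6,
                                      delta = 2, seed = 1L) {
  out <- list()
  for (k in seq_along(types)) {
    dir <- rep(0, n_features)
    dir[(k - 1) %% n_features + 1] <- (-1)^(k - 1)
    sp <- gaussian_mart_spec(n_per_class, n_features, delta,
                             type = types[k], seed = seed + k)
    out[[types[k]]] <- make_gaussian_mart(sp, direction = dir)
  }
  out
}
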