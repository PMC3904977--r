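# Solvent accessibility, interface labeling, areas, size classes, the
# dataset filter chain and redundancy reduction.

test_that("isolated and non-occluding spheres match the closed form", {
  a1 <- tibble::tibble(x = 0, y = 0, z = 0, vdw = 1.7)
  expect_equal(sasa(a1, probe_radius = 1.4), 4 * pi * (1.7 + 1.4)^2,
               tolerance = 1e-9)
  a2 <- tibble::tibble(x = c(0, 10), y = 0, z = 0, vdw = 1.7)
  expect_equal(sasa(a2), rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)
  expect_error(sasa(a1, n_points = 8), "n_points")
})

test_that("overlapping atoms lose area and agree with a dense-sampling oracle", {
  at <- tibble::tibble(x = c(0, 2.0, 3.1), y = c(0, 0.5, -0.4),
                       z = c(0, 0.3, 0.8), vdw = c(1.7, 1.52, 1.55))
  got <- sasa(at, n_points = 960)
  iso <- 4 * pi * (at$vdw + 1.4)^2
  expect_true(all(got < iso))
  ref <- oracle_sasa_dense(at)
  expect_equal(sum(got), sum(ref), tolerance = 0.02)
  expect_equal(got, ref, tolerance = 0.02)
})

test_that("labels partition residues and obey the accessibility inequality", {
  fx <- make_toy_complex(toy_complex_spec(n_residues = 10, len_b = 4,
                                          chain_sep = 8.5, patch_start = 3))
  cx <- parse_pdb(fx$text)
  lab <- label_residues(cx, ifr_config(n_points = 240))
  expect_true(all(lab$cls %in% c("IFR", "FSR", "BURIED")))
  expect_true(all(lab$acc_complex <= lab$acc_isolation + 1e-9))
  # designed contact patch: exactly those residues (and the facing chain)
  expect_setequal(lab$res_uid[lab$cls == "IFR"],
                  c(fx$truth$patch_a_uids, fx$truth$chain_b_uids))
})

test_that("well-separated chains produce no interface residues", {
  fx <- make_toy_complex(toy_complex_spec(n_residues = 6, len_b = 3,
                                          chain_sep = 100))
  lab <- label_residues(parse_pdb(fx$text), ifr_config(n_points = 240))
  expect_equal(sum(lab$cls == "IFR"), 0)
  expect_equal(interface_area(lab, "A"), 0)
  expect_equal(interface_area(lab, "B"), 0)
})

test_that("interface area equals the brute-force difference of the two passes", {
  fx <- make_toy_complex(toy_complex_spec(n_residues = 8, len_b = 4,
                                          chain_sep = 8))
  cx <- parse_pdb(fx$text)
  cfg <- ifr_config(n_points = 240)
  lab <- label_residues(cx, cfg)
  at <- cx$atoms
  iso_a <- residue_sasa(at[at$chain == "A", ], cfg$probe_radius, cfg$n_points)
  cpx <- residue_sasa(at, cfg$probe_radius, cfg$n_points)
  ref <- sum(pmax(iso_a$area - cpx$area[match(
    paste(iso_a$chain, iso_a$res_seq), paste(cpx$chain, cpx$res_seq))], 0))
  expect_equal(interface_area(lab, "A"), ref, tolerance = 1e-9)
  expect_gt(interface_area(lab, "A"), 0)
  expect_error(interface_area(lab, "Z"), "unknown chain")
})

test_that("interface area is invariant under rigid-body motion", {
  fx <- make_toy_complex(toy_complex_spec(n_residues = 8, len_b = 4,
                                          chain_sep = 8))
  cx <- parse_pdb(fx$text)
  cfg <- ifr_config(n_points = 960)
  a0 <- interface_area(label_residues(cx, cfg), "A")
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% rot
  cx$atoms$x <- xyz[, 1] + 5; cx$atoms$y <- xyz[, 2] - 3; cx$atoms$z <- xyz[, 3] + 1
  a1 <- interface_area(label_residues(cx, cfg), "A")
  expect_equal(a1, a0, tolerance = 0.03)
})

test_that("size classes follow the 800/3000 square-angstrom scheme", {
  expect_equal(size_class(c(0, 800, 801, 3000, 3500)),
               c("SMALL", "SMALL", "MEDIUM", "MEDIUM", "LARGE"))
  expect_error(size_class(-1), "non-negative")
})

test_that("the filter chain rejects entries at the documented stages", {
  cfg <- ifr_config(n_points = 120, min_chain_length = 4,
                    min_interface_area = 20)
  ok <- parse_pdb(make_toy_complex(toy_complex_spec(
    n_residues = 8, len_b = 4, chain_sep = 8))$text, pdb_id = "GOOD")
  lowres <- parse_pdb(make_toy_complex(toy_complex_spec(
    n_residues = 8, len_b = 4, chain_sep = 8, resolution = 3.5))$text,
    pdb_id = "LOWRES")
  short <- parse_pdb(make_toy_complex(toy_complex_spec(
    n_residues = 8, len_b = 3, chain_sep = 8))$text, pdb_id = "SHORT")
  apart <- parse_pdb(make_toy_complex(toy_complex_spec(
    n_residues = 8, len_b = 4, chain_sep = 60))$text, pdb_id = "APART")
  frag <- parse_pdb(make_toy_complex(toy_complex_spec(
    n_residues = 8, len_b = 4, chain_sep = 8))$text, pdb_id = "FRAG",
    is_fragment = TRUE)
  olig <- parse_pdb(make_toy_complex(toy_complex_spec(
    n_residues = 8, len_b = 4, chain_sep = 8))$text, pdb_id = "OLIG",
    oligomeric_state_consistent = FALSE)
  out <- filter_dataset(list(ok, lowres, short, apart, frag, olig), cfg)
  expect_equal(vapply(out$kept, function(e) e$pdb_id, ""), "GOOD")
  lg <- out$log
  expect_equal(lg$rejected_by[lg$pdb_id == "LOWRES"], "resolution")
  expect_equal(lg$rejected_by[lg$pdb_id == "SHORT"], "chain_length")
  expect_equal(lg$rejected_by[lg$pdb_id == "APART"], "interface_area")
  expect_equal(lg$rejected_by[lg$pdb_id == "FRAG"], "fragment")
  expect_equal(lg$rejected_by[lg$pdb_id == "OLIG"], "oligomeric_state")
})

test_that("interface areas straddling the threshold split keep/reject", {
  cfg_lo <- ifr_config(n_points = 240, min_chain_length = 4,
                       min_interface_area = 150)
  cx <- parse_pdb(make_toy_complex(toy_complex_spec(
    n_residues = 8, len_b = 4, chain_sep = 8))$text, pdb_id = "MID")
  area <- max(interface_area(label_residues(cx, cfg_lo), "A"),
              interface_area(label_residues(cx, cfg_lo), "B"))
  below <- ifr_config(n_points = 240, min_chain_length = 4,
                      min_interface_area = area + 10)
  above <- ifr_config(n_points = 240, min_chain_length = 4,
                      min_interface_area = area - 10)
  expect_equal(filter_dataset(list(cx), below)$log$rejected_by, "interface_area")
  expect_true(filter_dataset(list(cx), above)$log$kept)
})

test_that("redundancy reduction clusters by global-alignment identity", {
  s <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL"
  expect_equal(nrow(redundancy_reduce(c(a = s, b = s))), 1)

  set.seed(9)
  r1 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30, TRUE),
              collapse = "")
  r2 <- paste(sample(c("W", "Y", "G", "P"), 30, TRUE), collapse = "")
  if (pairwise_identity(r1, r2) < 0.1) {
    expect_equal(nrow(redundancy_reduce(c(a = r1, b = r2))), 2)
  }

  # one ~50%-identical pair among three sequences -> 2 clusters, matching
  # an all-pairs oracle
  half <- paste0(substr(s, 1, 15), "GGGGGGGGGGGGGGG")
  other <- "WWWWWWWWWWYYYYYYYYYYPPPPPPPPPP"
  seqs <- c(x = s, y = half, z = other)
  got <- redundancy_reduce(seqs, identity_cutoff = 0.30)
  idm <- outer(seqs, seqs, Vectorize(pairwise_identity))
  expect_gt(idm["x", "y"], 0.30)
  expect_lt(idm["x", "z"], 0.30)
  expect_lt(idm["y", "z"], 0.30)
  expect_equal(nrow(got), 2)
  # representatives are mutually below the cutoff
  expect_true(all(outer(got$sequence, got$sequence,
                        Vectorize(pairwise_identity))[upper.tri(diag(2))] <= 0.30))
})
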