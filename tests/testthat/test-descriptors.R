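# Density, sponge, hydrophobicity, electrostatic potential, CLO/CPO, CED
# and the weighted neighbor averages.

single_atom_pdb <- "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C"

test_that("density of a lone carbon matches the one-term closed form", {
  cx <- parse_pdb(single_atom_pdb)
  d3 <- density_descriptor(cx, "CA", radius = 3)
  expect_equal(d3$density, 12.011 / (4 / 3 * pi * 27), tolerance = 1e-12)
})

test_that("sponge of a lone atom is one minus its own volume fraction", {
  cx <- parse_pdb(single_atom_pdb)
  s3 <- sponge_descriptor(cx, "CA", radius = 3)
  v_c <- 4 / 3 * pi * 1.7^3
  expect_equal(s3$sponge, 1 - v_c / (4 / 3 * pi * 27), tolerance = 1e-12)
  expect_true(all(s3$sponge >= 0 & s3$sponge <= 1))
})

test_that("density and sponge match brute-force scans and grow monotonically", {
  cx <- make_toy_corpus(n_entries = 1, seed = 13)[[1]]
  at <- cx$atoms
  r <- residues(cx)
  prev_mass <- rep(0, nrow(r))
  for (rad in 3:7) {
    dd <- density_descriptor(cx, "CA", radius = rad)
    ss <- sponge_descriptor(cx, "CA", radius = rad)
    v <- 4 / 3 * pi * rad^3
    mass_in <- numeric(nrow(r))
    for (i in seq_len(nrow(r))) {
      ctr <- c(r$ca_x[i], r$ca_y[i], r$ca_z[i])
      d <- sqrt((at$x - ctr[1])^2 + (at$y - ctr[2])^2 + (at$z - ctr[3])^2)
      mass_in[i] <- sum(at$mass[d <= rad])
      expect_equal(dd$density[i], mass_in[i] / v, tolerance = 1e-12)
      vol_in <- sum(4 / 3 * pi * at$vdw[d <= rad]^3)
      expect_equal(ss$sponge[i], max(v - vol_in, 0) / v, tolerance = 1e-12)
    }
    expect_true(all(mass_in >= prev_mass))   # enclosed mass is monotone in radius
    prev_mass <- mass_in
  }
})

test_that("hydrophobicity is the scale value weighted by relative accessibility", {
  expect_equal(hydrophobicity("ILE", 0), 0)
  expect_equal(hydrophobicity("ILE", 1), 4.92)
  expect_equal(hydrophobicity(c("ASP", "TRP"), c(0.5, 0.25)),
               c(-8.72 * 0.5, 2.33 * 0.25))
})

test_that("electrostatic potential vanishes without charges and follows the screened sum", {
  # CA-only glycines carry no termini or side-chain charges
  cx <- parse_pdb(paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    sep = "\n"))
  ep <- electrostatic_potential(cx, ifr_config(n_points = 60))
  expect_true(all(ep$`EP@Ca` == 0))
  expect_true(all(ep$`EP@Avg` == 0))

  # charged fixture: brute-force screened Coulomb over the formal charges
  fx <- make_toy_complex(toy_complex_spec(seq_a = c("LYS", "ALA", "ASP"),
                                          seq_b = "ALA", chain_sep = 30))
  cx2 <- parse_pdb(fx$text)
  cfg <- ifr_config(n_points = 60)
  ep2 <- electrostatic_potential(cx2, cfg)
  at <- cx2$atoms
  a <- at[at$chain == "A", ]
  # charge sites: NZ (+1), OD1 centroid (-1), N-terminal N (+1), C-terminal O (-1)
  sites <- rbind(
    cbind(a[a$atom == "NZ", c("x", "y", "z")], q = 1),
    cbind(a[a$res_type == "ASP" & a$atom == "OD1", c("x", "y", "z")], q = -1),
    cbind(a[a$res_seq == 1 & a$atom == "N", c("x", "y", "z")], q = 1),
    cbind(a[a$res_seq == 3 & a$atom == "O", c("x", "y", "z")], q = -1))
  ca2 <- unlist(a[a$res_seq == 2 & a$atom == "CA", c("x", "y", "z")])
  d <- sqrt((sites$x - ca2[1])^2 + (sites$y - ca2[2])^2 + (sites$z - ca2[3])^2)
  ref <- sum(sites$q * exp(-d / cfg$ep_lambda) / (cfg$ep_epsilon * d))
  got <- ep2$`EP@Ca`[ep2$res_uid == "A_2_"]
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("potential of a single positive group decays with distance", {
  fx <- make_toy_complex(toy_complex_spec(seq_a = c("LYS", rep("ALA", 5)),
                                          seq_b = "ALA", chain_sep = 40))
  cx <- parse_pdb(fx$text)
  # keep only the lysine charge: strip termini by removing N of residue 1
  # and O of the last residue
  cx$atoms <- cx$atoms[!(cx$atoms$chain == "A" &
                           ((cx$atoms$res_seq == 1 & cx$atoms$atom == "N") |
                              (cx$atoms$res_seq == 6 & cx$atoms$atom == "O"))), ]
  ep <- electrostatic_potential(cx, ifr_config(n_points = 60))
  a <- ep[grepl("^A", ep$res_uid), ]
  vals <- a$`EP@Ca`[order(as.integer(sub("A_(\\d+)_", "\\1", a$res_uid)))]
  expect_true(all(vals > 0))
  expect_true(all(diff(vals[2:6]) < 0))  # farther residues see less potential
})

test_that("cross-link and cross-presence order match exhaustive pair scans", {
  cx <- parse_pdb(make_hairpin_pdb(40))
  cfg <- ifr_config()
  contacts <- detect_contacts(cx, cfg, intra_only = TRUE)
  r <- residues(cx)
  got <- clo(contacts, r$res_uid, cfg$min_seq_sep)
  # brute-force double loop over residue pairs
  ref <- integer(nrow(r))
  for (i in seq_len(nrow(r))) {
    partners <- character()
    for (k in seq_len(nrow(contacts))) {
      if (contacts$uid1[k] == r$res_uid[i]) partners <- c(partners, contacts$uid2[k])
      if (contacts$uid2[k] == r$res_uid[i]) partners <- c(partners, contacts$uid1[k])
    }
    partners <- unique(partners)
    seps <- abs(r$seq_index[match(partners, r$res_uid)] - r$seq_index[i])
    ref[i] <- sum(seps >= 30)
  }
  expect_equal(got$CLO, ref)
  expect_gt(sum(ref), 0)  # the hairpin does bring distant residues together

  cp <- cpo(cx, "CA", radius = 8, min_seq_sep = 30)
  ref_cpo <- integer(nrow(r))
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(nrow(r))) {
      if (i == j) next
      d <- sqrt((r$ca_x[i] - r$ca_x[j])^2 + (r$ca_y[i] - r$ca_y[j])^2 +
                  (r$ca_z[i] - r$ca_z[j])^2)
      if (d <= 8 && abs(r$seq_index[i] - r$seq_index[j]) >= 30) {
        ref_cpo[i] <- ref_cpo[i] + 1
      }
    }
  }
  expect_equal(cp$CPO, ref_cpo)
  expect_gt(sum(ref_cpo), 0)
  # CLO counts contacting partners only, so it cannot exceed a pure
  # proximity count at a generous radius
  cp_wide <- cpo(cx, "CA", radius = 12, min_seq_sep = 30)
  expect_true(all(got$CLO <= cp_wide$CPO + 1e-9))
})

test_that("short-range partners are excluded by sequence separation", {
  fx <- make_toy_complex(toy_complex_spec(n_residues = 5, len_b = 2,
                                          chain_sep = 8))
  cx <- parse_pdb(fx$text)
  cp <- cpo(cx, "CA", radius = 8, min_seq_sep = 30)
  expect_true(all(cp$CPO == 0))   # 5-residue chain: no pair reaches sep 30
})

test_that("weighted neighbor averages reduce correctly and match brute force", {
  set.seed(21)
  n <- 30
  pos <- matrix(runif(n * 3, 0, 12), n, 3)
  rel <- runif(n)

  # constant field is a fixed point in both modes
  cval <- rep(3.25, n)
  expect_equal(wna(cval, pos, "DIST", 15), cval)
  expect_equal(wna(cval, pos, "SURF", 15, rel), cval)

  # a single neighbor dominates regardless of weight
  p2 <- matrix(c(0, 0, 0, 5, 0, 0, 100, 100, 100), 3, 3, byrow = TRUE)
  v2 <- c(1, 9, 4)
  expect_equal(wna(v2, p2, "DIST", 15)[1], 9)
  expect_equal(wna(v2, p2, "SURF", 15, c(0.2, 0.7, 0.9))[1], 9)
  expect_equal(wna(v2, p2, "DIST", 15)[3], 4)   # no neighbors: own value

  vals <- rnorm(n)
  vals[c(4, 17)] <- NA
  for (mode in c("DIST", "SURF")) {
    got <- wna(vals, pos, mode, 15, rel)
    ref <- oracle_wna(vals, pos, mode, 15, rel)
    expect_equal(got, ref, tolerance = 1e-12)
  }
  # bounded by the neighbor value range
  got_d <- wna(vals, pos, "DIST", 15)
  rng <- range(vals, na.rm = TRUE)
  expect_true(all(got_d >= rng[1] - 1e-12 & got_d <= rng[2] + 1e-12, na.rm = TRUE))
  expect_error(wna(vals, pos, "DIST", -1), "non-negative")
})

test_that("the descriptor table emits every suite column exactly once", {
  cx <- make_toy_corpus(n_entries = 1, seed = 2)[[1]]
  cfg <- ifr_config(n_points = 120)
  desc <- compute_descriptors(cx, config = cfg)
  expected <- c("Hydrophobicity", "EP@Ca", "EP@LHA", "EP@Avg", "EP@Surf",
                sprintf("CED@%s_INT_%d", rep(c("Ca", "LHA"), each = 5), 3:7),
                "CLO", paste0("CPO@", c("Ca", "Cb", "LHA")),
                "PHI", "PSI", paste0("CHI", 1:4),
                sprintf("Density@%s_%d", rep(c("Ca", "LHA"), each = 5), 3:7),
                sprintf("Sponge@%s_%d", rep(c("Ca", "LHA"), each = 5), 3:7),
                paste0("Energy_", c("HYDROPHOBIC", "AROMATIC", "HB_MM", "HB_MS",
                                    "HB_SS", "HB_MWM", "HB_MWS", "HB_SWS",
                                    "HB_MWWM", "HB_MWWS", "HB_SWWS",
                                    "CHARGED_ATTRACTIVE", "CHARGED_REPULSIVE",
                                    "DISULFIDE")), "Energy_Total")
  expect_true(all(expected %in% names(desc)))
  expect_false(any(duplicated(names(desc))))
  aug <- wna_augment(desc, cfg)
  expect_true(all(paste0(expected, "_WNADist") %in% names(aug)))
  expect_true(all(paste0(expected, "_WNASurf") %in% names(aug)))
})

test_that("ced integrates only contacts whose midpoint falls in the sphere", {
  cx <- parse_pdb(make_hairpin_pdb(40))
  cfg <- ifr_config()
  ct <- detect_contacts(cx, cfg, intra_only = TRUE)
  expect_gt(nrow(ct), 0)
  r <- residues(cx)
  cc <- ced(cx, ct, "CA", radius = 5)
  v <- 4 / 3 * pi * 125
  for (i in seq_len(nrow(r))) {
    d <- sqrt((ct$mx - r$ca_x[i])^2 + (ct$my - r$ca_y[i])^2 +
                (ct$mz - r$ca_z[i])^2)
    expect_equal(cc$ced[i], sum(ct$energy[d <= 5]) / v, tolerance = 1e-12)
  }
})
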