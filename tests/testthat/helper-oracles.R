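# Independent brute-force oracles used to check the package's numeric
# paths. These deliberately avoid the implementation's code routes.

# signed torsion via normal-vector geometry (acos + oriented sign)
oracle_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# SASA by independent random-direction sampling at high density
oracle_sasa_dense <- function(atoms, probe = 1.4, n = 20000, seed = 42) {
  set.seed(seed)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atoms$vdw + probe
  vapply(seq_len(nrow(xyz)), function(i) {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * rad[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      free <- free & (rowSums(sweep(p, 2, xyz[j, ])^2) >= rad[j]^2)
    }
    mean(free) * 4 * pi * rad[i]^2
  }, 0)
}

# Mann-Whitney concordant-pair AUC (ties count half)
oracle_mw_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# weighted mean over explicit neighbor loop
oracle_wna <- function(values, pos, mode, cutoff, rel_acc = NULL) {
  n <- length(values)
  out <- values
  for (i in seq_len(n)) {
    ws <- 0; acc <- 0; found <- FALSE
    for (j in seq_len(n)) {
      if (i == j || is.na(values[j])) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d > cutoff || d == 0) next
      w <- if (mode == "DIST") 1 / d else rel_acc[j]
      if (is.na(w)) next
      ws <- ws + w; acc <- acc + w * values[j]; found <- TRUE
    }
    if (found && ws > 0) out[i] <- acc / ws
  }
  out
}

# Welch statistic from first principles
oracle_welch <- function(a, b) {
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# hairpin chain: two antiparallel strands so sequence-distant residues are
# spatially adjacent (exercises CLO/CPO); written directly as PDB text
make_hairpin_pdb <- function(n = 40, strand_gap = 3.1) {
  half <- n / 2
  lines <- character(); serial <- 0
  emit <- function(nm, res, ch, seq, x, y, z, el) {
    serial <<- serial + 1
    nm4 <- if (nchar(nm) < 4) paste0(" ", nm) else nm
    lines <<- c(lines, sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      "ATOM", serial, nm4, "", res, ch, seq, "", x, y, z, 1, 0, el))
  }
  for (i in seq_len(n) - 1) {
    if (i < half) { s <- 3.8 * i; y <- 0 } else { s <- 3.8 * (n - 1 - i); y <- strand_gap }
    emit("N", "ALA", "A", i + 1, s, y, 0, "N")
    emit("CA", "ALA", "A", i + 1, s + 1.3, y + 0.45, 0.9, "C")
    emit("C", "ALA", "A", i + 1, s + 2.5, y, 0, "C")
    emit("O", "ALA", "A", i + 1, s + 2.5, y - 0.6, -1.0, "O")
    emit("CB", "ALA", "A", i + 1, s + 1.3, y + 0.45, 2.45, "C")
  }
  paste(c(lines, "END"), collapse = "\n")
}

# toy bundle trained once per test run (shared by prediction tests)
.fixture_cache <- new.env(parent = emptyenv())
cached_toy_training <- function() {
  if (is.null(.fixture_cache$bundle)) {
    cfg <- ifr_config(n_points = 120, k_folds = 3, seed = 7)
    corpus <- make_toy_corpus(n_entries = 8, seed = 7)
    .fixture_cache$config <- cfg
    .fixture_cache$corpus <- corpus
    .fixture_cache$bundle <- suppressWarnings(train_ifr(corpus, cfg))
  }
  list(bundle = .fixture_cache$bundle, corpus = .fixture_cache$corpus,
       config = .fixture_cache$config)
}
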