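# Numerical rolling-probe solvent accessible surface area (Shrake-Rupley
# style point sampling) with a deterministic golden-spiral point set, so
# identical inputs always give identical areas.

#' Deterministic unit-sphere point set (golden spiral)
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * (i - 0.5)
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent accessible surface area per atom
#'
#' Rolling-probe SASA: each atom's solvent-expanded sphere (van der Waals
#' radius + probe radius) is sampled at `n_points` deterministic surface
#' points; a point is accessible when it lies outside every neighbor's
#' expanded sphere. The per-atom area is the accessible fraction times the
#' expanded-sphere area.
#'
#' @param atoms tibble with columns `x`, `y`, `z`, `vdw` (one row per atom).
#' @param probe_radius solvent probe radius in angstrom (water: 1.4).
#' @param n_points sampling points per atom; at least 12.
#' @return numeric vector of per-atom areas in square angstrom.
#' @export
#' @examples
#' a <- tibble::tibble(x = 0, y = 0, z = 0, vdw = 1.7)
#' sasa(a)              # isolated sphere: 4*pi*(1.7+1.4)^2
sasa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  stopifnot(nrow(atoms) >= 1, probe_radius > 0)
  if (n_points < 12) {
    stop("n_points must be >= 12: fewer sampling points are not meaningful")
  }
  pts <- sphere_points(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atoms$vdw + probe_radius
  n <- nrow(xyz)
  areas <- numeric(n)
  # neighbor pruning on pairwise center distances
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    ri <- rad[i]
    nb <- which(d2[i, ] < (ri + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      areas[i] <- 4 * pi * ri^2
      next
    }
    p <- sweep(pts * ri, 2, xyz[i, ], `+`)   # n_points x 3 test points
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p[acc, 1, drop = TRUE] - xyz[j, 1]
      dy <- p[acc, 2, drop = TRUE] - xyz[j, 2]
      dz <- p[acc, 3, drop = TRUE] - xyz[j, 3]
      acc[acc] <- (dx * dx + dy * dy + dz * dz) >= rad[j]^2
    }
    areas[i] <- mean(acc) * 4 * pi * ri^2
  }
  areas
}

#' Per-residue solvent accessible area
#'
#' Sums [sasa()] per-atom areas over each residue's atoms.
#'
#' @param atoms tibble of atoms with locator columns `chain`, `res_seq`,
#'   `ins` plus `x`, `y`, `z`, `vdw`.
#' @inheritParams sasa
#' @return tibble with `chain`, `res_seq`, `ins`, `area`.
#' @export
residue_sasa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  atoms$area <- sasa(atoms, probe_radius, n_points)
  atoms |>
    dplyr::group_by(.data$chain, .data$res_seq, .data$ins) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop")
}
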