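---
title: "Predicting protein–protein interface residues from structural descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interface residues from structural descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protifr)
```

## The problem and the model

When two protein chains form a complex, a patch of each chain's surface is
buried against the partner. The residues of that patch — interface-forming
residues (IFRs) — are distinguishable from the remaining free-surface
residues (FSRs) by their local physicochemical and structural
nano-environment alone, without any sequence-conservation signal. protifr
implements this idea end to end:

1. **Labeling.** Solvent-accessible surface area is computed twice per
   residue by numerical rolling-probe sampling: once with the chain in
   isolation and once in the full complex. A residue losing more than a
   small threshold of exposed area upon complexation is an IFR; other
   residues are FSRs when sufficiently exposed and buried otherwise. The
   per-chain interface area is the summed accessibility loss.
2. **Descriptors.** For every residue a suite of structure-derived
   descriptors is computed: accessibility-weighted hydrophobicity
   (Radzicka scale), screened electrostatic potential at four anchors,
   typed contact energies (hydrophobic 0.6, aromatic 1.5, hydrogen bond
   2.6 — direct and water-mediated —, charged pair 10.0, disulfide 85.0
   kcal/mol), their "unused" counterparts (the gap to the corpus maximum
   for the amino-acid type), contact energy density in probe spheres of
   3–7 Å around the Cα and the last heavy atom (LHA), cross-link order
   (contacting partners ≥ 30 positions away in sequence), cross-presence
   order (residues within 8 Å and ≥ 30 positions away), local mass
   density and emptiness ("sponge") in 3–7 Å spheres, and backbone
   (φ/ψ) and side-chain (χ1–χ4) dihedrals.
3. **Neighbor averaging.** Each descriptor *D* is additionally averaged
   over the residues within 15 Å, weighted by inverse distance
   (`_WNADist`) or by the neighbors' relative accessibility (`_WNASurf`):
   the spatial context of a residue carries much of the interface signal.
4. **Per-type classification.** The labeled descriptor matrix is split
   into one datamart per amino-acid type. Within each datamart, columns
   with pairwise |r| > 0.85 are pruned, the remainder standardized and
   projected onto the principal components of the training correlation
   matrix retaining ≥ 95% of the variance, and a two-class linear
   discriminant (Gaussian class-conditionals, pooled covariance, priors
   from class frequencies) maps each residue to a posterior interface
   probability. The 20 type-specific classifiers are applied side by side
   and their outputs concatenated; no cross-type recalibration is done.
   The motivation for per-type models is empirical: the descriptor
   correlation structure — and hence the retained component count —
   differs between amino-acid types.
5. **Evaluation.** ROC curves are built by sweeping every distinct
   posterior as a threshold; AUC is the trapezoidal integral (identical
   to the Mann–Whitney concordant-pair statistic, ties counting half),
   and the Matthews correlation coefficient is tracked per threshold to
   report the maximum-MCC cutoff. Cross-validation is split at the level
   of whole structures, never residues, and every fitted stage —
   energy maxima, correlation pruning, PCA, LDA — sees training folds
   only. Classifier families are compared by Welch's unequal-variance
   t-test on per-fold AUCs.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | water probe for accessibility |
| `n_points` | 960 | – | sampling points per atom (deterministic spiral) |
| `delta_area` | 0.1 | Å² | accessibility loss defining an IFR |
| `exposure_min` | 0.05 | – | relative accessibility defining the surface |
| `hbond_cut` | 3.2 | Å | N/O–N/O hydrogen-bond distance |
| `charged_cut` | 6.0 | Å | charged-group pair distance |
| `hydrophobic_cut` | 3.9 | Å | apolar carbon pair distance |
| `aromatic_cut` | 5.0 | Å | ring-centroid distance |
| `disulfide_cut` | 2.5 | Å | SG–SG distance |
| `wna_cutoff` | 15 | Å | neighbor-average radius |
| `cpo_radius` | 8.0 | Å | cross-presence probe sphere |
| `min_seq_sep` | 30 | residues | "sequence-distant" threshold |
| `cor_threshold` | 0.85 | – | pruning threshold on \|r\| |
| `variance_target` | 0.95 | – | retained PCA variance |
| `k_folds` | 10 | – | cross-validation folds |
| `decision_cutoff` | 0.50 | – | posterior call threshold |

The dataset filter chain keeps complexes at resolution ≤ 3 Å with no
nucleic-acid chains, a consistent oligomeric-state flag, at least two
chains of ≥ 50 residues, interface area ≥ 200 Å² and no fragment flag;
redundancy is removed by greedy clustering at 30% global-alignment
identity. Interfaces are sized small (≤ 800 Å²), medium (≤ 3000 Å²) or
large.

## Design choices where the design was open

* **Contact geometry.** The energy table fixes energies per interaction
  type but no geometric criteria; the cutoffs above are our convention
  and are config-exposed. Charged, aromatic and disulfide contacts are
  recorded once per residue pair (they are group-level interactions);
  hydrogen bonds and hydrophobic contacts once per qualifying atom pair.
  An atom pair inside two charged side-chain groups is a charged
  contact, never double-counted as a hydrogen bond, and sequence-adjacent
  residues are never contact partners.
* **Electrostatics.** The potential is a Debye-screened Coulomb sum
  (λ = 8 Å, ε = 80) over a chain's formal charges (Asp/Glu −1,
  Lys/Arg/His +1, termini ±1), exposed behind the same descriptor
  interface a Poisson–Boltzmann solver would use, so a full solver can
  be plugged in without touching the pipeline.
* **Neighbor-average weights.** `WNADist` uses w = 1/d and `WNASurf`
  uses the neighbor's relative accessibility; with no neighbor in range
  (or all-zero weights) the residue's own value is kept.
* **Unused-energy reference.** The per-type maxima are computed over the
  training corpus supplied at fit time and persisted inside the bundle,
  keeping training reproducible and prediction self-contained.
* **Cross-validation freezing.** The retained component count per type
  is frozen from the first fold and reused in the others, so fold models
  differ only in their fitted parameters, not their dimensionality.
* **Contact-derived descriptors use intra-chain contacts** and the
  potential sums a chain's own charges, so the full suite is computable
  for an unbound chain; density and sponge spheres see all protein atoms
  of the structure as given.
* **Degenerate inputs.** Missing atoms never abort processing: the
  dependent descriptors are marked missing and such rows are dropped
  from the datamarts (with a per-type log). A numerically singular
  pooled covariance is ridge-regularized (1e-6 on the diagonal) with a
  warning; undefined precision (no predicted positives) is reported as
  `NA`, never as 0; tie groups of equal scores are collapsed into single
  ROC points.
* **Torsion sign.** Dihedrals follow the standard IUPAC signed
  convention (invariant under reversing the atom chain), verified
  against an independent vector-algebra formulation and bio3d.

## What the synthetic generators emulate — and what they do not

`make_toy_complex()` builds two chains on an idealized extended backbone
(N–CA 1.46/CA–C 1.52/C–N 1.33 Å spacing along x), side chains as single
pseudo-atoms at the last-heavy-atom position (full linear side chains for
Ser/Cys/Lys/Met/Glu where χ angles are exercised), with a facing contact
patch and optional planted contacts placed at exact distances. This gives
fixtures whose interface set, contact list and geometry are known by
construction. `make_gaussian_mart()` draws two identity-covariance
Gaussian classes at separation Δ, whose Bayes-optimal AUC is
Φ(Δ/√2) — an analytic yardstick for the classifier stack — and can plant
duplicated/linearly dependent columns to exercise pruning and PCA.

Neither generator mimics real protein folds, packing, rotamer
distributions, crystallographic noise or the class imbalance of real
interfaces. Passing tests therefore demonstrate that every stage computes
what it claims on inputs with known answers — not that the shipped
defaults reach any particular accuracy on real complexes, which requires
training on a curated structure corpus.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
toy corpora of 5–8 two-chain complexes (10 + 4 residues) at 120 sampling
points per atom for end-to-end training, 960 points where accessibility
itself is under test, Gaussian datamarts of 2 000–5 000 rows for the
analytic checks, and 100 000 simulated residues for the
random-classifier limits. These sizes were chosen so each property is
measured well inside its tolerance; all of them are parameters, and
users can scale them up freely.

## A small end-to-end run

```{r example, eval = FALSE}
cfg <- ifr_config(n_points = 120, k_folds = 3, seed = 7)
corpus <- make_toy_corpus(n_entries = 8, seed = 7)
bundle <- train_ifr(corpus, cfg)
tidy(bundle)

pred <- predict_structure(bundle, corpus[[1]])
roc <- roc_auc(pred$p_ifr[!is.na(pred$p_ifr)],
               as.integer(pred$cls[!is.na(pred$p_ifr)] == "IFR"))
glance(roc)
autoplot(roc)
```

## Known limitations

* The electrostatic descriptor is a screened-Coulomb stand-in, not a
  finite-difference Poisson–Boltzmann solution.
* No sequence-conservation descriptor is computed (it needs homologue
  alignments and, by design, the structural suite is meant to stand on
  its own).
* Structures are used as given: no repair, hydrogen placement or
  symmetry expansion; the oligomeric-state and fragment flags are
  accepted as metadata, not recomputed.
* The accessibility normalizer uses theoretical per-type maxima, so
  `relative_acc` can slightly exceed 1 for distorted geometry.
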