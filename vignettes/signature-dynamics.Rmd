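---
title: "Signature dynamics of structural ensembles: models and methods"
author: "sigdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature dynamics of structural ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdyn)
```

## The problem

A protein family that shares one fold — such as the seven-transmembrane
(7-TM) bundle of class A G-protein coupled receptors — usually has many
experimentally resolved structures spread over species, subtypes, and
functional states (active vs inactive). Two complementary questions arise:

1. **What does the ensemble of structures itself say?** Treating each
   member as a point in 3N-dimensional Cα coordinate space, principal
   component analysis (PCA) of the ensemble covariance identifies the
   dominant directions of structural variability, and member projections
   reveal whether those directions separate activation states or species.
2. **What dynamics does the shared fold encode?** Elastic network models
   (GNM/ANM) predict, from a single structure, the equilibrium
   fluctuations intrinsic to the fold. Aggregating per-member mode
   spectra across the family yields the family's *signature dynamics*:
   per-residue mean-square fluctuation (MSF) profiles, per mode regime,
   with their variation across members.

`sigdyn` implements both analyses end to end, plus the statistical
machinery to compare labeled subsets (e.g. active vs inactive) against
randomized splits, and a fully seeded synthetic generator so the entire
pipeline is testable without downloading any structure.

## Ensemble construction

Members are parsed at Cα resolution from PDB text (`parse_ca_structure()`;
one chain each, altlocs resolved to the highest-occupancy conformer with
ties to altloc A, insertion codes appended to the residue key, residues
with a known parent mapped to their one-letter code and truly unknown
residues to `X`). Each member is mapped onto a chosen reference by global
Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 1); members
below 20% identity are flagged unmappable. Reference positions resolved in
fewer than a fraction `occupancy_threshold` (default 0.9) of members are
dropped, then members resolving less than 80% of the retained positions
are dropped; the filter iterates to a fixed point so both guarantees hold
simultaneously.

Superposition is iterative: each member is Kabsch-superposed (proper
rotations only, mask-weighted) first onto the reference and then
repeatedly onto the running ensemble mean until the mean moves by less
than `tol` (default 1e-4 Å RMSD). After convergence, the few coordinates a
member did not resolve are imputed with the ensemble mean at that
position. Imputation keeps one common position set for PCA and GNM — the
alternative (dropping every position any member misses) discards far more
data — but the mask is retained, and per-position occupancy is carried
into all profile outputs so low-occupancy positions can be judged
accordingly.

## Similarity metrics

Three pairwise matrices summarise the family (all symmetric, with the
metric-appropriate diagonal, asserted at construction):

* **Sequence**: identity fraction *f* over aligned non-gap columns of the
  pairwise alignment; the normalized Hamming distance is 1 − *f*. We use
  pairwise alignments rather than one joint multiple alignment because
  they are deterministic and order-independent; for the tight families
  this pipeline targets the two give nearly identical identities.
* **Structure**: RMSD over commonly resolved positions after a *fresh*
  pairwise superposition (never through imputed coordinates).
* **Dynamics**: spectral distance `d = arccos(SO)` where `SO` is the
  covariance overlap of the two members' GNM spectra over a mode window
  (default modes 1–20, the slow range where family signal concentrates).

Heatmap ordering uses average-linkage hierarchical clustering of the
sequence matrix; the same order is reused for the structure and dynamics
maps so the three spaces can be compared panel by panel. A degenerate
all-ties matrix preserves input order.

## Elastic network models

The **GNM** places a node at each Cα and a uniform spring (force constant
`gamma`) between nodes within `cutoff` (default 10 Å). The Kirchhoff
matrix Γ is the contact-graph Laplacian; its eigendecomposition (one zero
mode removed; more than one means a disconnected graph and is an error)
gives modes `u_k` with eigenvalues `λ_k`. The MSF of residue *i* over a
mode subset is `Σ_k u_k[i]² / λ_k`, in units of 1/`gamma` — the thermal
prefactor kT/γ is deliberately omitted since all downstream use is
shape-based (profiles are normalized to unit sum before aggregation,
because each member's absolute scale is arbitrary).

The **ANM** extends this to 3N dimensions with the standard super-element
Hessian (contact blocks `−γ d dᵀ/|d|²`; cutoff default 15 Å). A
non-degenerate structure has exactly six zero modes (rigid translations
and rotations); any other count is an error. A two-bead dimer is admitted
as the closed-form limiting case (five zero modes, one bond-stretch mode
of eigenvalue 2γ). Zero modes are detected at `λ < 1e-8 × max(λ)` — a
scale-free tolerance, so results are invariant to the units of `gamma`.

ANM modes of the reference structure are compared to ensemble PCs by the
absolute correlation cosine of the two unit 3N-vectors; the absolute value
is used because eigenvector signs are arbitrary.

## Ensemble PCA

PCA eigendecomposes the 3N × 3N covariance of member coordinate vectors
about the ensemble mean with divisor M − 1. Component signs are fixed
(largest-magnitude entry positive) for determinism. Variance fractions are
eigenvalue over total coordinate variance. Per-residue mobility profiles
take the Euclidean norm of each residue's (x, y, z) triplet within a
component, scaled by √eigenvalue so that profiles carry displacement units
and leading components are visibly larger. Unsuperposed input is refused
outright: rigid-body motion would otherwise masquerade as leading
variance.

## Mode matching, overlap, and signature profiles

Corresponding modes drift in rank across homologs, so each member's GNM
modes are matched to the reference spectrum greedily in ascending
reference-mode order: reference mode *r* takes the unassigned member mode
with the largest absolute overlap, and the sign making that overlap
positive is recorded. Greedy matching is deterministic and, on ensembles
of homologous structures where mode crossing is local, agrees with
optimal assignment for the slow modes that matter here.

The covariance overlap between members A and B over modes i..j, with GNM
mode variances `σ_k = 1/λ_k`, is

    SO = 1 − sqrt[ (Σσ_A + Σσ_B − 2 Σ_kl √(σ_Ak σ_Bl) (u_k·v_l)²)
                   / (Σσ_A + Σσ_B) ]

which is 1 for identical spectra and 0 for orthogonal equal-variance
spectra. The bracket cancels to machine precision for equal spectra, so
relative values below 1e-14 are treated as exactly zero; the result is
clipped to [0, 1]. The quantity is invariant to mode order and sign within
the window.

Signature profiles aggregate per-member, unit-sum-normalized regime MSFs
elementwise: mean, population variance (divisor M — the profile is a
descriptive envelope, not an inferential estimate), minimum and maximum.
Mode regimes follow the reference numbering through the matching:
*global* = modes 1–3, *low-frequency* = 4–20, *low-to-intermediate* =
21–60; the *fastest* regime takes each member's ten highest-frequency
modes and needs no matching. Raw (unnormalized) aggregation is available
via `normalize = FALSE`.

## State comparison and the randomized null

`split_comparison()` builds one signature profile per labeled subset and
reports the per-position absolute mean difference and the variance ratio
(first label over second, floored at 1e-12). `randomized_split_null()`
repeats the same computation over seeded label-blind splits that preserve
the subset sizes — size preservation keeps the null comparable — and
returns per-position 50/95/99% quantile bands. `mode_overlap_map()`
computes mode–mode overlaps member-pairwise across the two subsets and
only then averages; averaging profiles first would destroy the dispersion
(the standard deviation of the mode–mode correlations), which is itself a
diagnostic: tight-but-different dynamics across states show low mean
overlap *and* low dispersion relative to random splits.

No formal p-values are attached to the per-position difference: the
comparison is presented, as in common practice, against the null band.

## The synthetic generator

`make_bundle()` builds an idealized antiparallel helix bundle (defaults: 7
helices × 25 residues, rise 1.5 Å, 100°/residue, helix radius 2.3 Å, on a
12 Å circle, 6-residue connecting arcs; 211 positions). Loop arcs bulge
beyond the helix ends with an apex raised as needed to keep ~3.2 Å
spacing; geometry closer than 2.0 Å between any two Cα is an error.

`plant_ensemble()` draws members as `template + Σ_k z_k √(variance_k)
mode_k + noise` with orthonormal planted modes — a linear-Gaussian model
chosen deliberately so the PCA ground truth is exact and parameter
recovery is a sharp test. `plant_two_state()` adds a labeled shift along a
segment-localized, translation-orthogonalized raised-sine mode (an
"ICL3-like" loop signal) and extra isotropic disorder on that segment for
the inactive group. Default study conditions, chosen once on physical
grounds: within-state coordinate noise 0.3 Å (typical Cα positional
uncertainty), inactive-segment extra noise 1.5 Å (flexible-loop disorder),
within-state shift-mode SD 0.5 Å, background collective variances 2 and
1 Å², shift amplitude 6 Å (the scale of a cytoplasmic loop opening).

What the generator does *not* emulate: side chains and sequence-structure
coupling (mutated sequences do not move coordinates), membrane anchoring,
anharmonic loop dynamics, and crystallographic artifacts beyond isotropic
noise plus missing residues. Tests passing on this generator therefore
validate the estimators and their statistical contracts, not the biology
of any particular receptor family.

## Problem sizes and numerical choices in the test suite

The packaged tests and the acceptance script use: 20 replicate two-state
ensembles of 20 members per state (a deliberate scale-down of a
family-sized ensemble — large enough that random-split label imbalance
does not smear a planted shift into the null band), 500 random splits per
null, M = 500 members for planted-variance recovery on a 12-residue
template, and 20–50 random chains for the elastic-network oracle checks.
Oracles are independent implementations: the Kirchhoff pseudoinverse
diagonal (`MASS::ginv`) for GNM MSFs, singular value decomposition of the
centered data matrix for PCA eigenvalues, Horn's quaternion eigenproblem
for Kabsch superposition, and an explicit double-loop evaluation of the
covariance-overlap formula.

Other numerical conventions: covariance divisor M − 1 and population
variance (divisor M) for profile envelopes; eigen-sign fixing for
determinism; all randomness flows from explicit seeds (the randomized null
*requires* one); clustering ties preserve input order; degenerate
geometries (collinear point sets, disconnected contact graphs) raise
errors rather than returning silently wrong results.

## Limitations

* The mapping is sequence-guided; structurally analogous but sequence
  divergent members (below 20% identity) are dropped rather than aligned
  structurally.
* Imputed (mean-filled) positions slightly shrink apparent variance at
  low-occupancy positions; occupancy is reported alongside every profile.
* Greedy mode matching can be suboptimal where many modes cross strongly;
  the slow regimes analysed here are robust to this in practice.
* The variance envelopes are descriptive; the randomized-split null is
  the only inferential device, and it controls subset sizes but not
  covariates such as species composition.

## A minimal run

```{r, eval = FALSE}
dir <- tempfile()
ds <- write_synthetic_dataset(dir, m_per_state = 8, seed = 1)
cfg <- pipeline_config(dir, ds$metadata, reference_id = "TS001",
                       out_dir = file.path(dir, "out"), seed = 1)
res <- run_pipeline(cfg)
res$pca                      # variance fractions of PC1..3
res$state$comparison         # active/inactive signature difference
plot(res$profiles$global)    # signature envelope, global modes
```
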