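---
title: "Quantifying backbone conformational variability across structure ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying backbone conformational variability across structure ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensvar)
library(dplyr)
```

## The model

`ensvar` measures local backbone variability of one protein across many of
its crystal structures. The measurement chain has four stages.

**1. Structural-letter encoding.** Every four consecutive Cα atoms form a
fragment whose geometry is summarized by four numbers: the three "long"
inter-Cα distances `d13`, `d14`, `d24` and the signed projection `chi` of the
fourth Cα onto the normal of the plane through the first three (the sign
carries handedness, so mirror conformations are distinguishable). A hidden
Markov model over these descriptors — Gaussian emissions per letter, a
first-order transition matrix — assigns each fragment a symbolic state, a
*structural letter*. A gap-free chain of `p` residues yields `p − 3` letters,
each anchored to the third residue of its fragment. The canonical published
alphabet has 27 letters labelled `a, A–Z`; its fitted parameters are not
re-estimated here. They are a versioned JSON model file (see
`read_alphabet_model()`), which isolates the package from any uncertainty
about the exact published descriptor parameterization: the model file *is*
the contract. Decoding is Viterbi by default; a nearest-centroid mode exists
for models without a trusted transition matrix.

**2. MSLA.** Each chain's letters are projected through the amino-acid
multiple sequence alignment: every aligned cell holds the letter anchored at
that residue, or a missing symbol when the cell is a gap, the residue is
unresolved, or the residue carries no letter (the first two and the last
residue of every encodable run). The package consumes a precomputed aligned
FASTA — computing alignments is a solved problem and is left to the
aligners built for it.

**3. neqSL.** For each aligned column the letter counts (missing cells
excluded) give frequencies `p_i`, and

`neqSL = exp(−Σ p_i ln p_i)`

is the effective number of local conformations: 1 for a fully conserved
column, up to the alphabet size for a uniform one. Columns are categorized
as conserved (exactly one distinct letter — an integer test, not a float
comparison), weakly variable (`1 < neqSL < 1.5`) or variable
(`neqSL ≥ 1.5`; the boundary belongs to "variable"). Excluding missing
cells rather than treating them as a 28th letter keeps the statistic a
property of *observed* conformations instead of crystallographic disorder.

**4. Subset contrasts.** Ligand-induced variability is read from
`Δ = neqSL(apo + holo) − neqSL(apo)`, banded at `Δ ≥ 1` (moderate) and
`Δ ≥ 2` (substantial). No printed threshold exists for the opposite sign, so
any negative Δ is flagged `stabilized` and reported; the severity threshold
`delta_stab` is configurable with default 0 (report-only).

## Companion measurements

**Flexibility.** Raw B-factors are incomparable across structures
(resolution, temperature and refinement shift and scale them), so each
chain's Cα B-factors are z-scored within the chain:
`Bnorm = (B − mean)/sd`. Any affine per-structure distortion cancels
exactly. The sample (n−1) standard deviation is used; the population variant
is a flag. Positions with mean Bnorm (one vote per chain, homo-oligomer
copies included) strictly greater than 0 are *flexible*, all others *rigid*
— the measure-zero case `mean = 0` deliberately falls on the rigid side of
the strict rule.

**Pockets.** All chains are Kabsch-superposed (SVD with the determinant
correction, so reflections are impossible) onto a configurable reference
chain, pairing Cα atoms through the alignment. Every co-crystallized
ligand's heavy atoms are merged — without deduplication — into a
*superligand*; a chain's pocket is every protein atom within 4.5 Å
(inclusive) of any superligand atom, applied identically to apo and holo
chains; the consensus pocket is the union of pocket residues over chains.
The distance rule is evaluated by exact chunked arithmetic, bit-equivalent
to the brute-force double loop the tests compare against.

**Ligand typing.** Pairwise Tanimoto similarities of binary fingerprints
(166-bit structural keys in the reference setup) are rounded to three
decimals *before* clustering, so downstream results depend only on the
stored matrix. Clustering is Ward's method in the squared-dissimilarity
variant (`hclust(method = "ward.D2")`) on `1 − T`, cut at `k = 7` by
default; singleton clusters are dropped and survivors relabelled in order of
first appearance. Fingerprint generation from chemistry is an adapter at the
boundary — the module consumes bit vectors, which keeps it testable without
a chemistry toolkit.

**Contact network.** Superligand atoms are k-means clustered in 3D over a
scan of cluster counts. Two diagnostics are kept per count: *uniqueness*
(fraction of cluster × complex pairs holding ≤ 1 atom) and *occupancy*
(fraction holding exactly one). The default selection filters on a
uniqueness floor (0.95) and then maximizes occupancy, breaking ties by
minimal within-cluster sum of squares and then by smaller k. Occupancy — the
"one ligand atom per structure per cluster" ideal enforced in both
directions — is the deciding criterion because WCSS alone cannot decide: it
is non-increasing in k, so minimizing it over an admissible set always
drives the choice to the top of the grid, whereas occupancy peaks where
clusters correspond one-to-one with recurrently occupied sites. Contacts are
(residue, ligand-atom) pairs within 4.5 Å between a chain and *its own*
ligands; they are deduplicated to (aligned position, atom cluster) edges and
kept only when present in strictly more than 10 % of complexes. The network
is bipartite (igraph), residue nodes annotated with neqSL/category/
flexibility, cluster nodes with size and small-molecule enrichment banded at
0.3/0.7.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| variability thresholds | 1.5 (and exact 1) | effective letters | the published three-category rule |
| Δ bands | 1, 2 | effective letters | the published moderate/substantial bands |
| pocket / contact cutoff | 4.5 (inclusive) | Å | the published heavy-atom contact radius |
| recurrence filter | > 0.10 (strict) | fraction of complexes | "present in over 10 %" |
| ligand tree cut `k` | 7 | clusters | the published protocol; singletons dropped after the cut |
| k-means scan | grid + `n_init = 50`, final `n_init = 500` | — | mirrors the published 50-start scan and 500-start final fit; tests scale the grid down |
| uniqueness floor | 0.95 | fraction | "each cluster should ideally contain only one atom per structure", allowing a small tolerance |
| `min_length` | 50 | residues | separates target chains from peptide ligands; dataset-specific, always explicit |

## Numerical decisions

- Viterbi runs entirely in log space with a floor of −1e12 on log densities,
  so emission underflow can never propagate NaN; ties break toward the lower
  letter index.
- Alternate locations keep the highest-occupancy conformer, ties broken by
  altloc label order; residues order by `(resnum, icode)` with empty
  insertion codes first.
- Chain breaks (author-numbering step ≠ 1 or missing Cα) split chains into
  runs; geometry is never interpolated across a break, because fabricated
  fragments would contaminate the letter statistics.
- Kabsch superposition refuses < 3 points and collinear configurations, and
  forces det(R) = +1.
- k-means augments the random multi-start with one deterministic
  farthest-point-seeded run and keeps the better objective: random starts
  alone routinely miss the global optimum exactly at the true cluster count
  when clusters are tight and well separated, which is the regime the scan
  is trying to detect.
- `stats::kmeans` refuses `k = n`; that case is the exact zero-WCSS optimum
  and is constructed directly.
- Reported neqSL values are rounded to 2 d.p. in outputs; all internal
  comparisons use full precision. Logo information content is the
  uncorrected `log2(27) − H₂` (no small-sample correction), which keeps the
  cross-module identity `info_bits = log2(27) − log2(neqSL)` exact.

## The synthetic generator

`make_ensemble()` emulates the *shape* of a curated crystallographic
ensemble so that every stage has a ground truth to recover:

- Chains are ideal α-helices (radius 2.3 Å, rise 1.5 Å/residue,
  100°/residue — generator constants, not claims about any real protein)
  split into segments by author-numbering gaps, the in-silico analogue of
  unmodelled loops. Coordinates carry ≤ 0.05 Å of uniform jitter; each chain
  sits in its own random rigid "crystal frame" on a 250 Å grid.
- **Planted conformational variability** lives at the anchor of the *final*
  four-Cα window of a segment: per chain a letter is drawn from a specified
  distribution (default: the 67 %-majority five-letter mix of a worked
  substituted-position column) and realized by displacing the segment's last
  residue radially by that letter's characteristic offset (±2 Å, ±4 Å …).
  Displacing any interior residue would perturb all four windows containing
  it and smear the signal over neighbouring aligned positions; the final
  residue of a segment belongs to exactly one window, so the planted signal
  lands on exactly the chosen positions and nowhere else. The matched
  alphabet model's emission means are computed *from the generator's own
  geometry* (σ = 0.08 Å, isotropic), with a generator self-check that all
  letter means are ≥ 6σ apart.
- **Planted flexibility** is a B-factor profile (baseline 30 Å², bumps of
  +3 profile-scale at chosen positions) observed through a per-chain affine
  distortion (`a ∈ [0.5, 2]`, `b ∈ [−5, 10]`) plus small per-residue noise
  (sd = 20 % of the bump scale). Attributing the dominant inter-structure
  variation to affine effects is exactly the premise of the Bnorm
  normalization; it also makes sign-rule recovery of the planted loop
  deterministic at the 50-chain scale, where a pure per-residue-noise model
  would produce false "flexible" calls by chance.
- **Ligands** are atom clouds around blob centres placed 4 Å radially out
  from evenly spaced mid-chain residues (the "groove"); holo chains carry
  one atom per blob (σ = 0.25 Å). `make_ligand_set()` additionally produces
  block-structured fingerprints (within-block bit-flip rate 2 %, blocks
  mutually random) whose planted blocks Ward clustering must recover, with
  size-one blocks as planted singletons.
- All randomness flows from one seed; every PDB file embeds it in a REMARK;
  same seed ⇒ byte-identical outputs.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: side chains and realistic loop geometry,
sequence divergence across chains (the trivial alignment is exact by
construction), correlated motions, crystallographic noise models,
resolution-dependent B-factor pathologies, and chemically realistic
fingerprints. The generator validates the *machinery*; scientific
conclusions still require real ensembles.

## Problem sizes in the test-suite

The suite runs at desk scale, chosen to keep the whole run under a minute
while leaving the recovery properties deterministic: ensembles of 50 chains
× 60 residues for planted-signal recovery, 12 ligands × 12 atom blobs for
the cluster-count scan (grid 6–20), 10–25 ligands for Ward-partition checks
(where exhaustive partition enumeration is still feasible), 1000 random
distributions for entropy-oracle equivalence, and 50-point clouds for
superposition-oracle equivalence. Full-dataset quantities (e.g. a
14,110-atom superligand over 130 chains, 200–400 k-means grids) are linear
extensions of the same code paths.

## Known limitations

- The encoder assumes the model file's descriptor convention matches the
  alphabet it ships with; a model fitted to a different four-Cα
  parameterization would decode nonsense. The JSON schema check catches
  shape errors, not semantic ones.
- Exclusions that require visual inspection (fused-helix conformers,
  partner chains occupying the groove) are supported only as deny-list
  entries in `curation_config()`; the package does not attempt to automate
  them.
- Ligand-to-chain assignment uses nearest-Cα proximity, a deliberate
  simplification of "occupies the groove of"; with touching chains in a
  crystal interface it can mis-assign.
- `neq()` on amino-acid columns (sequence entropy) works identically but no
  separate pipeline stage is provided for it.
- mmCIF input, symmetry expansion and hydrogens are out of scope.
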