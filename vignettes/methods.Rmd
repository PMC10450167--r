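---
title: "Methods: density-based base typing, backbone-derived pairing, and probabilistic sequence assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-based base typing, backbone-derived pairing, and probabilistic sequence assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nucleic-acid models built into cryo-EM or crystallographic maps at typical
working resolutions (3–5 Å) carry an inherent base-type ambiguity: the two
purines (A, G) are barely distinguishable from one another in density, and
likewise the pyrimidines (C, U/T). What the map *does* reveal reliably is
(i) the purine/pyrimidine class of each base — purines scatter more and
extend further from the glycosidic bond — and (ii) the conformation of the
comparatively heavy sugar-phosphate backbone. `nucassign` exploits exactly
these two signals to assign, identify and validate nucleotide sequences,
and to generate base-pair restraints for refinement.

## Residue descriptors and the base-type classifier

Each nucleotide is summarized by a **residue descriptor**: density values
sampled at a fixed cloud of grid points around the expected base region,
expressed in a canonical local frame (origin at the glycosidic nitrogen,
`e_x` along the glycosidic bond, `e_y` the ribose best-fit-plane normal
orthogonalized against `e_x`, `e_z` their cross product). The cloud is
built once, from an idealized guanine: the base atoms (hydrogens included)
are swept through all rotations about the glycosidic bond in 1° steps, and
the nodes of a 1.0 Å grid lying within a calibrated cutoff of any swept
position are kept. The cutoff is calibrated inside [0.8, 1.2] Å so that
exactly **403** nodes survive (shipped value 0.937 Å); because the swept
solid is rotationally symmetric about the glycosidic axis, exact distance
ties occur at the boundary shell and are resolved deterministically in
lexicographic grid order. The rotational sweep makes the cloud cover the
base *wherever* the glycosidic torsion placed it, so no base conformation
is assumed. In practice the cloud is aligned to each residue through the
C2′/C1′/O4′ sugar atoms by least-squares superposition, the map is
interpolated trilinearly at the 403 transformed points, and the vector is
z-score normalized (standard-deviation floor 1e-6). Normalization makes
maps on arbitrary scales — cryo-EM reconstructions, 2mFo-DFc syntheses —
commensurable; whether to normalize per residue, per map, or not at all was
an open choice, and per-descriptor normalization was selected because it
also absorbs local resolution variation.

The classifier is intentionally small: input 403, one fully connected
hidden layer of 403 ReLU units, dropout (P = 0.5) between the layers during
training, and a 2-unit log-softmax output, trained with ADAM (learning rate
1e-5, batches of 20, 10% validation split) under a negative log-likelihood
loss. Defaults follow that recipe with 1000 epochs; the package's own tests
use 200 epochs, which this task does not need more of (the synthetic
problem saturates much earlier). Weight initialization is seeded
Glorot-uniform; training is bit-reproducible for a fixed seed, and
inference consumes no randomness. Cryo-EM and crystallographic maps differ
in fine detail, so two weight sets of the same architecture (one per
modality) are intended; the package trains weights from data and ships
none.

## Backbone-only base-pair detection

Folded RNA is modular: double-helical stems and recurrent loop motifs
conserve their backbone geometry much more strongly than their sequence.
Base pairs are therefore inferred without ever looking at base atoms:
small **search fragments** of known secondary structure are superposed
onto the model through phosphorus-atom triplets. All P-triplets of the
fragment are compared against model P-triplets pre-filtered by pairwise
distance compatibility (1.0 Å per distance by default, which also prunes
the O(n³) triplet space); each compatible correspondence yields a rigid
transform, every fragment residue is mapped to its nearest model phosphate
(within 3 Å, injectively — the mapping rule itself is an implementation
choice, as only "matching nucleotides" is prescribed by the approach), and
the match is refined by least squares on all shared sugar-phosphate
backbone atoms. Matches with refined RMSD below **1.0 Å** transfer the
fragment's annotated pairs to the model.

Assignment proceeds in two steps: first a 2-base-pair ideal A-RNA or B-DNA
fragment detects Watson–Crick pairs and helical stacking; then, for RNA
models with a user-supplied motif library, interior residues of stacked WC
runs (interpreted as runs of ≥ 3 consecutive pairs, keeping the flanking
pair on each side — the run-length threshold is a design choice) are
removed and each library motif matched against the remainder. Conflicts
prefer second-step assignments, then lowest RMSD; a residue keeps at most
one WC partner. Step-1 stacking annotations are retained when step 2
removes stem interiors. Motif libraries are pluggable (a directory of PDB
files with sidecar pair-annotation tables); the package deliberately ships
none, since the useful ones are large curated collections.

Restraints for WC pairs use standard donor/acceptor pairs (G·C: O6–N4,
N1–N3, N2–O2; A·U/T: N1–N3, N6–O4) at 2.9 Å with σ = 0.15 Å; for pairs
whose base identity is unknown — the normal situation before sequence
assignment — a single glycosidic-N–glycosidic-N restraint at 8.9 Å
(σ = 0.3 Å) encodes the pair without committing to identities. The numeric
targets are standard WC geometry, chosen here because only the output
formats, not the values, are externally fixed.

## The idealized duplex generator

Ideal A-RNA (twist 32.7°, rise 2.81 Å) and B-DNA (36.0°, 3.38 Å) duplexes
are generated from idealized nucleotide monomer templates placed under the
helical screw. One rigid reference placement per form — shared by both
base classes, which is essential: the sequence-independent matching step
presumes the backbone is the same whatever the base — plus one glycosidic
torsion per class are refined numerically (multi-start continuation least
squares) so that the backbone closes under the screw (O3′(i)–P(i+1) ≈
1.6 Å for every purine/pyrimidine transition) while the strand-dyad G·C
hydrogen-bond geometry (2.9 Å targets) is maintained. Every residue then
copies the reference backbone verbatim and receives letter-specific base
atoms superposed through the sugar ring with the torsion normalized to the
reference. The refined placement parameters are shipped as plain-text
package data and reproducible with `optimize_duplex_placements()`. The
resulting helices have exact fibre rise and twist, uniform backbone, and
near-ideal WC geometry (N9–N1 across a pair ≈ 8.9 Å); they are generation
fixtures, not refined experimental conformers — sugar puckers come from
the monomer templates, and propeller/inclination degrees of freedom are
not modelled.

## Simulated maps, and what passing tests do not show

`simulate_map()` renders atoms as Gaussians of width σ = 0.225·resolution
(the Fourier amplitude falls to ~1/e at spatial frequency 1/resolution),
weighted by atomic number and occupancy, plus optional seeded white noise
expressed as a fraction of the map standard deviation, on an orthogonal
grid (default voxel = resolution/3, 5 Å padding). An optional B factor
adds 8π²-scaled variance. This captures resolution-dependent blurring and
contrast but none of the real pathologies: no CTF, no solvent flattening
artefacts, no model bias in crystallographic phases, no local-resolution
variation, no radiation damage. Tests passing on these fixtures establish
that the algorithms are implemented correctly and behave as designed under
their stated assumptions — not that the headline accuracies transfer
quantitatively to PDB/EMDB data, which depend on experimental map quality.

One numerical point matters for the descriptor invariance property: at the
default voxel of 1.0 Å the simulated Gaussians (σ ≈ 0.68 Å at 3 Å
resolution) are under-sampled for trilinear interpolation, and the
resulting interpolation error acts as extra descriptor noise (absorbed in
classifier training, where it is harmless). The rigid-motion invariance
checks therefore simulate at 0.3 Å voxels with B = 30 Å² — a typical
atomic B factor at this resolution — which is the regime where the ≤ 0.05
per-component invariance claim is meaningful.

## Sequence assignment and p-values

For a continuous fragment (maximal runs with O3′–P ≤ 2.5 Å; connectivity,
not author numbering, decides) the classifier yields per-residue
purine/pyrimidine probabilities, clipped to [1e-3, 1−1e-3] to keep log
scores finite. A gapless placement at offset *k* on the target scores

  log S(k) = Σᵢ log pᵢ(class of target letter) + Σ_{(i,j)∈WC} log c_ij,

with c_ij = **0.1** when the two letters aligned to a fragment-internal WC
pair fall in the same base class (a same-class WC pair is chemically
implausible) and 1 otherwise; ambiguous letters (N) contribute probability
0.5. The correction applies once per offending pair. All offsets are
enumerated (no gaps — register-shift detection comes from windowed
comparison, not gapped alignment); ties resolve to the smaller offset.

Significance is the probability of seeing an equally good *best* placement
on a random target of the same length. The background simulates that null
directly: the best score is computed in each of `n_random` (≥ 200)
independent random decoy targets of the target's length, and the reported
p-value is the empirical exceedance among these block maxima, with a
method-of-moments Gumbel fit providing tail extrapolation beyond the
sampled range. Working with maxima of target-length blocks, rather than
fitting a parametric form to single-placement scores and exponentiating,
keeps the p-value calibrated in the presence of overlapping-window
dependence (the package's null-calibration test holds a KS uniformity
check to α = 0.01 over 500 replicates). When the target is exactly
fragment-sized each block contains a single placement and the p-value
reduces to the plain empirical exceedance. Degenerate (zero-variance)
backgrounds — e.g. an uninformative constant profile — return p = 1 with a
warning. Note one practical consequence of the empirical construction:
profiles whose probabilities take exactly repeated values produce tied
discrete scores and hence conservative p-values; classifier-derived
profiles are continuous and unaffected.

## Identification and validation

For database identification the profile is encoded as a multiple sequence
alignment whose column letter frequencies equal the predicted
probabilities (100 rows by default, giving 0.01 frequency resolution;
purine mass split evenly between A and G, pyrimidine between C and U/T;
rows shuffled column-independently with a fixed seed) with the
backbone-derived pairing as the `#=GC SS_cons` line — only the maximal
nested subset of pairs, since the consensus annotation cannot express
pseudoknots. The Stockholm file is compiled with INFERNAL's `cmbuild`,
calibrated with `cmcalibrate`, and searched with `cmsearch` (CM mode);
profile-HMM mode adds `--hmmonly` and skips calibration. Every fragment of
at least 20 residues is queried and hits are merged by E-value (3 returned
by default). Where INFERNAL is not installed, the package can run
HMM-mode searches through HMMER's `nhmmer` instead (`engine = "hmmer"`);
this ignores base-pairing information by construction.

Validation scans each chain with windows (20 residues, stride 5 by
default), assuming chain residue *i* carries sequence position *i*, and
compares the deposited placement's p-value (single-placement background —
the deposited position is a fixed hypothesis) against the best
alternative's p-value (full placement multiplicity — the alternative is
selected). A window is flagged when the alternative is significant
(p < 0.05) and at least two orders of magnitude more probable; the
reported shift is the offset difference, so a one-residue tracing deletion
appears as a run of flagged windows with shift +1 after the error.

The `--randomize`-style utility class-swaps a seeded random subset of
nucleobases (purines → pyrimidines and vice versa), co-mutating WC
partners to exact complements so every canonical pair stays canonical, and
rebuilds base atoms from templates with the backbone untouched — the
standard way to manufacture sequence-scrambled decoy models for map-bias
benchmarks.

## Problem sizes used by the automated checks

The packaged checks run on desk-scale synthetic data chosen to exercise
every claim: 50 duplexes (4–20 bp) for pair detection, pristine and with
0.3 Å seeded coordinate noise; 2000 balanced descriptors from simulated
3 Å maps (200 training epochs, 200 held out) for the classifier; 100
synthetic 40-mers for assignment recovery and p-value separation; 500
replicates for null calibration; 20 random rigid motions for descriptor
invariance; and a 100-nt hairpin against 50 decoys for identification.
These sizes are the package's own choices for a thorough offline
verification of correctness; published benchmark figures on deposited
structures are a different experiment that requires the corresponding
public map and model archives.

## Known limitations

- The duplex generator produces idealized fibre geometry; real helices are
  sequence-dependently distorted, which is precisely why 2-bp search
  fragments (rather than longer ideal stems) are the default.
- Gaussian-atom maps ignore electron- vs X-ray scattering differences,
  solvent and experimental noise structure.
- Assignment is gapless and forward-strand; insertions or deletions inside
  a fragment surface only indirectly, as a register shift at the next
  window.
- The MTZ reader handles the common little-endian machine stamp and a
  single amplitude/phase column pair in P1 (or pre-expanded reflections);
  symmetry expansion is out of scope.
- Modified residues are classified geometrically (N1/N9 within
  3.6–4.6 Å → purine) and their descriptors use parent-like anchor atoms;
  base modifications as such are ignored, consistent with training that
  ignores them.
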