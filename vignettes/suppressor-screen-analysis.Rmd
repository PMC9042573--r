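---
title: "Quantitative analysis of saturation-mutagenesis suppressor screens"
author: "supscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of saturation-mutagenesis suppressor screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supscreen)
```

## The experimental design this package models

A site-directed saturation-mutagenesis suppressor screen replaces, one codon
at a time, every position of a protein window with a fully random NNN codon,
transforms the pooled library into a conditional-lethal host, and selects
colonies (revertants) that grow under the restrictive condition. Sanger
sequencing of each revertant identifies the single amino-acid substitution
responsible. The system this package is built around is the fission-yeast
cohesin complex: the head-coiled-coil junction of Psm3 (SMC3), residues
Glu95-Tyr168 (74 positions), and the N-terminal domain of the kleisin Rad21,
residues Trp18-Lys87 (70 positions), screened for suppressors of a
temperature-sensitive separase mutant that cannot cleave cohesin.

The analysis questions are positional and biochemical: which positions
tolerate (indeed reward) substitution, what kinds of residues replace what,
how that pattern relates to evolutionary conservation, and where the
suppressor sites sit in the three-dimensional complex — at the subunit
interface, in hydrophobic cores, or elsewhere.

## Statistics computed per position

For a set of identified substitutions the package computes, per region
position:

* **Substitution number** — the count of distinct mutant amino acids
  recovered at the position (0-19).
* **Mean relative molecular weight**, mean over the position's
  substitutions of MW(mutant) − MW(wild type), in Da. Positive means the
  position tends to be replaced by bulkier residues. Molecular weights are
  those of the free amino acids; because only differences enter, the free
  amino-acid and residue-mass conventions give identical relative values
  (the 18.02 Da of water cancels), so the choice is immaterial and we
  document it rather than agonise over it.
* **Mean relative hydrophobicity**, the same construction on the
  Kyte-Doolittle hydropathy index (dimensionless, each residue in
  [-4.5, 4.5], so any single difference lies in [-9, 9]). Negative means
  substitutions make the position more hydrophilic. Alternative scales can
  be supplied as a two-column CSV via `read_property_scale()`.
* **Conservation** — see below.

Positions with no substitutions have *undefined* (NA, serialised as empty
CSV cells) means, never zero: an unmutated position carries no evidence, and
a zero would fake a "neutral" signal.

Both relative properties are antisymmetric by construction; the test suite
checks this exhaustively over all 400 ordered residue pairs, and checks the
profile means against a brute-force group-by oracle on random record sets.

## Conservation scoring

Conservation is scored from a user-supplied multiple sequence alignment
(aligned FASTA or Clustal; running the aligner is out of scope). For each
region position, mapped into alignment columns through the reference
sequence's gap structure, we compute Shannon entropy
\(H = -\sum_a p_a \log_2 p_a\) over the 20 standard amino acids and report

* `entropy_bits` — raw H, in [0, log2 20 ≈ 4.32];
* `raw_score` — 1 − H / log2(20), in [0, 1];
* `relative_ecs` — the min-max rescaling of the raw score over the scored
  region.

Three choices are open in principle and fixed here, recorded in the output
attributes: entropy base 2 (bits); gaps and ambiguity codes (B, Z, X, ...)
excluded from column frequencies, with columns whose gap fraction exceeds
0.5 flagged low-confidence; and "relative" scores defined by min-max scaling
over the plotted region, the simplest normalisation consistent with a
relative score in [0, 1] — raw scores are always emitted alongside so any
other normalisation can be applied downstream. No sequence weighting is
applied (a deliberately uniform default): with it, duplicated sequences
would be down-weighted, but typical curated homologue sets for this purpose
are small and hand-picked.

## Structural annotation

Given a coordinate model (PDB or mmCIF; hydrogens dropped, alternate
locations resolved to highest occupancy), suppressor sites are classified
as:

* **interface** — the residue participates in at least one inter-chain
  contact. Residue pairs with minimum heavy-atom distance ≤ 4.0 Å are
  contacts; a pair is a *salt bridge* when an Asp/Glu side-chain oxygen
  lies within 4.0 Å of a Lys/Arg/His side-chain nitrogen, an *H-bond* when
  any N/O-N/O pair lies within 3.5 Å, and otherwise *van der Waals*. The
  cutoffs follow common structural practice and are config-overridable;
  the classification is deliberately geometric, with no energetics.
* **hydrophobic core** — the residue is hydrophobic (A, V, L, I, M, F, W,
  Y by default) and buried. Burial uses a neighbour-count proxy: the
  number of heavy atoms of *other* residues within 7.5 Å of the side-chain
  centroid (C-alpha for glycine), with threshold 30. The proxy is
  deterministic, dependency-free and, on packed synthetic clusters and
  random coordinates, exactly reproducible by an O(n²) brute-force count
  (tested). A solvent-accessibility backend could replace it behind the
  same contract; ranks of buried vs exposed residues agree for the
  compact domains this package targets.
* **other / unresolved** — neither of the above, or absent from the model
  (disordered); unresolved sites are excluded from fraction summaries.

`site_summary()` reports the fraction of substitutions per category; on the
published screen's counts (80 core-site substitutions of 300) it reproduces
the ≈27 % headline share.

## Conformational comparison

`superpose()` implements Kabsch least-squares rigid-body superposition over
C-alpha atoms paired by author residue number, with the proper-rotation
branch enforced (determinant +1, no reflections). `segment_rotation_angle()`
measures how far a segment pivots between two conformations: superpose on a
common frame (e.g. the ATPase head), take each state's segment axis as the
dominant principal direction of its C-alpha trace oriented N→C, and return
the inter-axis angle in [0°, 180°]. Only the magnitude is reported; a signed
"inward/outward" direction would need a reference plane that the user should
define case by case. On a constructed 20° hinge in a synthetic helix the
measurement recovers 20° within 0.05°; tests also recover 5°, 45° and 90°
hinges and verify RMSD invariance under arbitrary rigid pre-transforms.
Applied to the deposited cohesin structures in the DNA/loader-bound and
unbound states (aligned on the Psm3 head, segment = the coiled coil emerging
from it) the same call measures the ≈20° coiled-coil rotation between the
two states; those files are not shipped, and the exact residue range taken
as "the coiled coil" is a configuration choice the user must fix against the
deposited models.

## The screen simulator

`screen_config()` / `run_screen()` emulate the screen so the entire pipeline
can be exercised with a known ground truth:

1. per position, `n_per_position` transformants each carry one codon drawn
   uniformly from all 64 (the mutagenic primers are fully random, so stop
   codons enter at expected rate 3/64);
2. a hidden `truth_set()` of (position, mutant) pairs plays the role of the
   unknown complete suppressor repertoire;
3. a transformant survives iff its translated residue differs from wild
   type, is not a stop, is in the truth set, and an independent
   Bernoulli(detection probability) draw succeeds;
4. survivors aggregate into substitution records whose hit counts are
   revertant counts, exported in the same TSV dialect the real pipeline
   reads.

Defaults (`n_per_position = 1000`, `detection_prob = 0.05`) are sized so
that a screen over a 70-odd-residue window with a repertoire of one-to-three
alleles per hot position yields a few hundred revertants — the scale real
plate screens of this design recover. All draws are position-major from a
single seeded generator, so identical seeds give bit-identical outputs.

What the simulator deliberately does **not** model: codon usage bias (real
NNN libraries are uniform by construction, but transformation and PCR can
skew them), growth competition between revertants (selection here is
all-or-none plus a per-allele detection probability), multi-hit constructs,
and the host-cell biology. Consequently, passing parameter-recovery tests
demonstrates that the *analysis* is sound — e.g. that hydrophilic-biased
truth alleles at designated positions are recovered as negative mean
relative HS and positive mean relative MW at exactly those positions — not
that real screens are unbiased. In particular the published multi-hit
saturation fractions (≈70 % in Rad21-NTD, ≈50 % in Psm3-HCJ) cannot be
re-derived from first principles because per-allele detection probabilities
are unknown; the simulator instead shows the statistic's sensitivity to
detection skew, and its uniform-sampling behaviour matches the closed-form
occupancy expectation within Monte-Carlo error (tested with 200 replicates;
the per-replicate screens use a 50-position window at depth 30, so the suite
runs in seconds).

## Hotspot calling

The published analysis identifies hotspot intervals (Psm3 124-131, Rad21
19-22 and 53-59) visually; no numeric criterion exists. `hotspot_call()`
operationalises "frequently mutated" as maximal runs of at least `min_run`
consecutive positions with substitution number ≥ `min_count`, defaulting to
5 and 3. Both knobs are exposed and recorded in run metadata, and interval
recovery on real data is explicitly threshold-dependent.

## Packaged reference data

The shipped `psm3_hcj_region()` / `rad21_ntd_region()` wild-type sequences
are **synthetic stand-ins**: residue identities are pinned at every
suppressor site used in the documentation and fixtures (K106, E126, S127,
A128, G129, G164, ... in Psm3; H42, A53, R55, Q59, ... in Rad21) and filled
with a neutral repeating pattern elsewhere. They keep every example
self-consistent without redistributing the biological sequences; for real
analyses construct the regions from the true psm3/rad21 sequences with
`region_spec()`. Likewise the packaged substitution TSVs contain only the
alleles named in running text (12 for Psm3-HCJ, 3 for Rad21-NTD) and are
flagged partial — the complete 113- and 188-substitution lists exist only as
published figure matrices.

## Degenerate inputs and numerical corner cases

* Identity substitutions, stop-codon records and non-standard letters are
  rejected at parse time with row numbers; the simulator, by contrast, must
  generate stops and have selection remove them.
* Hit count 0 means "unknown"; saturation statistics refuse unknown counts
  rather than silently treating them as 1.
* Duplicate (position, mutant) rows merge by summing hit counts: multiple
  isolates of one allele are independent revertants.
* An all-gap alignment column has undefined entropy (NA), not 0; a
  constant-score region has no spread to rescale and reports relative ECS 0.
* Superposition requires ≥ 3 paired atoms, segment axes ≥ 4 residues (the
  principal direction of 3 points is unstable); ties in the axis sign are
  broken by orienting N→C.

## Orchestration

`run_pipeline()` sequences the stages from a JSON/YAML config and writes the
report bundle (matrix, profile, sites and hotspot CSVs plus
`run_metadata.json` recording every threshold actually used and the seed).
Stages are skippable — no alignment means empty conservation columns, no
structure means no site annotations — and output is byte-deterministic given
inputs and seed. The package is a library: its users drive it from R, so
orchestration is exposed as functions rather than a shell executable.
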