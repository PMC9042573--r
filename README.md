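# supscreen

Quantitative analysis of site-directed saturation-mutagenesis suppressor
screens on protein domains, built around the fission-yeast cohesin system:
the Psm3 (SMC3) head-coiled-coil junction, residues Glu95-Tyr168, and the
Rad21 (kleisin) N-terminal domain, residues Trp18-Lys87, screened for
suppressors of a temperature-sensitive separase mutant.

It is written for people analysing (or planning) such screens: every codon
of a window is randomised to NNN, revertants surviving selection are Sanger
sequenced, and the resulting substitution lists are mined for positional and
biochemical signal.

## What it computes

Given a validated list of substitutions (position *i*, wild type *wt*,
mutant *mut*, optional revertant hit count), the package produces:

* the position × 20-amino-acid **substitution matrix** and per-position
  **substitution number** (distinct mutants recovered, 0-19);
* per-position **mean relative molecular weight**
  (mean of MW(mut) − MW(wt), Da) and **mean relative hydrophobicity**
  (mean of KD(mut) − KD(wt), Kyte-Doolittle units) — positive relative MW
  means the position attracts bulkier residues, negative relative HS more
  hydrophilic ones;
* wild-type / mutant **amino-acid preference counts**, and the
  **multi-hit saturation fraction** (share of alleles seen in ≥ 2
  independent revertants);
* **conservation profiles** from a multiple sequence alignment: Shannon
  column entropy H (bits), raw score 1 − H/log₂20, and a min-max-rescaled
  relative evolutionary conservation score (ECS);
* **structural site annotation** from PDB/mmCIF coordinates: interface
  contacts (van der Waals ≤ 4.0 Å, H-bond ≤ 3.5 Å, salt bridge ≤ 4.0 Å) and
  hydrophobic-core membership by a burial neighbour-count proxy, with
  category fractions (the published screen maps 80 of 300 suppressors,
  ≈27 %, to hydrophobic cores);
* **Kabsch superposition** and a head-aligned **segment rotation angle**
  between two conformations (the cohesin coiled coil pivots ≈20° between
  the DNA/loader-bound and unbound states);
* **hotspot intervals** — maximal runs of highly substituted positions;
* a seeded **screen simulator** (per-position NNN libraries, hidden truth
  set, Bernoulli detection) so the whole pipeline runs and is tested
  without any experimental data.

## Worked example

```r
library(supscreen)

region <- psm3_hcj_region()   # synthetic stand-in sequence, 74 positions
tsv <- system.file("extdata", "psm3_hcj_substitutions_partial.tsv",
                   package = "supscreen")
recs <- read_substitution_table(tsv, region)

prof <- position_profile(recs, region)
subset(prof, substitution_number > 0)
#>    position wt_aa substitution_number mean_rel_mw mean_rel_hs
#> 12      106     K                   1     28.0100   -0.600000
#> 33      127     S                   4     40.5725   -2.575000
#> 34      128     A                   3     66.7500   -5.766667
#> 35      129     G                   3     80.7700   -3.566667
#> 70      164     G                   1     58.0300   -3.100000
```

The partial fixture holds only the alleles named in running text, yet the
signal is already the published one: the S127/A128/G129 patch is the most
substituted, and its means are positive in relative MW and negative in
relative HS — suppressors there are bulkier and more hydrophilic, consistent
with destabilisation of the Psm3-Rad21 interface. A run scan calls that
patch as an interval:

```r
counts <- substitution_number_profile(substitution_matrix(recs, region))
hotspot_call(counts, min_count = 3, min_run = 3)
#>   start end length max_count
#> 1   127 129      3         4
```

A simulated screen flows through the identical analysis:

```r
truth <- sample_truth_set(rad21_ntd_region(), 60, seed = 1,
                          mut_pool = c("R", "K", "E", "G"))
cfg <- screen_config(rad21_ntd_region(), n_per_position = 1000,
                     detection_prob = 0.05, seed = 1)
sim <- run_screen(cfg, truth)
sim
#> <revertant_sample> 163 revertants, 55 distinct alleles (library 70000)
hit_saturation(sim$records)
#> [1] 0.7090909
```

`run_pipeline()` ties the stages together from a JSON/YAML config and writes
the CSV report bundle plus run metadata; see the vignette
(`vignettes/suppressor-screen-analysis.Rmd`) for the model, the parameter
defaults and the design choices.

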