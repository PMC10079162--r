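---
title: "Methods: simultaneous solubility and stability design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous solubility and stability design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solstab)
```

## Overview

`solstab` implements an automated pipeline that proposes protein variants
improving *both* conformational stability and solubility. The pipeline takes a
structure (PDB), one multiple sequence alignment per designable chain, and a
configuration; it emits ranked single- and multi-mutation designs together
with full intermediate tables. A companion module benchmarks the false
discovery rate (FDR) of stability predictions under phylogenetic filters.

The stages are:

1. **Input processing** — parse the structure, resolve identity groups
   (chains with identical sequences, e.g. the two halves of a homodimer),
   build a PSSM per designable chain, compute relative solvent exposure
   (Shrake–Rupley) and a residue contact map.
2. **Site selection** — collect candidate positions from four categories
   (below).
3. **Single mutational scan** — evaluate every PSSM-permitted substitution at
   every site; filter; score.
4. **Combination** — assemble multi-mutation designs, rank within size
   groups, select the best group sizes by a knee rule, shortlist.
5. **Interaction check** — re-evaluate designs whose sites are in structural
   contact, sequentially and in context.
6. **Reporting** — CSV tables, mutant FASTA, a markdown report, and advisory
   antigen-contact flags.

## Phylogenetic model

Per alignment column the amino-acid frequencies are smoothed with a
background-proportional pseudocount (default 1.0). With at least 50 sequences
the matrix stores log-likelihoods `ln(f/bg)` against background frequencies
("loglik"); below that, smoothed raw frequencies ("pwm"), because
log-likelihood estimates are unstable for shallow alignments.

A substitution is *permitted* at a position when its support exceeds the wild
type's under the active mode:

* `ll_pos` — mutant log-likelihood > 0 (frequency above background);
* `ll_and_delta` (default, stricter) — additionally the mutant must beat the
  wild type, `ll(mut) − ll(wt) > 0`.

For PWM matrices the analogues are a 0.05 frequency floor and
`f(mut) > f(wt)`. The **conservation index** `CI = 1 − H/ln 20` (H the
Shannon entropy of the column) is computed from the *raw*, unsmoothed,
gap-excluded frequencies so that an invariant column scores exactly 1.0;
smoothing would otherwise bound CI away from 1 in a depth-dependent way.

## Solubility surrogate

Per residue, a raw score combines three published scales, each z-scored over
the 20 amino acids so the weights are comparable:

`r = w_h·(−ĥ) + w_q·|q| + w_b·(−β̂)`

with ĥ the Kyte–Doolittle hydropathy, q the formal side-chain charge
(D/E −1, K/R +1, H +0.1) and β̂ the Chou–Fasman beta-sheet propensity.
Defaults `w_h = 1.0, w_q = 0.5, w_b = 0.5`: hydrophobicity is the dominant
aggregation driver, charge and beta propensity are secondary. The intrinsic
profile is a 7-residue sliding-window mean (windows truncated at the
termini) — aggregation-prone regions act over short contiguous stretches,
and 5–9 residue windows are the conventional choice for such profiles.

The **global score** of a sequence set pools all per-chain profiles `p` as
`G = mean(p) − (1/L)·Σ max(0, −1 − p)`: the mean is re-penalised for
residues deep below the −1 floor, so one severe hotspot cannot be bought off
by a benign remainder. Each chain is windowed independently; for identical
chains pooling equals concatenation.

The **structurally corrected profile** reweights the intrinsic profile by
exposure and 3-D neighbourhood:
`p̃_i = e_i · (Σ_{j∈{i}∪contacts(i)} p_j) / (1 + |contacts(i)|)` — a buried
residue (e ≈ 0) cannot nucleate surface aggregation however sticky it is,
while an exposed residue inherits the stickiness of its spatial
neighbourhood.

## Stability surrogate

Stability prediction is pluggable: any closure `f(mutation, context)`
returning a `ddg_estimate` works, and `table_ddg_adapter()` wraps CSV output
of an external energy function, aggregating replicate runs by mean and
population standard deviation (the replicates are the entire population of
runs made, not a sample from a larger one). The bundled surrogate is a
transparent additive model with burial `b = 1 − exposure`:

`ΔΔG = 0.8·b·(ĥ_wt − ĥ_mut) + 1.0·b·max(0, V_mut − V_wt)/100
      + 1.0·[mut = P] + 0.5·[wt = G] + pair terms`

(negative = stabilising; kcal/mol; V in Å³). It encodes the dominant
first-order effects — hydrophobic core packing, over-packing, proline's
backbone rigidity, glycine's special conformational freedom — and is exactly
additive unless explicit pair terms between contacting sites are supplied,
which makes it ideal for verifying the combination and interaction-check
machinery. It is **not** a substitute for a physics-based energy function.

## Site categories and the scan

| category | rule |
|---|---|
| `sequence_solubility` | exposed (e ≥ 0.10) and intrinsic profile < −1 |
| `structure_solubility` | corrected profile < −0.5 |
| `conservation` | CI > 0.25 and the wild type weakly supported |
| `exposed_solubility` | exposed and some permitted substitution increases solubility, unless CI > 0.7 with a consensus wild type |

Sites are capped at 100; if the first three categories alone reach the cap,
the fourth is discarded entirely, otherwise its sites fill the remainder by
descending best achievable solubility gain. The scan then drops
substitutions that decrease solubility (except at buried conservation sites,
which are stability rescues, not solubility edits), substitutions whose
group-propagated ΔΔG is ≥ 0, and the aggregation/oxidation-prone targets C
and M.

Each survivor is scored by the **Mutation Score**
`MS = w_s·Δsol − w_g·ΔΔG + w_p·Δll/σ`, where Δll is normalised by the
standard deviation of the chain's full PSSM matrix so that chains with
alignments of different depth and diversity contribute comparably.

## Combination, knee rule and interaction check

Pairs enumerate all substitution pairs at distinct logical sites; from
triples onward only the top-ranked substitution per site is combined
(combinatorial control). Sums of ΔΔG and normalised Δll are used, but the
solubility change is recomputed on the fully mutated sequences because
windows of nearby mutations overlap. Ranking ties break deterministically:
score desc, then ΔΔG asc, Δsol desc, then name — byte-stable output.

With `M(n)` the top score among designs of size `n` and gains
`g(n) = M(n) − M(n−1)`, a size `n` is selected when the *next* gain falls
below the mean gain so far; if no size qualifies the largest is taken, and
the largest is additionally included when the score is still growing into it
at no less than the average rate. The shortlist takes three designs from
each best size and one from every other size.

Designs with at least two sites in contact (min heavy-atom distance ≤ 8 Å,
the conventional residue-interaction cutoff) are flagged and re-evaluated
sequentially: mutations are applied in descending single-mutation score, the
ΔΔG of each recomputed in the context of those already applied; a mutation
that turns destabilising is replaced by the best of up to three shortlisted
alternatives at its site, or the site is dropped. A checked design whose
size shrank competes in its new size group.

## FDR benchmark

A prediction is a false positive when predicted stabilising (ΔΔG < 0) but
experimentally non-stabilising (ΔΔG ≥ 0; the boundary counts as
non-stabilising because a measurement of exactly zero provides no benefit).
`FDR = FP/(FP + TP)`. Filters restrict the record set to phylogenetically
supported mutations (`ll_pos`, `ll_and_delta`) or to confident predictions
(`|ΔΔG_pred| ≥ ε`). Significance is assessed by resampling: `B` uniform
subsets of the filtered size are drawn without replacement from the full set
and `p = (1 + #{FDR_b ≤ FDR_obs})/(B + 1)` — the add-one form keeps the
estimate a valid p-value. This separates the effect of *which* records the
filter keeps from the generic effect of keeping fewer records.

```{r fdr-demo}
records <- make_ddg_benchmark(2000, seed = 1)
fdr_benchmark(records, n_resample = 2000, seed = 1)
```

## Fixtures: realism and limits

The fixture generators produce text-only, byte-reproducible inputs:

* `make_helix_pdb()` — ideal α-helices (φ = −57°, ψ = −47°, standard bond
  geometry) with backbone + Cβ atoms, rigid per-chain offsets, SEQRES
  records. Real proteins have side chains, loops and packing defects; the
  helices are sufficient to exercise exposure, contacts and burial exactly,
  but absolute SASA values are those of a poly-Cβ model.
* `make_msa()` — per-column consensus fractions and alphabets; columns are
  independent, unlike real alignments with phylogenetic correlation.
* `make_ddg_benchmark()` — a stratified table in which Δll > 0 records have
  a designed lower FDR; magnitudes are folded-normal, not ProTherm-like.
* `make_demo_complex()` — a homodimer with occluder helices burying one face
  of chain A and an antigen helix on the opposite side, plus an alignment
  that makes three buried polar positions conserved hydrophobic liabilities.

```{r demo, eval = FALSE}
fx <- make_demo_complex(tempdir(), seed = 1)
res <- run_design(fx$pdb, fx$msa, file.path(tempdir(), "run"),
                  config = fx$config)
res$finals
```

## Numerical choices

* SASA: Shrake–Rupley with 256 golden-spiral points per atom (probe 1.4 Å,
  Bondi radii, Tien max-ASA normalisation); 256 points bound the relative
  exposure error well below the 0.10 exposure threshold, as verified against
  a 2048-point oracle in the test suite.
* All randomness (fixture generation, resampling) runs under an explicit
  seed and saves/restores the caller's RNG state.
* Problem sizes: the pipeline is designed for single-domain proteins or Fab
  fragments (≤ ~1000 residues, ≤ 100 candidate sites, designs of up to 5
  mutations); all-pairs contact computation is O(n²) in residues.
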