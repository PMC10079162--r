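# solstab

Automated design of protein variants with improved solubility **and**
conformational stability, plus a false-discovery-rate (FDR) benchmark for
phylogenetically filtered stability predictions.

Given a structure (PDB), a multiple sequence alignment per designable chain
and a configuration, the pipeline:

1. parses the structure, resolves identity groups (identical chains), builds
   a PSSM per chain, and computes solvent exposure and a residue contact map;
2. selects candidate mutation sites from per-residue solubility profiles
   (sequence-based and structure-corrected), solvent exposure and
   evolutionary conservation;
3. scans every PSSM-permitted substitution, discarding ones that reduce
   solubility (outside buried conserved sites) or are predicted
   destabilising, and scores survivors with a combined Mutation Score
   (`Δsolubility − ΔΔG + normalised Δlog-likelihood`);
4. combines survivors into multi-mutation designs, picks the best design
   sizes with a knee rule on the score gains, and shortlists;
5. re-checks designs whose sites are in structural contact by sequential,
   in-context ΔΔG re-evaluation, and flags mutations near an antigen chain.

Stability prediction is pluggable: a transparent additive surrogate is
bundled, and `table_ddg_adapter()` / `make_table_predictor()` wrap CSV output
from any external energy function. See the vignette
(`vignettes/design-methods.Rmd`) for the model details and rationale.

## Worked example

The package bundles a deterministic demonstration complex: an A/B homodimer
of 27-residue helices, three occluder helices (chains C–E) burying one face
of chain A, an antigen helix (chain G) on the opposite side, and an
alignment that makes three buried polar positions (S9, S16, T20) conserved
hydrophobic liabilities.

```r
library(solstab)
fx  <- make_demo_complex(tempdir(), seed = 1)
res <- run_design(fx$pdb, fx$msa, file.path(tempdir(), "run"),
                  config = fx$config)
#> structure: 6 chain(s), 2 identity group(s)
#> chain A: 120 aligned sequences -> loglik matrix
#> candidate sites: 7
#> scan: 12 attempted substitutions, 9 shortlisted
#> combination groups: n=1:9 n=2:27 n=3:1
#> best group size(s): 2
#> final shortlist: 5 design(s)
```

The candidate sites mix the two routes into the design: the exposed
hydrophobic patch V3–I6 enters through the sequence-solubility profile,
while the buried polar positions enter through conservation:

```r
res$sites[, c("key", "wt", "exposure", "conservation", "identified_from")]
#>   key wt exposure conservation                                     identified_from
#>   A:3  V  0.12189        0.629 sequence_solubility;conservation;exposed_solubility
#>   A:4  L  0.27549        0.407                                 sequence_solubility
#>   A:6  I  0.10212        0.503                                 sequence_solubility
#>   A:7  V  0.02169        0.680                                        conservation
#>   A:9  S  0.00000        0.658                                        conservation
#>  A:16  S  0.00304        0.674                                        conservation
#>  A:20  T  0.00000        0.680                                        conservation
```

The final shortlist (three designs from the best size group, one from each
other group; every mutation is mirrored onto both chains of the homodimer):

```r
res$finals[, c("n", "rank", "mutations", "delta_solubility", "ddg_sum",
               "mutation_score", "potentially_interacting")]
#>  n rank        mutations delta_solubility ddg_sum mutation_score potentially_interacting
#>  1    1            TA20V         -0.02885  -2.147          5.772                   FALSE
#>  2    1       TA20V;SA9I         -0.07864  -3.432         10.707                   FALSE
#>  2    2      TA20V;SA16A         -0.04094  -3.535         10.686                    TRUE
#>  2    3       TA20V;SA9V         -0.07926  -3.805         10.618                   FALSE
#>  3    1 TA20V;SA9I;SA16A         -0.09073  -4.820         15.621                    TRUE
```

All tables (`sites.csv`, `scan_attempts.csv`, `scan_shortlist.csv`,
`combinations.csv`, `final_designs.csv`), the mutant sequences
(`designs.fasta`), per-chain PSSMs, the resolved configuration and a
markdown report are written to the output directory.

## FDR benchmark

`fdr_benchmark()` quantifies how phylogenetic filtering reduces the false
discovery rate of stability predictions (FP = predicted stabilising,
experimentally not), with a resampling p-value that controls for the reduced
subset size:

```r
records <- make_ddg_benchmark(2000, seed = 1)
fdr_benchmark(records, n_resample = 10000, seed = 1)
#>        filter n_kept  tp  fp  tn  fn    fdr    pvalue
#>          none   2000 838 345 419 398 0.2916        NA
#>        ll_pos   1535 666 231 330 308 0.2575 9.999e-05
#>  ll_and_delta   1039 510  95 218 216 0.1570 9.999e-05
```

## Command line

A thin CLI is installed under `inst/scripts/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/solstab-cli.R", package="solstab"))')" \
    design --pdb complex.pdb --msa chainA.fasta --out run_dir
```

Subcommands: `design`, `benchmark` (FDR table from a record CSV), and
`fixtures` (write the demo complex and a synthetic benchmark).

## Reproducing results

Everything is deterministic given the seed: fixture generators and the
resampling routine save and restore the caller's RNG state, and repeated
runs produce byte-identical CSV outputs.

* Test suite (unit, property and acceptance tests):

  ```sh
  Rscript -e 'testthat::test_dir("tests/testthat", package = "solstab",
                                 load_package = "installed")'
  ```

* Acceptance snapshot — runs the installed package on its bundled fixtures
  and writes the headline quantities (FDR under each filter, resampling
  p-value, site/scan/design counts, top design scores) as JSON:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
  ```

The numbers shown in this README are the verbatim output of the commands
above with seed 1.
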