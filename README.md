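# lcrpos — position-dependent analysis of low-complexity regions

Low-complexity regions (LCRs) are protein-sequence segments dominated by a
few amino acids (poly-Q tracts, S/T-rich stretches, ...). They are abundant,
structurally elusive, and implicated in flexible protein binding. This
package asks *where* LCRs sit in protein sequences and what their position
means for function, and provides everything needed to run and validate that
analysis:

* **Detection** — sliding-window Shannon entropy
  `H = -Σ_a f_a log2 f_a` computed at every window length `w` in a range
  (default 16–300 aa, stride 1). Per length, the empirical entropy
  distribution over the whole corpus yields a low-complexity threshold `t_w`
  (the lower 0.5% quantile, taken as an order statistic); a window is an LCR
  candidate when `H < t_w`. Overlapping candidates are resolved by keeping
  the region with the most extreme standardised score
  `Z = (H - mu_w)/sigma_w`.
* **Positional analysis** — normalised, folded centre positions; terminal
  (margin ≤ 25 aa) vs central (both margins ≥ 50 aa) classification; a
  two-sample Kolmogorov–Smirnov test of observed positions against an
  empirical null built by re-inserting each LCR at 1000 random positions
  within its own protein.
* **Network analysis** — Wilcoxon–Mann–Whitney degree comparisons (LCR vs
  non-LCR, terminal vs central, ...), OLS regression of degree on LCR length
  per positional subset, and network LCR enrichment
  `(Observed - Expected)/Expected`, cross-validated over multiple networks.
* **GO enrichment** — one-sided Fisher tests per term with per-branch
  Benjamini–Hochberg q-values.
* **Synthetic benchmark** — a seeded generator of proteome + PPI networks +
  annotations with planted positional bias, degree couplings and term
  enrichments, plus ground truth, so every stage is testable offline.

See `vignettes/lcr-positional-analysis.Rmd` for the model, parameter
rationale and validation design.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic bundle
(`Rscript analysis/01_simulate.R` … `05_go_enrichment.R`, outputs under
`results/`). The same thing in a session:

```r
library(lcrpos)

cfg    <- synthetic_config(seed = 101)
bundle <- generate_bundle(cfg)
report <- run_lcr_pipeline(bundle$seqs, bundle$networks, bundle$annotations,
                           seed = 303)
report$counts
#> n_proteins  n_with_lcr  n_single_lcr  n_terminal  n_central  n_intermediate
#>       1300         345           342         243         67              32
report$positional[c("D", "p")]      # folded positions vs re-insertion null
#> $D 0.418   $p 0 (underflows double precision)
report$networks$full$lcr_vs_nonlcr$p
#> 1.3e-76                            # LCR proteins have more partners
report$networks$full$regression_terminal[c("slope", "p")]
#> slope 0.042 interactions/aa, p = 2.5e-05   (planted: 0.05, terminal only)
report$networks$full$regression_central$p
#> 0.33                               # no length-degree coupling centrally
head(report$enrichment$terminal$report[, c("term", "k", "K", "q")], 1)
#> TP01  82  141  5.7e-28             # the terminal-planted term, recovered
```

Of 1300 synthetic proteins, 345 contain LCRs and 342 contain a unique LCR;
detected positions are strongly biased towards the extremities (KS D = 0.42),
LCR proteins out-degree non-LCR proteins, the planted 0.05 interactions/aa
length–degree slope is recovered for terminal LCRs only, and the planted GO
terms are recovered for exactly their target subsets. On real data, replace
the bundle with a FASTA file (`read_fasta()`), BioGrid-style edge lists
(`read_network(..., physical_only = TRUE)`) and a GAF or two-column
annotation table (`read_annotations()`).

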