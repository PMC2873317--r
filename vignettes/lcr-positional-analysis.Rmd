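---
title: "Detecting low-complexity regions and analysing their position-dependent roles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting low-complexity regions and analysing their position-dependent roles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Low-complexity regions (LCRs) are protein-sequence segments with strongly
biased amino-acid composition — poly-Q runs, serine-rich stretches, and the
like. They are abundant, evolve rapidly, rarely crystallise, and are thought
to mediate flexible, low-specificity binding. `lcrpos` implements a complete
analysis of LCRs in a proteome: entropy-based detection calibrated on
empirical window distributions, a positional-bias test against a random
re-insertion null, connectivity analyses in protein–protein interaction (PPI)
networks, and GO-term over-representation for positional subsets — together
with a synthetic-data generator that plants every signal the analysis is
meant to find, so the whole pipeline is validated end to end without any
external downloads.

## The detection model

For a window of $w$ residues the compositional Shannon entropy is

$$H = -\sum_a f_a \log_2 f_a,$$

with $f_a$ the within-window frequency of residue $a$. Low $H$ means few
distinct residues dominate — low information content. Because entropy
distributions shift with window length (their mean grows and their spread
shrinks as $w$ grows), a single absolute threshold cannot serve all lengths.
The package therefore scans the corpus at every window length
$w \in [w_{\min}, w_{\max}]$ (default 16–300 at stride 1; any larger stride
would bias the empirical distributions) and, per length, records the mean
$\mu_w$, standard deviation $\sigma_w$, and the low-complexity threshold
$t_w$: the empirical lower $\alpha$-quantile of all window entropies of that
length, with $\alpha = 0.005$. A window is called low-complexity when
$H < t_w$ — a deliberately stringent cut that selects only the flat
low-entropy tail where genuine LCRs sit.

Numerical choices worth knowing:

* $t_w$ is the **lower order statistic** `sort(H)[ceiling(alpha * n)]`, never
  an interpolated value, so the threshold is always an observed entropy and
  the flagged fraction of the calibration corpus can never exceed $\alpha$.
* The comparison is **strict** ($H < t_w$). On a degenerate distribution
  (every window identical) the threshold equals the common value and nothing
  is flagged, rather than everything.
* Every distinct character is its own symbol, so ambiguity codes (X, B, Z, U,
  `*`) simply enter the composition; `skip_ambiguous = TRUE` drops windows
  containing them instead.
* The calibration corpus defaults to the proteome under study. Calibration
  tables serialise to TSV (+ JSON metadata), so a table built once on a large
  sequence database can be reused on small inputs.

Overlapping candidates of different lengths are compared on the standardised
scale $Z = (H - \mu_w)/\sigma_w$. When candidates overlap, the one with the
most extreme $Z$ is kept and everything sharing a residue with it is
discarded, repeatedly (ties: longer window, then smaller start, so resolution
is deterministic). Reading "highest Z-score" literally would retain the
*least* significant overlap; `literal_z = TRUE` provides that reading for
completeness. Resolution is applied before the single-LCR restriction: all
positional and network analyses deal only with proteins carrying exactly one
resolved LCR, which keeps region-level and protein-level properties
interchangeable.

## Positional metrics and the re-insertion null

An LCR's position is its centre coordinate divided by the protein length;
folding ($\min(x, 1-x)$) maps N- and C-terminal distances onto one
centre-to-extremity scale, 0 at an extremity and 0.5 at the exact centre.
Terminal LCRs (t-LCRs) start or end within 25 residues of an extremity;
central LCRs (c-LCRs) keep both margins at least 50 residues; the 25–50
buffer is classified intermediate and excluded from both subsets. Margins
count residues outside the region (`start - 1` and `L - end`), "no more than
25" is $\le$, "at least 50" is $\ge$, and the central definition is read
conjunctively (both margins).

Whether observed positions are biased is decided against an empirical null:
each LCR is notionally removed from its protein and re-inserted at a
uniformly random admissible start, 1000 times by default. Only the two
lengths matter, so re-insertion is simulated arithmetically. The pooled null
(every LCR weighted equally) is protein-length dependent — flat in the folded
interior, decaying towards the extremity because a region of length $w$
cannot centre closer than $w/2$ to an end. Observed and null positions are
folded identically and compared with a two-sample Kolmogorov–Smirnov test
(asymptotic p-values; the pooled null is large and discrete, so the exact
computation does not apply). An unfolded variant is available by argument;
the folded comparison is the default because the positional question is about
distance-to-extremity, not N- versus C-terminal identity.

## Network and enrichment analyses

PPI networks are read from tab-delimited edge lists, symmetrised,
deduplicated and stripped of self-loops; an interaction-type column can
restrict the graph to physical interactions (the whitelist defaults to the
BioGrid "physical" label and is configurable). Degree comparisons between
protein groups use the Wilcoxon–Mann–Whitney test on the degrees of group
members *present in the network* — proteins absent from a network are
excluded rather than assigned degree zero. The test is two-sided by default
(exact when both groups have at most 50 members and no ties). The
length–degree relationship within a positional subset is an ordinary
least-squares regression of degree on LCR length, reported with slope
(interactions per residue), $r^2$ and the two-sided slope p-value. A
network's LCR enrichment is $(\mathrm{Observed} -
\mathrm{Expected})/\mathrm{Expected}$, where Expected scales the proteome's
LCR fraction to the node count.

GO over-representation uses the one-sided Fisher (hypergeometric upper-tail)
test per term against a configurable background, with Benjamini–Hochberg
q-values computed **within each ontology branch** (P, F, C) by default; a
pooled correction is available by argument. No GO-DAG ancestor propagation is
performed — annotations are taken as given. Reports default to $q < 0.1$.

## What the synthetic generator emulates

`synthetic_config()` freezes one set of study conditions used throughout the
package's tests:

| parameter | default | role |
|---|---|---|
| proteins | 1300, lengths U[150, 600] | desk-scale proteome |
| background residues | uniform over 20 aa (yeast-like preset available) | i.i.d. background |
| LCR fraction | 0.35 | planted single LCR per chosen protein |
| LCR length | U[20, 90] aa | length signal for the regressions |
| composition | 2 dominant residues, 95% mass | entropy far below background |
| terminal placement | probability 0.7, margin 25 aa | positional bias |
| degree baseline | gamma, mean 5, shape 8 | realistic spread, workable noise |
| LCR degree boost | +3 expected interactions | LCR vs non-LCR contrast |
| terminal slope | +0.05 interactions/aa | length–degree coupling, terminal only |
| annotations | 20 terms × 3 branches, base rate 0.05, planted odds 8 | enrichment contrasts |

Two design points deserve explanation. First, the planted LCR fraction and
lengths keep planted windows a small share (~4–5%) of all scanned windows.
With self-calibration the 0.5% tail is a competition among the planted
windows themselves; when they are too large a share, only fragments of each
segment clear the threshold, long terminal segments get truncated to short
interior windows, and a truncated terminal region can sit 50 residues from
both termini and be misclassified as central. Keeping the share small makes
whole-segment windows win the greedy resolution, which is also the regime of
a real proteome, where genuine LCRs are a small minority of windows. Second,
degrees are realised by an expected-degree (Chung–Lu style) Bernoulli
pairing: simple, seedable, no self-loops or duplicate edges, and adequate for
rank-based tests — exact degree sequences are not needed, and realisation
noise is Poisson-like (variance ≈ mean degree), which the baseline gamma
shape was chosen to respect.

What the generator does **not** emulate: natural residue correlation
(real sequences are not i.i.d.), repeat periodicity inside LCRs, interactome
topology beyond degree structure (no clustering, no hub–satellite structure),
evolutionary dynamics of slippage/recombination, and a GO DAG. Passing tests
therefore demonstrate that the pipeline recovers planted statistical
structure of the kind the real analysis assumes — not that it reproduces any
particular organism's numbers.

## Validation design and problem sizes

The package's validation has three tiers, all seeded:

* **Exact oracles.** Streamed sliding entropies against direct per-window
  recomputation (≤ 1e-9 bits); greedy overlap resolution against exhaustive
  search over all disjoint candidate subsets (≤ 10 candidates, 200 random
  instances); Mann–Whitney U against brute-force pair counting; Fisher
  p-values against direct hypergeometric tail summation (≤ 1e-12); BH
  q-values against the hand-written step-up formula.
* **Type-I control.** With nothing planted (uniform placement, no degree
  boosts, annotation odds 1), the positional KS test, the length–degree
  regression and the per-term q < 0.05 calls are run on 200 generated
  replicates of ground truth; rejection stays within nominal bounds. These
  nulls run on the generator's truth records rather than on detected regions:
  uniform planted placement *is* the re-insertion null, and the properties
  under test belong to the statistical procedures, not the detector.
* **Planted recovery.** Fifty full pipeline runs (calibrate → detect →
  resolve → classify → KS → degrees → enrichment) on the default conditions
  must recover every headline contrast: positional KS rejection, higher
  degrees for LCR proteins, terminal above central, a length–degree slope
  recovered within 3 standard errors and significant only for the terminal
  subset, and the planted terminal term significant (q < 0.01) only in the
  terminal study set.

Pipeline runs scan window lengths 16–120 (the planted lengths top out at 90,
and windows above ~120 add cost without touching any planted signal); the
function defaults keep the full 16–300 contract for real proteomes. A full
pipeline run on the default bundle takes roughly ten seconds on one core.

## Known limitations

* Detection keeps single flagged windows; it does not merge adjacent flagged
  windows or refine boundaries, so a detected region can be shorter than the
  underlying biased segment, and (rarely) an interior fragment of a terminal
  segment classifies as central. The buffer zone reduces, but cannot
  eliminate, this leakage.
* The entropy statistic ignores residue order: periodic and disordered
  compositionally biased segments are indistinguishable to it.
* Self-calibration couples the threshold to the input's LCR content; for very
  small or very LCR-rich inputs, supply a calibration table built on a larger
  corpus instead.
* Identifier mapping between FASTA records, network nodes and annotation
  genes is the caller's responsibility; `read_network()` accepts an optional
  two-column synonym map, but nothing validates that the three input sources
  share a namespace.
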