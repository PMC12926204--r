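---
title: "fusionscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fusionscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fusionscape` packages the quantitative analyses used to dissect a
chromosomal fusion site and its flanking heterochromatin in great apes.
This vignette is the package's account of the underlying models, the
tunable parameters and the design decisions that were genuinely open —
and of what the synthetic-data validation does and does not demonstrate.

## 1. The multispecies coalescent and the windowed ILS scan

### Model

For one haploid lineage sampled per species, genealogies are simulated
branch by branch on a dated species tree: within a branch carrying `k`
lineages and diploid effective size `Ne`, coalescence waits are
exponential with rate `choose(k, 2) / (2 Ne)` per generation.  For a
species triplet whose internal branch spans `tau = Δt_gen / (2 Ne)`
coalescent units, the two discordant rooted triplet topologies each have
probability `exp(-tau) / 3`, so total discordance is
`(2/3) exp(-tau)` (`expected_discordance()`).  Branch lengths convert to
substitutions per site via the per-generation mutation rate.

The scan (`scan_windows()`) mirrors how such signals are measured in
practice: a region is cut into 500 bp windows, each window's alignment is
fitted against the three resolved quartet topologies under HKY85, and the
winning topology — after outgroup rooting — yields the call
`concordant`, `ILS_HG` or `ILS_PG`.  Windows with fewer than `min_sites`
(default 3) parsimony-informative sites, or with best-versus-runner-up
support below `support_threshold` (default 0, i.e. no support filter),
are `unresolved` and excluded from the discordance denominator; the
proportion over all windows is reported alongside
(`ils_proportion()$proportion_all`), since published proportions do not
always state which denominator they use.

### Likelihood machinery

Per-window likelihoods use Felsenstein pruning over site patterns with an
analytic HKY85 transition matrix, implemented in C++.  Branch lengths are
optimised coordinate-wise (three sweeps, convergence when a sweep gains
< 1e-6 log-units).  Each branch is maximised by safeguarded Newton on the
analytic first and second derivatives of the likelihood in the branch
length — HKY85's `P(t)` is a sum of two exponentials, so the derivatives
are closed-form — with bisection on the derivative sign as fallback and a
branch-length tolerance of 1e-6 on `[1e-9, 4]`.  Newton typically needs
5–8 evaluations per branch where golden-section needs ~30, which is what
makes scans of 10^5 windows take minutes rather than hours.  Exact
likelihood ties between candidate topologies are broken by candidate
order and flagged.  Base frequencies are estimated per window by default
(with a +1 pseudocount); `kappa` is fixed (default 4) rather than
optimised, which is adequate for topology ranking at quartet scale.
Optional gamma rate heterogeneity uses four discrete categories.

### The simulation benchmark and its calibration

`ils_benchmark_spec(tau)` defines the conditions under which the scan is
validated against the closed form: a four-taxon
(human, chimpanzee, gorilla, orangutan) tree with splits at 7, 9.1 and
16.5 Mya, a 20-year generation time, and the Homo-Pan ancestral branch
parameterised directly by `tau`.  Two parameters deliberately depart from
realistic hominid values, because the benchmark's purpose is to test
coalescent recovery, not to imitate apes:

* **Mutation rate 1e-7 /site/generation** (~8x the hominid rate).  At the
  realistic rate a 500 bp window carries roughly one informative
  substitution; most windows would be unresolvable and the scan would
  measure resolution rate, not discordance.
* **African-ape-ancestor Ne of 3e5** (`ne_ancestral`).  Misclassification
  is concentrated in windows whose gene tree has a near-zero internal
  branch (the classifier's only signal); since the post-divergence
  coalescence that creates that branch happens in the ancestral branch,
  enlarging its Ne stretches those branches — provably without changing
  the discordance probability, which depends only on the Homo-Pan
  branch's `tau`.
* **`ils_benchmark_params()`: kappa = 1 with equal frequencies** (the
  Jukes–Cantor special case).  Transition bias concentrates homoplasy on
  fewer substitution channels; spreading mutations evenly minimises
  convergent sites, whose effect is to push calls toward the uniform 1/3
  mixture and hence bias the discordance estimate upward.

Two alternatives were evaluated and rejected during design: raising the
mutation rate further (homoplasy on the long terminal branches grows
faster than internal-branch signal, worsening the bias) and pushing the
outgroup far out so that its lineage can never coalesce within the
triplet (the resulting long outgroup branch adds long-branch noise that
again inflates apparent discordance).  With the chosen settings the
residual estimator bias is about +0.01 in absolute discordance at 2,000
windows — well under one part in three of the binomial 3σ band used by
the validation — and per-window call accuracy against the true genealogy
is 0.90–0.95 across `tau` in [0.25, 1].

### Gradient panels

`simulate_window_panel()` realises a breakpoint-polarized discordance
profile by rescaling the Homo-Pan branch per window so that
`(2/3) exp(-tau_w)` equals the target probability (background on the
proximal side, background x fold within the distal flank).  The truth
label recorded per window is the realised gene-tree topology, so realised
discordance is binomial around the target — the property the polarity
test (`polarity_contrast()`, permutation of side labels, two-sided) and
the fold-change summary are validated against.  Because the MSC cannot
exceed 2/3 total discordance, `background x fold > 2/3` is rejected.
The chromosome-wide background in real scans is the mean over all
resolved windows; in two-sided synthetic panels the proximal side plays
that role.

## 2. Population-genetic statistics

`pi_windows()` computes per-window nucleotide diversity as the sum over
sites of the unbiased heterozygosity `2 p (1-p) n/(n-1)` divided by the
window span (20 kbp windows, 10 kbp steps by default, matching common
VCF-tool settings); with complete data this equals the mean pairwise
difference exactly, which the tests verify against an O(n²) oracle.
Missing genotypes use site-wise complete-case sample sizes, the common
behaviour for assembly-derived panels.  `tajima_d_windows()` implements
`D = (π̂ − S/a₁)/sqrt(e₁S + e₂S(S−1))` with the standard constants; `S = 0`
yields `NaN` (undefined), never 0.  The neutral-coalescent generator
(`simulate_haplotype_panel()`) drops Poisson mutations on a sampled
Kingman genealogy, so `E[S] = θ L a₁` (Watterson) and the neutral mean of
D is near zero — both used as calibration checks.

## 3. Synteny and segmental duplications

`nonsyntenic_segments()` complements the union of aligned blocks over a
target and reports regions ≥ 10 kbp separately from the total unaligned
bp (the two quantities answer different questions and are not mutually
derivable).  `sd_copy_count()` applies the ≥98 % identity and ≥20 kbp
filters and merges overlapping passing hits per target before counting.
"Full-length" copies additionally require `min_query_cov = 0.8`: the
publication record does not define the coverage that distinguishes a
full-length copy from a truncated derivative (e.g. a 32 kbp spacer
derived from a 50 kbp SD), and 0.8 separates exactly that pair; the
parameter is exposed.  Ortholog grouping follows flanking-region synteny:
reciprocal, co-linear flank mapping within a 100 kbp tolerance (50 kbp
flanks), connected components as groups.  Identity heatmaps use canonical
k-mers (k = 21) and the containment transform `c^(1/k)` with
`c = |A∩B|/min(|A|,|B|)` — the min makes self-comparisons symmetric.

## 4. Heterochromatin: satellites, methylation, CDRs

`detect_satellite_arrays()` finds monomeric tandem arrays by
autocorrelation at the monomer period (default 32 bp, the subterminal
satellite unit), smooths matches over two monomer lengths, and snaps
boundaries to the monomer grid via a phase consensus; boundaries land
within one monomer of truth on simulated caps.  The default monomer
shipped with the generator is a synthetic AT-rich 32-mer, not a published
consensus.  `spacer_stats()` reports the mean spacing between consecutive
spacer midpoints and the modal spacer length on a 1 kbp histogram
(reported as the bin midpoint; finer bins are available when sub-kbp
modes matter).

`call_cdrs()` tiles a HOR array with 5 kbp windows and calls CDRs among
windows below the lower quartile (Q1) of all window means.  The literal
"all below-Q1 runs" reading has a structural problem: a quartile
threshold admits ~25 % of background windows by construction, so noise
shoulders would be called.  The default `"deep"` mode therefore requires
member windows to be deep — `mean ≤ min + depth_frac (Q1 − min)`,
`depth_frac = 0.5` — and each run to contain a local minimum; the global
minimum window is always inside a call, and every called window is below
Q1 (both invariants are asserted on every output in the tests).  The
literal rule remains available as `mode = "q1"`.  Window methylation
means are unweighted by default (coverage weighting via a flag), since
site frequencies are already coverage-normalised.

Group comparisons (`compare_methylation_groups()`) chunk tracks into
17.1 kbp sliding windows (step 8,550 bp — the half-window; where the
published parameter strings disagree with the stated window size, the
stated size wins), exclude CDR-overlapping chunks and compare chunk means
by two-sided Mann–Whitney U with normal approximation and tie correction
(the nonparametric default for unequal group sizes when the published
test is unnamed).  `classify_structural_haplotypes()` clusters each
array's length distribution in 1-D, splitting where sorted neighbours
differ by more than `gap_frac` (0.25) of the median, and labels samples
by their tuple of classes.

## 5. SUNKs

`build_census()` counts canonical k-mers (k = 31 by default — the value
is not standardised in the literature, so it is logged in every report);
a SUNK is a target-region k-mer with count exactly 1 in every same-lineage
panel census and 0 in every outgroup census (the outgroup-absence
requirement is a flag, default on).  `query_presence()` reports the
detected fraction to one decimal percent, the convention used when
quoting archaic-genome retention.  The census is held in memory: the
package targets desk-scale regions, not whole-genome k-mer databases.

## 6. Trees: distances, NJ, RF, dating

Pairwise p/JC/K2P distances use pairwise deletion; JC distances at
`p ≥ 0.75` are saturated and returned as `Inf` with a warning rather than
`NaN`.  `nj_tree()` validates and delegates to the canonical
neighbor-joining implementation; on additive matrices recovery is exact,
which the tests assert on 1,000 random trees.  `rf_distance()` is an
in-package bipartition implementation (normalised by `2(n−3)` on
request); an information-theoretic "generalised" RF variant is
deliberately not implemented, since several inequivalent definitions
exist — congruence testing (`cophylogeny_permutation_test()`) uses plain
normalised RF with leaf-label permutation and the add-one p-value
estimator.

`strict_clock_dating()` replaces full Bayesian divergence dating with a
documented strict-clock surrogate: a single rate fitted by least squares
through the origin from calibrated node depths, node ages as
depth / rate, and bootstrap-over-columns CIs with the tree re-estimated
per replicate.  Two consequences are documented rather than hidden: CIs
are narrower than a relaxed-clock posterior would give, and rooting
matters — `root_with_outgroup(clock = TRUE)` places the root on the
outgroup edge so ingroup and outgroup depths balance, which is the
correct rooting under the clock assumption (plain outgroup rooting leaves
the whole outgroup path on one side and corrupts every depth).

## 7. Validation scale and what it shows

The shipped validation (test suite plus `scripts/acceptance.R`) runs at
the sizes the analyses are designed for: 2,000-window scans per `tau`,
twenty 10,000-window gradient panels, 1,000 random instances per
brute-force oracle, 200 planted-dip CDR tracks, 1,000 NJ matrices, 200 ML
quartet replicates and 40 dating replicates at 10 kbp — a few minutes in
total on one CPU.  Planted CDR dips are placed on the caller's 5 kbp
window grid, so recovery is assessed at the caller's resolution.

The generators reproduce the statistical structure the analyses assume —
MSC genealogies, site-independent HKY substitution, hypermethylated
satellite with hypomethylated pockets, neutral panels, planted unique
k-mers — and deliberately omit features of real data: no indels or
alignment error (windows are consumed post-alignment and cleaned in real
pipelines), no recombination within a window, no selection, no gene flow
(an ancestral-introgression pulse mode is a possible extension; ghost
introgression in the ape ancestors is a known alternative explanation for
fusion-site signals), no sequencing-error model for methylation beyond
gaussian site noise, and no satellite higher-order structure.  Passing
tests therefore demonstrate correctness of the statistics under their own
model assumptions, not robustness to real-data artefacts.

## 8. Defaults worth knowing

| Parameter | Default | Where |
|---|---|---|
| window length (scan) | 500 bp | `simulate_window_panel`, scan inputs |
| min informative sites | 3 | `scan_windows` |
| support threshold | 0 (off) | `scan_windows` |
| Pan representative | chimpanzee | `default_taxon_map` |
| π / D windows | 20 kbp / 10 kbp step | `pi_windows`, `tajima_d_windows` |
| SD filters | ≥ 0.98 id, ≥ 20 kbp, ≥ 0.8 cov | `sd_copy_count` |
| identity k-mer | k = 21, canonical | `windowed_identity_matrix` |
| monomer period | 32 bp | `detect_satellite_arrays` |
| CDR window / mode | 5 kbp, `"deep"` (depth_frac 0.5) | `call_cdrs` |
| methylation chunks | 17,100 / 8,550 bp | `compare_methylation_groups` |
| SUNK k | 31, canonical | `build_census` |
| clock bootstrap | 1,000 columns resamples | `strict_clock_dating` |

All coordinates are 0-based half-open internally; region strings are
1-based inclusive and accept both hyphen and en-dash.
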