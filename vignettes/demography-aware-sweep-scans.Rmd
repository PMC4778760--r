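---
title: "Demography-aware genome scans for selective sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demography-aware genome scans for selective sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A recent selective sweep leaves three linked signatures in the population
that experienced it: locally reduced nucleotide diversity, an excess of
rare variants (a left-shifted site-frequency spectrum), and elevated
differentiation from a related population that did not share the sweep.
All three signatures are also produced, window by window, by neutral
demography — bottlenecks and founder events generate coalescent trees that
can be indistinguishable from those under selection. An "empirical
outlier" scan, which flags the top x% of windows, therefore has no control
over its false-discovery rate: under a bottleneck, its outliers are
enriched for neutral windows that merely drifted hard.

`sweepfdr` implements the model-calibrated alternative for a
two-population design (a *sweep* population such as dogs, contrasted
against a *reference* population such as wolves, with an outgroup for
allele polarization): window statistics are referred to their distribution
under an explicit neutral demographic model, simulated by coalescent
machinery, and discoveries are controlled by false discovery rate rather
than by rank. The demography-free comparator is implemented alongside so
the two approaches can be contrasted on the same data.

## Window statistics

Windows are 100 kb sliding intervals advanced in 10 kb steps (defaults of
`window_spec()`); a window is retained only if its callable length —
positions covered by the user-supplied mask — is at least 30 kb. Trailing
partial windows at contig ends are scanned and governed by the same rule.
Within each window, from per-site allele counts restricted to fully
observed sites (every sample called, so the chromosome sample size `n` is
constant):

* within-population diversity
  $\pi = \sum_s c_s (n - c_s) / \binom{n}{2} / L_\mathrm{callable}$,
  the average pairwise difference per callable site; mixed haploid/diploid
  panels simply contribute their chromosomes to `n`;
* between-population diversity $\pi_B$, the average difference between one
  chromosome from each population;
* $F_{ST} = (\pi_B - \bar\pi_W)/\pi_B$ with $\bar\pi_W$ the arithmetic
  mean of the two within-population diversities (Hudson/Slatkin style
  ratio-of-averages). Which within-population average to use is a genuine
  choice; the arithmetic mean is adopted and fixed here. $F_{ST}$ is
  undefined when $\pi_B = 0$ and negative values are retained;
* Tajima's D per focal population from `S` and the mean pairwise
  difference, with the standard 1989 constants. D is undefined when
  `S = 0` — and also for `n <= 3`, where the variance constants cancel
  exactly; both cases propagate as `NA`;
* the contrasts scanned for dog-lineage sweeps, oriented so that a sweep
  inflates their right tails: `delta_pi` $= \ln(\pi_{ref}/\pi_{sweep})$
  and `delta_td` $= D_{ref} - D_{sweep}$. The natural log is a fixed
  choice; any base is a monotone rescale and leaves every p-value
  unchanged. When $\pi_{sweep} = 0$ the denominator is replaced by half of
  one pairwise difference over the window,
  $0.5/(L_\mathrm{callable}\binom{n}{2})$ — a deterministic per-window
  floor, so a fully swept window still gets a finite, extreme ratio.
  Windows without sweep-population polymorphism have no `delta_td`; they
  are excluded from that statistic's test and from composite ranking, but
  keep their other q-values.

## The coalescent null and FDR calibration

`simulate_null()` draws independent, fully callable neutral windows under
a `demographic_model()` (piecewise-constant sizes, splits, optional
migration), using msprime through a bundled Python bridge; the three
contrasts are computed from the simulated allele counts by the same
kernels used on observed data. Observed windows are 30–100 kb callable
while null windows are a full 100 kb; no rescaling is applied, which makes
short observed windows slightly noisier than the null they are compared
to — a documented approximation, acceptable because per-site statistics
are length-normalized and the retention floor is 30 kb.

For each statistic, the empirical p-value of a window is the fraction of
simulated windows with a value at least as large (`p = k/N`, no
continuity correction, so `p` can be exactly 0); q-values come from the
Benjamini–Hochberg step-up applied genome-wide per statistic, with
undefined entries excluded from the number of tests. Overlapping windows
are dependent; BH is known to be robust under positive regression
dependence and no further correction is attempted. Windows with
`q <= 0.01` for any statistic are significant; the composite score
`cms = (1 - q_dpi)(1 - q_fst)(1 - q_dtd)` ranks them.

`simulate_null_posterior()` repeats the simulation with parameters drawn
from a joint posterior table instead of fixed values; with draws
concentrated near the fixed values the two calibrations produce q-values
that correlate above 0.99 on a signal-bearing window table — provided the
nulls are large enough that Monte Carlo noise is small against the
q-value spread (the test suite uses 20,000-window nulls for this check;
smaller nulls measurably degrade the correlation before any real
disagreement appears).

## Regions, ranking, classification

Significant windows (from any statistic) merge into regions when the gap
between interval boundaries is at most 200 kb, transitively, on the
growing region envelope; the boundary is inclusive because the merge rule
is "within 200 kb". Regions are ranked by the maximum composite score of
their member windows; the tie convention for display is the average rank.
The minimum region-maximum score among the top 100 regions defines the
"high-CMS" cut, and windows are classified into the four quadrants of
{high/low CMS} x {low/high FDR}. A validation filter against an
independent diversity panel fails any region whose mean panel diversity
over member windows is not below the mean over non-member windows within
500 kb flanks — one defensible formalization of what was originally a
manual judgment; regions without usable flank windows are left untested.

The empirical comparator converts each statistic to percentile ranks
(maximum-rank ties — the convention is unstated in the field and fixed
here), multiplies them, percentile-ranks the product, and flags the top
1%. Outlier windows merge into regions by the same 200 kb rule and rank
by maximum joint percentile.

## The synthetic-data generator

`generate_dataset()` emits a complete, self-contained study: VCF (mixed
ploidy), callable mask, gene models, term map, panel diversity table,
panel allele frequencies, site functional classes, and truth tables. Its
defaults are the package's study conditions and are fixed: two 10-Mb
contigs; a stylized canid demography (`canid_model()`: three basal dog
lineages of size 10,000 splitting 800 generations ago from a dog stem of
size 2,500 that diverged from wolves 1,000 generations ago out of a
35,000 ancestor; wolves at 15,000; an outgroup splitting 25,000
generations ago; mutation and recombination both 1e-8 per bp per
generation); ten sweep loci of width 100 kb and intensity 100, five per
contig, 2 Mb apart; 15% random mask dropout in 2 kb tiles; a gene every
50 kb; 40 terms; a 24-chromosome diversity panel; 80 planted fixed sites.

Two design points deserve emphasis.

* **Sweeps are emulated demographically, not by forward simulation.**
  Inside a sweep locus the dog-stem size is divided by the intensity
  during a crash epoch (820–980 generations ago), forcing all dog
  lineages to coalesce on the stem — the genealogy a completed
  domestication-era sweep leaves behind. Each dog lineage then
  accumulates only post-sweep variants, giving reduced diversity, a
  rare-variant excess (negative sweep-population D), and elevated
  differentiation, while keeping a few segregating sites so `delta_td`
  stays computable. Sweep segments are simulated independently of their
  neutral flanks, so there is no linkage "shoulder" beyond the locus —
  the approximation sharpens sweep edges relative to real hitchhiking.
* **The pooled dog sample is structured, and that structure matters.**
  With a single panmictic bottlenecked dog population, rare neutral
  windows (order 1e-4) lose *all* dog variation at once and are
  statistically indistinguishable from a complete sweep; no calibration
  can separate what the model itself makes identical. The sampling
  design the package targets pools long-separated basal lineages, which cannot
  all coalesce recently — under `canid_model()` the neutral null's
  maximum log diversity ratio over 20,000 windows stays near 1.3 while a
  swept window sits near 4, so sweeps are cleanly separable. This is why
  `demographic_model()` supports `stat_groups` (model populations pooled
  into one statistic population).

What the generator does *not* emulate: mutation-rate and recombination
heterogeneity along the genome, genotyping error, linked background
selection, admixture pulses, and partial or soft sweeps. Passing tests
therefore show that the scan is correct and calibrated *under its own
model class*, not that real genomes satisfy that model.

## Downstream analyses

Fixed-site analysis requires polarized sites (ancestral allele = the
allele fixed in the outgroup): candidates carry the derived allele on
every sweep-population chromosome while the reference population and
outgroup are fixed ancestral; candidates are retained when their derived
frequency in the panel is at least 0.75 (inclusive), and a Pearson
chi-square (no continuity correction) tests whether functional classes
distribute differently inside vs outside outlier regions.

Enrichment takes the genes within 25 kb of the peak window of the top 100
validated regions and tests each term with the plain hypergeometric upper
tail against the annotation background, Benjamini–Hochberg adjusted across
terms and reported on a percentage scale with a 10% default cut. Popular
web-service enrichment tools use a modified test statistic and a bespoke
FDR column; neither is reproduced here — the fold-enrichment column is
formula-exact and is what the tests pin down.

## Problem sizes and numerical choices

The test suite runs at the package's chosen desk scale: a 5,000-window
null; one sweep-injected 20-Mb genome for recovery and ranking checks,
plus a single-sweep variant for the method-contrast check (with many
strong sweeps, the top-1% percentile set is arithmetically forced to
coincide with FDR discoveries; the contrast between the two philosophies
only shows when true signals are few relative to the flagged 1%); 50
neutral 20-Mb replicate genomes (two 10.2-Mb contigs, fully callable,
simulated at the allele-count level and pushed through the same window
and scan operations) for the calibration check that the per-statistic
probability of any `q <= 0.01` discovery under the global null stays at
or below 0.1 — each replicate calibrated by one of ten independent
5,000-window nulls, because a `q <= 0.01` trigger under the global null
is essentially a "window beyond the null maximum" event, and sharing one
null realization across replicates would make the measured fraction
hostage to that single maximum rather than an estimate of the design
rate; and 20,000-window nulls for the fixed-vs-posterior agreement
check. Oracles are brute-force pair
enumeration for diversities and Tajima's D, a hand-coded BH step-up, and
exhaustive hypergeometric enumeration. Ties, zero-diversity floors,
undefined-statistic propagation and merge-gap boundaries are all exercised
at their exact boundary values.

One desk-scale caveat is worth recording: with ~2,000 windows and ~10
isolated true loci, a BH discovery at `q <= 0.01` effectively requires
swept windows to *exceed the entire null* (`p = 0`), because a handful of
windows cannot carry a step-up at interior ranks the way hundreds of
sweep windows can in a full-genome scan with ~200,000 windows. The
bundled model was therefore chosen so that a complete sweep's signal lies
beyond the neutral null's reach — the regime any workable scan of this
design must operate in.

## Limitations

Haplotype-based statistics (iHS, XP-EHH) are out of scope; detection
power is limited to strong, effectively complete sweeps; the null model
is supplied, not inferred; and the simulated-window length mismatch for
short observed windows mildly inflates their variance relative to the
null.
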