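---
title: "Window-based differential methylation: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based differential methylation: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
library(dplyr)
```

# The analysis in one paragraph

MeDIP-seq measures DNA methylation indirectly: an antibody against
5-methylcytosine pulls down methylated fragments, so sequencing coverage
over a genomic region is a proxy for its methylation level. medipdmr
implements the downstream statistics of this assay for a two-group
comparison (e.g. fertile vs. infertile sperm donors, or therapy
responders vs. non-responders). The genome is tiled into fixed 1000-bp
windows; mapped reads are counted into windows; per-sample depths are
equalized by random subsampling; each window is tested for differential
coverage with a negative-binomial exact test; windows below a stringent
p-value threshold nucleate differentially methylated regions (DMRs)
whose edges are extended at a relaxed threshold; and the RPKM read depth
over the DMR windows defines a low-dimensional biomarker via PCA onto
which held-out samples are projected. A permutation of group labels
gives a null distribution for the DMR count.

# The window test

For a window, counts are pooled within each group. Under the null of
equal relative coverage, the group-A pooled count $a$ given the grand
total $t = a + b$ follows the conditional law of two independent
negative binomials: group A's pooled count is $\mathrm{NB}(\mu_A,
n_A/\phi)$ and group B's $\mathrm{NB}(\mu_B, n_B/\phi)$, with
$\mu_A/\mu_B$ equal to the ratio of summed library sizes and $\phi$ the
common dispersion in $\mathrm{var} = \mu + \phi\mu^2$. At $\phi = 0$
this reduces to $a \mid t \sim \mathrm{Binomial}(t, w_A)$ with $w_A$
group A's library-size share. The two-sided p-value sums the
probabilities of all outcomes no more likely than the observed one (the
minimum-likelihood rule; tail doubling is available via `rule =
"doubletail"`). Pooling samples into a single negative binomial per
group is exact when library sizes are equal within groups — the
situation `subsample_counts()` is there to create — and in that regime
the test coincides with edgeR's classic exact test to floating-point
precision (this is asserted against edgeR in the test suite; edgeR is
never used in the computation itself).

Windows with zero counts in every sample carry no information. They are
assigned $p = 1$ and excluded from the Benjamini–Hochberg family so
they do not dilute the FDR (`drop_empty_from_fdr = FALSE` restores the
naive behavior).

## Dispersion

The common dispersion is estimated by a pooled method of moments:
counts are scaled to the mean library size, and within each group and
window the sample mean $m$ and variance $s^2$ satisfy $E[s^2 - m] =
\phi m^2$ under the NB model, giving the ratio estimator $\hat\phi =
\sum (s^2 - m) / \sum m^2$, floored at zero. This weights windows by
$m^2$, is deterministic, and recovers a simulated $\phi = 0.2$ to
within $\pm 0.05$ with 2000 windows and 6+6 samples (tested). Tagwise
or trended shrinkage as in modern edgeR is deliberately out of scope:
the subsampled, depth-equalized setting this package targets gains
little from it, and the single-$\phi$ model keeps the exact test exact.

# DMR calling

Three tunable parameters, all recorded on the result object:

* `sig_threshold` (default `1e-5`): seed windows must fall below this
  p-value. This is the stringent genome-wide threshold the windowed
  MeDIP design makes natural — with ~3 million windows in a human-scale
  genome, `1e-5` keeps the expected number of null seeds in the tens.
* `edge_threshold` (default `0.1`): windows below this relaxed
  threshold are absorbed during edge extension.
* `edge_distance` (default: the window size, i.e. 1000 bp): maximum gap
  between a window and the current DMR span for merging or absorption.

The caller (1) merges seed windows on a chromosome whose spans lie
within `edge_distance`, (2) iteratively absorbs any sub-`edge_threshold`
window within `edge_distance` of the current span until a fixed point is
reached, and (3) merges extended spans that touch or overlap. The
extension sentence that defines this procedure can be read either as a
single pass or as an iteration; we treat iteration to a fixed point as
the primary reading (a newly absorbed window can pull in its own
neighbor) and expose `iterate = FALSE` for the single-pass alternative.
Extension is conservative by construction: lowering `edge_threshold`
never enlarges a DMR.

`sig_windows` counts only seed windows, so the "DMRs with $k$
significant windows" tables are well-defined regardless of how far
extension reached. Whether regions fused by extension should be
reported merged or separate is ambiguous; we report them merged and
retain the pre-merge group count as the `n_seed_groups` attribute, so
both counts are available. A DMR's direction (methylation increase or
decrease) is the sign of the log2 fold change at its minimum-p seed
window, ties broken toward the larger absolute fold change — the
strongest signal defines the biomarker sign, rather than a span
average that extension windows could wash out. The caller is verified
window-for-window against a literal one-step-at-a-time fixed-point
oracle on hundreds of randomized tables.

Cluster detection (`find_clusters()`) uses single-linkage chaining with
`max_gap = 2` Mb and `min_size = 3` by default; these are reporting
conventions, not statements about the data, and are plain arguments.

# Coordinates, CpG counting, and counting policies

All coordinates are 0-based half-open, as in BED, in every table and
file. CpGs are counted as forward-strand `CG` dinucleotides wholly
inside a window; a pair straddling a boundary belongs to neither
window, soft-masked bases count as their uppercase base, and `N` never
matches. Counting one strand is a convention, not an approximation —
`CG` is its own reverse complement, so double-strand counting would
simply double every value. CpG density is reported per 100 bp and
binned at integer edges; DMR lengths in 1-kb bins.

Reads are assigned to windows by their midpoint (`floor((start +
end)/2)`), so each read is counted exactly once and column sums equal
library sizes on a fully tiled genome; `overlap_any` is available for
sensitivity analysis and counts boundary-spanning reads in every window
they touch. Library size is defined as total input reads, not in-window
reads, matching the "per million mapped reads" denominator of RPKM:
$\mathrm{RPKM}_{ij} = c_{ij} / ((L_i/10^3)(N_j/10^6))$.

Depth equalization draws, for each sample above the target, a
multivariate hypergeometric sample of the target size from its window
counts. This is distributionally identical to subsampling the read file
and re-counting, column totals hit the target exactly, and a fixed seed
is bit-reproducible.

# The synthetic-data generator

`sim_config()` describes the generative model the analysis assumes,
and its defaults are the conditions under which the package's
statistical claims are tested: two chromosomes of 10 Mb (20,000 windows
of 1000 bp), 6+6 training samples, mean depth $2\times 10^5$ reads per
sample with lognormal coefficient of variation 0.1, NB dispersion
$\phi = 0.1$, window CpG rates cycling over 1–4 CpG per 100 bp (the
low-density regime the MeDIP design targets), and 10 spiked regions of
fold change 6 spanning 1–4 consecutive windows, 90% of them
methylation increases. The spike-width cap mirrors the observation
that real DMRs in this assay are predominantly 1–4 kb; the 90/10
increase/decrease mix mirrors the hypermethylation-dominated pattern
reported for infertility signatures. Expected window coverage is
proportional to $(1 + \mathrm{CpG})^{e}$ with $e = 1$ by default —
MeDIP enrichment grows with the number of methylated CpGs, but the
true coupling curve is unknown, so the exponent is exposed rather than
asserted. Spiked expected counts are multiplied by the fold change for
increases and divided for decreases, keeping the two directions
symmetric on the log scale.

Two deliberate simplifications: `simulate_genome()` realizes the CpG
landscape in actual sequence (a CG-free background plus a Poisson
number of injected `CG` dinucleotides per window, so realized
per-window counts are exactly Poisson), while `simulate_windows()`
draws the same Poisson counts without building sequence — the two are
distributionally equivalent and the fast route is used where only the
count pipeline is exercised. `counts_to_reads()` places one
fixed-length interval per counted read with its midpoint uniform in the
window, so midpoint re-counting reproduces the matrix exactly; this is
a round-trip check of the coverage stage, not a fragmentation model.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: mappability and copy-number
artifacts, GC and fragment-length bias, CpG-coupling normalization
issues, batch effects, within-group biological heterogeneity of
methylation (every case sample carries every spike at full strength),
and chromosome-scale covariance. Results on real MeDIP-seq data depend
on upstream alignment and filtering choices this package intentionally
does not perform.

# The permutation null, and a caveat worth knowing

`permutation_null()` reruns the entire analysis — dispersion
re-estimated, every window re-tested, DMRs re-called with the same
configuration — under random relabelings that preserve group sizes,
and reports the add-one empirical p-value $(1 + \#\{\mathrm{null} \ge
\mathrm{obs}\})/(1 + n_{\mathrm{perm}})$, whose floor at the default 20
permutations is $1/21 \approx 0.048$. Permutations are drawn with
replacement from the label-assignment space, and a configurable minimum
of 3 samples per group is required before the analysis is allowed.

A property of this design deserves emphasis. With 6+6 samples, about
8% of size-preserving relabelings agree with the true grouping in 5 of
6 case positions. If the differential signal is strong and
concentrated — as with the generator's deterministic spikes — such a
permutation retains a diluted fold change large enough to clear even a
$10^{-5}$ threshold, so over 20 permutations the null distribution
typically contains a few counts close to the observed one, while the
remaining ~17 permutations sit at zero. This is correct behavior of a
permutation test, not a defect: the null being estimated is "no
association between labels and coverage", and near-copies of the true
labeling are legitimate, if improbable, draws. It does mean that with
small cohorts the observed count cannot be expected to strictly exceed
*every* null count when effects are strong and homogeneous; on real
data, where effect sizes are modest relative to biological variability,
label dilution is far more destructive and the null collapses toward
zero. The `autoplot()` method shows the full null histogram rather than
a single summary for exactly this reason.

# PCA biomarker and projection

Features are the RPKM values of DMR member windows — one feature per
window, preserving multi-window DMR structure; `mode = "dmr_mean"`
gives the one-feature-per-DMR alternative. Features are mean-centered
but not variance-scaled (RPKM is already a common scale, and scaling
would let near-constant windows dominate), decomposed by SVD, and the
first three components retained. Held-out samples never influence the
means or loadings; `project_samples()` applies the frozen centering and
rotation, so a held-out copy of a training sample lands exactly on its
training score. Component signs are fixed by making each loading
column's largest-magnitude entry positive, so serialized models are
reproducible run to run. `assign_group()` is deliberately minimal —
nearest training-group centroid in the 3-component space, with the
distance margin reported and exact ties flagged — because with cohorts
of this size anything more elaborate than a sanity-check classifier
would overfit.

# Cohort conventions

Total motile count is volume (mL) × concentration (million/mL) ×
motile fraction. Motility is stored as a fraction in $[0,1]$; the TSV
readers accept the clinically reported percent scale and convert on
input. A responder is a patient whose concentration and/or motility
rose at least `fold_threshold`-fold (default 2, the operational reading
of "2–3 fold" / ">2-fold") between two chosen semen analyses; an
increase from a zero baseline counts as a response, zero-to-zero does
not. Which pre-treatment sample (enrollment or treatment start) anchors
the fold change is a clinical choice the data cannot arbitrate, so
`classify_responders()` takes explicit pre/post tables and leaves it to
the caller.

# Numerical choices and degenerate inputs

* Log fold changes use a pseudocount of 0.5 reads per million in both
  numerator and denominator, so all-zero group means give a defined
  (zero-shrunk) value.
* Exact-test tie handling adds a $10^{-10}$ relative slack when
  collecting outcomes "no more likely than observed", absorbing
  floating-point ties; if every outcome qualifies the p-value is
  exactly 1.
* `estimate_common_dispersion()` returns 0 for all-zero matrices and
  under-dispersed (sub-Poisson) data rather than a negative value.
* Empty DMR sets, empty read sets, empty association tables and empty
  null distributions are all representable and tested; plotting and
  summarizing them does not error.
* Seeds: every stochastic function takes an explicit `seed` and leaves
  the caller's RNG state untouched; compound stages derive child seeds
  deterministically below $2^{31}$.

# Problem sizes used by the test suite

The suite exercises the caller-vs-oracle comparison on 500 randomized
tables of up to 200 windows, type-I calibration on $10^4$ null windows
per seed across 10 seeds, spike recovery on the full default
configuration (20,000 windows) across 10 seeds, a 20-permutation null
on a 4,000-window genome, and PCA validation with 4 held-out samples —
sizes chosen so each property is measured with useful resolution while
the whole suite stays comfortably interactive.

# Known limitations

No CpG-coupling normalization (as in MEDIPS), no TMM or GLM framework,
no tagwise dispersion, no promoter/TSS-aware gene association (distance
is measured to gene bodies, strand ignored), and no pathway statistics
— gene categories come from a user-supplied two-column map. The
package consumes already-mapped read intervals; alignment, duplicate
marking and quality filtering are upstream concerns.
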