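---
title: "Model and methods behind sortshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind sortshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortshift)
```

## The problem

In a sorting-based pooled CRISPR screen, cells carrying a library of guide
RNAs are FACS-sorted into discrete gates by the expression of a reporter
(protein stain, Flow-FISH signal, ...), and each gate's guide content is
sequenced, together with an unsorted aliquot that captures the overall
library composition. A guide that shifts expression of the target gene
changes where its cells land in the sorted distribution, and therefore how
its reads distribute across the gates. `sortshift` turns those per-bin read
counts into a per-guide estimate of the mean expression shift, and
aggregates guides into element-level effect sizes and significance.

## The guide-level model

**Quantile normalisation of the sorting space.** The only property of a
gate the model uses is the fraction of sorted cells it captured, recorded
during sorting. Mapping cumulative cell fractions through the standard
normal quantile function places every gate in a common expression space
with mean 0 and SD 1: a gate capturing quantiles $[q_0, q_1]$ has bounds
$Z_{b0} = \Phi^{-1}(q_0)$, $Z_{b1} = \Phi^{-1}(q_1)$. Because the vast
majority of guides in a screen do not alter expression, the overall
distribution's SD is, to good approximation, the no-effect SD, and we model
every guide's cells as $\mathrm{Normal}(\mu_g, 1)$ in this space — a single
shared unit variance, no per-guide variance estimation.

**Bin occupancy.** The expected fraction of a guide's cells falling in bin
$b$ under shift $\mu$ is
$$S(b, \mu) = \Phi(Z_{b1} - \mu) - \Phi(Z_{b0} - \mu),$$
so $S(b, 0)$ is exactly the bin's recorded cell fraction
(`bin_occupancy()`).

**Expected read fraction.** With $r_{\varnothing g}/R_\varnothing$ the
guide's fraction of the unsorted library, the expected fraction of bin
$b$'s reads belonging to the guide is
$$P_b(g \mid \mu) = \frac{r_{\varnothing g}}{R_\varnothing}
  \cdot \frac{S(b, \mu)}{S(b, 0)}.$$
At $\mu = 0$ this is just the library fraction; enrichment in a tail gate
raises it, depletion lowers it.

**Read likelihood and the shift MLE.** Sequencing read counts are modelled
as negative binomial: the count $r_{gb}$ for guide $g$ in bin $b$, given
the bin's total $R_b$, has NB size $R_b$ and success probability
$1 - P_b(g\mid\mu)$. The estimate $\hat\mu_g$ maximises
$\sum_b \log \mathrm{NB}(r'_{gb};\, R_b,\, P_b(g \mid \mu))$ over $\mu$,
where $r'_{gb}$ is the pseudocounted count described below. Maximisation
uses Brent's bounded one-dimensional method (`stats::optimize`) on
$\mu \in [-5, 5]$ SD with tolerance $10^{-4}$; $\pm 5$ SD exceeds any
realistic FACS shift, and the likelihood in $\mu$ is unimodal for valid
inputs. Terms constant in $\mu$ are dropped inside the optimiser; the
reported `ll_ratio` is the log likelihood at $\hat\mu_g$ minus that at 0
(natural log), floored at 0.

**Pseudocount prior.** To keep poorly covered guides from producing wild
estimates, 10 pseudocounts per million reads of bin coverage are added to
each sorted-bin count ($r'_{gb} = r_{gb} + 10\, R_b/10^6$). Since the added
counts are proportional to each bin's sequencing depth, a guide with few
reads sees its profile pulled toward the depth profile of the bins, which
under near-uniform binning favours $\mu = 0$. The unsorted column is left
untouched: the library fraction is a separately measured quantity, not part
of the bin likelihood the prior is meant to regularise. The pseudocounted
counts are non-integer, so the NB log mass is evaluated through `lgamma`
(`nb_log_pmf()`), which coincides with `dnbinom` at integers.

**Control centring.** Raw $\hat\mu_g$ are re-centred by subtracting the
mean $\hat\mu$ of the negative-control guides
($Z_g = \hat\mu_g - \bar{\hat\mu}_{\mathrm{ctrl}}$), because targeting
guides with real effects shift the overall distribution the gates were
quantile-normalised to. The mean makes controls average exactly zero; a
median option is available for outlier robustness but is not the default.
Guides absent from the unsorted library cannot be quantified; they are kept
in the output with $\hat\mu = 0$, `ll_ratio = 0` and an `unquantifiable`
flag so row counts are stable across experiments.

## Element-level statistics

Guides are grouped into elements either by an annotation column or by
sliding windows (below). Each element gets three Z-scores:

* **effect size** — the mean of member guide Z-scores;
* **Stouffer Z** — $\sum_i Z_i / \sqrt{k}$;
* **significance Z** — the Stouffer Z divided by the SD of a matched null.

The null is built from the negative controls: each control Z is replicated
10 times (`resample_factor`) into a pool, and for every guides-per-element
count $k$ in use, 10,000 draws of $k$ scores are taken without replacement
and Stouffer-combined; the SD of those null statistics is the scaling
denominator. This absorbs both the guide-level noise scale (control Z-scores
are not exactly unit variance) and the dependence on $k$, so the scaled
statistic is standard normal under no effect. The pool is sorted before
drawing, so results are invariant to guide input order at a fixed seed.
Degenerate nulls (identical controls, or a pool exhausted by a single draw)
are an error, as is any $k$ exceeding the pool.

Tail probabilities come from the standard normal: `p_up` (upregulation),
`p_down` (downregulation), and a two-tailed
`p_either = min(1, 2 min(p_up, p_down))`. Doubling keeps `p_either` a
valid p-value (the raw minimum of two tails is anti-conservative); the
uncorrected minimum is kept as a diagnostic column `p_min`.
Benjamini–Hochberg FDR (`stats::p.adjust`) is applied separately per
experiment and per tail family.

**Sliding windows.** For tiling screens, a candidate window of fixed width
(default 500 bp; tune to the tiling density) is anchored at every guide
position, guides within $[p, p + w]$ form its set, duplicate sets are
collapsed, and sets smaller than `min_guides` (default 5) are dropped.
Anchoring at guide positions suffices: any window can be slid until its
left edge touches its leftmost member without losing members, so every
maximal guide set is enumerated. Reported coordinates span the member
guides, since the window grid itself is arbitrary. With replicate
experiments, `combine_replicates()` retains elements below the FDR
threshold in every replicate with a consistent direction of effect.

## What the simulator emulates

`simulate_screen()` implements the generative process the inference
assumes, plus the two experimental noise stages that it does not:

1. library abundance $A_g \sim \mathrm{Poisson}(1000)$ (library
   construction noise);
2. sorted cells $S_g \sim \mathrm{Poisson}(A_g)$;
3. expression per cell: $\mathrm{Normal}(\mu_g, 1)$ in mean-altering mode,
   or a mixture — responders at $\mathrm{Normal}(1, 1)$ with probability
   $r_g$, the rest at $\mathrm{Normal}(0, 1)$ — in proportion-altering
   mode; a cell sorts into the bin whose Z bounds bracket its expression;
4. reads per bin $\sim \mathrm{NB}(10 \times \sum_i S_{bi},\;
   S_{bg}/\sum_i S_{bi})$ (10 reads per sorted cell), and the unsorted
   library sequenced analogously from the $A_g$.

Cells are assigned to bins with one multinomial draw per guide over the
partition of the expression axis into gates and uncaptured gaps — exactly
equivalent in distribution to simulating each cell's expression, and far
faster. A single seeded RNG stream drives the stages in a fixed order, so
identical seeds give identical screens.

**Recorded bin sizes are the realized fractions.** By default the
simulator reports each gate's *observed* cell fractions as the bin
quantile bounds, because that is what a sorter records and what the
quantile-normalisation step expects. When many guides shift expression,
the realized tail fractions differ noticeably from the design fractions;
feeding the nominal design bounds to the inference compresses strong
estimates by roughly 10% in our checks. `record_bins = "nominal"` restores
the design bounds for studying exactly that mismatch.

The reference configuration (`simulate_reference_screen()`) has 200
elements with 5 guides each (effects 0.01–1.00 SD, or responder fractions
1–100%, across the 100 effective elements), 1000 negative controls, and
six 10% gates on the distribution extremes. What passing recovery tests on
it shows is that the estimator inverts its own generative model with the
experimental noise stages included; what it cannot show is robustness to
features real screens add — guide-specific efficacy and off-target
activity, fitness effects coupling abundance to the perturbation, PCR
jackpotting beyond NB dispersion, or mis-recorded gate fractions.

## The bin-design study

`evaluate_configuration()` asks how gate number and placement affect
screen performance. Layouts (`bin_configuration()`) are symmetric about
the median and contiguous from each tail inward, described by per-tail
widths (e.g. `c(5, 10, 20)` is the six-bin A5_B10_C20 layout). Each layout
is scored on simulated screens dominated by small effects (defaults: 1000
effective elements with shifts 0.01–0.1 SD, 1000 ineffective; our test
suite and examples run a half-scale version with 200 + 200 elements, which
preserves every ordinal conclusion) by the Pearson correlation between
true and inferred effects and by true positives at 1% FDR, averaged over
replicates with seeds `base_seed + 1:n`. `rank_configurations()` sorts by
one metric, breaking ties by the other and then by label.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pseudocount` | 10 | reads per million bin reads | shrinks low-coverage guides toward no effect |
| `mu_limits` | (−5, 5) | SD | generous bracket for any real FACS shift |
| `tol` | 1e−4 | SD | optimiser precision, well below biological noise |
| `center` | mean | — | controls average exactly 0; median available |
| `window_bp` | 500 | bp | match to guide tiling density |
| `min_guides` | 5 | guides | below this, element calls are outlier-driven |
| `resample_factor` | 10 | copies | enlarges the control pool for without-replacement draws |
| `n_draws` | 10,000 | draws | null SD estimated to about 1% |
| `fdr_threshold` | 0.01 | — | convention for calling elements |

## Numerical choices and degenerate inputs

* Shifts that drive an expected bin fraction to 1 or beyond get a finite,
  monotone likelihood penalty, steering the optimiser back without
  NA/Inf; occupancy underflow at extreme shifts is floored at `1e-300`.
* If the optimum does not beat $\mu = 0$ (numerically), the guide is
  reported at exactly 0 with `ll_ratio = 0`.
* Bin fractions need not sum to 1 — an unsorted middle is typical — and
  are never renormalised; overlapping gates, quantiles outside $[0,1]$,
  and Q/Z pairs disagreeing beyond $10^{-6}$ are validation errors naming
  the offending bin.
* Guide positions are 1-based; BED export converts to 0-based half-open.
* Ranking ties break by the secondary metric, then label, so reports are
  deterministic.

## Limitations

Proportion-altering (bimodal) effects are deliberately summarised by their
population-average shift $r_g \times 1$ SD — the estimator fits a single
mean, not a mixture. Guide fitness effects on library composition are not
modelled (screens should harvest the unsorted aliquot at sort time).
Overlapping significant windows are reported individually, not merged into
regions. Gate fractions are taken as supplied; no FCS parsing.
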