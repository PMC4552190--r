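---
title: "Methods: rank-ordered sliding-window pathway enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-ordered sliding-window pathway enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankwin)
```

## The analysis in one paragraph

`rankwin` analyses an annotated de novo transcriptome — a table of ESTs
(non-redundant transcript contigs) with lengths, per-sample read counts
and GO/KEGG/EC term memberships — under a two-condition design, here
nitrogen-replete versus nitrogen-depleted cultures of the hydrocarbon
alga *Botryococcus braunii*. ESTs are sorted either by expression level
in the replete (log-phase) condition or by the depleted/replete
expression ratio. The working assumption is that member ESTs of a
co-regulated pathway sit at similar positions in such a ranking; the
detector therefore slides a window of consecutive ranks along the sorted
list and asks, for every annotated term, whether the window holds more
of the term's members than its genome-wide share predicts.

## The window statistic

Let $N$ be the ranked universe, $K$ the term's membership within it,
$n$ the window size and $x$ the member count inside the window. The
null model treats the $n$ window positions as Bernoulli trials with
success probability $p_0 = K/N$:

$$p_{\text{raw}} = P[X \ge x], \quad X \sim \mathrm{Binomial}(n, p_0),$$

with density fold $(x/n)/p_0$. The binomial form (sampling *with*
replacement) is deliberate — it is slightly conservative relative to
the hypergeometric induced by placing a fixed membership on fixed
ranks, which only helps family-wise control. A (term, window) pair is
flagged when fold $> 2$ **and** the Bonferroni-adjusted p-value is
below $\alpha = 0.05$.

Key parameter choices, all overridable:

* **Window geometry** (`window_spec`): 1024 consecutive ESTs, step
  512. Only full windows are enumerated, starting at ranks
  $1, 513, 1025, \dots$, so a 12,292-EST universe yields exactly 23
  windows and the trailing 36 ranks are uncovered. Interior covered
  ranks belong to exactly two windows, the leading and trailing
  step-width margins to one.
* **Eligibility** (`eligibility_policy`): a term participates only with
  strictly more than 30 members inside the ranked universe, evaluated
  after filtering — small terms make the binomial tail erratic and the
  fold unstable.
* **Bonferroni family** (`family`): the default counts eligible terms
  × windows, the most conservative reading of "correct all tests". A
  `per_term` family (windows only) is also supported. The choice
  matters at the detection margin: a term of $K = 60$ concentrated at
  exactly 3× background density in one 1024-rank window of a
  12,292-EST universe realises $x = 15$ expected members against 5,
  an upper tail of $2.2\times10^{-4}$ — decisive within a 23-window
  family ($p_{\text{adj}} \approx 0.005$) but not within a
  45-term × 23-window family ($p_{\text{adj}} \approx 0.22$). Our
  power analyses therefore quote per-term-family recovery for 3×
  plantings; under the conservative default a single-window signal
  needs roughly 3.5× density at this term size.
* **Determinism**: ranks are 1-based, windows closed intervals, and
  ranking ties break lexicographically on EST id, so every result is
  reproducible to the byte.

Two companions reuse the same machinery: `top_k_term_enrichment`
applies the identical binomial tail to the single block of the top $k$
ranks (the "top-30 most abundant ESTs" style of statement), and
`subset_pathway_enrichment` tests a fixed EST subset (for instance
every EST whose description matches "dehydrogenase") against each term
with the one-sided hypergeometric upper tail — there the subset is a
draw without replacement from the universe, so the exact test is the
right null.

## Expression summaries and the DE stand-in

FPKM is computed from raw counts as
`count / (length/10^3) / (library_size/10^6)`; condition summaries are
arithmetic replicate means, and the response ratio is depleted over
replete, reported as log2. ESTs are filtered before analysis with
strict thresholds — length > 300 bp, summed count > 40, and no zero
FPKM in any sample — matching the boundaries observable in the data
the generator emulates (minimum length 301, minimum total count 42).

Differential-expression calls combine an effect gate (fold change > 2)
with a significance gate (p < 0.05). The package accepts externally
computed p-values; when none are available it offers a self-contained
stand-in: an exact two-sided binomial test of each EST's pooled
depleted count against the depleted share of the total library. This
test is exactly calibrated when replicate noise is Poisson — on
Poisson-null synthetic data its empirical type-I error stays below
nominal — but it ignores biological overdispersion and becomes
anti-conservative when replicate variance is strongly super-Poisson.
That limitation is intrinsic to any pooled count test and is the
reason dedicated count models (negative-binomial GLMs) exist; supply
their p-values when you have them. A second caveat of the stand-in is
compositional: very strong induction of even a few transcripts shifts
the library-size share, which biases the test (and log fold changes)
slightly negative for unchanged ESTs. The fold-change gate absorbs
this in our simulations, but it is visible as a mild excess of
down-calls at high abundance.

## Enzyme panels

For enzyme-level statements ESTs are grouped by EC number and the
expression of an enzyme is the **sum** of its member ESTs' condition
means — summing before forming the ratio, not averaging per-EST
ratios, because the biological question is whether total transcript
output for the activity changed. An enzyme is flagged at a >2-fold
change in either direction; an enzyme with a zero sum in one condition
gets an undefined ratio and is reported but never flagged.

Whether two transcriptomes detect overlapping subsets of a proposed
enzyme list is tested with the exact hypergeometric upper tail
(`panel_overlap_test`), verified against brute-force enumeration of
all draws on small universes. For the canonical very-long-chain
fatty-acid panel configuration — a 55-enzyme universe, 20 and 19
detected, 11 shared — the exact tail is 0.01760. Somewhat smaller
figures occasionally quoted for comparisons like this one are not
reproduced by any exact one-sided variant we tried (swapped margins,
mid-p, binomial approximation); `rankwin` always reports the exact
summation and flags the overlap as significant at 0.05 either way.

## Physiology calculators

Growth is summarised from replicate cell-dry-weight series with the
geometric-growth rate $r = (x_{t_2}/x_{t_1})^{1/(t_2-t_1)} - 1$
(per day), computed per replicate over consecutive 2-day periods from
day 0 to day 8. The *average* growth rate is the unweighted mean of
the four period means and the *maximum* is the largest period mean —
a deliberate choice over regression-based rates, because it reproduces
the tabulated summaries exactly and is robust to the post-exponential
flattening after day 8. Display rounding is three decimals.

Chlorophyll follows the two-wavelength ethanol-extract formula
$C\,(\mathrm{mg/L}) = 20.2\,\mathrm{OD}_{645} + 8.05\,\mathrm{OD}_{663}$;
PSII quantum yield is $Y(II) = (F_m' - F)/F_m'$; lipid content is
component mass over CDW × 100. One arithmetic note on the packaged
lipid fixture: the nitrogen-replete hydrocarbon row computes to 19.3 %
of CDW from its own entries (0.31/1.61), and the package always
reports the value computed from the formula.

## What the synthetic generator emulates — and what it does not

`generate_table` produces the study conditions the detectors assume:

* 12,292 ESTs, two conditions × two replicates;
* log-normal lengths truncated to [301, 8268] bp, median ≈ 663;
* heavy-tailed per-EST total counts floored at 42, median ≈ 174,
  upper range ~10^5, giving realised library sizes around 2 × 10^6
  mapped fragments per sample over this annotated subset;
* negative-binomial replicate noise with dispersion 0.1 (a typical
  bulk-RNA-seq biological-replicate value; 0 gives Poisson);
* 593 up- and 116 down-regulated ESTs, ups drawn from the
  low-abundance quarter and downs from the high-abundance quarter of
  the baseline, with exponential-shaped log2 magnitudes (most modest,
  a few extreme, expected maximum near 12 for ups and 4.5 for downs);
* a catalog of 44 uniformly assigned GO-like background terms, all
  above the eligibility threshold;
* optionally, planted terms. Planting assigns membership directly on
  the realised level ranking: exactly
  $\mathrm{round}(m \cdot K/N \cdot |W|)$ members are placed uniformly
  inside the target window set $W$ and the remainder uniformly
  outside, after expression has been sampled. This keeps annotation
  decoupled from expression sampling while realising the target
  density multiplier exactly up to rounding (well within ±15 %), and
  it fails fast when a requested multiplier exceeds window capacity.
  FPKM is always derived from the sampled counts through
  `compute_fpkm`, never sampled directly, so normalisation code is
  exercised by every fixture.

The generator does **not** emulate: sequence content or isoform
structure; the unannotated majority of a real assembly (library sizes
here are those of the annotated subset only); correlation between
terms (real GO terms overlap and nest — the flat catalog is
independent); length–expression coupling; or batch effects. Passing
the simulation-based tests therefore demonstrates correctness of the
statistics under their stated nulls and power under clean plantings,
not robustness to annotation bias in real data.

## Validation problem sizes

The test suite checks the window machinery against exhaustive
enumeration for every universe up to 5,000 and against explicit
binomial sums on random universes up to 200; family-wise error on
fully null data and recovery of 3×-planted terms are each measured
over 200 simulated datasets at full scale ($N = 12{,}292$);
distributional calibration of the generator uses 20 seeds and the
growth-noise checks 100. These sizes give Monte-Carlo standard errors
comfortably below the margins being asserted (e.g. ±1.5 % on a 5 %
family-wise rate) while keeping the default suite under a minute.

## Known limitations

* Bonferroni is the only multiplicity correction offered — by design,
  no FDR procedures.
* Term sets are flat: no GO-DAG ancestry, so parent/child terms are
  independent entries.
* The binomial window null ignores the overlap dependence between
  half-overlapping windows; control is family-wise via Bonferroni, not
  per-window-independent.
* The DE stand-in is a pooled count test: use it for self-contained
  pipelines and simulations, not as a substitute for a dispersion-aware
  model on real replicated data.
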