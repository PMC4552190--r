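# rankwin

Rank-ordered sliding-window pathway enrichment for annotated de novo
transcriptomes, with the surrounding pipeline: FPKM normalisation,
fold-change differential-expression flagging, enzyme-level summative
panels, batch-culture physiology arithmetic, and a ground-truthed
synthetic-data generator.

## The problem

Non-model organisms — here the hydrocarbon-accumulating microalga
*Botryococcus braunii* under nitrogen deprivation — come without a
reference genome. Their transcriptomes are assembled de novo into ESTs
(non-redundant transcript contigs) and annotated by homology with GO
functions, KEGG pathways and EC numbers. A natural question is which
pathways are transcribed coherently: if the member ESTs of a pathway
are co-regulated, they should occupy similar positions when the whole
transcriptome is sorted by expression level (in log-phase cells) or by
the response ratio (after a perturbation such as nitrogen removal).

`rankwin` detects such subsets. With ESTs at ranks $1 \dots N$, a
window of $n$ consecutive ranks, and a term with $K$ members in the
universe of which $x$ fall inside the window, it tests

$$p = P[X \ge x], \qquad X \sim \mathrm{Binomial}(n,\; p_0 = K/N),$$

and flags the (term, window) pair when the density fold
$(x/n)/p_0 > 2$ and the Bonferroni-adjusted $p < 0.05$. The default
geometry (window 1024, step 512, full windows only) turns a
12,292-EST universe into exactly 23 half-overlapping windows. The same
tail serves top-$k$ blocks; subset-versus-term questions use the exact
hypergeometric, as does the enzyme-panel overlap test.

It is an analysis package for transcriptomics practitioners who want
the window statistic, its calibration and its inputs to be inspectable
and re-runnable, not a wrapper around any aligner or assembler.

## Worked example

Growth summary from a packaged replicate cell-dry-weight series
(double-strength BB medium):

```r
library(rankwin)
gs <- summarize_growth(read_growth_series(
  system.file("extdata", "growth_bb2x.tsv", package = "rankwin")))
gs
#>  period  rep1  rep2  rep3  mean    sd
#>     0-2 1.283 1.207 1.200 1.230 0.046
#>     2-4 0.485 0.447 0.474 0.469 0.020
#>     4-6 0.182 0.258 0.251 0.230 0.042
#>     6-8 0.155 0.095 0.138 0.129 0.030
#> average growth rate: 0.515 per day
#> maximum growth rate: 1.230 per day
```

Each cell is the per-replicate geometric growth rate
$\sqrt{\mathrm{CDW}_{t+2}/\mathrm{CDW}_t} - 1$ for one 2-day period;
the average rate is the mean of the four period means (0.515 g g⁻¹
day⁻¹) and the maximum is the best period (1.230, days 0–2).

Window enrichment on a synthetic transcriptome with a known planted
signal — a 60-member light-harvesting-like term concentrated at 3×
background density in the top window of the level ranking:

```r
cfg <- generator_config(planted_terms = list(
  plant_term("GO:0009765", size = 60, windows = 1, multiplier = 3)))
sim <- generate_table(cfg, seed = 1)

expr <- summarize_expression(sim$table)
rk   <- rank_ests(expr, "by_level")
enr  <- window_term_enrichment(rk, sim$table$annotations,
                               family = "per_term")
subset(enr, flagged)
#>      term_id namespace window start  x    n  K     N      p0 fold    p_raw
#> 1 GO:0009765     GO_BP      1     1 15 1024 60 12292 0.00488    3 0.000215
#>     p_adj flagged
#> 1 0.00495    TRUE
```

The detector recovers exactly the planted configuration: 15 of the 60
members in window 1 (3.0× the background density of 60/12292), upper
binomial tail 2.2 × 10⁻⁴, significant after correcting for the 23
windows — and none of the 44 random background terms is flagged.

Enzyme-panel overlap between two transcriptomes that detected 20 and
19 enzymes of a 55-enzyme proposed pathway, sharing 11:

```r
panel_overlap_test(55, 20, 19, 11)
#> panel overlap: 11 shared of (20, 19) in universe 55; expected 6.91, p = 0.0176
```

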