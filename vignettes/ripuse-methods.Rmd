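---
title: "Methods: identifying miRNA targets from AGO2-RIP-seq and RNA-seq"
author: "ripuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying miRNA targets from AGO2-RIP-seq and RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripuse)
```

## The problem and the approach

A microRNA loaded into the RISC complex represses transcripts it
base-pairs with, mostly through its *seed* (nucleotides 2--8 at the 5'
end) pairing to sites in 3'UTRs. Expression-only screens (overexpress the
miRNA, look for down-regulated transcripts) cannot separate direct from
secondary effects, and sequence-only site prediction cannot tell which
sites are used in a given cell. This package integrates three sources of
evidence for one miRNA in one cellular context:

1. **AGO2-RIP enrichment.** After miRNA overexpression, transcripts
   co-immunoprecipitated with Argonaute-2 are quantified against an input
   or control library. Transcripts truly loaded by the miRNA are enriched.
2. **Post-overexpression repression.** RNA-seq of the same cells against a
   negative-control mimic; direct targets are down-regulated.
3. **Unbiased word enrichment.** Instead of assuming the canonical seed
   grammar, every 6--8mer is tested for enrichment along the two ranked
   transcript lists. Canonical seed words should surface on their own; any
   other recurrent word (for example U-rich motifs, or words matching
   non-seed parts of the miRNA) indicates noncanonical interaction.

Direct targets are then called as the overlap of the top AGO2-enriched
and the top down-regulated sets, with an exact hypergeometric test, and
the canonical-site classes are validated by comparing the fold-change
distributions of site-bearing versus site-free transcripts.

## Seed grammar

For a mature miRNA with sequence $m_1 m_2 \dots m_L$ (RNA, 5'→3'), the
mRNA-strand site words are, in the field's standard classification:

* **6mer** — reverse complement of $m_2..m_7$;
* **7mer-m8** — reverse complement of $m_2..m_8$;
* **7mer-1A** — the 6mer followed by a literal `A`;
* **8mer** — the 7mer-m8 followed by a literal `A`.

The terminal `A` is required as a genomic A in the UTR, not derived by
pairing, which is the standard convention. Classes are strictly ordered
8mer > 7mer-m8 > 7mer-1A > 6mer; when occurrences overlap, only the
highest class is annotated, and a transcript's class is its best site.
Internally everything is DNA (`U` is normalized to `T` at ingestion,
because UTR FASTA files are DNA); `N` or any other character breaks a
match rather than acting as a wildcard; coordinates are 0-based,
half-open, on the given UTR strand only.

```{r seeds}
seed_words(mir125b_5p())
```

## Ranked lists

Abundances are consumed as RPKM-like non-negative tables (a
`counts_to_rpkm()` helper is provided). Replicate columns are averaged
arithmetically per condition and the ranking statistic is the
pseudocounted log ratio $\log_2\frac{t + c_0}{u + c_0}$ with $c_0 = 0.5$
by default on the RPKM scale — a plain, monotone statistic chosen because
the downstream word statistics depend only on the *order* of transcripts;
negative-binomial differential-expression machinery is deliberately out
of scope. The RIP list is sorted most-enriched first. The RNA-seq list is
sorted most-down-regulated first, so that repressed targets lead the list
and motif enrichment appears at the head of both lists symmetrically; a
flag reverses the direction if the opposite convention is wanted. Ties
break lexicographically by transcript id, making every ranking
deterministic and invariant to row permutations of the input.

## The word-enrichment landscape

For each word $w$ of length $k \in \{6,7,8\}$ and each rank cutoff $n$,
the landscape tests whether transcripts containing $w$ concentrate in the
top-$n$ of the list. With $N$ ranked transcripts, $K_w$ of which contain
$w$ at least once, and $x_w(n)$ of those in the top $n$, the upper-tail
hypergeometric probability $P(X \ge x_w(n))$ measures enrichment. The
stored score is signed:
$$ s_w(n) = \begin{cases} -\log_{10} P(X \ge x) & x/n > K_w/N \\
 \;\;\log_{10} P(X \le x) & \text{otherwise,} \end{cases} $$
so depletion is as visible as enrichment (a reversed list flips the peak
sign). Two design choices matter:

* **Presence, not occurrence counts.** The per-transcript indicator makes
  the hypergeometric model exact; occurrence-weighted alternatives need a
  composition-bias correction that is out of scope here. Tails are
  computed in log space, so extreme scores stay finite.
* **Cutoff grid.** Default is 20 evenly spaced cutoffs from $N/20$ to
  $19N/20$ — enough resolution to localize a peak without multiplying the
  test burden.

Multiple testing is handled by Bonferroni over (words of that $k$) ×
(cutoffs), matching the unbiased framing: with no planted signal, the
minimum corrected p stays above 0.05 in ≥95% of simulated replicates
(this calibration is exercised by the test suite over a 100-seed grid).
Words containing `N` are never counted.

## Repression validation by site class

Transcripts are partitioned by best site class and each class's log2
fold-change distribution is compared with the **site-free** background
(not "all transcripts" — the contrast the cumulative-distribution figures
of this literature draw) by a two-sided two-sample Kolmogorov–Smirnov
test, asymptotic by default (`exact = TRUE` is available for small
samples; below 8 observations a warning is issued). The report also
flags whether the mean shifts respect the canonical hierarchy
$\mu_{8mer} \le \mu_{7m8} \le \mu_{7m1A} \le \mu_{6mer} \le 0$. Because it
is ambiguous whether such figures pool site classes, the report carries
both the per-class rows and a pooled "any site" row.

## Target calling

Direct targets are the intersection of the top $K$ AGO2-enriched and top
$n$ down-regulated transcripts. Significance is the exact hypergeometric
upper tail $P(X \ge x)$ (observed value included), with expected overlap
$Kn/N$ and fold enrichment $x/(Kn/N)$; the universe $N$ is the set of
transcripts present in *both* rankings after filtering, which is the
conditioning set of both lists. The default prefixes are the published
choices — 4000 AGO2-loaded and 1300 down-regulated transcripts — kept
absolute for universes of ≥20000 transcripts and scaled proportionally
(20% and 6.5%) below that, so desk-scale simulations exercise the same
fractions of their universe.

`density_profile()` offers the data-driven way to choose prefixes: an
unweighted GSEA-style walk (+$1/\#hits$ on site-bearing transcripts,
−$1/\#misses$ otherwise) whose argmax marks the rank where site density
is highest. Unweighted increments keep the walk parameter-free. **Known
limitation:** the walk's argmax sits at the rank where the local hit
density crosses the global average. On a noisy measured ranking this
crossover lies beyond the planted/true target stratum — with loading
+1.0 and noise sd 0.4 the overshoot is ~1.5× the stratum size — so the
suggested prefix is an upper bound; on a ranking that separates the
stratum cleanly the argmax matches its size exactly. The same boundary
smearing shifts the seed-word peak cutoff of the landscape outward.

## Seed census against the random-word null

To ask whether a seed word is unusually frequent or rare across a
transcriptome, its total (overlapping) occurrence count over all UTRs is
compared with the census distribution of *all* $4^k$ same-length words:
$z = (\text{obs} - \bar c)/s_c$, plus an empirical percentile. The
exhaustive ensemble replaces Monte-Carlo sampling of random words (a
sampled mode exists and requires a seed); 16384 words for $k=7$ and
65536 for $k=8$ are both cheap to enumerate. Occurrences, not presence,
are counted here because the claim is about the *number* of seeds in the
transcriptome. When every comparison count is equal (degenerate null)
the z-score is reported as undefined and only the percentile is given. A
GC-matched comparison set is a natural refinement but is deliberately not
the default: with the uniform-composition synthetic UTRs the exchangeable
null is exact.

## The synthetic-data generator

`simulate_ripuse_experiment()` emulates the experimental design at the
level the pipeline consumes — abundance tables, not reads:

* UTRs are drawn per-base at a configured GC fraction (default 0.5,
  uniform composition; see limitations), lengths uniform on 500–1000 nt.
* Site planting is **exact**: strata of transcripts receive one site of
  their class at a random position; insertion positions are
  rejection-sampled so flanking bases never upgrade the class (a planted
  7mer-m8 followed by a chance `A` would otherwise scan as an 8mer), and
  background sequences are rejection-sampled to contain none of the four
  site words. The truth manifest therefore matches `scan_sites()` exactly
  (`verify_manifest()` checks this per run).
* Abundances are log-normal (`meanlog = log 20`, `sdlog = 1.2`,
  RPKM-like); every replicate measurement multiplies the transcript's
  base abundance by $2^{\epsilon}$, $\epsilon \sim N(0, 0.4^2)$ by
  default. True targets additionally carry $2^{\text{effect}}$ in the
  mimic condition (defaults −0.8/−0.6/−0.4/−0.2 log2 units for
  8mer/7mer-m8/7mer-1A/6mer — the canonical efficacy ordering) and
  $2^{+1.0}$ in the RIP condition.
* Defaults plant the four classes on 10/15/10/10% of 2000 transcripts,
  with every planted transcript a true target; the planting fractions,
  the effect sizes, the loading and the noise are all configurable, and a
  seed is mandatory — identical seeds reproduce the experiment byte for
  byte.

What the generator does **not** emulate: AT-rich real UTR composition and
repeat structure, isoform overlap, count noise at low expression,
secondary (indirect) regulation, and transcripts carrying sites without
any site-free background contamination in reverse — so passing recovery
tests demonstrates the statistical machinery, not performance on real
libraries, where annotation choice and composition bias dominate.

## Numerical choices and degenerate inputs

* Hypergeometric tails via `phyper` on the log scale; the test suite
  checks every landscape cell and overlap p against exhaustive point-mass
  summation (≤1e−12) for small universes.
* Ranking ties break lexicographically; empty universes, duplicate ids,
  negative abundances, ragged tables, missing UTRs and infeasible
  planting are all hard errors, not warnings.
* An empty UTR scans to an empty annotation set (not an error); a word
  absent everywhere has p = 1 at every cutoff and score 0.
* Floats written to TSV are fixed at 6 significant digits so artifacts
  diff cleanly across platforms.

## Problem sizes used by the test suite

The reference simulation is 2000 transcripts (the scale at which the
published prefix choices translate to 400 and 130); module tests run
200–500-transcript versions of the same designs, and replicate-grid
properties (null calibration at 100 seeds; smaller 5–20-seed versions in
module tests) state their replicate counts alongside the tolerance they
assert. All randomness flows through explicit seeds.

## Worked example

```{r example}
sim <- simulate_ripuse_experiment(
  synth_config(planting = c("7mer-m8" = 0.15),
               effects = c("7mer-m8" = -0.6), seed = 1))
fit <- rip_use(sim$utrs, sim$config$mirna, sim$rip, sim$input,
               sim$mimic, sim$control, k_set = 7)
summary(fit)
```

```{r plots, fig.width = 6, fig.height = 4}
plot(fit, type = "cdf", main = "Repression by site class")
plot(fit, type = "landscape", main = "Seed-word landscape (RNA-seq ranking)")
```
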