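---
title: "Methods: linking EV miRNA cargo to recipient-cell repression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking EV miRNA cargo to recipient-cell repression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evlink)
```

## The analysis and its assumptions

`evlink` formalizes a cargo-linkage analysis for extracellular-vesicle
(EV) small-RNA studies with a two-source design: replicate miRNA count
libraries from a source of interest (e.g. trophoblast-spheroid EVs) and a
control source (e.g. kidney-cell EVs), plus a differential-expression
table from recipient cells exposed to the first source's EVs. The chain
is: call source-exclusive miRNAs from presence/absence across replicates,
map their high-confidence predicted targets into the DE table, and ask
whether miRNA abundance predicts the depth of repression among
downregulated targets.

The analysis is deliberately correlative. It assumes (i) that raw counts
are comparable across libraries after per-library CPM normalization, (ii)
that target predictions with high scores are enriched for true
interactions, and (iii) that canonical silencing, if present, manifests as
a negative association between cargo abundance and the mean log2 fold
change of downregulated targets. None of these establish causality; the
statistic quantifies consistency with a silencing signal.

## Detection and exclusivity

A miRNA is *detected* in a group at threshold $t$ when its raw count is
$\ge t$ in at least $m$ of the group's libraries. The comparison is
inclusive ($\ge$), and the same convention is used everywhere — in the
specificity rule and in the threshold sweep — to avoid off-by-one
inconsistencies between the two surfaces. The default $m$ is
$\lceil \tfrac{2}{3}\,\text{group size} \rceil$, which reproduces the
common 2-of-3 replicate-membership rule for triplicate designs and
generalizes it to other replicate counts; it can be overridden.

A miRNA is *exclusive* to group $g$ when it is detected in $g$ **and** has
a raw count of exactly zero in every library of every other group. "Not
detected at all" is read literally: the zero clause carries no threshold,
so exclusivity calls tighten with $t$ only through the detection side.
Consequences tested as properties: detected and unique sets are monotone
non-increasing in $t$ and $m$, the two groups' unique sets are disjoint,
and calls are invariant to permuting libraries within a group.

## Abundance

CPM is computed per library as count / (library total miRNA-assigned
counts) × 10⁶. This denominator is the only total visible to a miRNA
count matrix; studies that prefer total genome-mapped reads as the
denominator can rescale upstream, since CPM here is linear in 1/total.
The per-group summary is the arithmetic mean CPM; its log2 is taken *after*
averaging (`log2_of_mean`, the default) so that zero-count libraries do not
require a pseudocount. miRNAs with zero mean CPM get an undefined (`NA`)
log2 abundance rather than an arbitrary pseudocounted value. The
alternative convention, the mean of per-library log2 CPM (`mean_of_log2`),
is provided because published "mean log2 CPM" axes are ambiguous between
the two; it is defined only when every library has non-zero CPM.

## DE classification and target linkage

Genes partition into DOWN (FDR ≤ cutoff and log2FC < 0), UP (symmetric)
and NON_DE. The default applies no fold-change magnitude requirement,
matching the common practice for recipient-cell DE calls; an optional
strict $|\log_2 FC| > c$ clause (typically $c = 1$) serves cargo
enrichment/depletion contrasts. Predicted targets are filtered at a target
score $\ge 90$ (inclusive — the conventional high-confidence boundary for
0–100 prediction scores), collapsed to gene level through the
transcript→gene map with set semantics (isoforms deduplicate), and
restricted to genes present in the DE table; genes absent from it are
excluded from every count but reported, as are predictions whose
transcripts have no mapping. Identifier version suffixes (`.N`, possibly
repeated) are stripped at load on both sides, since version mismatches
otherwise silently drop genes at the join.

## The weighted correlation

Across the source-exclusive miRNAs, $x_i$ = mean log2 CPM, $y_i$ = mean
log2FC of miRNA $i$'s DOWN targets, $w_i$ = its number of DOWN targets:

$$ r_w = \frac{\sum_i w_i (x_i - \bar x_w)(y_i - \bar y_w)}
{\sqrt{\sum_i w_i (x_i-\bar x_w)^2 \sum_i w_i (y_i-\bar y_w)^2}} $$

Weighting by the DOWN-target count lets miRNAs whose $y_i$ averages more
targets (and is therefore less noisy) count for more; with integer weights
$r_w$ equals the plain correlation of the dataset in which point $i$ is
replicated $w_i$ times, which is the brute-force oracle the test suite
checks against to $10^{-12}$.

A miRNA with no downregulated target has undefined $y_i$ and zero weight;
it cannot enter the statistic and is excluded. Degrees of freedom follow
the *contributing* points: $t = r\sqrt{(n-2)/(1-r^2)}$ with $n$ = number
of positive-weight miRNAs, referred to Student's $t$ on $n-2$ df,
two-sided. This exclusion-based df convention is a genuine design choice —
the t reference is the standard companion of Pearson's $r$, and counting
excluded points in $n$ would overstate the evidence; the formula is
validated in the tests against `stats::cor.test` on datasets constructed
to have an exact sample correlation. The t approximation treats the
weights as fixed; with strongly unequal weights the effective sample size
is below $n$ and the test is mildly anticonservative, which is why the
null calibration is checked by simulation (below) rather than assumed.

The sensitivity grid re-runs the entire chain per (target-score, FDR)
cutoff pair (defaults {80, 85, 90} × {0.05, 0.10, 0.20}). No
multiple-testing correction is applied across cells: the grid is
descriptive, exposing how the single headline statistic depends on
filtering, not a family of hypotheses. Cells with fewer than three
contributing miRNAs or degenerate variance are reported as `NA` with a
note.

## The synthetic-data generator

`sim_config()` defaults define the emulated study: 3 vs 3 replicate
libraries, 150 shared miRNAs, 11 miRNAs exclusive to the silencing source
and 2 to the control source, ~5×10⁵ miRNA-assigned counts per library
(jittered ±20%), negative-binomial counts with dispersion 0.15 (a typical
replicate-level dispersion for small-RNA libraries), a 15,000-gene
transcriptome with 100 true targets and 150 decoy predictions per
exclusive miRNA, true scores uniform on [90, 100] and decoy scores on
[50, 100] (so a fifth of decoys survive the high-confidence cutoff —
an analytic tail the tests verify), and 65% of genes present in the DE
table, reflecting that prediction spans the transcriptome while DE is
only testable for expressed genes.

Design choices worth spelling out:

- **Exclusive miRNAs are structural zeros** in the other group, not merely
  low-expectation draws, because the exclusivity rule requires literal
  zeros and planted truth must be unambiguous. A `leaky_rate` option adds
  Poisson contamination for robustness experiments.
- **Silencing acts on the DE summary, not on simulated reads.** A true
  target's mean log2FC is shifted by $-\beta \times$ (mean log2 CPM of its
  targeting miRNA); genes targeted by several exclusive miRNAs take the
  shift of the most abundant one (the strongest silencer), since shifts
  are means, not sums of independent effects. Simulating at this level
  keeps bundles fast while preserving exactly the statistical structure
  the correlation assumes.
- **Background DE applies to every gene, targets included.** With
  probability `frac_background_de` (default 0.1) a gene's mean log2FC is
  shifted by ±2 irrespective of targeting, because real recipient cells
  regulate genes for many reasons besides cargo miRNAs — which is also
  what makes target sets contain upregulated genes. Under $\beta = 0$
  this makes target and non-target fold changes exchangeable, so the
  correlation's null behaviour can be measured honestly.
- **p-values are generated by the same noise model** (two-sided z against
  the log2FC noise SD, default 0.5), and FDR is Benjamini–Hochberg across
  all genes, so FDR-based DOWN calls enrich for true targets exactly as
  the analysis assumes. The BH step is `stats::p.adjust`, validated in
  the tests against a hand-computed five-p-value example.

What the generator does **not** emulate: read-level noise and alignment
artefacts, UMI deduplication, cross-miRNA sequence similarity, correlated
expression between genes, and dependence between a miRNA's abundance and
its number of predicted targets. Passing tests therefore demonstrate that
the pipeline recovers planted structure under a faithful statistical
abstraction of the design — not that any particular biological dataset
will show a silencing signal.

## Numerical conventions and degenerate inputs

Zero p-values in the GSEA ranking statistic $-\log_{10}(p)\times\log_2 FC$
are clamped to the smallest representable positive double (with a warning)
so scores stay finite and sortable; the ranking is documented as *not*
invariant under monotone rescaling of p-values (a counter-example lives in
the tests). Zero-total libraries are a data error for CPM; fewer than
three positive-weight points or zero weighted variance raise typed errors
(`evlink_insufficient_data_error`, `evlink_degenerate_data_error`) that the
sensitivity grid converts to `NA` cells. All file readers reject
out-of-range scores and FDRs, duplicate identifiers, negative or
non-integer counts, and transcripts mapped to two genes; writers emit a
canonical tab-separated form that round-trips byte-identically.

## Problem sizes in the test suite

Unit and property tests run on small bundles (40 shared miRNAs, 2,000
genes, 40 targets per miRNA) chosen so the whole suite stays in the
one-minute range; the recovery and calibration checks — power of the
abundance–repression correlation at $\beta = 1$ and its type-I rate at
$\beta = 0$ over 100 seeds each, and the 11 + 2 exclusive-miRNA recovery —
run at the full default scale. Reported calibration: power ≥ 0.9 required
(observed 1.0), null rejection within the binomial 95% band around 5%.

## Known limitations

The pipeline consumes a DE table and never fits the DE model itself;
dispersion estimation, batch terms and outlier handling live upstream.
With ~11 contributing miRNAs the correlation has wide confidence bounds,
and the weighted t test is approximate for very uneven weights. Exclusivity
based on literal zeros is sensitive to sequencing depth: deeper control
libraries make exclusivity harder to attain, which is why the detection
sweep and the sensitivity grid are first-class outputs rather than
diagnostics.
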