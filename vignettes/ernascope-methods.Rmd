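---
title: "ernascope: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ernascope: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and
why: the procedures, the tunable parameters with their defaults, the
numerical conventions, what the synthetic-data generator emulates, and
the limits of what passing tests demonstrate.

# Coordinate and counting conventions

All in-memory tables are 0-based, half-open `[start, end)` (BED
convention); 1-based formats would be converted at the file boundary.
Overlap requires at least one shared base; adjacent half-open
intervals do not overlap but have distance 0, so proximity thresholds
("within 1 kb") are applied as `distance < radius`. Distance between
an interval and a point (TSS, TES) is 0 when the point lies inside the
interval and the bp gap otherwise; queries on chromosomes with no
annotated gene return `Inf`, and such peaks are rejected as
`unassignable` rather than silently qualified, because the
TSS-proximity criteria cannot be certified there.

Three tag-counting rules exist, chosen per use: **midpoint** (each tag
increments exactly one bin, so track totals conserve tag counts; the
default for coverage and window tests), **overlap** (a tag increments
every bin it touches; available by flag), and **5′-position** for
stranded RNA counting (a read belongs to the window containing its 5′
end: `start` on `+`, `end − 1` on `−`), which partitions reads
unambiguously between the proximal and far eRNA windows.

# Signal profiling

Tags are extended 100 bp past their 3′ end (the `end` coordinate on
`+`, `start` on `-`), approximating sonicated fragment size; the
alternative reading — resizing to a fixed fragment length from the 5′
end — is exposed as `fixed_length = TRUE` rather than guessed as
intent. Extension results are clamped to `[0, chromosome length)`.
Deduplication keeps one tag per `(chrom, start, strand)` key; because
extension changes coordinates, the pipeline fixes the order
deduplicate → extend (the two do not commute). Deduplication is
applied only when the measured duplication rate exceeds 0.3 — "high"
duplication is not a crisp notion, so the threshold is an explicit,
configurable parameter.

Coverage uses 100-bp bins; RPM is `count × 10⁶ / total_mapped`. Anchor
(metagene) profiles collect the `2·half_width/bin_size` bins centred
on the bin containing each anchor point (default half-width 5 kb),
reverse the window for `−`-strand anchors, and average position-wise;
anchors truncated by chromosome ends contribute only their defined
positions. FPKM is `count × 10⁹ / (length × total_mapped) + 0.01`; the
additive 0.01 is exactly 1 read per 10⁸ mapped reads per kilobase on
the FPKM scale, so empty regions have a defined floor and ratios stay
finite.

# Enhancer annotation

The five qualification predicates (score ≥ 60, no H3K4me3 overlap,
RefSeq TSS ≥ 1 kb, EST TSS ≥ 2 kb, H3K4me1 overlap) are all evaluated
for every peak — never short-circuited — so every rejected peak
carries its complete reason set. H3K4me3 exclusion uses the union of
peaks across all supplied conditions (the stricter reading when
conditions disagree). TSS distances are measured from the peak
interval, not its summit, since it is the peak that must not be near a
promoter. Intragenic means fully contained in a RefSeq transcription
unit; extragenic peaks within 5 kb of a TES are set aside
(`excluded_near_tes`) instead of being profiled, so transcription
end-site Pol II cannot masquerade as enhancer signal. Activity
classing surfaces mark conflicts (`conflicted` when both the
acetylation and the repressive mark overlap) rather than resolving
them silently; class fractions downstream exclude that group.

# eRNA quantification and filters

eRNAs are short, bidirectional transcripts, so quantification is
restricted to fixed 2-kb windows flanking the p300 summit and no
transcript-length estimation is attempted. The four exclusion filters
and their parameters:

* **strand ratio** — `(n₊ + 1)/(n₋ + 1) > 5`, with a pseudocount of 1
  tag on both strands (minimal and symmetric) to avoid division by
  zero. The test is one-directional by default, exactly as the rule is
  stated; `symmetric_ratio = TRUE` also flags minus-strand-dominant
  loci, which are equally suspect but are flagged rather than assumed.
* **flanking signal** — a +2–4 kb or −2–4 kb window with more signal
  than its proximal window indicates a long/genic transcript. Counts
  are compared raw when window lengths are equal and as per-bp
  densities when chromosome-end clamping has made them unequal.
* **repeat signal** — repetitiveness is not inferred from alignments;
  an externally supplied per-locus flag (e.g. blacklist or mappability
  derived) combined with the > 1 FPKM gate operationalizes "aberrantly
  high signal at repetitive loci".
* **rRNA homology** — implemented as interval overlap with a supplied
  rRNA blacklist BED; no sequence search is performed.

Filters are order-independent and idempotent; all applicable reasons
are recorded. Induction is the ratio of stimulated to unstimulated
total FPKM (plus + minus window), each condition normalized by its own
library; the FPKM floor bounds the denominator at 0.02.

# Differential enrichment and inducible sets

A dedicated differential peak caller is deliberately not
re-implemented; the contribution here is the *rule* (enrichment at
FDR < 0.1 intersecting qualified enhancers), so the stand-in test is
the simplest defensible one: per window, a one-sided exact binomial
test of `count_stim` out of `count_stim + count_ctrl` against the
depth-expected proportion, BH-adjusted across windows. Zero-count
windows are untestable and get p = 1. Windows default to the qualified
enhancer intervals padded ±500 bp. Pre-called differential peaks in
BED form can be substituted for the stand-in entirely.

Inducible genes: the expression matrix (log2 scale) is
quantile-normalized across samples (limma), then per gene an unpaired
equal-variance Student's t-test (Welch by flag) and the mean log2 fold
change are computed; inducible means log2FC > 1 and p < 0.05. Each
group needs ≥ 2 samples, or the variance is undefined and the call
errors. Probe-level processing and background adjustment are out of
scope; inputs are assumed background-corrected.

# EPU assignment

The full published enhancer-promoter-unit construction depends on
details deferred to external supplementary material, so the package
implements a documented simplification behind a single interface:
chromosomes are partitioned into blocks at CTCF peak summits
(duplicate summits collapse; chromosome ends close terminal blocks;
an empty CTCF set yields one block per chromosome), and each enhancer
is assigned to the nearest target-gene TSS sharing its block within
`max_range` (default 200 kb — the underlying rule states no cap, so
the cap is explicit and configurable). Ties break toward the lower
coordinate; unassigned enhancers record `no_tss_in_block` or
`out_of_range`. One gene per enhancer; one gene may collect many
enhancers. Removing a CTCF site can only merge blocks and therefore
never unassigns a previously assigned enhancer.

# Occupancy and promoter dynamics

Promoter windows default to TSS ± 1 kb (configurable; the promoter
universe is always reported alongside fractions, since overlap
percentages are meaningless without it). Site classification takes
promoter precedence over enhancer — by construction a qualified
enhancer cannot sit inside a promoter window, so the two universes are
near-disjoint and precedence only resolves edge overlaps. Ranking and
top-N selection break ties by (chromosome, start), so outputs are
byte-reproducible under input permutation. "Normalized to input" is
the ratio of window-mean RPM values with a symmetric pseudo-RPM of
0.01 on both numerator and denominator; the ratio is depth-invariant
for RPM tracks up to the epsilon.

# The synthetic-data generator

The generator emulates the statistical structure the pipeline is built
to detect: planted enhancers bearing p300 + H3K4me1 (±
H3K9ac/H3K27ac or H3K9me3/H3K27me3 by class), promoters bearing
H3K4me3, bidirectional stranded eRNA clusters at enhancer summits,
decoys violating each qualification criterion and each eRNA filter,
CTCF sites creating assignable, insulator-blocked and out-of-range
enhancer-gene cases, condition-dependent acetylation gains at
inducible enhancers, binding-site redistribution from enhancers to
inducible promoters, promoter H3K9me2 depletion on stimulation, and a
two-condition expression matrix with planted fold changes.

Layout is slot-based: every element owns a 60-kb region, so spacing
between elements always exceeds every qualification radius and
expected outcomes are computable from the configuration alone.
Counts are Poisson; expression noise is Normal on the log2 scale —
the minimal models the downstream procedures implicitly assume. Decoy
rates are margin-safe so each decoy trips exactly its intended filter
with overwhelming probability (e.g. the unidirectional decoy uses
150 vs 5 expected tags, not a marginal 6:1 ratio; far windows of
non-flanking decoys are silent so no second filter can fire
stochastically).

Default conditions (the reference fixture): an 8-Mb two-chromosome
genome; 45 qualified enhancers (28 generic extragenic across
activity classes, 4 intragenic, 3 near-TES, 10 EPU-case) and 10
decoys, two per rejection class; 12 true eRNA loci with 30 expected
tags per strand per proximal window and 2 per far window, plus 2
decoys per exclusion class; H3K9me2 at 1000 expected tags per
promoter window with 2-fold depletion at the 10 inducible promoters
after stimulation, over a 2×10⁵-tag background and a 10⁶-tag input
library; H4ac/H3K9ac at 60 expected control tags per enhancer window
with 5-fold gains at inducible enhancers; 50 binding sites composed
70/10/20 over enhancer/promoter/other with 20% of enhancer sites
relocated to inducible promoters on stimulation; and a 1000-gene
expression matrix, 10% induced at log2 effect 2.0, replicate noise SD
0.25, 3 replicates per group. These sizes run the full pipeline in
well under two minutes on one CPU.

Expression baselines are Normal(8, 2). The spread matters: quantile
normalization assumes largely unchanged distributions, and when the
between-gene spread is narrow relative to the planted effect the
top-ranked induced genes are compressed toward the reference
distribution and can lose most of their fold change. A baseline SD of
2 — typical of log2 array intensities — keeps shifted genes blended
into the rank distribution, which is the regime quantile
normalization is designed for.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: no read-level sequence or mapping
error, no fragment-size variation, no spatial autocorrelation of
background, no copy-number or mappability structure, no peak-caller
noise (peaks are emitted directly, since peak calling is out of
scope), no overdispersion beyond Poisson, and no partial or ambiguous
decoys — real data violate criteria marginally, not cleanly. On a
miniature genome the planted loci are also a large fraction of each
library, so depth normalization produces composition effects a real
library would not show: the reported eRNA induction median (~1.45 at
default settings) is smaller than the planted 2-fold rate change
because the stimulated library's total grows with the induced loci
themselves. This is faithful behaviour of FPKM ratios under
composition shift, reported as computed, not corrected away.

# Numerical choices and degenerate inputs

Zero-variance genes report p = 1 (all values identical) or p = 0
(groups constant but separated); zero-count windows p = 1; empty
anchor sets, empty annotation and sub-minimal group sizes are errors,
not silent defaults. Missing peak summits fall back to the interval
midpoint (eRNA windows need an anchor). Empty CTCF input degrades to
whole-chromosome blocks. All thresholds compare strictly where the
rule says "more than" (a ratio of exactly 5 passes) and inclusively
where it says a minimum (a score of exactly 60 qualifies).

# Known limitations

* The EPU construction is a nearest-in-block simplification; the
  assignment interface isolates it so a faithful variant can be
  swapped in.
* The binomial window test ignores replicate dispersion; it is a
  calibrated stand-in (type-I control is verified by simulation in
  the test suite), not a negative-binomial framework.
* Transcription units are single intervals — no exon structure, no
  GFF/GTF parsing, no liftover.
* eRNA analysis never assembles transcripts or detects directional
  pairs beyond the two fixed windows.
* Condition labels are opaque strings; the pipeline models exactly
  two conditions per contrast.
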