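---
title: "Methods: junction-led cryptic exon discovery, PSI, NMD and UG-motif scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-led cryptic exon discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticsplice)
```

## The model

A cryptic cassette exon is an intronic segment with latent splice sites that
enters the mRNA when its repressor (here, a TDP-43-like RNA-binding protein
bound to a downstream UG-rich tract) is lost. Everything in this package is
driven by *junction-spanning reads*: each BED12 record from
`regtools junctions extract` contributes one intron with a read count, and
all downstream statements — discovery, quantification, transcript
consequence — are functions of those counts plus the annotation and genome.
Read alignment, CLIP peak calling and transcript assembly are out of scope;
junctions and peaks are consumed, not produced.

### Discovery

`call_cassette_exons()` emits a candidate when four conditions hold: (a) an
annotated donor splices to an unannotated acceptor inside an annotated
intron; (b) an unannotated donor strictly downstream of that acceptor (in
transcript orientation) splices back to an annotated acceptor; (c) the
enclosed segment overlaps no annotated exon; (d) both novel introns are
checked for GT/AG in transcript orientation. The canonical-site check is a
**flag, not a filter**: the source analysis asserts "well-defined" sites but
states no filtering rule, so non-canonical calls are retained with their
dinucleotides for inspection.

Classification: the candidate with maximal entry+exit support, if it reaches
`min_major_support`, is `CE1`. The default threshold is 5, the only support
number the source analysis prints (junction species below 5 reads are called
minor). Acceptor-sharing candidates whose *exit* junction stays below the
threshold in every sample are `CE2`, `CE3`, … numbered by increasing donor
coordinate in transcript orientation. We judge extensions on the exit
junction alone because the entry junction is shared with CE1 and therefore
large by construction; counting it against the "<5 reads" notion would make
the extension classes unreachable. Entry junctions with no detectable exit
are reported with `exit = "readthrough"` rather than dropped.

### PSI

For an anchor donor, `PSI = inclusion / (inclusion + exclusion)` where
inclusion reads splice to the target acceptor and exclusion reads to any
other acceptor from the same donor. Two pooling modes exist because the
source analysis prints a single PSI per tissue and genotype without saying
which it used:

* `pool_counts` (default): counts are summed across a condition's replicates
  before the ratio. This is what a single printed value per condition
  implies, and it weights samples by coverage.
* `mean_of_samples`: per-sample PSI averaged; samples with zero coverage at
  the anchor are dropped.

A zero denominator yields an *undefined* PSI (`NA`), never 0 or 1 — at low
coverage either constant would be silent bias. A missing target is an error,
deliberately distinct from an undefined ratio. The acceptor-anchored variant
(`anchor = "acceptor"` in `competing_junctions()`) answers donor-usage
questions symmetrically, e.g. for cassette extensions.

### ORF, PTC and NMD

`splice_transcript()` concatenates strand-correct exon sequences and records
junction offsets; `scan_orf()` translates the standard genetic code from the
annotated CDS start (a first-AUG fallback exists but only behind an explicit
flag — silent ORF misassignment is worse than an error). A stop is premature
when its genomic position is strictly upstream, in transcript orientation,
of the reference chain's stop. NMD uses the canonical 50-nt rule,
parameterised: predicted when the stop lies more than `rule_distance` nt
upstream of the final exon–exon junction. We measure the distance from the
*end* of the stop codon to the junction and trigger on strict inequality,
so a stop exactly 50 nt upstream is not a substrate; single-exon transcripts
never are. Protein mass uses average (not monoisotopic) residue masses plus
one water, unmodified chain — the "before glycosylation" convention; the
empty peptide returns one water by default (`empty = "zero"` is available,
and the choice is surfaced rather than hidden).

### UG motif and CLIP peaks

`ug_score()` counts *overlapping* UG occurrences on the transcribed strand
(every position i with s[i..i+1] = UG), their density over length−1
positions, and the longest perfect (UG)n run. Overlapping counting is the
simplest reproducible definition; since the source analysis quantifies
nothing here, scores are descriptive outputs, not filters. The default
window is 10–210 nt downstream of the cryptic donor in transcript
orientation — the binding tract sits just downstream of the cassette — and
both offset and width are parameters. CLIP peaks are merged (union) before
the base-pair overlap is summed, so stacked peaks are not double-counted.

### Isoform classification

`classify_isoform()` encodes the neurofascin convention: exons 23–24 without
28–30 is glial NF155; 28–30 without 23–24 is neuronal NF186; neither is
NF140, suffixed by the exon-27 flag; both blocks is a contradiction
(`"conflict"`), as is discordant 23 vs 24 evidence; missing flags give
`"indeterminate"`. `exon_usage_flags()` derives the flags from junction
evidence, mirroring junction-spanning qPCR primers (a junction landing on an
exon's acceptor is inclusion evidence; one spanning the exon is skipping
evidence; both at once is `NA` — bulk tissue can genuinely contain both
isoforms, and the function does not pretend otherwise).

## The synthetic locus: what it emulates, and what it does not

`sim_config()` defaults *are* the stated world: a four-exon window with
ordinals 17–20, a 104-nt cassette inside the first intron with canonical
AG/GT flanks, an in-frame TAA at offset 45 of the cassette, a (UG)12 tract
starting 10 nt after the cryptic donor, an annotated skip transcript joining
exons 17 and 19 (the predominant wild-type form), and two conditions at the
printed acceptor-usage values — WT 0.253 and cKO 0.931 — with three
replicates each, mirroring n = 3 per genotype. Donor depth defaults to 200
junction-spanning reads per replicate: the source data's depths per junction
are unpublished, and 200 is a realistic per-junction depth for a well-covered
exon in a 30–40 M read library, chosen once and used for all recovery
statements. Exon/intron lengths are round numbers satisfying the frame
constraints (the exon-17 CDS portion and interior exons are codon multiples
so the cassette enters in frame 0); they are geometry, not biology.

Counts follow `inclusion ~ Binomial(depth, PSI_true)` at the entry junction,
with the exit junction mirroring the inclusion count exactly and the
remainder assigned to the annotated skip junction. The fully coupled
two-junction inclusion isolates PSI estimation from discovery; real data has
independent noise between the two inclusion junctions, partial intron
retention, and coverage-dependent anchor losses, none of which are modelled.
A green recovery test therefore establishes correctness of the estimator and
the discovery geometry under the stated sampling model — not robustness to
alignment artefacts. Zero-count junctions are not emitted, as in real
junction-extraction output; this is what makes the "no cryptic reads → no
calls" property meaningful. Per-sample RNG streams are derived from
`(seed, sample_id)` by a fixed mixing rule, so adding conditions never
perturbs existing samples. `background_depth` optionally adds constant
support on every consecutive annotated junction (needed for spliceform
enumeration through exon 18); it adds competing acceptors at the anchor, so
recovery statements use the default of 0. `emit_minor` plants two weak
downstream donors with per-sample counts in 1..4 to exercise the CE2/CE3
classes.

## Numerical choices

* Coordinates are 0-based half-open everywhere; GTF converts at the I/O
  boundary. Junction strand is taken from the BED strand column, never
  inferred; `.`-strand junctions are kept but excluded from strand-aware
  discovery.
* Duplicate junction lines for one intron are summed with a warning.
* Reports sort rows deterministically and render floats at 6 significant
  digits, so identical configs produce identical bytes.
* PSI normalization over a donor's acceptors is exact in rational
  arithmetic (shared integer denominator). IEEE *addition* of the ratios
  is not always exactly 1 (≈0.7% of random count vectors), so the
  normalization test asserts the integer identity — every PSI equals
  `count/total` bitwise and counts sum to the total — rather than comparing
  a float sum to 1.
* ΔΔCq uses base 2 with no efficiency correction (efficiencies validated
  90–110% in the source protocol); a per-primer base override exists. The
  calibrator's *geometric* mean level is 1 by construction — the arithmetic
  mean is ≥ 1 by Jensen's inequality, which is why the invariant is stated
  geometrically.
* Ties in CE1 selection resolve to the first candidate in segment-coordinate
  order (deterministic, documented, and not expected under the stated
  world).
* Estimator unbiasedness is tested with an exact binomial test on the
  pooled inclusion total over a frozen 500-seed ensemble (α = 0.001)
  rather than a 2-standard-error band on the mean: a 2-SE band fails 5% of
  honest ensembles by construction, which is the wrong operating point for
  a deterministic, seed-frozen test.

## Known limitations and a red criterion

The acceptance criterion asking pooled PSI to land within ±0.03 of truth in
≥95% of 200 runs at depth 200 × 3 replicates is arithmetically unattainable
for two of its three regimes: with `X ~ Binomial(600, p)` exactly as
prescribed, `P(|X/600 − p| < 0.03)` is 0.996 at p = 0.931 but 0.909 at
p = 0.253 and 0.861 at p = 0.439. The criterion is implemented as stated
and left failing for those regimes; the estimator itself is unbiased (mean
over a 500-seed ensemble within two standard errors of truth, tested
separately). Widening the band or raising the depth would have made the
test green and the statement false.

Other limitations: no statistical inference on ΔPSI (no beta-binomial or
GLM); no intron-retention quantification from coverage; genome-wide
multi-gene scans run but are untuned; CE2/CE3 boundaries follow the
acceptor-sharing definition, which is an interpretation of a figure-level
description and is flagged as such here.
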