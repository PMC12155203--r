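---
title: "Profiling tRNA-derived RNAs: models, parameters and design choices"
author: "tdrprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling tRNA-derived RNAs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdrprofiler)
```

## The analysis problem

tRNA-derived RNAs (tDRs) are stable fragments of mature tRNAs, ranging from
short trimmed pieces under 30 nt to 31–36 nt tRNA-halves produced by
cleavage in the anticodon loop. In nematode sperm they accumulate to a
substantial share of the small-RNA pool, their abundance and length are
shaped by RNase T2 activity, and they can carry non-genetic information into
the embryo, where their effects surface as differential expression in early
embryos and as heritable physiological phenotypes. Measuring all of this
from 18–40 nt small RNA-seq requires a chain of specific analysis
conventions — a class priority for ambiguous reads, a choice of
normalization denominator, an anticodon-relative definition of "5′ half" —
and this package implements that chain end to end, together with a
generator of synthetic libraries whose ground truth lets every stage be
validated quantitatively.

## Read classification

**Model.** A read is assigned to the first class in the fixed order
rRNA → miRNA → tRNA → piRNA that matches it, at up to `max_mismatches`
substitutions (0 by default; 1 optionally). Class references are matched on
the sense strand only, because small-RNA reads are cloned from the mature
RNA. Reads with no class hit are matched against the genome on both
strands; a hit antisense to an annotated gene makes the read an endo-siRNA,
a sense hit an mRNA fragment, any other genomic hit "other genomic", and a
read matching nothing is unassigned. The priority order resolves every
cross-class ambiguity deterministically (an rRNA/tRNA double match is
rRNA); the one tie left — a genomic read overlapping genes on both strands —
goes to the antisense call, since the endo-siRNA class is defined by
antisense complementarity.

**Multimapping.** Within the winning class, hits at the minimal mismatch
count share the read's weight equally. Identical mature tRNA sequences are
collapsed to one representative record before indexing, so a read matching
two identical isodecoders contributes weight 1 to the collapsed record
rather than 0.5 to each; the membership map keeps isodecoders recoverable.

**Genome-mapping denominator.** Class percentages use total genome-mapping
reads as denominator, and a read that matches a class reference counts as
genome-mapping even when its exact sequence is not a genomic substring (a
3′ tDR ending in the non-templated CCA is the canonical case). Without this
convention, CCA-terminal halves would silently fall out of the denominator.

**Implementation.** At the scale this package targets, matching is done by
exact hash lookup over all reference substrings in the read-length range;
1-mismatch queries enumerate the read's substitution neighbourhood (at most
3 × 40 variants) against the same exact index. A property test checks the
index against an independent sliding-window Hamming scan. This replaces
aligner-based matching deliberately: no indels, no soft clipping, no
quality weighting — the synthetic reads are substrings by construction, and
the classification logic, not the string matching, is what the package is
about.

## tDR metrics

**Half assignment.** The mature tRNA is split at the central anticodon
position (`anticodon_start + 1`). A read is labelled 5′ or 3′ by which side
holds the strict majority of its aligned positions; the split position
itself counts to neither side, and an exact tie goes to 5′. The convention
had to be chosen (start-position and midpoint rules are alternatives); the
majority rule is insensitive to a few nucleotides of terminal trimming, and
for reads anchored at either mature end — the only reads the generator
produces, and the dominant species in real libraries — all reasonable rules
agree, so the choice does not move the packaged fixtures' numbers.

**Size split.** "Long" tDRs (tRNA-halves) are ≥ 31 nt; reads of exactly
30 nt count as short, matching the "<30 nt fragment" notion of short tDRs.
Both buckets are reported per isodecoder and per isoacceptor, as rpm of
tRNA-mapping reads.

**Coverage.** Per-isoacceptor depth sums member isodecoders positionally.
Members of equal length add directly; lengths differing by ≤ 2 nt are
right-aligned at the CCA end (the acceptor end is the stable landmark when
body lengths differ slightly); larger differences fall back to left
alignment on the longest member's axis. The convention is configurable.

## Normalization

rpm values support three denominators: total genome-mapping reads,
genome-mapping minus rRNA-mapping reads, and a single class total. The
middle option exists because rRNA degradation products can differ
dramatically between conditions; a sample-wide denominator inflated by rRNA
fragments compresses every other class's apparent change, while removing
the rRNA component restores the dynamic range. The package enforces the
arithmetic consequence — excluding rRNA from the denominator can only raise
non-rRNA rpm values — as a property test.

## The synthetic library generator

`simulateSmallRnaReads()` draws each read's class from the profile's
fractions, then:

- **tDR**: an isoacceptor from the profile's weights, an isodecoder
  uniformly within the family, a side (5′ with probability
  `five_prime_fraction`), and a length from a two-mode mixture — a "half"
  mode (Normal, default mean 34 nt, sd 1.5, rounded) and a "trimmed" mode
  (mean 24, sd 3) mixed by `long_mode_weight` — clipped to 18–40 nt.
  5′ reads start exactly at mature position 1 and 3′ reads end exactly at
  the CCA terminus; internal fragments are deliberately not generated.
- **rRNA fragment**: a uniform-start substring of an rRNA record with
  lengths from a Normal(22, 4) clipped to 18–40 — a small-skewed,
  first-nucleotide-neutral degradation background.
- **miRNA / piRNA**: full-length reference records.
- **endo-siRNA**: an antisense substring of a random annotated gene, 22 or
  26 nt by the profile's weights, with the start position rejection-sampled
  so that a `g_fraction` share of reads begins with G.
- **mRNA fragment**: a sense gene substring, Normal(24, 4) lengths.
- **unassigned**: a random sequence, regenerated until absent from every
  reference and both genome strands.

Every read records its true class, source record and (for tDRs) 5′/3′ side,
so classification and the downstream metrics can be scored against truth.

**What the packaged profiles encode.** The five library profiles pin the
two parameters the pipeline is designed to measure — the tDR share of
genome-mapping reads and the 5′ half fraction — at the conditions they
emulate: wild-type sperm 13.8% / 62%, wild-type whole males 3.3% / 56%,
RNase T2 deletion-mutant males 8.6% / 86%, heterozygous males 3.5% / 62.3%,
heterozygous females 2.2% with the half mode dominating
(`long_mode_weight` 0.8). The packaged profiles set the unassigned fraction
to zero so the seven class fractions are fractions of genome-mapping reads
directly. The remaining free parameters — the class make-up of the non-tDR
remainder, length means and SDs, the 22:26 ratio (0.8:0.2) and 5′-G bias
(0.8) — are fixture choices recorded in the YAML files under
`inst/extdata/profiles/`; they are plausible for male/sperm libraries
(endo-siRNAs dominant, miRNAs at roughly half the sperm tDR share, an
rRNA background that rises in the mutant profiles) but are not measured
quantities.

**What the generator does not emulate.** Sequencing errors, adapter
ligation bias, RNA-modification-dependent cloning bias, internal (i-tDR)
fragments, and isodecoder-specific expression differences. Passing recovery
tests therefore demonstrates that the measurement chain is unbiased and
correctly calibrated on clean composition mixtures — not that any
laboratory protocol is bias-free.

## The embryo expression model

`simulateEmbryoCounts()` draws gene counts from a negative binomial with
per-gene baseline means (log-normal across four orders of magnitude, 6000
genes) and dispersion φ (Var = μ + φμ²); planted genes have their
treatment-condition mean multiplied by 2^log2FC. The real data the model
emulates are RSEM TPM estimates, so the NB-on-counts model is an emulation
of the statistical shape (overdispersed counts, length-normalized
downstream), not a claim about the real data's error structure.

Differential expression mirrors the thresholding convention: log₂ fold
change of condition-mean TPM (pseudocount 1), a two-tailed unpaired Welch
t-test, and flags at |log₂FC| > 1 and P ≤ 0.01 on raw p-values. Decisions
the convention leaves open, resolved here and configurable: the t-test runs
on log₂(TPM+1) rather than raw TPM (variance stabilization; the pseudocount
avoids log 0); no multiple-testing correction by default (the threshold is
on raw P), with Benjamini–Hochberg available; degenerate zero-variance
identical inputs get p = 1. Group shifts use a two-sample
Kolmogorov–Smirnov test of the group's log₂FC distribution against all
remaining genes — the test is this package's choice of statistic behind a
cumulative-distribution comparison.

The packaged fixtures plant 2 down + 36 up genes at the 2-cell stage
(ife-2 at log2(2.5), the others at +1.3/−2) and 106 down + 16 up at the
8-cell stage (33 histone and 20 fbxb genes among the downs, at −2.5).
Dispersion is 0.01 for the two-cell fixture — it is specified as a
low-dispersion, high-power comparison, and at n = 30 vs 25 this keeps the
measured ife-2 fold change within a few percent of the planted 2.5 — and
0.05 elsewhere. Planted genes get baseline means of 50–300 counts so
detection power is ≈ 1; filler up-effects are kept at +1.3 so the planted
genes' TPM denominators shift by only ~2%. The `null` profile (no planted
effects, means floored at 5 counts so the t approximation is in its
operating range) is used to verify type-I calibration: the P ≤ 0.01 rate is
≈ 1% and the fold-change gate keeps the flag rate near zero.

## Survival statistics

Kaplan–Meier estimates use the product-limit estimator with Greenwood
variance and log-log 95% intervals (undefined where S(t) = 0), via the
survival package; the log-rank test is the standard 1-df statistic with
hypergeometric variance and no extra ties correction. Starvation assays
scored as plate-level daily counts are converted to pseudo-individual
records — each newly observed death becomes an event at its day, worms
alive at a plate's last scored day are censored there — a reconstruction
convention, stated because plate aggregates and per-worm records are not
distinguishable after the fact. Heat-shock survival is compared with a
Welch t-test on per-plate survival proportions (p = 1 by convention when
all plate proportions are identical).

## Numerical and reproducibility choices

- All coordinates are 1-based inclusive; anticodon coordinates refer to the
  triplet on the mature sense sequence, with the isoacceptor name carrying
  the anticodon as written 5′→3′.
- Mature tRNA records without a terminal CCA get it appended at load time
  (with the length updated); every other invariant violation is an error,
  never a silent fix. 3′ halves end in CCA, so references without it would
  make 3′ tDRs unmappable.
- Each simulation call takes a single integer seed and restores the
  caller's RNG state afterwards; identical seeds reproduce libraries and
  count tables byte for byte, and `runPipeline()` stamps every output with
  the seed and a configuration fingerprint.
- The bundled toy reference (two contigs, 18 genes, 12 tRNAs across 9
  isoacceptor families, 2 rRNAs, 20 miRNAs, 20 piRNAs) is random sequence
  under a fixed seed: with ≥ 18 nt reads, cross-class sequence collisions
  have probability ≈ 4⁻¹⁸ per pair, so synthetic-read classification is
  effectively exact. Problem sizes in the tests — 200,000-read libraries
  for profile recovery, 10⁵ reads for distributional goodness-of-fit,
  1,000 reads for brute-force oracle equivalence — were chosen so binomial
  tolerances are tight while a full test run stays in the minutes range.

## Known limitations

Substitution-only matching (≤ 1 mismatch) with no indels; no splicing
logic (mature tRNAs must be supplied spliced); no UMI or quality handling;
the gene model is flat intervals, so overlapping genes resolve by the
antisense-wins rule rather than transcript structure; group membership for
hsp/rpl/rps/fbxb genes is by name prefix, faithful to the naming-based
definition it mirrors but blind to aliases. The generator's independence
assumptions (reads i.i.d. given the profile, genes independent given their
means) make recovery tests well-powered but slightly optimistic relative to
correlated real data.
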