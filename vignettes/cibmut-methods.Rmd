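---
title: "cibmut: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cibmut: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cibmut)
```

# The analysis

`cibmut` implements the downstream half of a heavy-ion mutagenesis
resequencing study: it starts from per-line VCFs (mutant M6 lines and their
non-irradiated wild-type parents, called against one reference) and ends at
mutation spectra, genomic-context and coding-effect tables, hotspot calls
and back-projected M1 mutation rates. Read alignment and variant calling
are out of scope; the package mirrors the standard GATK hard-filter
expressions as record filters so that its inputs can be raw per-line calls.

## Induced-set derivation

Induced mutations are defined as mutant records whose exact
(chrom, pos, ref, alt) key is absent from the same-background wild-type
call set. Exact-allele keying (rather than position-only keying) is the
stricter, deterministic choice; a shared position with a different allele
counts as induced. Hard filters remove records with `QD < 2.0`,
`FS > 60.0`, `MQ < 40.0` or `GQ < 20`; a missing annotation passes its
filter, following the GATK convention that filters fire only on an explicit
threshold breach. Equal-length multi-base pairs (MNVs) fall outside the
two-class SBS/InDel scheme and are excluded with a logged count, as are
InDels longer than 50 bp. The original studies additionally discard calls
showing segregation distortion or read-level error patterns; that step
needs per-read data and is deliberately not re-implemented — the hard
filters approximate it, and the limitation is inherited by every count
downstream.

## Spectrum

Transitions are the within-class substitutions (A<->G, C<->T). The
directional 12-type spectrum is primary — published panels report G>A
separately from C>T — with the strand-collapsed 6-type view available via
`substitution_type(..., collapse = TRUE)`. Ti/Tv ratios are computed from
summed counts when ponds aggregate lines (never averaged over ratios),
rounded to 2 decimals internally and 1 decimal in reports. InDel
histograms use exact lengths 1..50.

## Genomic context and coding effects

Each mutation gets exactly one context category with precedence
exonic(CDS) > UTR5 > UTR3 > intron > upstream > downstream > intergenic.
Upstream/downstream windows default to 1 kb on the transcript's strand —
the value is nowhere standardized, so the ANNOVAR convention used by the
toolchain these studies run is adopted. Coding SBS effects rebuild the
affected codon on the coding strand (reverse-complementing minus-strand
transcripts) and translate with the standard nuclear code: same residue =
synonymous, new stop = nonsense, otherwise nonsynonymous. Stop-loss has no
class of its own in the four-way scheme and maps to nonsynonymous. Coding
InDels are frameshift when the number of *coding* bases inserted or
removed is not a multiple of 3 — an InDel spanning a CDS boundary is
classified by its CDS overlap, since only coding-length change moves the
frame. When several transcripts overlap a mutation, the highest-impact
call wins (frameshift > nonsense > nonsynonymous > inframe_indel >
synonymous), ties broken by lexicographic transcript id for determinism.

## Hotspot scan

Mutations are binned into 0-based half-open windows
(bin = floor((pos−1)/size)); 1 Mb and 100 kb are the conventional scales.
A window is high-frequency (HF) when its per-bp frequency is at least
`hf_fold` times the chromosome-mean frequency (total/chromosome length);
adjacent flagged windows merge, and the merged region reports its fold and
its share of the pond's mutations. The default `hf_fold = 20` is the
classical hotspot bound from the mutation-hotspot literature; observed
enrichments in CIB panels reach ~50–100×. The chromosome mean deliberately
includes hotspot windows (matching how published per-chromosome means are
quoted); `robust_mean = TRUE` re-flags against a mean that excludes
flagged windows. A terminal window shorter than 10% of the window size is
never flagged, because its denominator would explode. Colocalization of
SBS and InDel HF regions is made checkable by reporting the Jaccard index
of flagged-window sets plus the hypergeometric upper-tail probability of
the observed overlap under independent placement.

## Back-projection and rates

Under single-seed-descent selfing without selection, a mutation
heterozygous in M1 is homozygous mutant in Mn with probability
p(n) = (1 − 2^−(n−1))/2: the heterozygote halves each generation, and half
of what leaves the heterozygous state fixes. Detected Mn counts (treated
as homozygous, matching the "pure" phrasing of published tables) are
back-projected as N1 = round(Nn / p). Two modes exist because published M6
tables double the M6 count exactly — the asymptotic p = 1/2 — while the
Mendelian M6 value is p(6) = 31/64 (factor 64/31 ≈ 2.065). The printed
equation in the source literature is typographically corrupted, so the
table-implied doubling is the default (`mode = "table"`) and the exact
form is the documented alternative; a heterozygote-inclusive retention
(p + 2^−(n−1), `mode = "with_het"`) is offered but off by default.
Per-pond rates divide the summed N1 by lines × genome length; the
denominator is an explicit parameter (the bundled constant
`RICE_GENOME_LENGTH = 373,245,519` bp, the IRGSP-1.0 span, reproduces the
published 11.3 × 10⁻⁵ for a 42,202-mutation line) because the original
denominators are not printed and per-pond values imply slightly different
spans. Trait screening uses |mutant − mean(wt)| / sd(wt) ≥ 3 with the
sample (n−1) standard deviation and an inclusive cutoff.

# The synthetic-data generator

The generator states a world and stays there; its defaults are the
conditions the analysis assumes, not tuning knobs:

* **Spectrum**: Ti fraction 0.565 of SBSs (Ti/Tv ≈ 1.3, matching pond
  ratios of 1.2–1.4), G>A + C>T carrying 2/3 of transitions, uniform
  transversions; InDel fraction 0.118 of mutations (the ~88% SBS share);
  InDel lengths truncated-geometric on 1..50 with p = 1 − √0.35 so that
  1–2 bp events are ~65% of InDels; insertion/deletion balance 0.5.
* **Genome**: uniform ACGT background (configurable GC); the literature
  gives no composition parameters, and no attempt is made to mimic a real
  rice assembly. Genes are packed without overlap, each with 1–3 exons,
  UTRs, and a CDS of 50–140 codons that starts ATG, ends at a stop and
  contains no internal stop. The intergenic share of planted mutations is
  therefore *emergent* from gene density — tests target planted
  parameters, never published location percentages, which depend on the
  real annotation.
* **Hotspots**: planted as per-bp sampling-weight multipliers over BED-style
  regions, so a fold-50 region of 10 kb on a 1 Mb chromosome attracts
  ≈ 33.6% of mutations.
* **Plumbing**: one RNG stream per fixture, seed recorded in
  `metadata.json`; wild-type VCFs carry 500 shared background variants by
  default (so subtraction is genuinely exercised); induced records get
  passing QD=20/FS=1/MQ=60/GQ=99 annotations, with optional decoy records
  carrying failing values; 80% of induced genotypes are emitted homozygous
  (an M6-like panel).

What a green test does *not* establish: the generator has no sequencing
error, no read-level evidence, no segregation distortion, no structural
variants, and mutation positions are independent draws (hotspots are rate
multipliers, not fragile-site mechanics). Conclusions about the analysis
code's correctness transfer to real data; conclusions about biological
effect sizes do not.

The truth table carries an oracle effect for every planted coding
mutation, computed by full-CDS retranslation — an independent route from
the analysis module's single-codon path, which the test suite compares
against it (and against a third re-implementation in the test helpers).

# Numerical and degenerate-input choices

* Empty mutation sets summarize to all-zero summaries with an undefined
  (NA) Ti/Tv ratio; Ti/Tv is only reported when Tv > 0.
* An all-zero chromosome yields no HF regions (mean 0 is guarded), and
  `colocalization` of two empty sets reports NA Jaccard with tail
  probability 1.
* `back_project` rounds half away from zero only through base R's
  `round`; all published comparisons are integers doubled, so rounding
  mode is immaterial in table mode.
* VCF coordinates are 1-based throughout `variant_io`; window and HF
  arithmetic is 0-based half-open; every interface states its convention.
* Determinism: analysis stages contain no RNG; `set.seed` is confined to
  the generator, keyed by the fixture seed.

# Known limitations

* Errors from the VCF parser are wrapped with the file path but not a line
  number (the underlying reader does not expose one).
* HF-region boundaries are merged flagged windows; published hotspot
  bounds chosen by eye (e.g. "9–17 Mb") need not coincide exactly, and no
  claim of boundary-exact reproduction is made.
* The per-read "segregation distortion or sequencing error" screen of the
  original pipelines is approximated by hard filters only (see above).
* Table mode knowingly uses the asymptotic retention 1/2; for n = 6 this
  understates N1 by ~3.2% relative to the Mendelian value.
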