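---
title: "Methods: piRNA population statistics and the biogenesis simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA population statistics and the biogenesis simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A piRNA library is a population of ~24–32 nt RNAs bound by one
PIWI-clade protein. Which protein a population came from can be read
from four statistics: the read-length distribution, the fraction of
reads with a 5′ uridine (1U bias) or an adenine at position 10 (10A
bias), the sense/antisense balance of reads mapped to transposon
consensus sequences, and the distribution of 5′-5′ distances between
opposite-strand reads, whose enrichment at exactly 10 nt is the
Ping-pong signature of slicer-coupled secondary biogenesis. `pirnakit`
computes these statistics from FASTA/FASTQ input and provides a
generative simulator whose ground truth validates every stage.

## Conventions

Sequences are stored internally as DNA (U→T, uppercase); bias labels
are reported in RNA vocabulary ("U"). Reads containing N are dropped at
import with a warning; other foreign characters reject the record and
the run continues. Collapsed-FASTA headers carry counts as `_xN`
(bare `_N` also accepted on input; `xN` wins when both match).

Mapping coordinates are 0-based half-open against the consensus as
written in the input FASTA ("sense"). A sense hit's 5′ nucleotide is at
`start`; an antisense hit's is at `end − 1`. Matching is exact, on both
strands (the antisense strand is searched via the read's reverse
complement); mismatch-tolerant alignment is out of scope by design — the
simulator-driven validation never needs it and exactness keeps the
brute-force oracle trivial. Multimapping sequences are fractionally
weighted (count divided by the number of hits), so per-transposon
weights are count-conserving: total mapped weight plus unmapped count
equals the library total.

The index is a k-mer seed table (default `k = 12`): each query is
located by its first k-mer and verified by full-length string
comparison; reads shorter than k fall back to an all-substring scan.
With 4^12 possible seeds against ~10^3–10^5 consensus positions, seed
collisions are rare and lookups are effectively O(hits).

## Statistics

*Positional biases* are computed over all reads long enough to have the
position (so reads shorter than 10 nt never enter the 10A statistic),
weighted by abundance counts by default; `weighted = FALSE` gives the
unique-sequence variant. Published percentages do not always state
which convention they use, so both are exposed and the default is
declared: abundance-weighted. The four base fractions always sum to 1
over the eligible weight.

*Strand bias* per transposon is the signed sense fraction
`2f − 1 ∈ [−1, +1]`; heat-map renderings can be rebuilt from the TSV,
which carries both `f` and the score. Transposons with no mapped weight
are flagged `NA`, not scored. Modal read length breaks ties toward the
smaller length, deterministically.

*Overlap histogram*: for a sense hit with 5′ at `p` and an antisense
hit with 5′ at `q` on the same transposon, `d = q − p + 1`, so 5′ ends
9 nt apart score `d = 10` and coinciding 5′ ends score `d = 1`;
configurations with `d < dmin` (including all 3′-sided ones) are
ignored. Every opposite-strand pair across the two libraries
contributes the product of its hit weights; the histogram is therefore
exactly symmetric in its arguments. The default range 1–30 nt covers
piRNA lengths.

*Ping-pong z-score*: the target bin (default 10) against the mean and
sample (n−1) SD of all other bins in range. At least two background
bins are required (the minimum a sample SD needs). A perfectly flat
histogram scores 0; a spike over an all-zero background has undefined
SD and is flagged `NA` rather than infinite.

*Fivefold sorting* compares reads-per-million by default — the
immunoprecipitation libraries being compared differ in depth — with raw
counts behind a flag. Ties at exactly fold× go to the enriched side
(`≥`, stated so the boundary is testable). Absence means 0 rpm with no
pseudocount, so presence in only one library always yields that side's
exclusive class. Matching is exact full-sequence identity.

## The simulator

The generator encodes the secondary-biogenesis geometry: primary reads
are cut from the antisense strand of a consensus; secondary reads are
slicer products on the sense strand whose 5′ end lies exactly
`overlap` (default 10) nt into a sampled primary partner, so the
partner's 5′ U becomes the product's position-10 A by complementarity.
Defaults are the field's stated population features: `p_1U = 0.8`,
antisense primary orientation, 10-nt overlap, and unimodal 24–32 nt
triangular length laws with mode 28 nt (primary) and 27 nt (secondary).
Secondary 3′ ends are drawn independently of the partner — only the 5′
ends are coupled. A single Ping-pong round is modelled; iterated
amplification has no stated rates and is out of scope.

`p_1U` is defined as the **marginal** probability that a primary read
starts with U — the quantity reported as "1U bias" — not the weight of
a U-conditioned mixture component. Internally, for each read length the
generator solves the mixture weight `m = (p_1U − bg)/(1 − bg)` against
the background U frequency `bg` at valid start positions (clamped to
[0, 1]), then draws the 5′ coordinate from the U-conditioned pool with
probability `m` and uniformly otherwise. This makes the realised
u1_bias equal `p_1U` (up to binomial noise) whenever `p_1U ≥ bg`,
saturate at the background for smaller values (at `p_1U = 0` the draw
is fully unconditional, giving ~0.25 on a balanced consensus), and
reach exactly 1 at `p_1U = 1`. The design was chosen over the simpler
"probability-of-conditioning" semantics because it makes the generator
parameter directly comparable with measured 1U percentages and keeps
the analytic expectation closed-form for tests.

Mixture ("chimera-like") libraries resample parent libraries,
abundance-weighted, at given proportions, and with probability
`novel_fraction` emit a fresh random 24–32-mer instead; such novel
sequences are absent from the parents with overwhelming probability,
so the recovered "only in query" fraction estimates `novel_fraction`.
Ground truth records every read's origin, true coordinates and partner
link; truth tables round-trip as TSV.

All randomness flows through R's RNG; each generator accepts a `seed`
and the pipeline wrapper (`cmd_simulate`) derives per-stage seeds by
fixed small offsets from one base seed, so runs are byte-reproducible.

## What the tests do and do not show

Validation runs at desk scale, chosen to finish in seconds per suite: a
5-kb random consensus with 2,000–10,000 reads for signature recovery,
10,000-read libraries for the bias and sorting statistics, and 500
randomized cases for the mapping-vs-brute-force oracle. At these
densities an important caveat appears: the all-pairs overlap histogram
of 2,000 + 2,000 reads on 5 kb contains substantial coincidental weight
in 1–30 nt bins (any two opposite-strand reads whose 5′ ends happen to
fall near each other count), so the d = 10 bin dominates — modal bin
10, z ≈ 50 — but holds only ~15% of in-range weight. Near-total (>99%)
concentration at d = 10 is a property of sparse regimes only (verified
with 20 + 20 reads on 200 kb); real deep libraries behave like the
dense regime, which is why peak position and z-score, not the absolute
fraction, are the reported signature.

The simulator emulates population-level statistics, not sequence-level
biology: i.i.d. consensus composition (no repeats, no copy families),
no nuclease sequence specificity, no 3′ trimming or methylation, no
mismatch in mapping, and a single consensus per run by default. Passing
tests therefore demonstrate that the statistics recover the generative
parameters under the stated geometry — not that any particular
biological library will show them.

## Degenerate inputs and tie-breaks

Empty libraries: statistics error with a named message; an empty mapped
library yields an empty overlap histogram with a warning. Consensus
entries shorter than k contribute no seeds (warning). A consensus with
no U-start positions makes a `p_1U > bg` primary simulation impossible
and errors; impossible overlap geometry (no primary 5′ end at
coordinate ≥ overlap − 1) errors after bounded resampling. Modal-length
and fold-threshold ties resolve as stated above; hit order is
deterministic (transposon, start, strand), so identical inputs and
seeds give byte-identical outputs.
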