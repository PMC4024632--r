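# pirnakit

Population statistics for small-RNA (piRNA) libraries, and a mechanistic
simulator of piRNA biogenesis to validate them against.

PIWI-clade Argonaute proteins are distinguished not by the sequences of
individual bound RNAs but by statistical signatures of their whole piRNA
population: primary-type proteins (e.g. silkworm Siwi) carry ~24–32 nt
RNAs with a strong 5′-uridine preference (**1U bias**, ~80%) that map
predominantly **antisense** to transposon consensus sequences, while
secondary-type proteins (e.g. Ago3) carry **sense**-oriented RNAs whose
5′ ends overlap their partners' 5′ ends by exactly **10 nt** — the
Ping-pong signature — which by base-pair complementarity converts the
partners' 1U into an **A at position 10** (10A bias). `pirnakit`
implements the statistics used to read these signatures off
deep-sequencing libraries, and a generative simulator that produces such
libraries with full ground truth.

For a library of collapsed reads (unique sequence *s* with count *c(s)*):

- **1U / 10A bias** — abundance-weighted fraction of reads with U at
  position 1 (A at position 10), over reads long enough to have that
  position.
- **Strand bias** — per transposon, hits are weighted *c(s)/n(s)* for a
  sequence with *n(s)* exact hits; the score is the signed sense
  fraction 2f − 1 ∈ [−1, +1].
- **Ping-pong signature** — for every opposite-strand hit pair on a
  transposon with sense 5′ at *p* and antisense 5′ at *q*, the overlap
  is *d = q − p + 1*; the histogram of *d* over 1–30 nt is scored by
  *z = (count(10) − mean(background)) / sd(background)*.
- **Fivefold sorting** — a sequence is assigned to library A when
  rpm_A ≥ 5 · rpm_B (and vice versa), otherwise shared; a query
  ("chimera") library is partitioned into reads found in either parent
  versus reads only in the query.

Coordinates are 0-based half-open; a sense hit's 5′ nucleotide is at
`start`, an antisense hit's at `end − 1`. Mapping is exact substring
matching on both strands.

## Worked example

```r
library(pirnakit)

cons <- random_consensus(5000, gc_content = 0.5, seed = 1, name = "tp")
prim <- simulate_primary(cons, 2000, p_1U = 0.8, seed = 2)     # antisense, 1U-biased
seco <- simulate_secondary(prim$truth, cons, 2000, seed = 3)   # sense, 10-nt overlap

idx <- build_index(cons)
mp  <- map_library(idx, prim$library)
ms  <- map_library(idx, seco$library)

u1_bias(prim$library)
#> [1] 0.7935
a10_bias(seco$library)
#> [1] 0.8015
strand_bias_table(mp)$score   # -1 = all antisense
#> [1] -1
h <- overlap_histogram(mp, ms, dmin = 1, dmax = 30)
print(h)
#> overlap_histogram [1, 30] nt, total pair weight 26800.0
#>   peak at d = 10 (14.7% of weight)
pingpong_zscore(h, target_bin = 10)
#> pingpong_score: bin 10 nt, z = 57.00 (background 788.655 +/- 55.095)
```

The primary library's 1U bias sits at its target 0.8; the secondary
library's 10A bias emerges at the same value without being a parameter;
the overlap histogram peaks at exactly 10 nt, tens of background
standard deviations above the other bins. (At this read density the d = 10 bin
dominates but does not exhaust the histogram: with 2,000 reads per
strand on a 5-kb consensus many opposite-strand pairs fall within 30 nt
of each other by coincidence, exactly as in real libraries.)

Mixture sorting:

```r
mix <- simulate_mixture(list(prim$library, seco$library), c(0.3, 0.7),
                        2000, novel_fraction = 0.37, seed = 4)
partition_chimera(mix$library, prim$library, seco$library, fold = 5)
#> chimera_partition: 61.8% in parents (A_only 18.1%, B_only 43.6%, shared 0.0%), 38.2% only in chimera
```

A command-line wrapper over the same stages lives at
`inst/cli/pirnakit.R` (subcommands `simulate | map | stats | pingpong |
classify`), writing BED6/TSV/YAML outputs.

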