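---
title: "Methods: comparative TSS calling from 5'-enriched coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative TSS calling from 5'-enriched coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsscall)
```

## The signal model

Protocols that enrich primary transcripts (TEX treatment in dRNA-seq,
capping-based selection in Cappable-seq) produce, at a genuine
transcription start, a sharp rise in the enriched library's per-base
coverage that the non-enriched control library lacks. `tsscall` operates
entirely on this profile-level signature; it never sees reads. The working
assumptions are:

* coverage is a dense, non-negative per-base signal in a single shared
  coordinate system across all conditions (multi-strain analyses through a
  whole-genome-alignment coordinate map are out of scope);
* on the reverse strand transcription runs toward decreasing coordinates,
  so the "previous" position of `i` is `i + 1` there — a step is always a
  rise in the direction of transcription, while all reported coordinates
  stay genomic;
* the enriched and control library of one replicate/strand are a matched
  pair; input profiles are already depth-normalized between protocols
  (e.g. per million aligned reads), and the package only performs the
  *inter-library* normalization described next.

## Inter-library normalization

Stage one equalizes overall scale: for each pair the 90th percentile
`Q_PL` of the enriched track is computed **over non-zero positions only**,
and both tracks of the pair are multiplied by `Q_min / Q_PL` with `Q_min`
the smallest percentile across pairs. Percentiles are computed over
non-zero positions because prokaryotic coverage is sparse — over all
positions the 90th percentile is frequently zero, which would make the
scheme degenerate. Percentiles use linear interpolation between order
statistics (`quantile()` type 7). An all-zero enriched library is an
error, reported with the offending pair's identity.

Stage two equalizes apparent enrichment: per pair, the median of
`enriched(i)/control(i)` over positions where **both** values are strictly
positive (the ratio is undefined at zero) gives `median_EF`; every control
track is multiplied by `median_EF / EF_max`. Scaling the *controls* —
shrinking the control of weakly-enriched pairs rather than inflating it —
was a genuinely open design choice; it was adopted because it leaves the
enriched tracks, on which detection runs, untouched by the second stage,
and it makes the post-condition testable: after the stage, every pair's
median per-position enrichment factor equals `EF_max` (verified in the
suite to 1e-9 relative tolerance).

A consequence worth knowing: the normalized scale is pinned to `Q_min`,
which moves if any library is rescaled. Multiplying one pair's input by a
constant therefore leaves everything invariant *in `Q_min`-relative
units* — and hence leaves TSS calls unchanged, because the step-height
threshold is itself relative to `Q_min` (below) — but not the raw
normalized numbers.

## Detection parameters

| parameter | default | meaning |
|---|---|---|
| `step_height` (T_h) | 0.3 | minimum coverage rise, in units of `Q_min` |
| `step_factor` (T_f) | 2.0 | minimum fold rise (unitless, ≥ 1) |
| `enrichment_factor` (T_EF) | 2.0 | minimum enriched/control ratio (unitless) |
| `step_height_reduction` (ρ_h) | 0.2 | subtracted from T_h on re-evaluation |
| `step_factor_reduction` (ρ_f) | 0.5 | subtracted from T_f on re-evaluation |
| `window` (W) | 3 bp | close-candidate collapse window |
| `cross_replicate_shift` (Δr) | 1 bp | replicate-merge distance |
| `cross_condition_shift` | 1 bp | condition-merge distance |
| `min_replicates` (R_min) | 1 | detecting replicates required |
| `utr_length` | 300 bp | primary/secondary search range |
| `antisense_distance` | 150 bp | antisense association range |

The five shipped presets (`tss_presets()`) move T_h from 0.1 (*very
sensitive*) to 1.0 (*very specific*), with T_f 1.5–2.0 and T_EF 1.5–3.0;
they live in a plain TSV (`inst/extdata/presets.tsv`) so the values are
inspectable and adjustable without touching code. Expressing T_h relative
to `Q_min` makes one nominal threshold meaningful across experiments of
different depth: `detect_candidates()` receives the scale explicitly
(`height_scale = Q_min`, or 1 when normalization is disabled, in which
case the threshold is absolute coverage).

Numerical conventions at the degenerate points: a step out of zero
coverage has factor `+Inf` (passes any finite T_f — a rise from nothing is
maximal evidence); two zeros give factor 1; the candidate position itself
must carry positive coverage. Window reduction groups candidates by
*chaining* (consecutive neighbours ≤ W apart form one run, whatever the
run's total span); each run keeps its largest step height
(`reduction_mode = "strongest"`, ties to the smallest coordinate) or its
5'-most member (`"first"`, strand-aware). Chaining rather than
absolute-span grouping was chosen because it is order-independent and
idempotent — both properties are asserted in the suite.

## Consolidation

Within a condition, candidates of different replicates within Δr bp are
one TSS. Replicates lacking a detection there are re-tested in the ±Δr
neighbourhood of the cluster's strongest position against the *reduced*
thresholds `max(T_h − ρ_h, 0)` and `max(T_f − ρ_f, 1)`; subtraction (not
scaling) is used for the reduction, with the floors keeping the reduced
thresholds meaningful. The best-scoring qualifying position counts as that
replicate's detection. A TSS needs `min_replicates` detecting replicates
to survive. The enrichment factor is then evaluated at the TSS position in
every replicate (`Inf` when the control is zero there; undefined and
excluded when both libraries are zero), and the **maximum** across
replicates must reach T_EF — one clean replicate suffices as evidence of a
primary 5' end.

Enriched TSS of different conditions within the cross-condition shift are
clustered by single linkage; the representative position is the
contributing position with the largest step height (ties to the smallest
coordinate) — the merged coordinate had to be defined somewhere, and the
strongest signal is the least arbitrary anchor. Conditions that detected
but did not enrich a TSS in the window are recorded as
`detected, not enriched`; absent conditions get explicit
`detected = FALSE` records, so the MasterTable always carries one row per
condition per classification.

Two useful monotonicity facts follow from these definitions and are
enforced as tests: raising any of T_h, T_f, T_EF or R_min never increases
the number of enriched TSS.

## Classification

Classes are assigned at the cluster-representative position, one
classification per qualifying (TSS, gene) association, so a TSS can be,
e.g., primary for one gene and antisense for the gene opposite. Boundary
conventions that the literature leaves open were fixed as follows and are
worth stating precisely:

* the upstream (primary/secondary) window counts distances 1..300 from the
  translation start, *excluding* the start base itself;
* a TSS exactly at the translation start is therefore **internal**, not
  primary;
* "within 150 nt" for antisense is implemented inclusively
  (`≤ antisense_distance` from either gene boundary);
* among the upstream TSS of one gene, the primary is the one with the
  largest step height over its enriched conditions, ties broken toward
  the shortest 5' UTR; a configuration switch (`primary_rule = "first"`)
  selects the 5'-most signal instead;
* classes are shared by all condition rows of a TSS. With merge shifts of
  1–3 bp, per-condition positions virtually never straddle a class
  boundary; assigning classes per condition would multiply the bookkeeping
  for no practical gain.

## Differential testing

The enriched coverage in a ±50 bp window around each TSS (flipped on the
reverse strand so positive offsets are downstream), renormalized to sum 1,
is treated as an empirical distribution over offsets. For two conditions,
every replicate pair is compared with a two-sample Kolmogorov–Smirnov
test computed **directly on the weighted ECDFs** — deterministic, no
resampling of reads — with the asymptotic p-value at effective sample size
`n1·n2/(n1+n2)`, where each `n` is the window's rounded coverage mass
capped at 10,000 (the cap prevents absurd certainty from deep libraries;
the weighted statistic itself is verified in the suite against `ks.test()`
on expanded integer-mass samples). Per TSS the p-values are combined with
the Cauchy combination test (inputs clipped to `[1e-15, 1 − 1e-15]` before
the tangent), and the combined p-values are Bonferroni-corrected over the
number of tested TSS. The 50 bp half-window matches the upstream-sequence
convention used elsewhere in the package and is configurable. Degenerate
(all-zero) windows are excluded with a warning; a TSS with no valid
replicate pair is skipped and does not count toward the correction.

The whole construction is conservative by design (Bonferroni, capped
sample size); under a simulated null (500 TSS, 3 vs 3 replicates,
multinomial draws from one profile shape) the fraction of adjusted
p-values below 0.05 stays within the Monte-Carlo bound
`0.05 + 3·sqrt(0.05·0.95/500)`, as the suite asserts.

## The synthetic generator — what it does and does not show

`synthetic_spec()` / `generate_experiment()` build a complete experiment
from a declarative description: per planted TSS a sharp step of the
planted height followed by exponentially decaying gene-body coverage
(default decay 0.006/bp over 500 bp, i.e. the signal falls to ~5% across a
transcript — mimicking a full-read coverage profile), a control equal to
the enriched signal divided by the planted enrichment factor, per-replicate
scale factors (default 1, 1.5, 0.75) emulating depth differences, and
optional sparse uniform background noise (default off; 2% of positions,
amplitude ≤ the configured level). The default layout — four conditions ×
three replicates × two strands over a 20 kb replicon with 8 genes and 20
TSS spanning all five classes, including one primary/secondary pair and
treatment-only TSS — emulates the structure of a typical comparative
antibiotic-stress experiment. Everything is reproducible from a single
seed, to the byte.

What it is *not*: a read simulator. There is no mapping noise, no
position-dependent coverage bias, no processed-5'-end background, and the
control is an exact scaled copy of the enriched signal rather than an
independently sampled library. Perfect recovery on these fixtures
therefore demonstrates the correctness of the algorithmic chain
(normalization → detection → reconciliation → enrichment → clustering →
classification), not expected field performance on real libraries, where
threshold choice (the presets) does the heavy lifting.

Validation problem sizes, chosen to keep the whole suite around half a
minute while still exercising every code path: brute-force equivalence on
50 random instances (tracks ≤ 200 bp for consolidation; ≤ 50 genes,
≤ 200 TSS for classification), monotonicity on 10 seeded 2 × 2 datasets,
noise-robustness over 20 seeded runs, and the 500-TSS differential null.

## Known limitations

* One coordinate system: comparing strains through whole-genome-alignment
  mappings is not supported.
* Wiggle/bedGraph/GFF3 only; bigWig output for browsers is out of scope.
* The MasterTable column set is a documented superset of the columns such
  tables conventionally carry; it is not a byte-level clone of any other
  tool's output.
* The KS/Cauchy differential procedure treats coverage shape, not
  abundance: a TSS with identical profile shape but different absolute
  expression between conditions will not be flagged.
* First-base (5'-end-only) coverage profiles are sharper than the
  full-read profiles the defaults were chosen for; with such input, the
  more specific presets are the sensible starting point.
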