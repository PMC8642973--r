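---
title: "Ensemble consensus calling of gene fusions: model, filters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble consensus calling of gene fusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemble)
```

## The problem and the model

Gene fusions are common oncogenic drivers, particularly in pediatric
cancers, and RNA-Seq is the natural substrate for detecting them. No
single fusion-calling algorithm is simultaneously sensitive and precise:
sensitive callers emit hundreds to thousands of candidates per sample,
while conservative callers miss true drivers. `fusemble` implements the
downstream half of an ensemble strategy: it consumes the native output
files of up to seven callers (Arriba, CICERO, FusionMap, FusionCatcher,
JAFFA, MapSplice, STAR-Fusion) and reduces them to a short, prioritized
consensus list.

The consensus unit is the **unordered gene pair**. Two callers that
report the same two partners agree, even if they disagree about
breakpoints, donor/acceptor orientation, or report a reciprocal event.
For a pair $(g_1, g_2)$ let $C(g_1,g_2)$ be the number of distinct
callers reporting it; a caller reporting several isoforms of the same
pair counts once. Records are prioritized by $C$ (descending), then by
the maximum supporting read count over contributing calls, then by pair
key for reproducibility. When callers disagree on breakpoints, the
breakpoint pair of the call with the most supporting reads is promoted;
ties fall back to the breakpoint supported by most callers, then to the
lexicographically smallest coordinate tuple, so output is deterministic.

Before overlap, reported symbols are normalized to approved HGNC symbols
by alias matching. An alias resolving to several approved symbols is
disambiguated by the call's own breakpoint chromosome against each
candidate's cytogenetic band (chromosome + arm granularity); if that
fails the symbol passes through unchanged and is flagged — dropping it
would silently destroy sensitivity.

## Filters, rescue and scoring

A consensus record is kept when $C \ge$ `min_callers` (default 3) and it
survives three knowledge-based filters, all implemented with strict
inequalities exactly as the rules are stated:

* **read-through**: removed if both breakpoints are on the same
  chromosome and the same known strand, strictly fewer than 200,000
  bases apart. Neighbouring same-strand genes produce conjoined
  transcripts in normal tissue; this is the classic false positive. An
  unknown strand never triggers the filter (the same-strand condition
  cannot be asserted), and two overlapping genes at distance 0 with
  matching strands are filtered.
* **recurrent artifact**: removed if the pair's detection frequency in
  the cohort store is strictly greater than 10%. Frequency is per
  sample (isoforms collapse) and keyed on the pair alone. Exactly 10% is
  retained.
* **low evidence**: removed if no single caller supplies at least 4
  supporting reads. Where a dialect separates split reads from spanning
  pairs, a call's read count is their sum; otherwise the caller's one
  evidence count is used as-is.

A curated **known fusion list** counteracts over-filtering: a record
whose exact unordered pair is on the list is kept — overriding all three
filters and the consensus threshold — provided at least
`known_list_min_callers` (default 2) callers support it. Known-list
pairs seen by a single caller go to a supplementary **singleton
channel**, disjoint from the main output, so that a pathogenic fusion
supported by one read from one caller is reviewable rather than lost.
Rescue requires the exact pair; membership of an individual gene on the
list drives annotation only.

Each gene partner is annotated with the **Gene Partner Predicted
Pathogenicity Score**, derived from its frequency $f$ among list pairs.
With $f_{max}$ the largest such frequency, genes with $f \ge 3$ score

$$\mathrm{score}(f) = \min(10, \max(1, \mathrm{round}(10 f / f_{max})))$$

which is 10 at $f = f_{max}$, 1 at the $f = 3$ floor for large
$f_{max}$, and monotone in between. The literature's displayed formula
$10/(f_{max}-f)$ is undefined at $f = f_{max}$ and contradicts the
stated 10-to-1 range; it is available as `method = "reciprocal"` for
comparison but is not the default. This is a deliberate design choice:
the stated endpoints and monotonicity were taken as the contract, the
printed algebra as a typo.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_callers` | 3 | callers | 2-caller consensus admits correlated noise from the high-recall callers; 3 is the optimized operating point |
| `readthrough_max_distance` | 200000 | bases | separates neighbouring-gene transcripts from genuine intrachromosomal events (e.g. a 225 kb deletion is retained) |
| `max_cohort_frequency` | 0.10 | fraction of samples | recurrent benign/artifactual pairs sit well above this; true drivers rarely recur this often in a mixed cohort |
| `min_reads` | 4 | reads | one caller with ≥4 junction-supporting reads suffices |
| `known_list_min_callers` | 2 | callers | rescue floor; singletons go to their own channel |

Distance is measured between reconciled best breakpoints, not gene
boundaries — breakpoints are the only coordinates the pipeline
possesses.

## What the synthetic generator emulates — and what it does not

`fixture_spec()` / `generate_fixture()` produce per-caller files in each
native dialect with fully known provenance, emulating a reference-
standard experiment: by default 14 true fusions, all on the bundled
known list (the content of a commercial fusion RNA reference standard),
with per-fusion caller support drawn from a distribution skewed towards
full 7-caller consensus (weights follow the observed shares of 3-, 4-,
5-, 6- and 7-caller detections in a clinical cohort). Around them it
plants: same-strand neighbour pairs under 200 kb (read-through
material), cross-chromosome pairs pre-registered in a 22-sample cohort
store at 7/22 = 31.8% (recurrent artifacts), ≥3-caller decoys with every
read count below 4 (evidence-filter material), one single-caller
known-list fusion with one read (singleton material), and per-caller
unique false positives whose burden is shaped like the real callers'
relative noise (CICERO and JAFFA noisiest), scaled down roughly
tenfold so the default suite runs in seconds. One planted truth pair
(EML4–ALK by default) is also pre-registered at 31.8%, reproducing the
situation where a bona fide fusion sits at artificially high cohort
frequency and survives only by rescue.

Two true fusions are deliberately filter-prone: FGFR3–TACC3 (same
strand, under 200 kb — a real fusion that looks like a read-through)
and the recurrent EML4–ALK. Filtering without the known list therefore
recovers 12 of 14 (85.7% sensitivity at 100% precision) and the known
list restores 14 of 14 — the qualitative and quantitative shape of the
published ablation.

The truth pairs are the *first* `n` pairs of the known list in file
order rather than a seeded sample, so the stated world ("14 planted
known-list fusions") is identical across seeds; the seed governs caller
support, read counts, breakpoint positions, junction sequences and
noise. The generator does **not** model correlated errors between
callers (each false positive is unique to one caller), caller-specific
breakpoint biases, or sequencing-level effects — so a green end-to-end
test establishes that the consensus/filter/rescue logic is correct on
its stated inputs, not that real callers behave like the simulator. The
bundled gene annotation is likewise a synthetic stand-in with
approximate coordinates.

`dilution_series()` scales only the true fusions' read counts (floored,
per evidence class) and drops a call when its reads reach zero,
emulating serial dilution of the analyte into background RNA; artifact
rows keep full strength because their origin is not the diluted
material.

## Numerical and degenerate-input choices

* All threshold comparisons are strict, matching the rule statements
  ("fewer than", "greater than").
* Ties in breakpoint reconciliation and in prioritization are broken by
  the deterministic cascades above; outputs are byte-identical across
  runs and caller/row permutations.
* A caller file with a valid header and zero rows is a legitimate
  zero-fusion result, not an error. A file that fails to parse is
  skipped with a warning and the run continues on the remaining callers
  (one upstream tool failure never voids a sample).
* Chromosome names are normalized to a single namespace (no `chr`
  prefix, mitochondrial `MT`); 0-based dialects are converted to the
  internal 1-based fully-closed convention on parse.
* An empty cohort store yields frequency 0 for every pair; with zero
  identified fusions precision is reported as 0 with an explicit
  `precision_defined = FALSE` flag rather than NaN.
* Re-registering a sample in the store replaces its observations; by
  default the pipeline registers the ≥2-caller *unfiltered* consensus,
  because artifact filtering must be able to see artifacts.

## Known limitations

* Overlap is keyed on harmonized gene pairs only; annotation-free,
  coordinate-window overlap is out of scope, so two callers annotating
  the same breakpoint against different gene models will not merge
  unless the alias table reconciles the symbols.
* The bundled alias table and known list are small snapshots sufficient
  for the fixtures; production use should supply a full HGNC table and a
  curated list.
* Percentages are rounded to one decimal in benchmark output, matching
  the convention of the tables they mirror.
* Running the seven callers, and everything upstream of their output
  files, is explicitly out of scope.
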