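---
title: "Inversion-step analysis of polytene banding sequences: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inversion-step analysis of polytene banding sequences: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoband)
```

## The problem

Classical *Chironomus* karyosystematics reads each polytene chromosome arm
as a linear series of numbered bands (Keyl notation). Two layers of
rearrangement separate species:

* **within arms** — paracentric inversions reorder band segments; the
  minimal number of inversions converting one banding sequence into another
  ("inversion steps") is the divergence measure;
* **between chromosomes** — whole-arm translocations reshuffle the seven
  arms A–G into chromosomes, defining *cytocomplexes* (pseudothummi
  `AE CD BF G`, thummi `AB CD EF G`, parathummi `AC BF DE G`, and fused
  variants with haploid number 3).

Sequences shared across continents ("cosmopolitan basic" sequences, e.g.
the *C. piger* standard pigST, holA1, lonC1) are presumed older than the
cytocomplex split; sequences restricted to one region are endemic.
`karyoband` makes each of these notions computable and testable.

## The band model and its notation

An arm's *reference order* is its standard band list, sorted by
(major number, subband letters). A banding sequence is stored as a **signed
expansion**: a signed permutation of the reference ordinals, negative
entries marking bands inside inverted segments. Keyl text maps onto this
exactly, with one deliberate asymmetry:

* a descending token (`15-12`) is an inverted segment of ≥ 2 bands;
* a single-band token is always forward, because the inversion of one band
  with no lettered subbands is cytologically invisible.

The expansion is therefore the *physical* state and the text its **lossy
projection**: formatting prints a lone inverted band unsigned, and
`parse(format(s)) == s` holds exactly for every sequence born from text,
while `parse ∘ format` is an idempotent projection for arbitrary in-memory
states (e.g. simulation output). We chose to keep hidden orientations in
memory rather than normalise them away: normalising changes the physical
state and can inflate distances between a simulated ancestor and its
descendant, violating the invariant that `k` applied inversions can never
produce a distance above `k`.

A whole-arm flip (reading the photomap from the other end) is a convention,
not a mutation. `canonical_direction()` picks the representative whose
first band has the smaller ordinal, and `arm_distance()` additionally takes
the minimum over the relative flip of one input — a quotient metric over
the reading-direction action. The greedy first-band rule alone is not
enough: it can pick opposite representatives for two sequences one
inversion apart.

## Distance engine

Two comparable sequences are first cut at every breakpoint present in
either; the maximal common oriented blocks, not raw bands, become the
elements of a signed permutation (this keeps permutations short and makes
distances invariant to subband granularity). The minimal reversal count is
the classical breakpoint-graph formula on the permutation framed by virtual
end markers 0 and *n*+1:

\[ d = (n + 1) - c + h + f \]

with *c* the number of alternating cycles, *h* the hurdles (unoriented
components whose endpoints are circularly contiguous), and *f* the fortress
indicator (odd number of hurdles, all of them superhurdles). Scenarios are
reconstructed greedily: at each step the lexicographically smallest
interval whose reversal lowers the distance by one — deterministic by
construction, and a distance-reducing reversal always exists below the
optimum.

Correctness is not taken on faith. A compiled breadth-first search over the
full reversal graph (`2^n · n!` states, feasible to `n = 8`) is an
independent oracle; the suite checks **all 46,080 signed permutations of
n ≤ 6** and random `n = 7, 8` cases for exact equality. Hurdles occur in
that range; fortresses do not (the smallest needs ~15 elements), so the
fortress branch follows the textbook construction but is exercised only
structurally.

`bfs_oracle_distance()` deliberately refuses `n > 8`; unsigned-model
distances (all orientations unknown) are out of scope — the NP-hard variant
is excluded by design, and singleton-block orientation ambiguity is handled
physically (see above) rather than by minimising over assignments.

## Cytocomplex classification

Combinations are canonicalized (arms sorted within groups, groups sorted by
first arm) and looked up in a data-driven JSON registry shipped with the
three complexes the target study needs; the remaining named complexes of
the genus can be added without code changes. A combination absent from the
registry is reported `unrecognized`, except that fused karyotypes are
recognized by splitting: if dividing one group into two reproduces a
registered combination, the call is "modified <name>" with the reduced
haploid number — mirroring how fused `AB CD FEG` karyotypes are described.
Whole-arm translocation distance is computed by breadth-first search over
the 877 partitions of seven arms, with translocation, fusion and fission
each costing one move.

## Pool counting and basic/endemic classification

The pool size of a species is `sum(max(1, sequences on arm))`: an arm with
no mapped or named sequence still contributes one, because a monomorphic,
never-photomapped arm is still one arrangement. This single rule reproduces
all five published pool totals (9, 10, 7, 8, 7) from transcriptions of the
species descriptions alone, which is the strongest desk check available.

A sequence is *cosmopolitan basic* iff its inversion distance to a
registry entry of scope `cosmopolitan_basic` is exactly 0 — the texts say
"identical", so the threshold is not a tunable. Sequences at distance 1–2
from a basic sequence are reported as `derived-from:<name>:<k>` but counted
endemic. Unmapped arms are endemic by default. pigST is scoped
cosmopolitan-basic on arms A/E/F (where the sources call pigST-identical
sequences basic) and reference-standard on arms C/D (where it is only the
comparison standard); this distinction is what makes the published
3-basic/6-endemic split of *C. alluaudi* fall out without special cases.

## Networks and trees

Relation diagrams are always **per arm**; arms are never concatenated.
`distance_matrix()` gives exact integer step counts; `mst_network()` builds
a minimum spanning tree with Kruskal and a full lexicographic tie-break
(weight, then sorted label pair), so outputs are reproducible;
hypothetical intermediate sequences are never invented. `nj_tree()` wraps
standard neighbor joining (\pkg{ape}) and recovers additive matrices
exactly; Newick, PHYLIP square-matrix and Graphviz DOT writers cover the
common downstream tools. Bootstrap support is a non-goal: there is no
resampling unit under an integer distance on single sequences.

## Synthetic data: what it emulates, what it does not

The generator states a world at the scale of the motivating study:

| parameter | default | meaning |
|---|---|---|
| `n_bands` | 20 (10–30 allowed) | numbered regions per arm, matching the ~15–25 of real photomaps |
| `subband_rate` | 0.15 | probability a region carries 2–3 lettered subbands |
| `n_species`, `complex_mix` | 6; 3/2/1 pseudothummi/thummi/parathummi | the study design |
| `polymorphism_rate` | 0.3 | chance of a second sequence on an arm (half that for a third), giving 0–3 polymorphic arms per species |
| `step_range` | 0–4 | inversion steps from the shared basic ancestor per arm (published counts run 1–8; small counts dominate) |

Reversal endpoints are uniform over band positions; single-band and
whole-arm intervals are rejected as degenerate (invisible or free,
respectively) — the paracentric model, with arms stored
centromere-exclusive. Every operation threads one integer seed explicitly
(`with_seed` restores the caller's RNG), so identical seeds give
byte-identical study files.

The generator does **not** emulate: band-content change (duplications,
deletions — arms are band-conserved), inversion frequencies over
generations, pericentric inversions, or correlated inversion hotspots. A
green recovery test therefore establishes that the pipeline measures what
the model generates — not that real chromosomes evolve by uniform random
reversals.

Recovery behaviour under the stated defaults: after `k` random inversions
the measured distance is ≤ `k` by construction (it is a minimal count) and
equals `k` in ≥ 90% of replicates for `k ≤ 3` on 20-band arms; the suite
prints the full equality table per `k`.

## Fixtures

The published formulas are figure-locked, so the shipped species records
(`inst/extdata/*_synthetic.json`) carry synthetic formulas constructed to
satisfy the *relations* the texts state: declared-identical sequences share
the registry formula exactly; "simple inversion" polymorphisms and stated
one-to-two-step derivations are enforced at exactly that distance; larger
stated counts (3–8 steps) are emulated by that many seeded inversions,
which guarantees a distance *at most* the stated count. Published per-arm
step counts are therefore deliberately not asserted as numbers anywhere;
the property suites carry that weight instead. Fixture reference orders
(per-arm band counts) are likewise plausible placeholders, flagged in the
file notes. All fixtures are projected through their own text form before
writing, so files reparse to exactly what was measured.

## Numerical and degenerate-input choices

* Distances are integers; no correction for multiple hits — the field
  counts minimal scenarios.
* `to_signed_permutation(a, a)` is the identity of length 1; empty
  formulas, gaps, overlaps and unknown bands raise classified errors
  (`kb_parse_error` / `kb_validation_error`), and karyotype validation
  reports *every* violated invariant at once.
* Arms shorter than 3 bands cannot receive random inversions (no legal
  interval); `generate_ancestor` enforces `n_bands ≥ 10`.
* The scenario search is quadratic per step and intended for arm-scale
  block counts; pass `scenario = FALSE` for distance-only use on long
  permutations.

## Known limitations

* Hurdle/fortress handling is exhaustively verified only to `n = 8`
  (oracle limit); beyond that correctness rests on the standard theory.
* Minimal distances may undershoot historically curated step series; where
  published counts came from curated cytological chains, an exact minimal
  algorithm is a lower bound of the curation.
* Ancestral (median) genome reconstruction and mixed
  translocation+inversion models are out of scope.
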