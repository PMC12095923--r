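---
title: "Transitive-closure structural similarity search: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transitive-closure structural similarity search: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldclosure)
```

## The problem and the method

Modern structure databases are large enough that an exhaustive precise
comparison of a query against every entry is impractical, while the fast
comparison methods that do scale sacrifice recall: structurally divergent
relatives of the query are missed because their similarity falls below
what a single-shot scan can distinguish from noise. The consequence is
familiar from protein fold space: members of a diverse superfamily are
often connected *through* intermediates — A resembles B, B resembles C,
but a direct A–C comparison scores poorly in a fast method even though a
precise aligner confirms the relationship.

`foldclosure` implements a two-tier answer to this. A precomputed
all-vs-all graph of fast comparisons (directed edges labeled by e-value)
provides cheap candidate generation; a precise aligner score (a Dali-style
Z-score with an alignment length, `lali`) provides validation. The search
walks the fast graph in shells, like a web crawler following links:

1. **Shell 1** is the query's own fast-search hit list under a relaxed
   e-value cutoff (`e_first`, default 1.0) — sensitivity at the entry
   points.
2. Every shell is thinned by **greedy representative selection**:
   candidates are ranked by e-value relative to their parent (ties broken
   on id), and a candidate within the masking radius (`e_mask`, default
   1e-5) of an earlier representative is deferred, unvalidated, behind
   that representative. This exploits the heavy redundancy of predicted
   structure databases, where near-identical entries are abundant.
3. Representatives are validated against the **original query** (never
   against their parent). Matches require `Z > zcut` and
   `lali >= minlali`. Accepted representatives contribute their stored
   neighbors under a stricter cutoff (`e_later`, default 0.01) to the next
   shell; rejected representatives are dead ends and their neighborhoods
   are pruned.
4. When a shell brings no new candidates, the **final validation round**
   evaluates the deferred neighbors of accepted representatives only.
   Deferred ids behind rejected representatives are never validated.

The result is the transitive closure of the query in the validated
similarity graph: everything reachable through chains of fast-graph edges
whose endpoints the precise aligner confirms.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `zcut` | 2.0 | minimum precise score; 2 is the aligner's reporting floor, so the default accepts every reported match |
| `minlali` | nH + nE of the query | minimum aligned residues (common-core size); defaults to the query's helix + strand residue count, on the assumption that the conserved core consists of secondary-structure elements |
| `e_first` | 1.0 | first-shell e-value ceiling (strict `<`) |
| `e_later` | 0.01 | later-shell ceiling; stricter to keep precision as the search expands |
| `e_mask` | 1e-5 | redundancy radius; 0 disables masking entirely |
| `timeout` | Inf | wall-clock limit in seconds; on expiry the partial result is returned with `timed_out = TRUE` |

The core size is the critical dial: too small and the search wanders
indefinitely through spurious low-coverage matches; too large and it
terminates before reaching divergent relatives. The nH + nE default is a
reasonable middle ground for compact single-domain queries.

## Determinism and numerical conventions

Representative sampling makes this family of algorithms only
semi-deterministic in general; this implementation removes the ambiguity
by fixing every ordering. Candidates are processed in ascending
(e-value, target id) order; when a later-shell candidate is reachable from
several accepted parents, its ranking e-value is the minimum over parents.
All cutoff comparisons on e-values are strict (`< cutoff`); the score test
is strict (`Z > zcut`) while the length test is inclusive
(`lali >= minlali`, switchable to strict via `lali_strict`). With these
conventions, identical inputs and configuration produce byte-identical
output files, which the test suite asserts.

Bookkeeping rules worth stating explicitly, because they are easy to get
subtly wrong:

* no (query, target) pair is validated twice in one search (results are
  cached by target id);
* a candidate masked under a representative is marked visited at masking
  time and is never re-enqueued from another parent in a later shell —
  its only route back into the search is the final round, and only if its
  representative was accepted;
* the final round never seeds further shell expansion;
* deferred hits inherit the shell index of their representative and carry
  a `deferred` flag;
* self-edges in the fast graph are dropped at load time, and the query
  itself must be held out of the target store (searching for a structure
  that is its own database entry is an input error, not a no-op).

## The synthetic fold space

Because the production inputs (an all-vs-all fast-comparison table over
a full structure database, plus a precise aligner) are external, the
package ships a generative stand-in that makes the entire pipeline
testable end to end. Structures are points in a latent feature space
(default dimension 8), placed hierarchically: a fold center, plus a
superfamily offset, plus a family offset, plus member noise, with strictly
decreasing spreads (defaults 8 / 3 / 1.2 / 0.4). Two similarities derive
from the latent Euclidean distance `d`:

* **precise score**: `Z = z_max * exp(-d^2 / z_decay^2)` (defaults
  `z_max = 60`, `z_decay = 8`), reported only above the floor `Z > 2`,
  with `lali = round(min(len_a, len_b) * exp(-d^2 / (2 z_decay^2)))`.
  This validator is deterministic and symmetric — the "slow but accurate"
  tier.
* **fast e-value**: `log10 e = alpha * d - gamma + N(0, e_noise_sd)`,
  with `(alpha, gamma)` calibrated once from the spreads so that
  family-level pairs land near 1e-10 and same-fold cross-superfamily
  pairs near 1; each directed edge is independently dropped with
  probability `p_miss` (default 0.3) and only `e < 1` is retained. This
  is the "fast but imprecise" tier: noisy, incomplete, asymmetric.

The calibration is recorded in the universe object, and every generator
output is reproducible from the seed. Under the defaults, members of a
family are nearly always direct fast neighbors, superfamilies are
connected below the later-shell cutoff, and cross-superfamily relatives
sit at the edge of the first-shell ceiling — exactly the regime in which
iterative expansion outperforms a single-shot scan. The default noise
level (half a decade in log10 e) and miss rate (0.3) were chosen once as
a plausible caricature of a fast structural comparison's behavior; they
are knobs of the simulation, not measurements of any particular tool.

`chain_universe(k)` constructs the adversarial extreme: `k` members on a
latent line, spaced so only adjacent pairs have fast edges (adjacent
e-value 1e-3; next-nearest 10, above the retention ceiling) while the
precise score against the query stays above the floor throughout
(`z_decay` scales with the chain length). Single-shot search recovers one
member; the closure recovers all `k`, in `k` shells.

What the synthetic model deliberately does **not** emulate: 3-D
coordinates and superposition (the algorithm consumes only e-values,
Z-scores and alignment lengths); partial-domain matches and the low-Z
tail they produce in real aligner output (synthetic scores are
whole-entry); any quantitative model of a real fast comparator's
false-negative structure. Passing tests therefore demonstrate the
correctness of the graph traversal, masking, bookkeeping and evaluation
machinery — not the biological recall of any particular aligner pairing.

## Evaluation framework

Completeness is assessed against a reference classification under three
nested filters: suffix 0 is raw membership; suffix 1 keeps findable
members (validated with Z > 2); suffix 2 additionally requires the common
core (Z > `zcut` and `lali >= minlali`). Positives are filtered
identically, and precision, recall and F1 follow the standard formulas
(`pr = |TP|/|P|`, `rc = |TP|/|TRUE|`, harmonic-mean F1). Undefined ratios
are reported as 0 with an explicit flag so batch evaluation never aborts.
Ranked result lists additionally support Fmax (best F1 over all cut
points, ties resolved to the most inclusive cutoff) and a precision-recall
curve with step-wise AUPRC (right-continuous summation over recall
increments, no interpolation). Hierarchical references are stratified
into family pairs, superfamily pairs (same superfamily, different
families) and fold pairs (same fold, different superfamilies), with
pooled, query-wise-mean and query-wise-median recall; queries with no
reference pairs in a stratum are excluded from the query-wise statistics
rather than zero-filled.

The package ships the evaluation counts of a twelve-case benchmark in
which curated sequence-family clans serve as positive controls
(`clan_benchmark()`, `clan_benchmark_queries()`). Every ratio-level
statement in the README derives from those counts at run time via
`benchmark_metrics()`; nothing is hard-coded.

```{r benchmark}
m <- benchmark_metrics()
sum(m$closure_recall_2 > 0.99)      # cases with closure recall_2 > 99%
round(min(m$closure_recall_2), 4)   # worst-case closure recall_2
sum(m$closure_f1_2 > 0.9)           # cases with closure F1 > 0.9
```

Label transfer from an external classification across a sequence
alignment uses the conventional rule: coverage of at least 80% of both
proteins, identity strictly above 40%, e-value below 1e-5
(`transfer_labels()`).

## Worked example: a chain that defeats single-shot search

```{r chain}
u <- chain_universe(5)
inp <- universe_search_inputs(u)
cfg <- search_config()

single <- single_shot_search(inp$query_id, inp$fast_searcher,
                             inp$validator, cfg, query_ss = inp$query$ss)
closure <- transitive_closure(inp$query_id, inp$fast_searcher, inp$store,
                              inp$validator, cfg, query_ss = inp$query$ss)
nrow(single$hits)    # 1: only the adjacent member
closure$hits[c("target", "z", "lali", "shell")]
```

## Design choices where the design was open

* **Masked-under-rejected candidates are not revisited.** Sequential
  greedy processing means a structure masked behind a representative that
  later fails validation could in principle be rediscovered through
  another parent. We mark masked ids visited immediately: simpler
  bookkeeping, no duplicate validations, and the cost is bounded by the
  masking radius (anything lost is within `e_mask` — essentially a
  near-duplicate — of a structure that *was* judged). The completeness
  property tested is exactly that: every exhaustive-BFS hit is either a
  closure hit or within the masking radius of one.
* **Ranking e-values for shell-2+ candidates** take the minimum over all
  accepted parents rather than the first parent encountered; this makes
  the ranking independent of shell processing order.
* **Query-anchored stacked alignments** drop target insertions rather
  than inserting gap columns, so rows have fixed width and a row's
  non-gap count always equals the pair's `lali` — which keeps fragment
  extraction for profile-based family assignment trivially consistent.
* **Seriation is greedy nearest-neighbor chaining** (anchor: the row most
  similar to the query's secondary structure), not an optimal
  traveling-salesman order; the objective (adjacent-row agreement,
  gap-gap columns excluded) is what is specified, and the greedy chain
  maximizes it well in practice at negligible cost.
* **Family assignment** from profile hits keeps the best trusted-cutoff
  e-value with a lexicographic tie-break and surfaces that e-value in the
  record, because fragment-concatenated sequences can produce spurious
  assignments that users may want to filter; the best family's clan is
  used even when a lower-ranked hit has one.
* **No multiple-testing correction** is applied anywhere: results are
  ranked by raw Z-score or e-value, as is standard for this kind of
  search.

## Problem sizes and runtime of the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
universes of 32–60 structures (10 independent seeds for the
oracle-equivalence check), chains of 3–10 members, and evaluation
fixtures of up to 50 items. These sizes keep the full suite under a couple of minutes while
still exercising multi-shell traversal, masking, deferred validation and
every evaluation code path; the algorithms themselves are linear in
validations performed and use indexed neighbor lookups, so nothing in the
implementation is specific to small inputs.

## Known limitations

* The neighbor store is held in memory and serialized as TSV; at the
  scale of a full predicted-structure database one would back the same
  query interface with an indexed on-disk relational store.
* Validation batches run serially. The structure of the algorithm
  (independent validations within a shell) parallelizes naturally, but
  no scheduler is included.
* External-tool adapters (fast searcher, precise aligner, profile
  search, secondary-structure assignment) are interfaces only: any
  `function(id, e_cutoff)` and `function(query, target)` pair with the
  documented return shapes will drive the engine, and the file formats
  are those tools' conventional tabular outputs — but no subprocess
  management is shipped.
* Precision measured against a positive-only reference classification is
  provisional: unlabeled true relatives count against precision, which
  is why recall is the primary criterion throughout.
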