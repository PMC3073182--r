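---
title: "Methods: building a process-drug-side-effect network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a process-drug-side-effect network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Drugs perturb biological processes, and perturbed processes surface as
phenotypes — including unwanted ones.  `psenet` operationalizes that idea as
a tripartite ABC network: **A** = biological processes (GO-style gene
sets), **B** = drugs, **C** = side effects.  Drugs bridge the two bipartite
layers.  If several drugs that cause the same side effect also share a
transcriptional process response, that process is a candidate mechanism for
the side effect.

The pipeline has three statistical stages:

1. **Enrichment.** Each treatment instance is a total ranking
   `L = (g_(1), ..., g_(N))` of the gene universe by treatment-vs-control
   response (rank 1 = most up-regulated).  For a gene set `S` of size
   `N_s`, a running sum walks down the list, adding
   `sqrt((N - N_s)/N_s)` at members and `-sqrt(N_s/(N - N_s))` at
   non-members.  The increments are zero-sum: the walk ends at exactly 0.
   The enrichment score `ES` is the walk's maximum deviation; up-regulation
   is scored on the list, down-regulation on the reversed list.
2. **Robust standardization.** For each (set, direction), `ES` values
   across all instances are standardized as
   `t = (ES - MED) / (1.4826 * MAD)` with the group median and median
   absolute deviation; 1.4826 makes the MAD a consistent estimator of the
   standard deviation under normality.  Drug-process edges keep `t > 3.0`
   (roughly p = 0.001 one-sided) for sets with at most 30 universe genes.
3. **Co-occurrence.** Side-effect relations with frequency of at least 20%
   are kept, drug names are normalized through a synonym table, and both
   layers are restricted to the shared (bridge) drugs.  For side effect
   `j` with `TD_j` bridge drugs and process `i`,
   `Score_ij = CD_ij / TD_j`, where `CD_ij` counts drugs doing both.
   Significance thresholds per `TD` come from a permutation null: draw
   `TD` drugs at random from the bridge, recount per-process
   co-occurrence against the real drug-process layer, pool counts, and
   find the smallest `CD >= 2` with tail probability below `alpha`.

## The enrichment-score convention

The two-sided ("signed") running-sum statistic — the signed value at the
maximum *absolute* deviation — has an identity worth knowing: the
reversed-list walk visits the same values mirrored and negated
(`Sum_rev(j) = -Sum(N-j)`), so the signed down score is exactly the
negated up score, and the signed per-set null across independent instances
is bimodal (a random set deviates about equally often upward or
downward).  A bimodal null inflates the MAD to roughly the mode
separation, which caps attainable `t` near 1.5 regardless of how extreme
an instance is — the threshold `t > 3` would never fire.

The pipeline therefore scores each direction with the *one-sided*
statistic (`convention = "positive"` in `compute_es_matrix()`): the
maximum deviation **above** zero along the traversed list.  The two
traversal directions then become genuinely distinct one-sided tests with
unimodal nulls, the `t > 3` cutoff corresponds to a per-instance null rate
of about 10^-3, and observed top t-scores land in the 3–5 range typical of
this kind of screen.  `compute_es()` still defaults to the classic signed
convention for users who want the textbook statistic; both run through the
same exact walk.

Numerically, the walk is done in integer arithmetic — hit `+(N - N_s)`,
miss `-N_s`, the same increment pair up to the positive per-set factor
`sqrt(N_s (N - N_s))` — and rescaled once at the end.  The zero-sum
identity is exact, ties are compared exactly, and ties at the extreme go
to the earliest position so output is deterministic.  Because median/MAD
standardization is invariant to positive per-set rescaling, the choice
among zero-sum increment conventions differing by such a factor cannot
change the edge set.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `t_threshold` | 3.0 | robust z | ~p = 0.001 one-sided; strict `>` |
| `max_set_genes` | 30 | genes in universe | "fewer than 31" keeps terms specific |
| `min_freq` | 0.20 | fraction | side-effect frequency filter, inclusive `>=` |
| `min_drugs` | 2 | drugs | a 1-drug effect has no co-occurrence signal |
| `n_perm` | 1000 | draws per TD | null precision ~ 1/sqrt(n_perm * n_processes) |
| `alpha` | 0.05 | level | strict `p < alpha`, no plus-one correction |
| `aggregate` | `"union"` | — | an edge exists if *any* instance passes |

Strictness of each comparison is exposed as a flag
(`strict_t`, `strict_freq`, `plus_one`) because the natural-language
conventions ("greater than", "threshold of 20%") leave ties ambiguous; the
defaults take `t` strictly and frequency inclusively.  Multi-instance
drugs default to the union rule because a single responsive instance is
evidence of perturbation; `"max_t"` keeps only the best instance per
(drug, set, direction) for a more conservative edge set.

Groups with `MAD = 0` (constant ES rows) are excluded rather than given
infinite t-scores: a constant row carries no evidence about any single
instance.  Frequency descriptions parse as percentages (`"26%"`), ranges
by midpoint (`"10-20%"` → 0.15 — deterministic and monotone in both
endpoints), or a configurable qualitative map
(`postmarketing`/`rare` → 0.001, `infrequent` → 0.01); unknown
descriptors become missing and never pass the filter.  Drug-name matching
is exact after trimming and case-folding — fuzzy matching silently merges
distinct drugs, which is worse than dropping an unmatched name.

## The permutation null

The null pools co-occurrence counts across all (process, direction) units
within one TD group.  A per-process null would give each process its own
threshold; the pooled version yields a single threshold per TD, matching
how such calibrations are published and applied (a degree-indexed lookup
table, see `co_threshold_table()`).  TD is held fixed and only drug
identity is resampled: the question is "how many of TD random drugs share
a process", not "how many drugs cause the effect".  The threshold floor
is `CD = 2` (one drug cannot co-occur with itself), and TDs where even the
most extreme attainable count is not rare enough are reported as
unattainable rather than silently significant.  Up and down directions
are carried through the whole chain independently and written to separate
association files.

## What the synthetic generator emulates

`generate_scenario()` builds all four inputs at reduced scale with known
ground truth: by default a 2,000-gene universe, 200 sets of 5–30 genes, 74
drugs with one instance each, and 30 side effects, each planted on 3
drugs.  A planted (drug, set, direction) moves `planted_strength * N_s` of
the set's genes (default 80%) to uniformly random positions inside the top
decile of that drug's ranking (bottom decile for down); all other ranks
are uniformly random permutations.  Planted drug-effect links get
frequency scores {0.25, 0.5, 0.75} (above the filter); every drug also
gets one decoy record at {0.001, 0.01, 0.1} (below it), written in the
same frequency dialect the parser reads.  Each drug carries a primary
name, a synonym and a capitalized brand name; `make_synonym_collisions()`
rewrites side-effect-layer names to brand aliases to stress the merge.

One RNG stream seeds the scenario and is forked per sub-generator (sets,
plants, frequencies, decoys, ranks, synonyms), so enlarging one component
does not reshuffle the others — regression tests stay stable.

What it deliberately does **not** emulate: correlated expression responses
across instances (real instances share cell lines, batches and mechanisms,
which widens the empirical ES null), probe-to-gene multiplicity (the
synthetic path ranks genes directly; a mapping table can be applied before
ranking on real data), dose/replicate structure, incomplete side-effect
reporting, and the 6,100-instance scale of a real rank-matrix compendium.
Passing the planted-recovery tests therefore demonstrates that the
*machinery* recovers signals of the stated geometry — not that real
compendium data will be as clean.

## Power at the smallest set sizes

With decile placement at 80% strength, a planted set of 5 genes puts 4
members in the top 10%; the one-sided statistic for so few genes has a
wide null (its typical deviation scales like `1/sqrt(N_s)`), and the
resulting planted t-scores land in the 2.6–3.6 range — straddling the 3.0
cutoff.  Planted sets of 6 or more genes are recovered essentially always
at default scale; 5-gene sets are recovered in most but not all seeds.
Recovery of an association survives one missed drug (the TD = 3 threshold
is typically CD >= 2), so whole-association misses are rare but do occur.
This is an honest power boundary of the method at its published
thresholds, not a tunable artifact; raising `planted_strength` or set
sizes in a scenario makes it vanish.

## Problem sizes used by the test-suite

The shipped tests run the full default scenario (74 drugs) once, a
15-drug mini scenario for structural checks, 50 zero-signal scenarios at
12 drugs / 300 genes / 250 permutations for the false-flag calibration,
and the exhaustive-vs-sampled null comparison on a 4-drug toy at 10,000
draws.  These sizes were chosen so each property is measured with
meaningful resolution while the whole suite stays quick to iterate on.

## Known limitations

- Standardization is over *all* provided instances jointly; per-cell-line
  standardization is not implemented.
- Frequency information is required: records without it are dropped, so a
  sparsely annotated side-effect source shrinks the network.
- The co-occurrence score weights all drugs equally; promiscuous drugs
  (many effects, many processes) are not down-weighted.
- The literature harness takes pre-extracted noun phrases as input and
  matches them by normalized Levenshtein similarity (threshold 0.55,
  inclusive); it does not retrieve or parse abstracts.  Literature
  rankings use raw match counts, with per-phrase normalization available
  as a column, and break ties lexically by GO id for determinism.
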