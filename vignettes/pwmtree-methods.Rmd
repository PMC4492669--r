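---
title: "Phylogeny-guided PWM classification: model, parameters, and design notes"
author: "pwmtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-guided PWM classification: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmtree)
```

## The model

`pwmtree` classifies a query sequence into one of a user-defined set of
reference taxa. The training inputs are a gapped multiple alignment of
reference sequences (each record labeled with its taxon) and a rooted
phylogeny of those taxa. Training attaches a position-specific weight
matrix (PWM) to every node of the phylogeny: a leaf matrix holds the
per-column relative frequencies of its taxon's sequences, and an inner
matrix models the clade below it. The gap character `-` is part of the
alphabet, so a PWM column assigns a probability to a deletion with respect
to the alignment just as it does to any residue.

Under the naive assumption that columns are independent, the probability
of an aligned sequence $r_1 \dots r_l$ given a matrix with column
frequencies $f_i$ is $\prod_i f_i(r_i)$. Products of small frequencies
underflow, so scoring is done in log space, scaled and rounded to integers:

$$\mathrm{score}(s) = \sum_{i=1}^{l} \big\lfloor k \,\ln \max(f_i(r_i),
\varepsilon) \big\rfloor .$$

Viewed as a function of the matrix with the query fixed, this is a
(log) likelihood, and classification picks the maximum-likelihood taxon
along a greedy path through the tree.

Classification of a raw query proceeds in two stages. First the query is
aligned once to the **root** PWM by semi-global dynamic programming:
global in the PWM (every matrix position is consumed exactly once, either
by a query residue or by emitting `-`, scored by the PWM's own gap
column), local in the query (any prefix or suffix of the query may be
skipped free; residues skipped between two emitted residues cost a
penalty). The aligned query is therefore exactly as long as the model.
Second, greedy descent: the aligned query is scored against the children
of the root, the best-scoring child is entered, and so on until a leaf.
Each decision records the rounded base-10 logarithm of the evidence ratio
between the best and next-best sibling, $(best - next)/(k \ln 10)$ — a
per-step confidence in the same spirit as the bootstrap confidences of
naive-Bayes rRNA classifiers. Queries are always assigned to a leaf; the
ER cutoff (below) is the mechanism for refusing unconvincing assignments,
not internal placement.

### Bias reduction

Reference sets over-represent well-studied taxa and sometimes contain
near-duplicate records. Before any matrix is built, the whole alignment is
weighted by the Henikoff position-based scheme: in each column, each of
the $r$ distinct residue types present (gap included) shares one unit of
weight equally among its $s$ occurrences, so a sequence collects
$1/(rs)$ per column; raw weights therefore sum to the number of columns.
Raw weights are divided by their minimum and rounded **up**, and each
record is repeated to its integer adjusted weight, so no sequence falls
below weight one. Weighting is applied once, to the whole input alignment
— per-clade reweighting is deliberately not offered.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 1000 | scale applied to natural-log probabilities before rounding to integers; 1000 keeps three decimal digits of log precision, so rounding error per column is below $10^{-3}$ log units |
| `epsilon` | $10^{-4}$ | probability floor applied *inside* the log for zero-frequency symbols; observed frequencies are never perturbed (no pseudocounts), but a symbol never seen in a column still yields a finite score $\lfloor k \ln \varepsilon \rfloor$ (−9211 at the defaults) |
| `innerMode` | `child_average` | inner matrices as unweighted means of their children, which gives sibling clades equal influence regardless of sampling depth; `clade_pooled` instead recounts over all clade sequences (the two coincide when every child contributes equally) |
| `skipPenalty` | floor score | cost of skipping a query residue *between* two emitted residues during alignment; end skips are free. Pricing internal skips like an unknown residue makes insertions relative to the reference region possible but strongly discouraged |
| `erCutoff` | 0 | a query is flagged unclassifiable if **any** finite decision on its path falls below the cutoff; 0 classifies everything |
| `trials` | 100 | leave-one-out trials, capped at the number of suitable records |
| `minPerTaxon` | 3 | a taxon enters cross-validation only with at least this many sequences (withholding one must leave the taxon represented, and 2 would make trial models degenerate) |

`k` and `epsilon` are stored in the model file, so a classifier always
scores queries with the constants it was trained under. Unknown residues
(ambiguity codes such as `N`/`X`) score at the epsilon floor everywhere:
maximally uninformative, never fatal.

## Numerical and procedural choices

* **Integer scores.** All per-column scores are integers; every DP cell
  and every total score is a sum of integers, far below the exact range of
  doubles, so exact equality comparisons in the alignment traceback are
  sound.
* **Determinism.** Ties in greedy descent go to the first child in model
  order (the order clades appear in the Newick input), reported with ER 0.
  The aligner's traceback prefers residue emission over gap emission over
  query skip, and the earliest query residue among equal-scoring end
  states. Training is fully deterministic; cross-validation and the
  fixture generator take explicit seeds and restore the caller's RNG
  state.
* **Adjusted weights.** The ratio raw/min is mathematically ≥ 1 but a
  floating-point quotient can land immeasurably above an integer; the
  ceiling is taken after subtracting 10⁻⁹ so integral ratios stay put.
* **Evidence-ratio display.** ERs are printed as rounded integers; values
  above 1000, and decisions with a single child (no next-best exists), are
  rendered `*`. Unlabeled inner nodes print as `unnamed`. Under a positive
  cutoff, failing queries are still printed, with a final `UNCLASSIFIED`
  column, so downstream pipelines see every input exactly once.
* **Degenerate inputs.** All-gap columns are legitimate (the gap is a
  modeled state) and are retained. Multifurcating trees are supported
  as-is; single-child chains are collapsed at parse time; duplicate record
  IDs warn rather than fail (the IDs only matter for reading validation
  output). Queries are stripped of gaps before alignment unless the
  pre-aligned flag is given, in which case their length must equal the
  model's.
* **Validation before training.** A tree leaf without sequences, or an
  alignment taxon missing from the tree, aborts training with *all*
  findings listed; single-sequence taxa are flagged as warnings because
  they cannot take part in cross-validation.

### Open design points, and how they were settled

The frequency definition for inner nodes can be read two ways — recount
over all clade sequences, or average the children. The two differ whenever
siblings are unequally sampled. Child averaging is the default because it
extends the bias-reduction intent to the tree dimension (a genus with 100
reference sequences should not drown its sister with 3); the pooled
variant is retained as an option and the two are verified to coincide on
balanced input.

Emitting `-` at a PWM position is scored by that column's own gap
frequency rather than a fixed penalty: the matrix already models the
probability of a deletion, so a fixed penalty would double-count. "Local
in the query" is interpreted on the query axis: any skipped prefix or
suffix of the query is free regardless of interleaved gap emissions, and
the exhaustive test oracle enumerates monotone alignments under exactly
that cost model.

The model container is a versioned binary file (magic bytes, format
version, payload length, then an R-serialization payload) so that
incompatible files fail fast with a clear message and round-trips are
bit-faithful, including every integer score matrix.

The command-line layer is one entry point with `train`, `classify`,
`xval` and `fixtures` subcommands rather than separate per-task
executables: a single namespace keeps flags consistent and the wrapper
trivially thin over the R functions, which remain the primary interface.

## What the synthetic generator emulates — and what it does not

`evolveReferences()` produces clade-structured reference families: a
random root sequence is mutated along each edge of a balanced taxon tree
with per-site probability `betweenDivergence` (uniform replacement among
the other symbols — Jukes–Cantor-like for DNA, uniform over 20 for
protein), each taxon's ancestral sequence then spawns its references plus
one withheld query at `withinDivergence`, and per-taxon shared gap columns
appear with probability `gapProb`. This exercises everything the
classifier does — hierarchical signal, within-taxon noise, gap-as-character
scoring, held-out evaluation — deterministically under a seed.

It does **not** emulate rate heterogeneity across sites, realistic indel
processes (gaps are taxon-wide columns, not per-sequence events),
alignment error, chimeras, or uneven taxon sampling. Passing tests on
these fixtures therefore demonstrate the *algorithmic* contracts
(optimality of the aligner, correctness of weighting and averaging,
determinism, the ~2·log₂(n) scoring count) and parameter recovery under
the stated noise model — not field accuracy on real amplicon data, which
depends on the quality and coverage of the user's references.

The `easy` preset (10 taxa × 6 sequences, length 300, within 0.02,
between 0.25 per edge, 2% gap columns) represents a comfortably separable
reference set: leave-one-out error is expected near zero, and greedy
descent is expected to agree with exhaustive scoring of all leaf matrices
on essentially every query. The `hard` preset (within 0.10, between 0.12)
deliberately narrows that margin — greedy search is *not* exhaustive
search, and disagreement there is documented behavior, not a defect. The
`tie` preset builds two identical taxa to pin down tie-breaking.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
properties they probe are fully expressed: exhaustive alignment
enumeration up to 6×6 (500 random instances), 60 leave-one-out trials on
the `easy` preset, and a 585-taxon balanced tree (depth ⌈log₂ 585⌉ = 10)
for the scoring-count property, where one maximal-depth descent scores
exactly 20 child matrices. The 585-taxon fixture uses one sequence per
taxon, zero within-taxon divergence and 0.05 between-clade divergence per
edge: with aggressive per-edge divergence the averaged matrices deep in a
585-leaf tree drift toward uniform and a descent can legitimately end in
a shallower clade, whereas the property under test concerns a
maximal-depth path.

## Known limitations

* Column independence is false in general (helices, covarying sites); it
  is the same trade-off all naive-Bayes-style classifiers make.
* Greedy descent can be misled at a high node when clades are poorly
  separated; the ER cutoff detects, but does not repair, such cases.
* Queries are always assigned to a leaf — a relative of the true taxon
  that is absent from the references will capture its queries.
* Taxon names are single tokens (second header token); names with spaces
  are unsupported.
* The aligner is quadratic in query length × model length, the price of
  PWM-based (rather than k-mer) matching; the decision tree amortizes it
  by aligning once and scoring only ~2·log₂(n) matrices.
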