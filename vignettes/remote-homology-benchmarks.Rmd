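---
title: "Benchmarking zero-shot remote homology retrieval from protein representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking zero-shot remote homology retrieval from protein representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remhombench)
```

## The problem

Remote homologs are proteins that share evolutionary ancestry — and therefore
structure — while their sequences have diverged below the "twilight zone" of
roughly 30% identity, where sequence similarity alone no longer betrays the
relationship. The SCOP/SCOPe classification encodes this hierarchy: proteins
in the same *Family* share high sequence similarity; Families with common
ancestry are bridged into *Superfamilies*; structurally similar Superfamilies
share a *Fold*. Two domains are remote homologs at the superfamily level when
they share a Superfamily but sit in different Families, and at the fold level
when they share a Fold but sit in different Superfamilies.

`remhombench` turns a classified domain database plus any per-protein vector
representation (pooled protein-language-model embeddings, or an external
pairwise match-score matrix) into a zero-shot retrieval benchmark: every
domain queries the rest of the database, candidates are ranked by cosine
similarity, and the ranking is scored against the homology labels. "Zero
shot" means the representations are used exactly as produced — no
fine-tuning, no supervision; the benchmark measures how much homology
structure the representation space already carries.

## Task construction

For a database of $N$ classified domains, each domain $q_i$ in turn becomes a
query against the remaining domains. At the superfamily level, every
candidate from $q_i$'s own Family is *excluded* — otherwise trivially
sequence-similar relatives would contaminate the positive set and the task
would measure ordinary homology rather than remote homology. Remaining
candidates are positives if they share $q_i$'s Superfamily and negatives
otherwise; note the negatives deliberately include same-Fold /
different-Superfamily domains. At the fold level the whole scheme shifts one
tier up (exclude same-Superfamily, positives share the Fold). A query with no
positive candidate is dropped from the evaluation and counted. The hardened,
identity-thresholded variant of the task enters through the data: databases
are pre-filtered (e.g. Astral subsets, or [greedy_identity_filter()] at toy
scale) so that no retained pair exceeds a stated identity threshold, which
the database carries as provenance metadata.

Representations enter either as pooled vectors or as per-residue $l_i \times
D$ matrices, which are mean-pooled over the sequence length
($p_i = \tfrac{1}{l_i}\sum_j s_{ij}$, in double precision). Ranking uses
cosine similarity $\cos(p_i, p_j) = p_i \cdot p_j / (\lVert p_i\rVert\,
\lVert p_j\rVert)$; zero-norm vectors are treated as corrupt input (error for
a query, logged drop for a candidate), never silently scored. Exact score
ties are broken by ascending candidate id so that every ranking is
bit-reproducible; statistical tie handling lives in the metrics instead.

## Metrics and aggregation

Per query: **AUROC** via the Mann–Whitney identity (probability that a
random positive outscores a random negative, ties credited ½ through
midranks), which equals the trapezoidal area under the ROC curve under the
standard threshold direction (score ≥ threshold ⇒ predicted positive);
**AUPRC** as average precision (mean of precision at each positive's rank,
under the deterministic tie-break) — the step-wise convention, chosen over
trapezoidal PR interpolation because interpolating precision between recall
points is known to overstate performance on heavily imbalanced rankings;
**Hit\@1** and **Hit\@10** as indicators that a true remote homolog appears at
rank 1 or within the top 10 (truncated at the list length).

Aggregation is either *unweighted* (mean over all queries) or *weighted*:
metrics are first averaged within each Superfamily (or Fold), then across
groups, so that a handful of giant groups cannot dominate the summary and
small groups count equally. The weighted scheme is the primary one.

Model agreement uses Spearman's rank correlation
$\rho = 1 - 6\sum_k d_k^2 / (n(n^2-1))$ between two models' AUROC lists
(midranks generalise the closed form under ties). The agreement matrix holds
per-group correlations in its lower triangle and per-query correlations in
its upper triangle, each on the intersection of groups/queries both models
scored. This distinguishes models that merely score similarly on average from
models that find the *same* cases easy.

## The synthetic generator

Real benchmarks need SCOPe downloads and multi-gigabyte language-model
weights; every stage here is instead testable against a synthetic generator
that emulates exactly the structure the method consumes:

* `generate_hierarchy()` builds a balanced Class→Fold→Superfamily→Family tree
  with systematic sccs paths and random sequences (lengths uniform in 50–200
  by default; sequence content is deliberately uncorrelated with the
  hierarchy, since embeddings, not sequences, carry the signal).
* `generate_embeddings()` draws one standard-normal centroid per fold,
  superfamily and family and emits
  $p_i = w_{fold} c_{fold} + w_{SF} c_{SF} + w_{F} c_{F} + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2 I)$. This additive-centroid model is the
  simplest generative process with independently tunable signal at each
  hierarchy level; the method under test assumes only that cosine proximity
  encodes homology, which this model realises when the matching weight is
  positive.
* `generate_per_residue_embeddings()` wraps each pooled target into an
  $l_i \times D$ matrix plus per-residue noise, so mean pooling recovers the
  pooled vector to order $\sigma_{res}/\sqrt{l_i}$ — exercising the pooling
  path.
* `generate_random_representations()` is the uniform-$[0,1)$ baseline of
  length 150: rankings from it are independent of the labels, so mean AUROC
  must sit at 0.5 and mean Hit\@1 at the positive prevalence. The uniform
  support is immaterial for rank-based metrics — any fixed continuous
  distribution gives the same null.

What the generator does *not* emulate: realistic sequence evolution, the
highly skewed group-size distributions of SCOPe, correlations between
sequence identity and embedding distance, or any model-specific geometry.
Passing tests therefore certify the *evaluation machinery* — labeling,
exclusion, ranking, metrics, aggregation — not any claim about real protein
language models.

## Calibration properties the suite verifies

* AUROC and AUPRC agree with exhaustive brute-force oracles on thousands of
  random small instances, including tied scores.
* Pure-noise embeddings and the uniform-random baseline score at chance
  (mean AUROC 0.5, Hit\@1 at prevalence); null mean average precision is
  checked against a Monte-Carlo permutation oracle rather than against the
  prevalence itself, because average precision exceeds prevalence for small
  positive counts.
* Noiseless superfamily-weight-only embeddings give AUROC = AUPRC = Hit\@1 =
  Hit\@10 = 1 for every retained query.
* Weighted AUROC increases strictly with the superfamily-signal-to-noise
  ratio (checked at ratios 0, 0.5, 1, 2, five seeds each, on a 24-domain
  database with dimension 8 and unit noise — small enough for seconds-scale
  runs, large enough that the four means separate cleanly).
* Fold-only signal produces strong fold-level retrieval on a multi-fold
  database while superfamily-level retrieval sits at chance on a single-fold
  database. The single-fold restriction matters: on a multi-fold database,
  fold-only signal *does* lift superfamily-level AUROC, because the
  superfamily task's negative pool is dominated by cross-fold domains that a
  fold-informed embedding pushes away. Chance-level behaviour is the correct
  expectation only where fold identity carries no discriminative
  information, i.e. within one fold.

## Numerical and design choices

* Tie policy: midranks inside AUROC and Spearman (statistically standard);
  ascending-candidate-id ordering inside ranked lists, average precision and
  Hit\@k (reproducibility). Both are stated so results are exactly
  replicable.
* Queries with zero negatives (possible in tiny databases after exclusion)
  are dropped and counted separately from zero-positive drops, as are
  queries with degenerate representations.
* The identity threshold is a property of the input database (pre-filtered
  subsets), not a runtime filter; the toy greedy filter exists so the
  hardening pathway is testable end-to-end at desk scale. Its identity
  definition — identical positions over alignment length, optimal global
  alignment with match 1, mismatch 0, linear gap −1 — is deliberately simple
  and fully stated; it is not a CD-HIT replacement and is guarded against
  long sequences.
* Preprocessing removes whole folds by an explicit id list (e.g.
  Rossmann-like folds and β-propellers, whose promiscuous similarity blurs
  homology boundaries) and multi-span sequences; the fold list is a
  configuration input because it is a curation decision.
* The embedding store is a keyed plain-text TSV with container-level
  metadata (`model_name`, `layout`, `dim`), one row per vector or per
  residue, 17 significant digits — exact double-precision round-trips with
  no binary dependency.
* Non-standard residues (X/B/Z/U) are retained in sequences; they count as
  mismatches in the toy identity filter and are otherwise inert carriers.
* The analysis drivers under `analysis/` use an 80-domain study database
  (4 folds × 2 superfamilies × 2 families × 5 domains) and run in seconds;
  all sizes are stated in the scripts and chosen so a full rebuild of every
  table is interactive.

## Limitations

Aggregate numbers from the synthetic workflow characterise the pipeline, not
any real model; the generator's balanced hierarchies make the weighted and
unweighted schemes nearly coincide, whereas on real SCOPe they diverge
substantially. Spearman agreement on eight synthetic groups is noisy (the
per-group lists are short); real analyses should report the intersection
sizes stored on the agreement matrix. Confidence intervals and significance
tests for metric differences are out of scope.
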