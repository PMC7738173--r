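---
title: "Predicting site-specific phosphorylation with motif-labeled knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting site-specific phosphorylation with motif-labeled knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoslink)
```

## The problem and the model

Protein kinases phosphorylate substrate proteins at specific serine,
threonine or tyrosine residues. Curated corpora record these events as
statements ⟨K, L, S⟩ — kinase K phosphorylates substrate S at site L — but
cover only a small fraction of the true network. Classical predictors score
the local sequence around a candidate site against kinase consensus motifs,
examining each site in isolation. `phoslink` instead treats prediction as
link prediction in a knowledge graph, so that the global structure of the
known network (which kinases share substrates, which substrates are
co-targeted) informs every prediction alongside the local motif signal.

The pipeline has four stages.

1. **Network compilation** (`parse_statements()`,
   `validate_against_sequences()`). Statements are read from a
   tab-separated table, filtered to one organism, deduplicated, and
   retained only when the stated residue matches the substrate sequence at
   the stated position (canonical sequence first, then isoforms; first
   match wins). The `2k+1`-residue context window around each site is
   extracted with `'-'` padding at sequence ends.

2. **Motif inference** (`infer_family_motifs()`). Kinases are grouped into
   families, which share sequence preferences. For each family, the
   context windows of its substrate sites are batched (default 50 windows
   per batch) and each batch yields up to 10 position-specific scoring
   matrices (PSSMs): log-odds of the pseudocounted per-position residue
   frequencies against the batch background. A window is *compatible* with
   a motif when its summed score is strictly positive; padding and
   ambiguity codes (X, U, B, Z) contribute exactly zero.

3. **Knowledge-graph conversion and embedding**
   (`to_knowledge_graph()`, `train_embeddings()`). Every statement
   ⟨K, L, S⟩ becomes one edge ⟨K, M, S⟩ per family motif M compatible with
   L's window; the relation label thus abstracts the site into a motif.
   Entities and relations are embedded as d-dimensional vectors under one
   of three score functions — TransE (−‖s + r − o‖), DistMult
   (Σᵢ sᵢrᵢoᵢ) and ComplEx (Re Σᵢ sᵢrᵢōᵢ, complex-valued, able to model
   the asymmetry of the kinase→substrate relation) — trained with the
   pairwise hinge loss max(0, margin − score(pos) + score(neg)) by
   mini-batch SGD. Negatives are generated by biologically constrained
   corruption (below). Raw scores are calibrated to (0, 1) by the logistic
   map, so 0.5 marks higher-than-random plausibility.

4. **Back-conversion and stringency** (`back_convert()`, `predict_all()`).
   A scored edge ⟨K, M, S⟩ fans back out to one prediction per known site
   of S compatible with M; duplicate (K, L, S) predictions keep the
   maximum score. The medium-stringency threshold is 0.5; the
   high-stringency threshold is derived from the data as the largest value
   such that 99.5% of the known positive edges score strictly above it.

## Constrained negative sampling

Random corruption of positives, the standard recipe in knowledge-graph
learning, is dangerous here: kinases are promiscuous, so a random
(kinase, substrate) pair has a fair chance of being a true but unobserved
phosphorylation. Training negatives therefore respect two constraints.
A *kinase corruption* ⟨K̄, M, S⟩ replaces K with a kinase from a different
family; a *substrate corruption* ⟨K, M, S̄⟩ replaces S with a substrate all
of whose known sites score non-positively against M. The default two
negatives per positive alternate the two operators, falling back to the
other when one has no eligible candidate. Eligibility for substrate
corruption is resolved exactly from a precomputed motif × site
compatibility scan, which is equivalent to rejection sampling against the
constraint but cannot emit a violator; every emitted negative can be (and
in the test suite is) verified by full rescoring. Per-positive seeds are
derived by hashing the positive edge together with the root seed, so the
negative set is reproducible and independent of input order.

The *benchmark* negatives are deliberately different: the evaluation
harness samples unconstrained random combinations of kinases with known
(substrate, site) pairs, because an evaluation pool must not be filtered
by the very signal the model is being tested on.

## Evaluation protocol

`run_benchmark()` repeats, for a configurable number of runs: a seeded
split of the positive statements (default 90% train / 10% test), negative
sampling from the pool at the configured positive:negative ratio (1:1 or
1:10), retraining of the embedding on the training portion, and scoring of
the test set. A statement is scored as the maximum calibrated score over
the compatible motifs of its kinase's family; statements the model cannot
score — no compatible motif, or an entity unseen in training — receive
exactly zero (*uncovered*), and coverage of positives and negatives is
reported alongside the metrics. AU-ROC is computed by the trapezoidal rule
with ties grouped by threshold (equal to the all-pairs Mann–Whitney
statistic with ties counted one half, which the tests verify); AU-PR uses
step-wise interpolation; precision-at-K uses a stable sort with an
optional tie-permutation average. P@K is computed on the pooled test
ranking, not per query protein (the alternative reading; the pooled form
matches how the metric is described alongside the ranking tables).

Hyperparameters are selected by `grid_search()`: an 80/20 split, 10-fold
cross validation on the 80% for every grid point, mean validation AU-ROC
as the criterion, ties broken towards the smaller embedding size and the
simpler model (TransE < DistMult < ComplEx). The reference configuration
used throughout the package is ComplEx with d = 50, 100 epochs, 10
batches, margin 1, learning rate 0.1 and two negatives per positive.

## The synthetic generator: what it emulates and what it does not

Because the curated corpora driving the original analyses are licensed,
the package ships a generator (`simulate_network()`) whose defaults define
the reference validation conditions: 4 kinase families × 5 kinases, 200
substrates × 3 sites, context size k = 7, motif strength 0.9, ~30
statements per kinase, and a 2 × 2 block structure (affinity 0.9 within a
family-group/substrate-group block, 0.1 across).

The generator reproduces the three structural properties the method
actually exploits in real corpora:

* **family-exclusive motifs** — each family has a hidden position-weight
  profile (preferred residue with probability 0.7 per off-centre position,
  a family-specific S/T/Y at the centre), and every substrate is owned by
  exactly one family, so site windows carry one family's signal;
* **block structure** — ownership is drawn through the group-affinity
  matrix, so kinase groups concentrate on substrate groups;
* **multi-site targeting** — a kinase that targets a substrate
  phosphorylates each of its sites with probability 0.8, giving roughly
  three sites per kinase–substrate pair, the ratio real corpora show
  (≈7 substrates but ≈22 sites per kinase). This matters because the
  knowledge graph abstracts sites into motifs: a held-out statement is
  often recoverable precisely because a sibling site of the same pair
  remains observed.

Under these conditions the full pipeline ranks held-out true statements
above pool negatives with AU-ROC ≈ 0.98 at ~98% positive and ~68% negative
coverage, and moving the test ratio from 1:1 to 1:10 lowers AU-PR
substantially while leaving AU-ROC nearly unchanged — the qualitative
fingerprints of the method on real data.

What the generator does *not* emulate: real degree distributions (hubs and
orphan kinases), cross-family site competition, sequence composition bias,
isoform-specific sites, and the sheer scale of real corpora. Passing tests
on synthetic data therefore demonstrate the pipeline's correctness and its
qualitative behaviour, not the absolute metric values attainable on any
real corpus.

## Numerical choices and degenerate inputs

* **Pseudocount** +1 per residue per position (Laplace) keeps log-odds
  finite on 50-window batches. The background model is order 0; an
  order-5 Markov background over 20 residues cannot be estimated from a
  50-sequence batch, so higher orders are deliberately unsupported.
* **Motif width selection.** Per-position relative entropy is
  non-negative, so "the sub-window with maximal total information" would
  always be the full window. Each position is therefore charged the
  small-sample baseline 19/(2·n·ln 2) bits — the asymptotic mean apparent
  information of an n-sample empirical distribution under the background —
  and the greedy pick maximises the net total over contiguous sub-windows
  (width ≥ 2) containing the centre, masking selected positions between
  picks and stopping when no candidate retains positive net information.
  Ties break towards the smallest start offset; at least one motif is
  always emitted per non-empty batch.
* **In-sample compatibility bias.** Statements are converted against
  motifs fitted on their own windows, so even at zero motif signal the
  expected in-sample score is slightly positive (≈ +KL(empirical ‖
  background)) and most statements stay compatible. The meaningful null
  statement — which the tests assert — is out-of-sample: fresh background
  windows are mostly incompatible, and null motifs carry a fraction of the
  information of planted ones.
* **Thresholds** use strict inequalities on both sides ("score above it"):
  a score exactly at the high threshold is medium, exactly 0.5 is below.
  The high threshold is returned just below the retention order statistic
  so the recount property (≥ 99.5% of positives strictly above) holds
  exactly, including for all-equal score vectors.
* **Ties in ranking** are grouped by threshold for the curves and broken
  by stable input order for P@K (`tie_permutations` averages over random
  tie orders instead when set).
* **TransE** entity vectors are projected to unit norm after each batch
  (standard stabilisation for translational models; configurable).
  DistMult/ComplEx are left unnormalised.
* **Degenerate inputs**: an empty network yields all-zero statistics; an
  empty batch yields no batches; a single-family pool makes kinase
  corruption unavailable (falls back to substrate corruption); AUC on a
  single-label test set is an error rather than a silent 0.5.
* **Problem sizes.** The reference experiments in the test suite use the
  default generator (≈600 statements, ≈1,700 positive edges, d = 50,
  100 epochs — a few seconds per retraining) and 3 benchmark repetitions
  per ratio; the same code paths scale to the 100-run protocol via
  `benchmark_config(n_runs = 100)`.

## Known limitations

* Motif discovery assumes windows pre-aligned on the phosphosite; it is
  counting-based and cannot separate a mixture of two motifs within one
  family's batch (families sharing identical substrate pools would yield
  blended matrices).
* Statement scores depend on the motif vocabulary fixed before
  benchmarking; per-split motif re-inference is not implemented (matching
  the reference procedure, which fixes the conversion before validation).
* Calibration is a fixed logistic map, not fitted; scores are comparable
  within a model, and the stringency thresholds are defined relative to
  that map.
* The candidate space streams in chunks but back-conversion materialises
  one chunk's fan-out at a time; chunk size trades memory for speed.
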