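---
title: "Cluster-guided active learning for clinical NER: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-guided active learning for clinical NER: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activeNER)
```

## The problem

Supervised clinical named-entity recognition (NER) — finding and typing
mentions of medical *problems*, *treatments* and *lab tests* in clinical
notes — needs annotated sentences, and expert annotation is the dominant
cost of building such models. Pool-based active learning (AL) tries to
reduce that cost: starting from a large pool of unlabeled sentences, the
learner repeatedly chooses which sentences an annotator should label next,
retrains, and stops when an annotation budget is exhausted.

The best-known query strategy, least-confidence (LC) uncertainty sampling,
ranks each unlabeled sentence by

$$LC(s) = 1 - P(\hat{y} \mid s),$$

where $P(\hat{y} \mid s)$ is the conditional probability of the tagger's
best tag sequence $\hat{y}$. Its weakness in batch mode is redundancy:
similar sentences receive similar scores, so a batch of top-ranked
sentences tends to contain near-duplicates that each teach the model the
same thing.

This package implements a cluster-guided variant, CAUSE (Clustering And
Uncertainty Sampling Engine), that queries sentences which are both
*informative* (high LC) and *representative* (from different regions of
the pool):

1. **Cluster ranking.** Every pool sentence belongs to one of the clusters
   computed in a preprocessing step. Each cluster containing unlabeled
   sentences is scored — by the mean LC of its unlabeled members (AUCS,
   the default), their maximum (MUCS), or a random score (RCS) — and the
   top $x$ clusters are selected, $x$ being the batch size.
2. **Representative sampling.** From each selected cluster, the unlabeled
   sentence with the highest LC becomes the cluster representative. The
   batch is the $x$ representatives in cluster-rank order, so a batch
   never contains two sentences from one cluster (as long as at least $x$
   clusters remain eligible).

Before any model exists, the initial sample is drawn by random cluster +
random representative (CAUSE) or plain random sampling (the baselines).

## The sequence tagger

The tagger is a linear-chain conditional random field (CRF) over BIO tags
(`B-`/`I-` prefixed by entity type, plus `O`), trained by L2-penalised
maximum likelihood with L-BFGS and decoded with Viterbi. Two details
matter for the querying engines:

* `best_path_prob` is exact: the Viterbi score minus the log partition
  function computed by a scaled forward pass, both restricted to legal BIO
  paths. Transitions into `I-x` from anything other than `B-x`/`I-x` (and
  sequences starting with `I-x`) carry zero probability mass, so decoded
  spans are well-formed without repair. The test suite checks the
  probability against exhaustive path enumeration on small label sets to
  $10^{-9}$.
* LC is **not** length-normalised by default. A length-normalised variant
  ($1 - P^{1/n}$) is available via `leastConfidence(..., lengthNormalize
  = TRUE)` and `simulationConfig(lengthNormalize = TRUE)` for sensitivity
  analyses; unnormalised LC systematically favours long sentences, which
  is part of the behaviour under study (actively selected sentences are
  longer and denser than randomly selected ones).

Token features are word forms in a ±2 window (lowercased, with
begin/end-of-sentence markers), 3- and 4-character prefixes and suffixes,
and orthographic flags; `featureTemplate()` controls all of these. Large
simulation sweeps use the reduced template `featureTemplate(window = 1,
affixes = FALSE)` — on the templated synthetic corpora the reduced set
loses little accuracy and trains several times faster.

Retraining inside the AL loop is warm-started from the previous iteration's
weights with a lower optimiser cap (`warmMaxit`, 20 by default in the
shipped experiment scripts vs. 80 for the cold start). Because only five
sentences are added per iteration, the penalised optimum moves little and
the warm-started fit reaches it reliably.

## Clustering preprocessing

CAUSE's clustering is computed once per pool, before the AL loop, and
never updated:

1. **Topic estimation** by latent Dirichlet allocation (collapsed Gibbs
   sampling) on *whole documents* — short clinical sentences are too
   sparse for sentence-level estimation. Only unlabeled text enters the
   model, so estimating on pool + test text leaks no labels. `K = 50`
   topics by default; the sampler runs 300 sweeps with $\alpha = 50/K$,
   $\eta = 0.1$.
2. **Sentence-level inference**: each sentence's topic mixture is obtained
   by a deterministic EM fixed point under the fitted topic-word
   distributions (out-of-vocabulary tokens are dropped; an all-OOV
   sentence receives the uniform vector and a flag).
3. **Cosine similarity** between all sentence pairs of topic vectors.
4. **Affinity propagation** (AP) on the similarity matrix, shared
   preference = median off-diagonal similarity, damping 0.9. On
   non-convergence the messages are re-run with damping 0.95, then 0.98,
   before failing with diagnostics. A deterministic, monotone $10^{-9}$
   perturbation of the preferences breaks the exact-tie degeneracy of
   duplicate points, keeping the procedure reproducible and
   order-independent (the test suite checks the partition against an
   independent implementation and under input permutation).

`K` deliberately exceeds the number of generating topics of the synthetic
corpus. With `K` at the generating dimension, all same-topic sentences
collapse onto nearly identical topic vectors and AP returns topic-level
clusters only; a larger `K` resolves finer facets (roughly at the level of
sentence templates), which is the granularity the representative-sampling
step needs. No quantitative tuning of `K` or the AP parameters was
performed; clustering-dependent results should be read qualitatively.

## Simulation protocol

`runSimulation()` mimics a fixed-length annotation session with an
error-free annotator and a cost of one word per second: batch size 5,
initial sample 5, retrain and evaluate after every batch, stop after the
first retrain whose training set holds at least 7,200 words (about 120
minutes of annotation). "Reaches the budget" is interpreted as *first
crossing*: the final training set may exceed 7,200 words by up to one
batch. The evaluation is span-level exact-match F (start, end and type all
equal), measured on a held-out test set that is never queried, trained on,
or scored for uncertainty. An optional annotator-noise model
(`annotatorNoise`) jitters one span boundary of a labeled sentence by one
token with the given probability, for robustness studies only.

`crossValidate()` splits the deduplicated corpus into `k` folds of sizes
differing by at most one; fold *i* is the test set and the rest the pool.
Fold curves are averaged by linear interpolation onto the union of their
cost grids, restricted to the range covered by all folds — batch word
counts differ across folds, so some interpolation convention is required;
linear interpolation between adjacent evaluation points is the least
committal choice.

The area under the learning curve (ALC) summarises a curve globally:
trapezoidal area between the first and last cost point, divided by the
span of the curve times a best-achievable F of 0.75. The 0.75 ceiling
reflects what clinical NER models reach within a 120-minute session on
real corpora; synthetic-corpus models can exceed it, in which case ALC
exceeds 1 — values are comparable between methods either way. Both area
terms measure from the first curve point, so the normalisation is
symmetric.

## The synthetic corpus generator

Real clinical corpora with gold concept annotations are access-restricted,
so the package ships a generator (`generatorConfig()`,
`generateCorpus()`) whose output exercises every module: documents draw a
(mildly skewed) topic mixture; each sentence draws a topic, then one of
the topic's slot templates — medication-list lines
(`<ctx> : <treatment> 500 mg p.o. q. <ctx> day prn .`), problem
reports, and lab-result lines — and fills entity slots from per-topic
lexicons of pronounceable pseudo-words. Gold spans are recorded for the
filled entity slots. Everything is deterministic given the config seed.

Calibration targets, fixed at design time: ~11 words per sentence and
entity density (entity words / total words) ~0.24, matching the
characteristics of de-identified clinical-note corpora used for concept
extraction; realised values are checked to ±10% in the tests. Three
choices give the corpus a realistic learning-curve shape rather than a
memorisable toy:

* entity widths vary by ±1 token around the template's nominal width, so
  span boundaries are not recoverable from context position alone;
* one template frame (`<ctx> assessment : <entity> reviewed today ...`)
  is shared across all three flavours, so the entity *type* in that frame
  is only recoverable from lexical knowledge — which grows with
  annotation, exactly as in real clinical NER;
* 5% of non-entity words are replaced by random vocabulary words.

What the generator does **not** emulate: real clinical language and
spelling variation, annotation-guideline subtleties (dose-in-entity
conventions, discontinuous mentions), sentence-length heavy tails, PHI,
or annotator disagreement. Passing tests therefore demonstrate that the
machinery behaves as specified under a controlled topic-structured regime
— not that the measured effect sizes transfer to any particular clinical
corpus.

## Problem sizes and numerical choices

The shipped experiments (acceptance script and the corresponding test)
use the generator defaults: 560 documents → ~5.6k sentences, deduplicated
and split 5:1 into a pool of roughly 4,700 sentences and a test set of
~950; 10 generating topics with 3 templates each; K = 50, AP damping 0.9;
reduced CRF features; five simulation seeds per querying method. These
sizes keep a full three-method, five-seed comparison to a few minutes on
one CPU while leaving the pool large enough for clustering structure and
querying differences to be visible.

Other conventions: entity spans are stored 1-based and end-inclusive (the
R/IRanges convention) everywhere in the API, and the BIO file format is
the only serialisation of annotations; ties in any ranking (LC scores,
cluster scores) break by ascending sentence id, making every selector
deterministic given its inputs; presentation rounding of reported ratios
is half-up at two decimals (`roundHalfUp()`), applied only at reporting
time; cluster scores are computed over unlabeled sentences only, since
scoring annotated sentences would keep re-selecting exhausted clusters.
Topic-model estimation errors out when `K` exceeds the vocabulary size
rather than silently degrading.

## Known limitations

* AP is dense: memory and time grow quadratically in the pool size.
  Pools beyond ~10k sentences need subsampling or a sparse similarity
  cut-off, neither of which is implemented.
* The CRF retrains from the full labeled set each iteration (warm-started
  but not incremental); true online CRF updates are out of scope.
* The annotation-cost model of the simulation is words-as-cost. The query
  log records per-sentence word counts so time-aware querying policies
  can be studied later, but none is implemented.
* Length-unnormalised LC confounds uncertainty with sentence length; the
  normalised variant is provided, but no default switch is made, since
  the unnormalised behaviour is the subject of study.
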