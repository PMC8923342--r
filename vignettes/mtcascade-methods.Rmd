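---
title: "Cascaded shared-private multitask classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded shared-private multitask classification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcascade)
```

## The problem

Sentences from suicide notes and similar clinical text carry three
related kinds of signal: a *temporal orientation* (is the author
dwelling on the past, describing the present, or projecting into the
future?), a *sentiment polarity*, and one to three fine-grained
*emotions* (forgiveness, happiness_peacefulness, love, pride,
hopefulness, thankfulness, blame, anger, fear, abuse, sorrow,
hopelessness, guilt, information, instructions — ordered by
predominance, the first being the *primary* emotion).  Emotion
recognition is the primary task; temporality and sentiment are
auxiliary tasks whose labels are cheap to obtain by weak supervision
and whose joint learning is expected to sharpen the emotion features —
emotions like abuse or guilt tend to co-occur with past orientation and
negative polarity, hopefulness or instructions with present/future and
positive/neutral polarity.

## Model

All architectures share an embedding layer (a *fixed* lookup table —
either pre-trained vectors in the usual text format or a seeded random
table; we do not fine-tune embeddings, which keeps the parameter space
identical across vocabulary sizes and removes one source of run-to-run
variance) and a bidirectional GRU encoder whose per-token states have
width `2 * encoder_units`.  Word attention scores each state `h_t` with
`tanh(W h_t + b) . u_w`, softmax-normalizes over unmasked tokens, and
returns the convex combination of states.  Padding tokens embed to zero
and receive attention weight exactly zero, so batch padding never
influences predictions (a property the tests assert).

The full model (`architecture = "spanmlc"`) wires four identical
attention layers over the shared encoder: one shared (`SAtt`) and one
private per task.  Each task's dense layer (ReLU, width `mlp_units`)
produces `Phi_i` from its private attention context.  Subnets are
cascaded through intermediate representations

`IR_1 = [Phi_1; SAtt]`, `IR_2 = [Phi_2; SAtt; IR_1]`,
`IR_3 = [Phi_3; SAtt; IR_2]`,

in the fixed order temporal → sentiment → emotion, and the task heads
read the `IR_i`.  With 256 encoder units and 128 dense units the widths
are 640, 1280, 1920.  The ablations differ only in wiring: `mtl1` keeps
a single shared attention and puts heads directly on the dense outputs;
`mtl2` cascades the *predicted probability vectors* (`IR_2` carries the
3-dim temporal output, `IR_3` the sentiment output) — the model's own
predictions, in training as in inference, never teacher-forced truth;
`mtl3` removes the private attentions but keeps the cascade; `mtl4`
keeps shared+private attentions but severs the cascade.  The contrast
between `spanmlc`/`mtl2` and `mtl4` is what makes the cascade
observable in the gradients: the emotion loss has a non-zero gradient
with respect to the first subnet's private attention parameters exactly
when a cascade path exists (a test asserts non-zero vs exactly-zero).

Training minimizes `L = p*L1 + q*L2 + r*L3` (categorical cross-entropy
for the softmax tasks, mean binary cross-entropy over the 15 sigmoid
outputs) with Adam.  The default weights `(0.3, 0.3, 1)` down-weight
the two weakly labeled tasks; `grid_search_loss_weights()` reproduces
the selection procedure over a grid that includes this point.

### Why no deep-learning framework

The encoder, attention, cascade, losses, backpropagation and Adam are
implemented directly in vectorized base R (`R/layers.R`,
`R/forward.R`).  The network is small and the architecture is the
object of study, so owning the computation keeps every wiring decision
explicit.  Correctness rests on finite-difference oracles: the test
suite compares analytic gradients against central differences for every
parameter tensor of every architecture (tolerance `1e-6 + 1e-3 *
|g|`, the noise floor of double-precision differencing).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `embedding_dim` | 300 | word-vector width (32 is plenty for the synthetic vocabulary) |
| `encoder_units` | 256 | GRU units per direction; states have width 512 |
| `attn_units` | `2*encoder_units` | attention projection width |
| `mlp_units` | 128 | width of each `Phi_i` |
| `dropout_rate` | 0.25 | after every attention and dense output |
| `batch_size` / `epochs` | 32 / 20 | fixed schedule, no early stopping |
| `loss_weights` | (0.3, 0.3, 1) | joint-loss weights `(p, q, r)` |
| `emotion_threshold`, `max_emotion_labels` | 0.5, 3 | decision rule |
| `max_len` | 95th pct, cap 64 | sequence truncation |

Decisions the architecture description leaves open, resolved here once:
the heads read `IR_i` rather than `Phi_i` (the concatenations precede
the output layers in the reference wiring); "256 neurons" is read as
256 units *per direction* (output width 512), the common framework
convention; `SAtt` is dropout-masked once before fanning out to the
three concatenations, and the `IR_i` themselves are not re-dropped
(dropout sits after attention and dense layers only); the dense width
is unspecified upstream and defaults to 128; initialization is seeded
Glorot-uniform.  The emotion decision rule — labels with probability ≥
0.5, at most the 3 highest, arg-max fallback so the decision is never
empty — implements the "at most 3 emotions" contract with the standard
0.5 sigmoid cut.

## Weak supervision

Sentiment labels are a deterministic function of the primary emotion
through the fixed polarity partition (6 positive, 7 negative, 2 neutral
classes); `derive_sentiment_labels()` applies it and is idempotent and
insensitive to secondary emotions.  Temporal labels come from a
trainable single-task classifier (`train_temporal_classifier()`, the
same encoder–attention–softmax stack); label quality is audited by
drawing a seeded uniform sample (`sample_for_audit()`) and computing
Cohen's unweighted kappa against manual (here: generator) labels.
Kappa is the unweighted form because no ordinal structure links the
classes.

## Evaluation protocol

`stratified_folds()` implements iterative multilabel stratification
over the 15-class multi-hot matrix: labels are processed rarest-first,
each example goes to the fold with the greatest remaining demand for
that label, ties broken by the example's total label demand, then fold
capacity, then a seeded draw.  On 300–500-record synthetic corpora
every class with at least `k` positives stays within 5 percentage
points of its global proportion in every fold.  Stratifying on the
primary emotion only is available as an option.  Metrics: accuracy and
macro-F1 for the single-label tasks (classes absent from a fold's truth
are dropped from the macro average, where their F1 would be undefined);
for emotions, *mean recall* — the unweighted mean of per-class recall
over classes with at least one positive, the natural reading of a
macro recall for a skewed multi-label problem — and *samples-F1*, the
per-sentence set-F1 averaged over sentences (empty∩empty counts as 1).
Multi-fold means are simple arithmetic averages of the per-fold
reports.

## The synthetic corpus

`default_synth_spec()` encodes the label statistics of the emulated
4932-sentence corpus: label multiplicity (0.76, 0.22, 0.02); primary
emotion marginals skewed toward the over-represented information /
instructions / hopelessness classes and chosen so the induced sentiment
marginals reproduce the printed positive/negative/neutral distribution
(885/1500/2547); and a temporal-given-polarity matrix solved so the
temporal mixture reproduces the printed 2300/792/1840 marginals while
negative-polarity sentences lean toward the past and neutral ones
toward present/future.  Sentences are 5–12 synthetic tokens; each
position draws, with probability `signal_strength` (default 0.8), from
a disjoint label-indicative pool — the temporal class's pool or the
primary emotion's pool, secondary emotions at half odds — otherwise
from background vocabulary.

What this does and does not show: the generator reproduces the *label
structure* and gives the tasks a common token signal, so it exercises
the full pipeline and makes the multitask-vs-single-task comparison
meaningful; it shares no lexical, syntactic or discourse structure with
real notes, so passing tests demonstrate correct mechanics and the
directional multitask effect under correlated tasks — not clinical
performance.  Published cross-validation numbers on the real corpus
(emotion mean recall near 60%) are not reproducible without the
restricted data and pre-trained embeddings, and the package does not
attempt them.

Benchmark problem sizes used by the tests and the acceptance script —
3000-sentence training corpora, 750-sentence test sets, 10 epochs, 64
encoder units, 32-dim random embeddings — are the package's standard
desk-scale configuration: large enough that the cascaded model's
emotion mean recall reliably exceeds the single-task model's across
seeds, small enough to rerun routinely.

## Numerical notes and limitations

Cross-entropies clamp probabilities at `1e-12`; softmax subtracts the
row maximum; the attention softmax assigns exactly zero to masked
positions and errors on fully masked rows (a tokenless record is
vectorized as a single unmasked padding position, predicting from the
zero context with a warning).  Determinism: initialization, batch
shuffling, dropout and generation all run under seeds derived from the
user seed; fits with equal seeds are bit-identical.  Known limitations:
no transformer or pre-trained language-model encoder, no subword
handling (out-of-vocabulary tokens share one vector), fixed 20-epoch
schedule without early stopping, and `mtl2`'s probability cascade can
propagate confidently wrong auxiliary predictions — which is precisely
the behaviour the representation cascade is meant to avoid.
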