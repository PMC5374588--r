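---
title: "Joint neural extraction of biomedical entities and relations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint neural extraction of biomedical entities and relations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionerel)
```

## The task and the model

Given a sentence such as *"A woman who was treated for thyrotoxicosis
with methimazole developed agranulocytosis."*, the goal is to recognize
the entity mentions (two diseases, one drug) and to decide which
type-compatible pairs stand in a task-specific relation (here, one
adverse drug event between *methimazole* and *agranulocytosis*).
`bionerel` implements a single joint network for both subtasks, in two
stacked stages that share parameters.

**Shared encoder.** Each token $w_i$ is represented by the
concatenation $t_i = [\mathrm{emb}(w_i), \mathrm{emb}(p_i), r_{w_i}]$ of
a frozen word embedding, a POS-tag embedding, and a character-level
representation $r_{w_i}$. The character representation comes from a
one-layer CNN: for each character position a window of $2C+1$ character
embeddings is concatenated, passed through
$o_i = \tanh(W_1 r_{c_i} + b_1)$, and the kernel outputs are max-pooled
per dimension. Out-of-word positions use a dedicated learned padding
vector, and unknown words/characters/POS map to learned UNK rows. A
bidirectional LSTM over $t_1 \dots t_N$ yields forward states
$\overrightarrow{h}_i$ (depending only on tokens $\le i$) and backward
states $\overleftarrow{h}_i$ (tokens $\ge i$).

**Entity head.** Tagging is greedy, left to right, over BILOU labels
(Begin/Inside/Last/Unit/Outside crossed with the entity types). Step
$i$ computes
$h^e_i = \tanh(W_2[\overrightarrow{h}_i, \overleftarrow{h}_i,
\mathrm{emb}(l^e_{i-1})] + b_2)$ and
$y^e = \mathrm{softmax}(W_3 h^e_i + b_3)$; the embedding of the
previous label lets the model learn soft label-dependence constraints
(an I-label should not follow O). A START label embedding covers the
first step. Because each step conditions on the previous *decision*,
exact dynamic programming is unavailable; decoding is greedy by design,
and no CRF layer is used.

**Relation head.** For a candidate entity pair, the last tokens of the
two mentions anchor a shortest dependency path (SDP) through their
lowest common ancestor in the projective dependency tree. Each path
token contributes
$x_i = [\overrightarrow{h}_i, \overleftarrow{h}_i, \mathrm{emb}(d_i)]$,
where $d_i$ is the dependency type to its governor. A second
bidirectional LSTM runs along the path: the forward parameter set over
the two bottom-up climbs (anchor to ancestor), the backward set over
the two top-down descents, giving four final states. Mean-pooled
mention representations $r_a, r_b$ (average of
$[\overrightarrow{h}_k, \overleftarrow{h}_k]$ over each mention's
tokens) compensate for the anchor-only path. The concatenation of all
six vectors passes through
$h^r = \tanh(W_4 \cdot + b_4)$ and a softmax over the relation labels.
The label set always contains an explicit `NONE` class: the model
classifies *all* type-compatible pairs, so candidates without a gold
relation are its negative examples.

**Parameter sharing.** The relation head consumes the very
$\overrightarrow{h}, \overleftarrow{h}$ objects produced by the shared
encoder, so relation-example gradients update the encoder and both
subtasks shape the same representation. The *pipeline* ablation
(`build_pipeline_model()`, or `mode = "pipeline"`) replaces those
states by plain word embeddings in $x_i$ and in $r_a, r_b$; the two
submodels then share nothing, which is the controlled comparison for
measuring what sharing buys.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.03 | AdaGrad learning rate |
| `lambda` | 1e-8 | L2 strength, applied as per-update weight decay |
| `dim_word` | 200 | word-embedding dimension (frozen) |
| `dim_feat` | 25 | POS / dependency / label embedding dimension |
| `dim_char`, `dim_char_repr` | 25, 25 | character embeddings and kernels |
| `char_window` | 3 | character window half-width; inputs are (2·3+1)·25 = 175 |
| `dim_hidden` | 100 | each direction of the shared sentence LSTM |
| `dim_sdp_hidden` | 100 | each direction of the path LSTM |
| `dim_ner_hidden`, `dim_rel_hidden` | 100 | hidden layers of the two heads |

These are the published operating point of the model family this
package implements; with them the entity representation has dimension
2·100 = 200 and the relation hidden layer reads 4·100 + 2·200 = 800
inputs. Feature embeddings initialize uniformly in (−0.01, 0.01).
The bounds for weight matrices and LSTM parameters are not pinned down
by that operating point; we use the fan-scaled uniform
±sqrt(6/(fan_in+fan_out)), a standard choice for tanh-saturating
units. Word embeddings can be loaded from a word2vec text file
(`read_word2vec()`) and are bitwise frozen throughout training either
way.

## Training

Training is online with AdaGrad (accumulators start at zero,
stabilizer 1e-8) and cross-entropy loss `-log prob` per example, with
the global L2 term realized as weight decay `lambda * theta` added to
each update's gradient — the natural per-update rendering of a global
penalty under online learning. For each sentence the two submodels are
trained alternately: every token is a tagging example, every candidate
pair built from *gold* entities is a relation example (at inference,
candidates come from the predicted mentions instead). The tagger is
teacher-forced by default — training steps condition on the gold
previous label, inference on the predicted one; a
`teacher_forcing = FALSE` switch conditions training on the model's own
running argmax instead. `NONE` pairs are not subsampled: training on
all of them is exact and cheap at the pair counts our schemas
produce.

`update = "sentence"` (the default) performs one AdaGrad update for a
sentence's tagging examples and one for its relation examples, with a
fresh encoder pass between the two groups; `update = "example"`
recomputes the shared pass and updates after every single example.
The grouped default was chosen deliberately: it preserves the
alternating, online character of the procedure at sentence granularity
while cutting the dense-parameter update cost by roughly the number of
examples per sentence, which matters in interpreted R. The two modes
reach the same separable-task accuracy in our tests.

Determinism: `config$seed` fixes initialization, per-epoch shuffling
and fold assignment; identical seed, corpus and configuration give
bitwise-identical parameters.

## Evaluation

Scoring is strict: an entity counts only if span and type both match a
gold mention one-to-one; a relation only if its type and both argument
mentions match exactly. Matching operates on token spans after
preprocessing, since gold offsets are projected onto tokens once at
read time. `prf()` applies P = TP/(TP+FP), R = TP/(TP+FN),
F1 = 2PR/(P+R), with zero denominators giving 0. `cross_validate()`
shuffles once under the seed, holds out each fold as the test set with
the next fold as development data, and macro-averages P, R and F1
independently over folds (the unweighted mean, which is what
"macro-averaged" is taken to mean here). The error taxonomy splits
entity errors into boundary vs type (exact-span-wrong-type is a type
error; every other mismatch, including no-overlap, is a boundary
error) and relation errors by whether the argument mentions were
recognized; a missed relation counts as "entities not found" when *at
least one* argument mention is missing. `cooccurrence_baseline()`
predicts the task relation for every compatible pair given gold
mentions — its recall is an upper bound for any classifier over the
same candidates.

## The synthetic corpus generator

Real corpora for these tasks require licensed downloads and an
external parser, so the package ships a deterministic generator
(`template_spec()`, `generate_corpus()`) that emulates their
*structure*: sentences instantiate templates with a trigger verb as
the hand-authored parse root ("X - induced Y", "the patient developed
Y after taking X", "X was isolated from Y"), slots filled from small
type-specific lexicons with a multi-token fraction of 0.3 to exercise
B/I/L labels and mention-span averaging, a distractor fraction of 0.3
drawn from treatment/negation templates whose compatible pair carries
no relation (so the `NONE` class is populated), and an optional noise
rate substituting filler tokens. With noise 0 the relation label is a
deterministic function of the trigger word, hence the task is
separable and a correct implementation must essentially solve it —
the learning check trains on 500 sentences and requires ≥ 0.95 entity
and relation F1 on 100 held-out sentences within 30 epochs (in
practice one or two suffice).

What the generator does *not* emulate: real lexical statistics and
vocabulary size, parse errors, ambiguous triggers, nested or
discontinuous gold annotations (those paths are exercised with
hand-constructed fixtures instead), document-level (inter-sentence)
relations, and annotation noise. Passing the synthetic checks
therefore certifies the machinery — I/O, encoding, gradients,
training dynamics, scoring — not benchmark-level accuracy on the real
corpora, which additionally needs the real data, pre-trained
biomedical word vectors and an external parser.

## Numerical and design choices

* LSTM cells are the standard input/forget/output-gate formulation
  with tanh candidate and no peepholes; biases start at zero.
* Softmax is max-shifted; probabilities are floored at 1e-12 before
  the log (a clamp that is also surfaced by `example_loss()` with a
  warning).
* The max-pool backward routes gradient to the argmax position only,
  with first-position tie-breaking.
* Nested-entity filtering keeps the *longer* mention (ties: first
  listed): the maximal span preserves the most annotation and matches
  common practice for models that cannot represent nesting. Overlapping-but-not-nested spans are
  resolved the same way, as the tagger cannot encode them.
* The BILOU repair rule is a deterministic left-to-right scan: an
  I/L without a compatible open run starts a new mention; an unclosed
  run closes at its last compatible token. It is frozen against an
  independent reference implementation over all length-2 sequences
  and random longer ones.
* Entity anchors are literal last tokens, even when tokenization
  leaves a punctuation token at the mention edge.
* An entity pair whose anchors coincide cannot happen after nested
  filtering; `generate_candidates()` still skips such pairs with a
  warning rather than failing.
* Ablation switches (`features`) zero the corresponding input block
  instead of re-dimensioning every downstream matrix, which keeps one
  parameter layout for all ablations.
* Gradient correctness is enforced by central-difference checks
  (step 3e-5, relative error `|a−n| / max(|a|+|n|, 1e-4)` below 1e-4)
  over every trainable parameter of both modes, on small-dimension
  models where the check is exhaustive.

Problem sizes in the shipped tests were chosen to keep the default
suite fast while still exercising every code path: toy dimensions
(hidden 4–6) for differentiation and cross-validation tests, the full
published dimensions for the dimension audit and the 500/100-sentence
learning check.

## Limitations

Only intra-sentence relations are modeled: candidates never cross
sentence boundaries, so document-level relations are invisible by
construction. POS tags and dependency parses are consumed, not
produced — a CoNLL sidecar from an external parser is part of the
input contract. Training is CPU-only, single-threaded, and intended
for corpora in the tens of thousands of sentences at most; there is no
GPU path, no mini-batching across sentences, and no early stopping
beyond fixed epochs with optional F1-threshold monitoring.
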