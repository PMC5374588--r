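# bionerel

Joint neural extraction of biomedical entities and their relations,
in pure R.

Biomedical text mining routinely needs both steps at once: find the
entity mentions in a sentence (drugs and diseases; bacteria and their
habitats) and decide which pairs stand in a task-specific relation (an
adverse drug event; a Lives_In relation). Pipeline systems solve the
two subtasks independently and suffer error propagation. `bionerel`
implements a *joint* model: a character-level CNN and a shared
bidirectional LSTM encode the sentence; a greedy BILOU tagger with
previous-label feedback recognizes mentions,

```
h_i^e = tanh(W2 [h→_i, h←_i, emb(l_{i-1}^e)] + b2),   y^e = softmax(W3 h_i^e + b3)
```

and a second bidirectional LSTM along the shortest dependency path
(SDP) between two entity anchors — stacked on the same encoder states,
plus mean-pooled mention representations r_a, r_b — classifies each
candidate pair,

```
h^r = tanh(W4 [↑h_a, ↑h_b, ↓h_a, ↓h_b, r_a, r_b] + b4),   y^r = softmax(W5 h^r + b5)
```

Because the relation head reads the shared hidden states, its
cross-entropy gradients update the encoder: the two subtasks are
trained jointly, online, with AdaGrad (α = 0.03, λ = 1e-8). A
pipeline ablation (`build_pipeline_model()`) replaces the shared
states with plain word embeddings, severing the coupling. All
networks and their backpropagation are implemented in vectorized base
R and verified against numerical differentiation.

The package also provides: readers/writers for BioNLP-ST standoff
(`.txt`/`.a1`/`.a2`) and sentence-record (ADE-style) corpora with
CoNLL parse sidecars, the published preprocessing (punctuation-aware
tokenization, lowercasing, digit folding, nested/discontinuous-mention
removal with drop counting), strict-match P/R/F1 scoring with 10-fold
cross-validation and macro-averaging, an error taxonomy
(boundary/type, entity-caused/classifier-caused), a co-occurrence
baseline, and a deterministic synthetic-corpus generator so everything
is testable without downloads.

## Worked example

```r
library(bionerel)

# a deterministic synthetic ADE corpus (drug/disease mentions + relations)
spec  <- template_spec("ade", seed = 42)
train <- generate_corpus(spec, 100)
test  <- generate_corpus(template_spec("ade", seed = 43), 50)

print(train[[1]])
#> <annotated_sentence> valproic acid - induced hepatitis .
#>   2 entities, 1 relations

cfg   <- model_config(epochs = 3, seed = 1)   # published hyper-parameters
model <- train_model(train, cfg, task = "ade")

pred <- predict_corpus(model, test)
sc   <- score_corpus(test, pred)
round(rbind(entity = sc$entity, relation = sc$relation), 3)
#>          precision recall f1
#> entity           1      1  1
#> relation         1      1  1
```

The templated task is separable, so the joint model reaches perfect
strict-match F1 on held-out synthetic sentences within a few epochs —
the numbers above are what the code prints. On real corpora accuracy
is of course far lower; the generator certifies the machinery, not
benchmark performance (see the vignette).

Reading real annotation formats:

```r
dir  <- system.file("extdata", "ade_sample", package = "bionerel")
corp <- read_ade(readLines(file.path(dir, "records.ade")),
                 paste(readLines(file.path(dir, "parses.conll")), collapse = "\n"))
```

The record dialect is one sentence per line,
`text|Type,start,end;...|i,j,Type;...` with 0-based half-open
character offsets and 1-based entity indices; `read_standoff()` reads
the equivalent `.txt` + `.a1`/`.a2` standoff triple. Both expect a
CoNLL sidecar (index, token, POS, head, deprel) from an external
parser.

A thin command-line front end lives at `inst/cli/bionerel`
(`synth`, `train`, `evaluate` subcommands).

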