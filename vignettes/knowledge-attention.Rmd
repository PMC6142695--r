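---
title: "Document-level CID extraction with knowledge attention: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Document-level CID extraction with knowledge attention: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidkat)
```

## The task

Chemical-induced disease (CID) extraction asks, for one Medline abstract at a
time, which (chemical MeSH id, disease MeSH id) pairs stand in a causal
induces-relation. The annotation is at the *entity* (concept) level within the
scope of the whole article, not at the mention level: roughly a third of gold
relations are inter-sentential, i.e. their two arguments never share a
sentence. A useful model must therefore read the document, not single
sentences, and it helps enormously to consult a curated chemical-disease
knowledge base: a pair already curated as *marker/mechanism* is far more
likely to be a CID relation than one curated as *therapeutic*.

`cidkat` implements the full pipeline: PubTator corpus IO, candidate-pair
construction, text preprocessing, a hierarchical neural document encoder, an
attention mechanism over knowledge-base relation embeddings, a softmax
classifier trained by RMSprop, a MeSH-tree hypernymy post-filter, and
entity-level stratified evaluation, together with a synthetic corpus
generator that makes every stage testable offline.

## Preprocessing

For a document and one candidate pair:

* Every mention is replaced by a type-prefixed id token (`ch_d014148`,
  `ds_d062787`); mentions of the two *candidate* entities are additionally
  bracketed with boundary markers, `ch_start ch_d014148 ch_end` and
  `ds_start ds_d062787 ds_end`, so the encoder can tell the pair under
  consideration from other entities. Replacement runs right to left so
  character offsets stay valid.
* The article is split into sentences by a deterministic rule (a terminator
  followed by whitespace and an upper-case letter/digit). The title is
  sentence 1 of the article and is *also* encoded separately as the theme.
* Bare numbers (no letters) become the token `NUM`; part-of-speech tags come
  from a pluggable tagger (`rule_pos_tagger()` by default, a closed-class +
  suffix rule tagger); reserved id/marker tokens are always tagged `ENT`.

Candidate pairs are all (chemical, disease) id pairs co-occurring in the
article; a pair is positive iff it is among the article's gold relations.
`min_span` is the smallest sentence distance over all mention pairs, and the
optional span filter removes pairs with `min_span >= K` (the default `K = 4`
admits distances 0-3; we read "within K consecutive sentences" as at most
K-1 boundary crossings). Filtered *negatives* vanish; filtered *gold
positives* are kept, flagged, excluded from the model input, and counted as
false negatives by the evaluator — they can contribute to POS but never to
TP. Mentions with the unmapped id `-1` are kept in the text but never form
candidates; composite ids (`D001|D002`) split into one mention per id.

## The model

Each token is the concatenation of a word embedding (width `l1`, default
100) and a PoS embedding (width `l2`, default 10). A sentence is encoded by
a bidirectional LSTM; the two final hidden states concatenate into the
sentence vector (width `2*h1`, default 220, matching the input width). On
the sequence of sentence vectors, three document-level views are computed:

* **A^t** — a document BLSTM over the sentence vectors (width `2*h2`,
  default 440), capturing long-range, non-adjacent dependencies;
* **A^c** — a width-`w` (default 5) convolution with `f` (default 300)
  filters, `ReLU(Wc x + bc)`, max-pooled over window positions, capturing
  local context among adjacent sentences;
* **T'** — a separate BLSTM over the title, the theme of the article.

Their concatenation `A' = [A^t; A^c; T']` (960-dimensional at defaults) is
the document representation of the candidate pair.

### Knowledge attention

The knowledge base maps a pair to a subset of
`{marker/mechanism, therapeutic, inferred}`; the sequence fed to the model
is padded with the fourth type `null` to fixed length 4 (an absent pair is
`[null, null, null, null]` — "no knowledge" is itself informative, so the
padding type takes part in attention like any real type). Real relations
precede padding in a fixed canonical order (marker/mechanism, therapeutic,
inferred, null); this makes the concatenating aggregation well-defined.

Each relation embedding `r_k` (width `m`, default 200) is scored against the
document representation,

    s_k = (A' W r_k) / m,      alpha = softmax(s),

and the weighted vectors `r'_k = alpha_k * r_k` are aggregated into the
knowledge representation `K'` by one of three variants: **sum**
(`K' = sum_k r'_k`, the default), **max** (the original, unweighted row at
the argmax weight, ties to the lower index), or **con** (concatenation of
all four weighted vectors, width `4m`).

### Classification and training

`D_s = [beta1 A'; beta2 K']` (both weights fixed at 1; learnable weights
did not help the reference system) feeds an affine softmax over
{null, CID}; exact probability ties resolve to null. Training minimises
cross-entropy with RMSprop (learning rate 0.001, decay 0.9), mini-batches
of 8, and dropout 0.5 applied to the LSTM outputs (the sentence vectors and
the title vector) and to the softmax input `D_s` — the reference
description places dropout "on the LSTM and softmax layers" without fixing
input vs recurrent placement, and output dropout is the simplest reading.
The `use_kb = FALSE` ablation zeroes `K'` while keeping all shapes. With a
fixed seed, initialisation (uniform on ±0.05, padding rows pinned at zero),
shuffling and dropout masks are all deterministic, so two runs produce
identical parameters. When a development set is supplied, the parameters
with the best development F-score are kept.

All forward and backward passes are written as vectorised batched linear
algebra with hand-derived gradients; the test suite pins every building
block (attention, aggregation, convolution/max-pooling, classifier) to
independent brute-force oracles and checks the complete gradient against
central finite differences.

### Numerical and masking choices

* Right-padded positions carry the previous LSTM state through, so a
  sequence ends in the state of its last real token and an all-padding
  sentence encodes to the zero vector.
* Convolution windows containing only padding sentences are excluded from
  the max; all-zero inputs with zero bias pool to zero.
* Over-long sentences and documents are head-kept (tail truncated) at
  `n2 = 120` tokens and `n1 = 30` sentences (defaults sized to the
  reference corpus).
* Softmax computations subtract the row maximum; the cross-entropy clamps
  probabilities at 1e-12.
* Argmax ties (aggregation and prediction) break toward the lower index.

## Post-processing and evaluation

Gold CID annotation targets the most specific disease discussed. The
hypernymy filter therefore demotes a positive prediction (c, d_i) when the
article also mentions a disease d_j whose MeSH tree number *strictly
extends* a tree number of d_i at a dot boundary (`C12.777` →
`C12.777.419`, any depth, never `C12.7779`), unless d_i is mentioned within
the title span. Mere presence of the more specific disease suffices; the
filter only ever demotes.

Evaluation is entity-level: predicted pairs per document against gold
pairs, P = 100·TP/(TP+FP), R = 100·TP/POS, F = 2PR/(P+R), reported overall
and stratified into intra-sentential (`min_span == 0`) and inter-sentential
pairs, percentages to one decimal.

## The synthetic generator

`generate_corpus()` emits PubTator files, a knowledge table and a MeSH tree
with a *known* label-generating structure: `knowledge_signal` is the
probability a pair's knowledge entry is label-informative (positives carry
marker/mechanism, possibly alongside uninformative types; negatives carry
therapeutic or nothing), `text_signal` the probability the lexical trigger
"induced" appears in the chemical's sentence iff the pair is positive, and
`inter_fraction` (default 1/3, the reference corpus's share) the fraction
of pairs whose entities never co-occur in a sentence. Entity ids are
synthetic (`D91xxxx`/`D92xxxx`) and globally unique, so no real MeSH
content ships with the package and every pair has its own knowledge entry;
because surface ids are unique, a model cannot memorise entities and must
rely on the markers, the knowledge base, or the trigger. The generator does
*not* emulate real Medline language: sentences are filler tokens, there is
no discourse structure, negation, or coreference, and entity names are
meaningless. Passing signal-recovery tests therefore shows that the
architecture can find and exploit the intended signal, not that it reaches
any particular accuracy on real abstracts.

## Experiment sizes

The packaged experiments run on one CPU at reduced widths chosen to keep
the architecture intact while training in minutes: `l1 = 24`, `l2 = 6`,
`m = 8`, `n1 = 10`, `n2 = 24`, `w = 3`, `f = 16`, `h1 = h2 = 16`, on
300-document corpora split 240/60, 20 epochs for the knowledge-signal
experiment and 30 for the text-signal experiment. Under these conditions
the knowledge-signal model reaches held-out accuracy above 0.9 with the
mean attention weight of marker/mechanism on positive instances clearly
above every other type, and the no-knowledge model reaches above 0.9 on the
pure text signal; both quantities are recomputed by the test suite and by
`scripts/acceptance.R`, and no other empirical claims are made.

## Known limitations

* The rule-based sentence splitter and suffix tagger are deterministic
  stand-ins for a full NLP stack; the tagger is injectable wherever tags
  are produced.
* Full-scale corpus results require the BioCreative V CDR corpus and a CTD
  dump, which cannot be redistributed here; loaders for both formats are
  included and tested on synthetic equivalents.
* Training embeddings (word2vec/TransE) is out of scope; pretrained vector
  files can be supplied through `read_word_vectors()` /
  `read_relation_vectors()`.
* Whether the original system ordered a pair's relations canonically or in
  knowledge-dump order is unknowable from the description; the canonical
  order used here only affects the concatenating aggregation.
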