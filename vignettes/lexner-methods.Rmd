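---
title: "Methods: a dual-branch lexicon- and radical-enhanced clinical NER model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dual-branch lexicon- and radical-enhanced clinical NER model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, the choices made
where the design was genuinely open, and what the synthetic experiments do
and do not establish. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Problem setting

Clinical narratives are tagged per character with BIO-type labels over a
small inventory of medical entity types. Two resources beyond the labeled
text are assumed: an *entity dictionary* (surface string, type) and a
*radical table* (character → semantic sub-character component). Both are
cheap to obtain in practice and both carry information that small labeled
corpora cannot: the dictionary identifies exact known surfaces; radicals
generalize across rare characters that share semantics.

## 2. Encoder

**Input.** `h_t = E_c[c_t] + E_p[t]`; the absolute table `E_p` can be
zeroed by a flag (`use_absolute_position`), independently of the relative
mechanism.

**Relative position.** The encoding of a signed offset interleaves
`sin(c_i t)` and `cos(c_i t)`. The frequency schedule is the standard
`c_i = 10000^(-2i/d)`; it was left unspecified in the lineage this model
follows, and the standard schedule keeps wavelengths spanning 1 to ~10⁴
tokens. Negating the offset negates exactly the sine slots, so the four
attention terms `q k`, `q R`, `u k`, `v R` can distinguish direction. Two
open points were resolved as follows:

* All four logit terms are scaled by `1/sqrt(d_k)`. The source material is
  internally inconsistent (its relative-attention equation is unscaled, its
  fusion equation is scaled); a single consistent scale is required for the
  geometric-mean identity tested in the acceptance suite to hold exactly.
* The relative-position terms are computed against the *fused* keys. The
  two mechanisms are presented for the same encoder without stating their
  composition; fusing first is the only order in which "entity information
  participates in attention" holds for every term involving `k_j`.
* `u`, `v` are per-head learnable vectors initialized at zero, so the first
  forward pass is pure content attention.

**Entity fusion.** Maximum matching assigns each character the id of the
longest dictionary surface covering it (ties: earliest start, then lowest
id; the rule is per-position argmax, not greedy segmentation — the
per-character definition makes the output independent of scan order, and
the implementation is checked against a brute-force oracle). Matched
positions average their key/value projections with the entity embedding's
projections; unmatched positions are plain self-attention. Disabling the
flag `use_entity_fusion` reproduces a plain relative-position transformer —
the ablation is a configuration, not a code fork.

**Stack.** Per layer: fused multi-head attention → residual + layer norm →
position-wise feed-forward (inner width `4 H_c`, GELU) → residual + layer
norm. There is deliberately *no* output projection after head concatenation:
the parameter inventory of the encoder is exactly
`W_q, W_k, W_v, W_ek, W_ev, u, v` per layer, and we keep to it. Dropout
(inverted, on each sublayer output) is active only in training mode; eval
mode is bit-deterministic.

## 3. Decode heads

**Boundary CRF.** Emissions are a linear map of encoder states to scores
over `{B, I, O}`; transitions include virtual start/stop. The partition
function uses the log-space forward recursion; decoding uses Viterbi with
deterministic lowest-index tie-breaking. By default the transitions `O→I`
and `start→I` carry a −10⁴ pseudo-score (`forbid_invalid_transitions`),
configurable off. −10⁴ rather than −Inf keeps the log-sum-exp arithmetic
finite.

**Type head.** Two CNN banks with kernel widths {2, 3, 4} and same-padding
— one over encoder states, one over radical embeddings — are concatenated
per token and passed through a fully connected layer. Supervision is **per
token** (no-entity is its own class), and span types are resolved after
boundary decoding by majority vote (ties: highest mean probability, then
lowest index). The alternative — a single sentence-level vector — was
rejected because it cannot supervise multiple entities of different types
in one sentence, which the generator produces routinely.

**Angular margin.** The classifier keeps unit-norm class directions
(re-normalized after every optimizer step) and uses the SphereFace margin
`phi(theta) = (-1)^k cos(m theta) - 2k` with integer margin `m` (default
4). Because the pure margin loss is hard to optimize from scratch, the gold
logit is blended as `(lambda cos + phi)/(1 + lambda)` with `lambda`
annealed `1000 → 5` (`lambda = max(5, 1000/(1 + 0.12 step))`); early
training is thus ordinary cosine softmax. At `m = 1` the loss reduces
exactly to cosine-softmax cross-entropy (an acceptance check). Inference
uses plain cosine logits.

**Confidence.** For self-training, a sentence's confidence is
`exp((S(path) − log Z)/T)` — the geometric mean per-token probability of
the Viterbi path — multiplied by the mean max type probability over
predicted entity tokens; a sentence with no predicted entities takes the
CRF factor alone. Both factors live in [0, 1] and penalize exactly the two
failure modes pseudo-labeling suffers from (boundary and type errors).

## 4. Training

Joint loss `alpha Loss_B + beta Loss_F` with `alpha = beta = 1` by default
(the weighting was left open; equal weights keep both branches'
gradients comparable since both are per-sentence/per-token means). AdamW
with differential learning rates — encoder 1e−3, heads 1e−2 at desk scale
(no pre-training, so the encoder trains faster than the fine-tuning regime
the published scale implies, but the head/backbone ratio is preserved) —
global gradient clip 2, weight decay 0.01 on projection and filter
matrices only. FGM adversarial training perturbs the character-embedding
table by `epsilon g/||g||`, adds the loss at the perturbed point, and
restores the table exactly; it is off by default at desk scale.

**Self-training.** Rounds: pseudo-label the remaining pool, stop if
nothing passes `tau` (so `tau = 1` returns the supervised model unchanged),
admit at most 20% of the original pool per round (prevents one-round
flooding by near-duplicate easy sentences), freeze admitted labels, and
continue training on labeled + pool with the loss
`(1 − theta) mean(labeled) + theta mean(pseudo)` realized by per-sentence
weights. Defaults `tau = 0.9`, `theta = 0.3`, 3 rounds. Training continues
from the current optimizer state rather than restarting — cheaper, and the
annealing schedules stay monotone across rounds.

## 5. Synthetic world

The generator emits the three on-disk formats the package reads, plus a
manifest of every planted span. Design:

* Characters and radicals are abstract **single Unicode codepoints**
  (Latin-Extended characters, Greek radicals). Single codepoints keep a
  dictionary surface equal to the concatenation of its characters, so
  maximum matching over the on-disk format is unambiguous; a CJK skin would
  be cosmetic.
* Each of K types owns a character pool; background characters come from a
  disjoint pool (boundary detection stays learnable at a few hundred
  sentences). Entity surfaces are sampled from their type's pool;
  sentences plant a truncated-Poisson number of non-overlapping,
  non-adjacent entities into background text.
* A type-pool character takes its type's radical with probability `rho`,
  otherwise a uniform radical — `rho = 1` makes the radical a perfect type
  signal, `rho = 0` removes it.
* With probability `ambiguity`, a surface's characters are drawn from a
  *different* type's pool while its label keeps the assigned type: its
  characters and radicals then argue for the wrong type and only the
  dictionary id resolves it.

Defaults (4 types, 25 chars/pool, 60 background chars, 40 surfaces of
length 2–4, ~2 entities per sentence, 12–20 background chars per sentence,
`rho = 0.9`) describe a world a desk-scale model solves nearly perfectly —
deliberately, since the end-to-end acceptance check asks whether the full
pipeline can recover what was planted, not whether the task is hard.

**What a green test does not establish.** The generator has no discourse
structure, no negation, no nested entities, no tokenization noise, and its
background vocabulary is disjoint from entity vocabulary; absolute F1 on it
says nothing about benchmark corpora. The experiments support *directional*
claims only (fusion helps when surfaces are ambiguous and sparse; radicals
help when character statistics are sparse; self-training does not hurt at
30% labels).

**Ablation corpora.** Two non-default worlds make the ablations
discriminative, both chosen for information-theoretic reasons rather than
tuned: (a) the fusion ablation uses a 200-surface dictionary over 250
sentences (~2.5 occurrences per surface) with `ambiguity = 0.5` — with the
default 40-surface dictionary every surface recurs often enough that a
character-level memorizer reaches perfect F1 and the dictionary channel is
redundant; sparse surface statistics restore the intended property that
ambiguous surfaces are resolvable only via the dictionary id. (b) the
radical ablation uses large pools (60 chars/type), a 120-surface dictionary
and 150 sentences at `rho = 0.95`: character-level evidence is sparse while
the 10-symbol radical channel stays dense, which is precisely the regime
where sub-character features should pay off.

## 6. Numerical and degenerate-input choices

* All softmax/partition computations are in log space with max-shift;
  attention logits are checked finite and the failing layer named.
* Zero-norm type features would make `cos theta` undefined; the guard
  treats their cosines as 0.
* `phi`'s derivative divides by `sin theta`; the denominator is floored at
  1e−6 (the `-2k` kink set has measure zero and is ignored, as is standard).
* Raw boundary predictions may violate the BIO scheme before CRF
  constraints are learned: an orphan `I` opens a new span; `merge_labels`
  therefore total-izes any boundary/type pair.
* Empty corpora, empty dictionaries, sentences longer than `max_len`, and
  out-of-range entity ids raise immediately with context.
* Ties anywhere (Viterbi, argmax types, span votes, matching) break toward
  the lowest index / earliest position, so every run is reproducible.

## 7. Known limitations

* Pure-R training: ~10 ms per sentence per epoch at desk scale. The
  paper-scale regime (width 768, 12 layers) is configurable but not
  practical without compiled code or hardware acceleration.
* No pretrained embeddings; the radical-vector load hook accepts external
  vectors but none ship with the package.
* Nested entities are out of scope; the CRF emits one flat segmentation.
* The entity-fusion mechanism uses one embedding per dictionary *entry*;
  unseen-in-training entries contribute an untrained row, so fusion's
  benefit concentrates on entries with at least a few training occurrences.
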