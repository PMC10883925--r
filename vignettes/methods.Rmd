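---
title: "Methods: transformer-based stability screening of deep eutectic solvent mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transformer-based stability screening of deep eutectic solvent mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Natural deep eutectic solvents (NADES) are mixtures of natural compounds —
sugars, polyols, organic acids, amines, quaternary ammonium salts — whose
melting point lies far below those of the pure components, leaving the
mixture liquid at room temperature. Discovering a new NADES means finding
both the right set of components *and* the right molar ratio, a search that
is mostly empirical. `nadescreen` treats this as a language problem: a
mixture is written as a single line of text and a transformer classifier
learns to predict, from that line alone, whether the mixture forms a stable
solvent (liquid and stable for more than a week at room temperature,
label 1) or not (label 0).

The pipeline has two stages:

1. **Pre-training.** A small ELECTRA-style model is trained on an unlabeled
   reaction corpus (one reaction per line, reactants and products in SMILES
   separated by the non-SMILES character `>`). A *generator* network does
   masked-language modeling; a larger *discriminator* is trained on
   replaced-token detection — for every position, decide whether the token
   was swapped in by the generator. The joint loss is
   $L = L_{\mathrm{MLM}} + \lambda\, L_{\mathrm{RTD}}$ with the canonical
   $\lambda = 50$.
2. **Fine-tuning.** The discriminator keeps its encoder, drops the
   replaced-token head, and receives a freshly initialized two-class head.
   It is trained on a small labeled mixture database; the *stability score*
   of a mixture is the softmax probability of the stable class, and a
   mixture is called stable when the score is strictly greater than 50%.

A screening engine then generates a large universe of random candidate
mixtures, scores them in batches, filters them by a compound of interest,
bins the score distribution in 5-percentage-point intervals, and exports
ranked CSV results.

## Mixture encoding

A mixture is a multiset of (compound, integer coefficient) pairs. It is
rendered as a single line by sorting components lexicographically by their
canonical SMILES (so the encoding is invariant under component
permutation), prefixing each component with a *ratio token* `[R1]`..`[R10]`
and joining components with `.`:

```
2 ethanol : 1 water   ->   [R2]CCO.[R1]O
```

Single-token ratios keep sequences short, and — because they never occur in
reaction SMILES — they are guaranteed to be absent from the pre-training
corpus, which is exactly the property the original recipe calls for. The
reference work never prints an example of its ratio characters, so this
syntax is this package's own choice.

Tokenization is the community-standard SMILES regex scheme: bracket atoms
(and the bracketed special tokens) are single tokens, `Cl`/`Br` are single
tokens, every other character is its own token. The tokenizer is lossless;
concatenating the tokens reproduces the input byte for byte. The
vocabulary places the 16 special tokens first, then corpus tokens by
descending frequency with lexicographic (byte-order) tie-breaks, truncated
to the configured cap (30,000 in the reference configuration — far more
than any SMILES corpus actually yields).

Canonicalization is a pluggable contract. The package default is a
syntax-checking identity mapping, so the core runs without a chemistry
engine; an RDKit bridge through an external `python` interpreter is
provided and is used as the independent oracle in the test suite. Under
either implementation the contract is the same: deterministic, idempotent,
and an explicit parse error on malformed input.

## Model and parameters

| parameter | default | note |
|---|---|---|
| generator / discriminator depth | 4 / 16 blocks | reference-scale; only the generator < discriminator sizing matters to the method |
| desk-scale depth | 1 / 2 blocks | `electra_desk_config()`, used throughout tests |
| hidden size / heads / FFN | 64 / 4 / 128 | desk-scale width |
| mask rate | 0.15 | canonical ELECTRA masking |
| $\lambda$ (RTD weight) | 50 | canonical ELECTRA |
| pre-train epochs | 40 (desk: 8) | reference value |
| fine-tune max sequence length | 128 tokens | longer inputs truncate with a warning |
| fine-tune batch size | 32 | reference value |
| fine-tune learning rate | 4e-5 | reference value |
| fine-tune epochs | 15 | the "optimum" setting; 40 reproduces the overfit regime |
| threshold $\tau$ | 0.5 | label 1 requires score *strictly* above $\tau$ |

The encoder is a pre-LayerNorm transformer with learned positional
embeddings, written directly in base R with exact hand-derived
backpropagation (verified against central finite differences in the test
suite) and Adam. "Hidden layers 4 and 16" in the reference description is
read as transformer-block depth; optimizer and schedule are unstated there,
so the package records its own choices (Adam, constant learning rate, no
warmup) in the configuration objects. Generator and discriminator keep
separate embedding tables (canonical ELECTRA ties them; at desk scale the
difference is bookkeeping, not behavior).

Two choices deserve explanation because the reference leaves them open:

* **Pooling.** Sequence classification usually reads the `[CLS]` state. At
  a learning rate of 4e-5 for 15 epochs on ~900 examples, Adam can move
  each weight by at most `epochs x batches x lr` ≈ 0.02 — enough to
  restructure weights initialized at std 0.02, but not enough to train an
  attention-routed `[CLS]` pathway from desk-scale scratch. The classifier
  therefore pools mean *and* max over the real positions of the final
  layer, which exposes token-composition features (how much oxygen, is
  nitrogen present, which ratio tokens occur) to the linear head directly.
* **Pre-training learning rate.** The reference specifies only the
  fine-tuning rate. Desk-scale pre-training uses Adam at 2e-4 rather than a
  conventional hotter rate, and the reason is the same displacement
  arithmetic as above: pre-training at 1e-3 grows encoder weights to ~6x
  their initialization scale, after which the 4e-5 fine-tuning budget
  cannot restructure them — measured on this package, such a pre-trained
  encoder *delayed* fine-tuning instead of helping it (stuck at MCC 0.0
  where a from-scratch baseline reached 0.4–0.75). At 2e-4 the encoder
  stays plastic: with the full ~900-record training set, fine-tuning the
  pre-trained encoder escapes the majority-class plateau around epoch 5–6
  and saturates near MCC 0.9–0.97 across every world and seed measured.
* **What pre-training does and does not buy here.** On this synthetic
  world a from-scratch encoder, trained identically, also saturates near
  MCC 0.9 at full scale — the latent rule is easy enough that the 435
  fine-tuning steps dominate, so no *excess* of the pre-trained model over
  the scratch baseline is reliably observable. Near the critical step
  count (~300 records, ~135 steps) outcomes of both arms are chaotic
  across seeds: either arm may or may not escape the plateau within 15
  epochs, and measured comparisons flip sign between worlds. The test
  suite therefore asserts what is stable — the pre-trained pipeline
  learns (train MCC ≥ 0.9, held-out MCC ≥ 0.4 under the reference
  protocol) — and this vignette, not a coin-flip test, records the
  baseline-comparison finding.
* **Head initialization.** The two-class head starts at exactly zero, so an
  untrained classifier scores every mixture at exactly 0.5 and — because the
  threshold is strict — labels everything unstable. That makes the
  zero-epoch baseline exactly chance level and the tie-at-0.5 convention
  self-consistent.

Model selection: the reference picks epoch 15 by watching the test curve.
The default here is `selection = "final"` (fixed-epoch protocol, which is
what the acceptance run uses); `selection = "validation"` carves 10% off
the training set and picks the best validation-MCC epoch so the test set
never guides selection; `selection = "paper"` reproduces the original
test-curve behavior on demand.

## Data augmentation and screening

The labeled database is imbalanced (800 stable : 200 unstable) because the
literature mostly reports successes. *Mixture Generator Alpha* rebalances
training by adding random mixtures labeled unstable: 3–5 distinct
components among the 198-compound library, coefficients 1–10. Negatives
colliding with the known database (or with each other) under the multiset
equality rule are rejected and redrawn — the reference does not state this
check, but it removes label noise at negligible cost. Mixture equality is
the exact multiset of (canonical SMILES, coefficient) pairs with **no**
ratio rescaling, because 1:1:1 and 4:1:1 versions of the same components
are genuinely different formulations with different outcomes.

*Mixture Generator Beta* produces the unlabeled screening universe with the
same generator minus labels and collision checks. With k components drawn
without replacement from N compounds the probability that a given compound
appears is $\mathbb{E}[k]/N$ by symmetry — for k uniform on {3,4,5} over
198 compounds, $4/198 \approx 2.02\%$, matching the ~2% marker-compound
fraction the screening stage reports. Score histograms use left-open
5-point bins labeled `50.1-55` … `95.1-100` (a score of exactly 85% falls
in `80.1-85`), binning everything above 50%.

## The synthetic world

The real labeled database and the full reaction corpus are not
redistributable, so the package ships a generator for a synthetic stand-in
world: 198 valid-by-construction chain SMILES over C/O/N (12% of compounds
carry 1–2 nitrogens, the rest are C/O-only; oxygen appears at 35% of chain
positions), one fixed marker compound playing ibuprofen's screening role,
and a deterministic latent stability rule

$$\mathrm{stable}(m) = 1 \iff o_{lo} \le \textstyle\sum_i c_i\,\mathrm{O}_i \le o_{hi}
\;\wedge\; \textstyle\sum_i c_i\,\mathrm{N}_i \ge n_{min}$$

with defaults $o_{lo} = 2$, $o_{hi} = 90$, $n_{min} = 1$. Both sums are
visible in the encoded token stream (ratio tokens carry the $c_i$, O/N are
literal tokens), so a token-level model can in principle learn the rule —
which is what makes the training-based acceptance checks meaningful rather
than vacuous.

Why these values? They were fixed from pilot simulations of *acceptance
rates only*, before any model training, to satisfy three constraints at
once:

* the labeled database (2–3 components, literature-like) is generated by
  rejection sampling at workable acceptance rates for both classes, with
  the natural imbalance close to the 4:1 of the real database;
* database negatives are dominated (~98%) by the nitrogen condition, so a
  trivial logistic baseline on the two weighted heteroatom sums separates
  the database almost perfectly — the suite's guarantee that the
  transformer has signal to find;
* the oxygen window's upper bound caps the coefficient-heavy tail, which
  grows with component count, so random 3–5-component mixtures are
  unstable more often than database-like 2–3-component ones.

**Known limitation.** These constraints genuinely conflict. A rule whose
negatives are nearly linearly separable through a monotone feature makes
mixtures with *more* components more likely stable, so in this world only
~60% of random 3–5-component mixtures are truly unstable — the
augmentation premise ("randomly mixed chemicals almost never form a stable
solvent") holds much more weakly than in reality. Green augmentation tests
therefore establish that random negatives do not hurt and qualitatively
help; they do not reproduce the near-zero false-label rate of the real
augmentation strategy. Likewise, the synthetic world has none of real
NADES data's hydrogen-bond physics, stereochemistry or charged species; a
green training run establishes that the pipeline can extract a
token-visible rule at the stated optimization budget, not that it predicts
real eutectic chemistry.

The synthetic reaction corpus writes lines `A.B>C` with `A`, `B` drawn from
the library and `C = A` with a terminal oxygen appended — a deterministic
"oxidation" edit that gives the corpus learnable reactant/product
statistics while keeping every line a one-`>` record.

## Numerical and procedural choices

* Splits: `|test| = round(fraction x N)`, uniform without replacement,
  unstratified (the reference protocol); stratified splitting is available
  but off by default. Cross-set deduplication removes training mixtures
  equal to a test mixture under the multiset rule and reports them.
* Degenerate MCC (a zero marginal) returns 0 by convention and logs the
  event; F1 is 0 when its denominator vanishes.
* Score ties in ranked output are broken by byte order of the encoded
  string; all sorting in the package uses locale-independent byte order.
* Sequences longer than 128 tokens truncate with a warning, never an error.
* Exact ternary combinatorics are computed in double-precision integer
  arithmetic with an explicit error beyond $n(n-1)(n-2) \ge 2^{53}$
  (pool sizes around 200,000), since no arbitrary-precision integer
  library is assumed.
* All randomness flows through explicitly seeded R RNG streams that are
  saved and restored, so identical seeds give byte-identical artifacts on
  the same machine, and seeded package calls never perturb the caller's
  RNG state.
* Desk-scale training runs in the test suite are scaled down (300-record
  DB, shortened schedules) where a property is qualitative; the
  acceptance-target run itself uses the full stated setup (1000-record DB,
  100 negatives, 15 epochs at 4e-5).

## What the package does not claim

Absolute reference numbers that depend on the authors' private database,
the full million-reaction corpus and GPU-scale training — test MCC 0.42,
accuracy/F1 0.82, loss 0.56, the 337 predicted stable mixtures, specific
histogram counts, and the wet-lab validation — are out of scope by design.
The acceptance suite checks exact in-scope quantities (combinatorics,
dataset plumbing, universe composition) and scaled-down surrogates of the
training behavior (the MCC ≥ 0.40 augmentation bound, the overfitting
signature) on the synthetic world.
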