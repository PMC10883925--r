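Package: nadescreen
Title: Transformer-Based Stability Screening of Deep Eutectic Solvent Mixtures
Version: 0.1.0
Authors@R:
    person("nadescreen", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether a mixture of natural compounds at given integer
    stoichiometric ratios forms a stable (natural) deep eutectic solvent.
    Implements SMILES tokenization with stoichiometric-ratio special tokens,
    ELECTRA-style pre-training (a small generator proposes token replacements,
    a discriminator learns replaced-token detection) on a reaction corpus,
    fine-tuning of the discriminator into a binary stability classifier with
    random-negative data augmentation, and a virtual-screening engine that
    generates large candidate-mixture universes, scores them with a softmax
    stability probability, filters by compound, bins scores and exports ranked
    CSV results.  The neural network is a small, self-contained transformer
    encoder written in base R, sized for CPU-scale experiments, and ships with
    a synthetic-data module that emulates the reaction corpus and labeled
    mixture database with a deterministic, token-visible latent stability rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
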