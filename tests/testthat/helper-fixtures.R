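# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code (no stored binaries); sizes are desk-scale so the whole
# suite stays within a CPU time budget.

options(nadescreen.verbose = FALSE)

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_world <- function() fx("world", function() synthetic_world(seed = 101L))

# small labeled DB (240 stable / 60 unstable) for fast model tests
fx_db_small <- function() fx("db_small", function()
  make_labeled_db(fx_world(), n = 300L, n_stable = 240L, seed = 102L))

fx_split_small <- function() fx("split_small", function()
  split_dataset(fx_db_small(), 0.2, seed = 103L))

fx_corpus <- function() fx("corpus", function()
  make_reaction_corpus(fx_world(), n_lines = 500L, seed = 104L))

# the desk-profile pre-trained model shared by model/screen/cli tests
fx_model <- function() fx("model", function()
  pretrain(fx_corpus(), config = electra_desk_config(), seed = 105L))

# a quick fine-tuned classifier (non-trivial scores, not the t4 protocol)
fx_classifier <- function() fx("classifier", function() {
  split <- fx_split_small()
  negs <- generate_negative_mixtures(50L, known_db = fx_db_small(),
                                     library = fx_world()$library, seed = 106L)
  train <- augment_training_set(split$train, negs, seed = 106L)
  finetune_classifier(fx_model(), train, split$test,
                      config = finetune_config(epochs = 8L), seed = 107L)
})

# random mixture drawn from a library (for round-trip style properties)
random_mixture <- function(library, k_range = 2:5, coef_range = 1:10) {
  k <- sample(k_range, 1L)
  idx <- sample.int(nrow(library), k)
  mixture(library$smiles[idx], sample(coef_range, k, replace = TRUE))
}
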