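# ELECTRA pre-training and classifier fine-tuning contracts.
# Training runs here use the shared desk-scale fixtures (see
# helper-fixtures.R); schedules are deliberately short to stay inside the
# suite's CPU budget, with the full protocol exercised in test-acceptance.R.

test_that("corrupt_sequence: rate rule, special-token immunity, determinism", {
  vocab <- build_vocabulary(fx_corpus(), V = 200L)
  toks <- rep("C", 20L)
  # 20 eligible tokens at rate 0.15 -> round(3) = 3 masked positions
  out <- corrupt_sequence(toks, 0.15, vocab, seed = 1L)
  expect_length(out$masked, 3L)
  expect_identical(sum(out$tokens != toks), sum(out$flags))
  # rate 0: untouched input, all flags false
  out0 <- corrupt_sequence(toks, 0, vocab, seed = 1L)
  expect_identical(out0$tokens, toks)
  expect_false(any(out0$flags))
  # determinism under a fixed seed
  expect_identical(corrupt_sequence(toks, 0.15, vocab, seed = 7L),
                   corrupt_sequence(toks, 0.15, vocab, seed = 7L))
  # special tokens are never corrupted
  mixed <- c("[CLS]", "[R2]", "C", "C", "O", ">", "[SEP]")
  for (s in 1:20) {
    oc <- corrupt_sequence(mixed, 0.5, vocab, seed = s)
    expect_identical(oc$tokens[c(1L, 2L, 6L, 7L)], mixed[c(1L, 2L, 6L, 7L)])
  }
})

test_that("pretraining learns (loss decreases) and is seed-deterministic", {
  model <- fx_model()
  mt <- model$metrics
  expect_identical(nrow(mt), 8L)
  expect_lt(mt$train_loss[nrow(mt)], mt$train_loss[1L])
  # train and test losses track each other on i.i.d. synthetic lines
  # (the convergence pattern, not any absolute value)
  expect_lt(abs(mt$train_loss[nrow(mt)] - mt$test_loss[nrow(mt)]),
            0.5 * mt$train_loss[1L])
  # determinism: re-runs from one seed give identical trajectories
  cfg2 <- electra_desk_config(pretrain_epochs = 2L)
  m1 <- pretrain(fx_corpus()[1:100], config = cfg2, seed = 9L)
  m2 <- pretrain(fx_corpus()[1:100], config = cfg2, seed = 9L)
  expect_equal(m1$metrics, m2$metrics, tolerance = 1e-12)
  expect_error(pretrain(character(0)), "empty corpus")
})

test_that("fine-tuning records per-epoch metrics and a 0-epoch head is chance level", {
  fit <- fx_classifier()
  mt <- fit$metrics
  expect_identical(names(mt),
                   c("epoch", "train_loss", "test_loss", "train_mcc", "test_mcc"))
  expect_identical(nrow(mt), 8L)
  expect_true(all(mt$train_loss >= 0))
  expect_true(all(abs(mt$train_mcc) <= 1 & abs(mt$test_mcc) <= 1))
  # 0 epochs: untouched zero head scores everything exactly 0.5 -> label 0,
  # MCC degenerates to the chance-level convention 0 on a balanced set
  sp <- fx_split_small()
  pos <- sp$test[mixture_labels(sp$test) == 1L]
  neg <- sp$test[mixture_labels(sp$test) == 0L]
  n_take <- min(10L, length(pos), length(neg))
  balanced <- c(pos[seq_len(n_take)], neg[seq_len(n_take)])
  fit0 <- finetune_classifier(fx_model(), sp$train, balanced,
                              config = finetune_config(epochs = 0L), seed = 1L)
  sc <- predict_scores(fit0$classifier, balanced)
  expect_true(all(sc$score == 0.5))
  expect_true(all(sc$label == 0L))
  expect_identical(mcc(confusion_matrix(mixture_labels(balanced), sc$label)), 0)
  expect_error(finetune_classifier(fx_model(), list(), sp$test), "empty training set")
})

test_that("fine-tuning is seed-deterministic", {
  sp <- fx_split_small()
  cfg <- finetune_config(epochs = 2L)
  f1 <- finetune_classifier(fx_model(), sp$train[1:64], sp$test[1:32],
                            config = cfg, seed = 11L)
  f2 <- finetune_classifier(fx_model(), sp$train[1:64], sp$test[1:32],
                            config = cfg, seed = 11L)
  expect_equal(f1$metrics, f2$metrics, tolerance = 1e-12)
})

test_that("predict_scores: softmax range, complement normalization, batching invariance", {
  fit <- fx_classifier()
  sp <- fx_split_small()
  sc1 <- predict_scores(fit$classifier, sp$test, batch_size = 1L)
  sc64 <- predict_scores(fit$classifier, sp$test, batch_size = 64L)
  expect_true(all(sc1$score > 0 & sc1$score < 1))
  expect_equal(sc1$score, sc64$score, tolerance = 1e-12)
  expect_identical(sc1$label, as.integer(sc1$score > 0.5))
  # stable and unstable probabilities are complements (softmax over 2 logits)
  pad_idx <- unname(fit$classifier$vocab$token_to_id["[PAD]"]) + 1L
  ids <- text_to_ids(sc1$encoded[1:8], fit$classifier$vocab, 128L)
  lg <- classifier_logits(fit$classifier$params, fit$classifier$cfg, ids, pad_idx)$logits
  p_stable <- 1 / (1 + exp(lg[, 1] - lg[, 2]))
  p_unstable <- 1 / (1 + exp(lg[, 2] - lg[, 1]))
  expect_equal(p_stable + p_unstable, rep(1, 8), tolerance = 1e-12)
  expect_equal(p_stable, sc1$score[1:8], tolerance = 1e-12)
})

test_that("sequences beyond max_seq_length are truncated with a warning, never an error", {
  fit <- fx_classifier()
  lib <- fx_world()$library
  big <- mixture(rep(lib$smiles[order(-nchar(lib$smiles))[1:10]], 2L),
                 rep(5L, 20L))
  expect_gt(length(tokenize_smiles(encode_mixture(big))), 128L)
  expect_warning(sc <- predict_scores(fit$classifier, list(big)), "truncated")
  expect_identical(nrow(sc), 1L)
})

test_that("model directories round-trip through save_model/load_model", {
  dir <- withr::local_tempdir()
  model <- fx_model()
  save_model(model, file.path(dir, "m"))
  expect_true(all(file.exists(file.path(dir, "m",
    c("config.json", "vocab.txt", "generator.rds", "discriminator.rds",
      "metrics.csv")))))
  back <- load_model(file.path(dir, "m"))
  expect_s3_class(back, "electra_model")
  expect_identical(back$vocab$tokens, model$vocab$tokens)
  # classifier round-trip preserves predictions exactly
  fit <- fx_classifier()
  save_model(fit$classifier, file.path(dir, "c"), metrics = fit$metrics)
  cback <- load_model(file.path(dir, "c"))
  sp <- fx_split_small()
  expect_equal(predict_scores(cback, sp$test[1:16])$score,
               predict_scores(fit$classifier, sp$test[1:16])$score,
               tolerance = 1e-12)
})

test_that("augmentation does not hurt held-out MCC (5-seed means, scaled-down run)", {
  # qualitative claim behind the data-augmentation strategy: adding random
  # negatives to the imbalanced training set should not lower test MCC.
  # Scaled down to the 300-record fixture DB and 6 epochs for CPU budget.
  sp <- fx_split_small()
  model <- fx_model()
  cfg <- finetune_config(epochs = 6L)
  m_aug <- numeric(5); m_plain <- numeric(5)
  for (s in 1:5) {
    negs <- generate_negative_mixtures(100L, known_db = fx_db_small(),
                                       library = fx_world()$library,
                                       seed = 300L + s)
    tr_aug <- augment_training_set(sp$train, negs, seed = 300L + s)
    m_aug[s] <- tail(finetune_classifier(model, tr_aug, sp$test,
                                         config = cfg, seed = 400L + s)$metrics$test_mcc, 1L)
    m_plain[s] <- tail(finetune_classifier(model, sp$train, sp$test,
                                           config = cfg, seed = 400L + s)$metrics$test_mcc, 1L)
  }
  expect_gte(mean(m_aug), mean(m_plain))
})
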