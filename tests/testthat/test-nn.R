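# Numerical core: exact backpropagation (checked against central finite
# differences), softmax/sigmoid losses, Adam determinism.

tiny_cfg <- list(V = 12L, d = 8L, H = 2L, ffn = 16L, n_layers = 2L,
                 max_pos = 10L, init_std = 0.2)

tiny_batch <- function() {
  list(ids = rbind(c(3L, 7L, 9L, 11L, 1L, 1L), c(5L, 6L, 8L, 10L, 12L, 4L)),
       mask = rbind(c(1L, 1L, 1L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L, 1L, 1L)))
}

# relative error with an absolute floor, standard for gradient checking
rel_err <- function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b))

test_that("encoder + pooled classification gradients match finite differences", {
  set.seed(42)
  p <- encoder_init(tiny_cfg)
  p$cls.W <- matrix(rnorm(16 * 2, 0, 0.2), 16, 2)
  p$cls.b <- rnorm(2, 0, 0.1)
  bt <- tiny_batch()
  labels <- c(1L, 0L)
  loss_fn <- function(pp) {
    fw <- encoder_forward(pp, tiny_cfg, bt$ids, bt$mask)
    pl <- pool_fwd(fw$out, bt$mask, 2L, 6L)
    lg <- pl$pooled %*% pp$cls.W + rep(pp$cls.b, each = 2L)
    softmax_ce(lg, labels + 1L)$loss
  }
  fw <- encoder_forward(p, tiny_cfg, bt$ids, bt$mask)
  pl <- pool_fwd(fw$out, bt$mask, 2L, 6L)
  lg <- pl$pooled %*% p$cls.W + rep(p$cls.b, each = 2L)
  ce <- softmax_ce(lg, labels + 1L)
  dY <- pool_bwd(ce$dlogits %*% t(p$cls.W), pl, bt$mask, 2L, 6L, nrow(fw$out))
  g <- encoder_backward(p, tiny_cfg, fw$cache, dY)
  g$cls.W <- crossprod(pl$pooled, ce$dlogits)
  g$cls.b <- colSums(ce$dlogits)
  eps <- 1e-5
  for (nm in names(g)) {
    x <- p[[nm]]
    for (ii in sample(length(x), min(length(x), 4L))) {
      pp <- p
      pp[[nm]][ii] <- pp[[nm]][ii] + eps; lp <- loss_fn(pp)
      pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps; lm <- loss_fn(pp)
      num <- (lp - lm) / (2 * eps)
      if (abs(num) < 1e-10 && abs(g[[nm]][ii]) < 1e-10) next
      expect_lt(rel_err(num, g[[nm]][ii]), 1e-5)
    }
  }
})

test_that("token-level MLM and RTD head gradients match finite differences", {
  set.seed(43)
  p <- encoder_init(tiny_cfg)
  p$mlm.W <- matrix(rnorm(8 * 12, 0, 0.2), 8, 12)
  p$mlm.b <- rnorm(12, 0, 0.1)
  bt <- tiny_batch()
  sel <- c(2L, 9L)                 # masked rows in the flattened layout
  target <- c(4L, 6L)
  loss_mlm <- function(pp) {
    fw <- encoder_forward(pp, tiny_cfg, bt$ids, bt$mask)
    lg <- fw$out[sel, , drop = FALSE] %*% pp$mlm.W + rep(pp$mlm.b, each = 2L)
    softmax_ce(lg, target)$loss
  }
  fw <- encoder_forward(p, tiny_cfg, bt$ids, bt$mask)
  lg <- fw$out[sel, , drop = FALSE] %*% p$mlm.W + rep(p$mlm.b, each = 2L)
  ce <- softmax_ce(lg, target)
  dY <- matrix(0, nrow(fw$out), tiny_cfg$d)
  dY[sel, ] <- ce$dlogits %*% t(p$mlm.W)
  g <- encoder_backward(p, tiny_cfg, fw$cache, dY)
  g$mlm.W <- crossprod(fw$out[sel, , drop = FALSE], ce$dlogits)
  g$mlm.b <- colSums(ce$dlogits)
  eps <- 1e-5
  for (nm in c("Etok", "l1.Wq", "l2.W1", "mlm.W", "mlm.b", "lnf.g")) {
    x <- p[[nm]]
    for (ii in sample(length(x), min(length(x), 4L))) {
      pp <- p
      pp[[nm]][ii] <- pp[[nm]][ii] + eps; lp <- loss_mlm(pp)
      pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps; lm <- loss_mlm(pp)
      num <- (lp - lm) / (2 * eps)
      if (abs(num) < 1e-10 && abs(g[[nm]][ii]) < 1e-10) next
      expect_lt(rel_err(num, g[[nm]][ii]), 1e-5)
    }
  }
  # RTD (sigmoid) head on all real positions
  p$rtd.w <- matrix(rnorm(8, 0, 0.2), 8, 1)
  p$rtd.b <- 0.05
  rows <- c(1:4, 7:12)
  flags <- c(0, 1, 0, 0, 1, 0, 0, 0, 1, 0)
  loss_rtd <- function(pp) {
    fw <- encoder_forward(pp, tiny_cfg, bt$ids, bt$mask)
    lg <- as.vector(fw$out[rows, , drop = FALSE] %*% pp$rtd.w) + pp$rtd.b
    sigmoid_bce(lg, flags)$loss
  }
  fw <- encoder_forward(p, tiny_cfg, bt$ids, bt$mask)
  lgv <- as.vector(fw$out[rows, , drop = FALSE] %*% p$rtd.w) + p$rtd.b
  sb <- sigmoid_bce(lgv, flags)
  dY <- matrix(0, nrow(fw$out), tiny_cfg$d)
  dY[rows, ] <- sb$dlogits %*% t(p$rtd.w)
  g <- encoder_backward(p, tiny_cfg, fw$cache, dY)
  g$rtd.w <- crossprod(fw$out[rows, , drop = FALSE], sb$dlogits)
  g$rtd.b <- sum(sb$dlogits)
  eps <- 1e-5
  for (nm in c("l2.Wv", "rtd.w", "rtd.b", "Epos")) {
    x <- p[[nm]]
    for (ii in sample(length(x), min(length(x), 4L))) {
      pp <- p
      pp[[nm]][ii] <- pp[[nm]][ii] + eps; lp <- loss_rtd(pp)
      pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps; lm <- loss_rtd(pp)
      num <- (lp - lm) / (2 * eps)
      if (abs(num) < 1e-10 && abs(g[[nm]][ii]) < 1e-10) next
      expect_lt(rel_err(num, g[[nm]][ii]), 1e-5)
    }
  }
})

test_that("softmax scoring matches closed forms and normalizes", {
  # logits (0, 0): score exactly 0.5; threshold is strict, so label 0
  expect_equal(1 / (1 + exp(0 - 0)), 0.5)
  expect_identical(as.integer(0.5 > 0.5), 0L)
  # logits (unstable 1, stable 3): e^3 / (e^1 + e^3)
  sc <- 1 / (1 + exp(1 - 3))
  expect_equal(sc, exp(3) / (exp(1) + exp(3)), tolerance = 1e-12)
  expect_equal(sc, 0.8808, tolerance = 1e-4)
  # softmax_ce probabilities are in (0,1) and rows sum to 1
  set.seed(5)
  lg <- matrix(rnorm(40, sd = 3), 20, 2)
  ce <- softmax_ce(lg, sample(1:2, 20, replace = TRUE))
  expect_true(all(ce$probs > 0 & ce$probs < 1))
  expect_equal(rowSums(ce$probs), rep(1, 20), tolerance = 1e-12)
})

test_that("Adam steps are deterministic and reduce a convex toy loss", {
  set.seed(8)
  run <- function() {
    p <- list(w = matrix(rnorm(4, 0, 1), 2, 2))
    st <- adam_init(p)
    target <- matrix(c(1, -2, 3, 0.5), 2, 2)
    losses <- numeric(50)
    for (i in 1:50) {
      g <- list(w = 2 * (p$w - target))
      losses[i] <- sum((p$w - target)^2)
      up <- adam_step(p, g, st, lr = 0.1)
      p <- up$params; st <- up$state
    }
    losses
  }
  set.seed(8); l1 <- run()
  set.seed(8); l2 <- run()
  expect_identical(l1, l2)
  expect_lt(l1[50], l1[1] / 10)
})
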