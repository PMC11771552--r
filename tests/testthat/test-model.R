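test_that("weighted BCE matches its closed forms", {
  expect_equal(weighted_bce(0.5, 1, 3), 3 * log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(0.5, 0, 7), log(2), tolerance = 1e-12)
  set.seed(31)
  p <- runif(50, 0.01, 0.99)
  y <- rbinom(50, 1, 0.4)
  expect_equal(weighted_bce(p, y, 1),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
  expect_error(weighted_bce(0.5, 1, 0), "pos_weight")
  # clamping keeps the loss finite at exact 0/1 probabilities
  expect_true(is.finite(weighted_bce(c(0, 1), c(1, 0), 3)))
})

test_that("model config is validated", {
  expect_error(model_config(10, 2, 3, d_model = 30, n_heads = 4), "divisible")
  expect_error(model_config(10, 2, 3, dropout = 1), "dropout")
})

test_that("forward outputs are probabilities, deterministic in eval mode", {
  fx <- tiny_model_fixture()
  p1 <- model_forward(fx$params, fx$batch)
  p2 <- model_forward(fx$params, fx$batch)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # permuting patients permutes outputs identically
  perm <- c(3, 1, 2)
  p3 <- model_forward(fx$params, painattn:::subset_batch(fx$batch, perm))
  expect_equal(p3, p1[perm], tolerance = 1e-12)
})

test_that("padded positions cannot influence the output", {
  fx <- tiny_model_fixture()
  batch2 <- fx$batch
  pad_pos <- which(!batch2$mask[1, ])
  batch2$tokens[1, pad_pos] <- sample(2:11, length(pad_pos), replace = TRUE)
  batch2$timestamps[1, pad_pos] <- 999
  expect_equal(model_forward(fx$params, batch2),
               model_forward(fx$params, fx$batch), tolerance = 1e-6)
})

test_that("patients with empty sequences are classified from statics", {
  fx <- tiny_model_fixture()
  batch <- fx$batch
  batch$mask[2, ] <- FALSE
  batch$tokens[2, ] <- 0L
  p <- model_forward(fx$params, batch)
  expect_true(p[2] > 0 && p[2] < 1)
  # sequence contents are then irrelevant
  batch3 <- batch
  batch3$tokens[2, ] <- 5L
  expect_equal(model_forward(fx$params, batch3)[2], p[2], tolerance = 1e-12)
})

test_that("embedding components follow the sinusoidal construction", {
  fx <- tiny_model_fixture()
  all_pad <- structure(list(tokens = rep(0L, 10), timestamps = rep(0, 10),
                            mask = rep(FALSE, 10)),
                       class = "tokenized_sequence")
  tok_comp <- embed_sequence(all_pad, fx$params, component = "token")
  expect_true(all(tok_comp == 0))

  seq1 <- structure(list(tokens = c(5L, 5L), timestamps = c(10, 400),
                         mask = c(TRUE, TRUE)), class = "tokenized_sequence")
  emb <- embed_sequence(seq1, fx$params)
  expect_gt(max(abs(emb[1, ] - emb[2, ])), 0)

  # timestamp 0: alternating sin(0)/cos(0) = 0/1 pattern
  seq0 <- structure(list(tokens = 3L, timestamps = 0, mask = TRUE),
                    class = "tokenized_sequence")
  time_comp <- embed_sequence(seq0, fx$params, component = "time")
  expect_equal(as.vector(time_comp), rep(c(0, 1), 4), tolerance = 1e-12)

  # independent R implementation of the sinusoid
  r_sinusoid <- function(v, d) {
    out <- numeric(d)
    for (i in seq_len(d / 2)) {
      f <- 10000^(-2 * (i - 1) / d)
      out[2 * i - 1] <- sin(v * f)
      out[2 * i] <- cos(v * f)
    }
    out
  }
  seq2 <- structure(list(tokens = 4L, timestamps = 123.5, mask = TRUE),
                    class = "tokenized_sequence")
  expect_equal(as.vector(embed_sequence(seq2, fx$params, component = "time")),
               r_sinusoid(123.5 / fx$cfg$time_scale, 8), tolerance = 1e-12)
  expect_equal(as.vector(embed_sequence(seq2, fx$params, component = "position")),
               r_sinusoid(0, 8), tolerance = 1e-12)
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- model_config(100, 5, 7, seed = 1)
  n1 <- n_parameters(cfg)
  cfg2 <- model_config(100, 5, 7, seed = 999)  # different seed, same shape
  expect_identical(n1, n_parameters(cfg2))
  # spot-check against the closed-form count for the default shape
  d <- 32; dff <- 32
  per_layer <- 4 * (d * d + d) + 2 * d + d * dff + dff + dff * d + d + 2 * d
  expected <- 100 * d + 2 * per_layer + (5 * 4 + 4) + (7 * 4 + 4) +
    (d + 8) * 1 + 1
  expect_equal(n1, expected)
})

test_that("PAD embedding row stays zero through initialization and training", {
  fx <- tiny_model_fixture(B = 6)
  expect_true(all(fx$params$emb[1, ] == 0))
  y <- c(1, 0, 1, 0, 1, 0)
  res <- painattn:::model_loss_grads(fx$params, fx$batch, y, 3)
  expect_true(all(res$grads$emb[1, ] == 0))
})

test_that("analytic gradients match finite differences", {
  fx <- tiny_model_fixture(B = 4)
  params <- fx$params
  set.seed(99)
  for (nm in names(params)) {
    params[[nm]] <- params[[nm]] +
      matrix(rnorm(length(params[[nm]]), 0, 0.05), nrow(params[[nm]]))
  }
  params$emb[1, ] <- 0
  attr(params, "config") <- fx$cfg
  class(params) <- "model_parameters"
  batch <- fx$batch
  y <- c(1, 0, 1, 0)
  res <- painattn:::model_loss_grads(params, batch, y, 3, training = FALSE)
  lossfun <- function(p) {
    attr(p, "config") <- fx$cfg
    class(p) <- "model_parameters"
    weighted_bce(model_forward(p, batch), y, 3)
  }
  expect_equal(res$loss, lossfun(params), tolerance = 1e-10)
  eps <- 1e-6
  for (nm in c("emb", "l1_Wq", "l1_Wo", "l1_ln1_g", "l2_W1", "l2_ln2_b",
               "demo_W", "survey_W", "head_W", "head_b")) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      if (nm == "emb" && ((i - 1) %% nrow(params$emb)) + 1 == 1) next  # PAD
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      fd <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_equal(res$grads[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("loss gradient on the logit scales linearly with the positive weight", {
  fx <- tiny_model_fixture(B = 2)
  y <- c(1, 1)
  g1 <- painattn:::model_loss_grads(fx$params, fx$batch, y, 1)$grads$head_b[1, 1]
  g3 <- painattn:::model_loss_grads(fx$params, fx$batch, y, 3)$grads$head_b[1, 1]
  g5 <- painattn:::model_loss_grads(fx$params, fx$batch, y, 5)$grads$head_b[1, 1]
  expect_equal(g3 / g1, 3, tolerance = 1e-9)
  expect_equal(g5 / g1, 5, tolerance = 1e-9)
})

test_that("pooled + head fast path reproduces the full forward exactly", {
  fx <- tiny_model_fixture(B = 5)
  pooled <- pooled_sequence(fx$params, fx$batch)
  expect_equal(head_probabilities(fx$params, pooled, fx$batch$demo,
                                  fx$batch$survey),
               model_forward(fx$params, fx$batch), tolerance = 1e-12)
})

test_that("model files round-trip and config mismatches fail loudly", {
  fx <- tiny_model_fixture()
  path <- tempfile(fileext = ".rds")
  save_model(fx$params, path)
  back <- load_model(path, expected_config = fx$cfg)
  expect_equal(unclass(back), unclass(fx$params), ignore_attr = TRUE)
  other <- model_config(vocab_size = 99, demo_dim = 3, survey_dim = 5)
  expect_error(load_model(path, expected_config = other), "config")
})
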