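test_that("splits are exhaustive, sized by rounding, and stratified", {
  set.seed(60)
  y <- rbinom(1000, 1, 0.176)
  sp <- split_dataset(y, seed = 5)
  expect_equal(lengths(sp), c(train = 700L, validation = 50L, test = 250L))
  all_idx <- sort(unname(unlist(sp)))
  expect_equal(all_idx, 1:1000)   # disjoint and exhaustive
  prev <- mean(y)
  for (s in names(sp)) {
    expect_lte(abs(mean(y[sp[[s]]]) - prev), 0.02)
  }
  sp2 <- split_dataset(y, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(y, seed = 6)))
})

test_that("a tiny all-negative validation split warns rather than fails", {
  y <- c(rep(0, 39), 1)
  # the lone positive lands in one split; the other two both warn
  expect_warning(expect_warning(split_dataset(y, seed = 1), "zero positive"),
                 "zero positive")
})

test_that("AUROC follows the rank formulation with tie handling", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.6, 0.4, 0.1)), 0.75)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_warning(a <- auroc(c(1, 1), c(0.2, 0.9)), "one class")
  expect_true(is.na(a))
  set.seed(42)
  expect_gte(auroc(rbinom(2000, 1, 0.5), runif(2000)), 0.45)
  expect_lte(auroc(rbinom(2000, 1, 0.5), runif(2000)), 0.55)
})

test_that("AUROC equals exhaustive pairwise enumeration and is rank-invariant", {
  pairwise_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(77)
  for (i in seq_len(40)) {
    n <- sample(4:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    expect_equal(auroc(y, s), pairwise_auc(y, s), label = paste("set", i))
    # invariance under a strictly monotone transform
    expect_equal(auroc(y, qlogis(pmin(pmax(s, 0.01), 0.99))),
                 auroc(y, pmin(pmax(s, 0.01), 0.99)))
  }
})

test_that("AUROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  for (i in 1:5) {
    y <- c(0, 1, rbinom(30, 1, 0.4))
    s <- round(runif(32), 2)
    expect_equal(auroc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("evaluation metrics match hand-computed confusion matrices", {
  rep1 <- painattn:::report_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(rep1$accuracy, 1.0)
  expect_equal(rep1$auroc, 1.0)
  expect_equal(as.vector(rep1$confusion), c(2, 0, 0, 2))

  rep2 <- painattn:::report_metrics(c(1, 0, 1, 0), c(0.9, 0.6, 0.4, 0.1))
  expect_equal(rep2$auroc, 0.75)
  expect_equal(rep2$accuracy, 0.5)

  # all predicted negative with positives present: recall 0, precision
  # flagged undefined and reported as 0
  rep3 <- painattn:::report_metrics(c(1, 1, 0), c(0.1, 0.2, 0.3), 0.5)
  expect_equal(rep3$recall, 0)
  expect_equal(rep3$precision, 0)
  expect_true("precision" %in% rep3$undefined)

  # metrics recomputed from the confusion matrix agree exactly
  set.seed(9)
  y <- rbinom(200, 1, 0.3)
  s <- runif(200)
  rep4 <- painattn:::report_metrics(y, s, 0.4)
  cm <- rep4$confusion
  expect_equal(rep4$accuracy, (cm[1, 1] + cm[2, 2]) / sum(cm))
  expect_equal(rep4$precision, cm[2, 2] / sum(cm[, 2]))
  expect_equal(rep4$recall, cm[2, 2] / sum(cm[2, ]))
  expect_equal(sum(cm), 200)
})

toy_features <- function(n = 10, seed = 3) {
  # linearly separable toy: one code decides the outcome
  set.seed(seed)
  L <- 8L
  y <- rep(c(1, 0), length.out = n)
  tokens <- matrix(2L, n, L)
  tokens[y == 1, 1] <- 3L
  batch <- list(tokens = tokens,
                timestamps = matrix(rep(seq(L * 10, 10, -10), each = n), n, L),
                mask = matrix(TRUE, n, L),
                demo = matrix(0.5, n, 2,
                              dimnames = list(NULL, c("age_norm", "race=White"))),
                survey = matrix(0, n, 3,
                                dimnames = list(NULL, paste0("s", 1:3))))
  feats <- list(splits = list(train = batch, validation = batch, test = batch),
                vocab = list(token_of = c("A:1" = 2L, "B:2" = 3L), size = 4L),
                demo_dim = 2L, survey_dim = 3L)
  list(features = feats, labels = list(train = y, validation = y, test = y))
}

test_that("training loss decreases on a separable toy problem", {
  toy <- toy_features()
  mcfg <- model_config(vocab_size = 4, demo_dim = 2, survey_dim = 3,
                       d_model = 8, n_heads = 2, n_layers = 1, d_ff = 8,
                       dropout = 0, seq_len = 8, seed = 2)
  tcfg <- train_config(epochs = 5, batch_size = 5, seed = 11)
  fit <- train_model(toy$features, toy$labels, mcfg, tcfg)
  expect_equal(nrow(fit$history), 5)
  expect_true(all(diff(fit$history$train_loss[1:5]) < 0))
})

test_that("training is deterministic and inert at zero learning rate", {
  toy <- toy_features()
  mcfg <- model_config(vocab_size = 4, demo_dim = 2, survey_dim = 3,
                       d_model = 8, n_heads = 2, n_layers = 1, d_ff = 8,
                       dropout = 0.1, seq_len = 8, seed = 2)
  tcfg <- train_config(epochs = 3, batch_size = 4, seed = 11)
  f1 <- train_model(toy$features, toy$labels, mcfg, tcfg)
  f2 <- train_model(toy$features, toy$labels, mcfg, tcfg)
  expect_identical(f1$history, f2$history)
  expect_equal(unclass(f1$params), unclass(f2$params), ignore_attr = TRUE)

  tcfg0 <- train_config(epochs = 3, batch_size = 4, seed = 11,
                        learning_rate = 0)
  f0 <- train_model(toy$features, toy$labels, mcfg, tcfg0)
  init <- init_params(mcfg)
  expect_equal(unclass(f0$params), unclass(init), ignore_attr = TRUE)
})

test_that("the sweep holds everything fixed except the positive weight", {
  toy <- toy_features()
  mcfg <- model_config(vocab_size = 4, demo_dim = 2, survey_dim = 3,
                       d_model = 8, n_heads = 2, n_layers = 1, d_ff = 8,
                       dropout = 0, seq_len = 8, seed = 2)
  tcfg <- train_config(epochs = 2, batch_size = 5, seed = 11)
  tab <- pos_weight_sweep(toy$features, toy$labels, mcfg, tcfg, weights = 3)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pos_weight, 3)

  tab2 <- pos_weight_sweep(toy$features, toy$labels, mcfg, tcfg,
                           weights = c(1, 3))
  tcfg1 <- tcfg; tcfg1$pos_weight <- 1
  fit1 <- train_model(toy$features, toy$labels, mcfg, tcfg1)
  rep1 <- evaluate_model(fit1$params, toy$features$splits$test,
                         toy$labels$test)
  expect_equal(tab2$auroc[1], rep1$auroc)
  expect_equal(tab2$recall[1], rep1$recall)
})
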