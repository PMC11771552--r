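#' Training configuration
#'
#' Defaults follow the study: a 70/5/25 train/validation/test split,
#' Adam with a constant learning rate of 0.001, 20 epochs, positive-class
#' weight 3.0. Batch size 64 and the 0.5 decision threshold are this
#' package's defaults where the study is silent.
#'
#' @param split_fractions train/validation/test fractions summing to 1.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training split.
#' @param pos_weight positive-class weight in the loss.
#' @param batch_size minibatch size.
#' @param decision_threshold probability cutoff for the thresholded
#'   metrics.
#' @param max_overfit_gap overfitting guard used in epoch selection: the
#'   returned parameters are those of the epoch with the best validation
#'   AUROC among epochs whose train minus validation AUROC does not
#'   exceed this value (the validation set's purpose is mitigating
#'   overfitting); if no epoch qualifies, plain best-validation-AUROC
#'   selection is used. Set to \code{Inf} to disable the guard.
#' @param seed seed for shuffling and dropout.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(split_fractions = c(train = 0.70, validation = 0.05,
                                             test = 0.25),
                         learning_rate = 0.001, epochs = 20L,
                         pos_weight = 3.0, batch_size = 64L,
                         decision_threshold = 0.5, max_overfit_gap = 0.10,
                         seed = 1L) {
  if (abs(sum(split_fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (pos_weight <= 0) stop("pos_weight must be > 0")
  structure(list(split_fractions = split_fractions,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 pos_weight = pos_weight, batch_size = as.integer(batch_size),
                 decision_threshold = decision_threshold,
                 max_overfit_gap = max_overfit_gap,
                 seed = as.integer(seed)),
            class = "train_config")
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Label-stratified dataset split
#'
#' Partitions indices into disjoint, exhaustive train/validation/test
#' subsets whose sizes are the fractions rounded to integers respecting
#' the total, with outcome prevalence preserved in each subset as closely
#' as the class counts allow. Deterministic under \code{seed}.
#'
#' @param labels 0/1 outcome vector.
#' @param fractions named fractions summing to 1.
#' @param seed RNG seed.
#' @return list of integer index vectors \code{train},
#'   \code{validation}, \code{test}.
#' @export
split_dataset <- function(labels, fractions = c(train = 0.70,
                                                validation = 0.05,
                                                test = 0.25),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(labels)
  k <- length(fractions)
  target <- largest_remainder(n * fractions)
  set.seed(seed)
  assign <- rep(NA_integer_, n)
  for (cls in sort(unique(labels))) {
    idx <- sample(which(labels == cls))
    cnt <- largest_remainder(length(idx) * fractions)
    assign[idx] <- rep.int(seq_len(k), cnt)
  }
  # reconcile per-split totals with the overall targets by moving members
  # of the largest class (deterministically) between splits
  sizes <- tabulate(assign, k)
  major <- as.integer(names(which.max(table(labels))))
  while (any(sizes != target)) {
    from <- which(sizes > target)[1L]
    to <- which(sizes < target)[1L]
    cand <- which(assign == from & labels == major)
    if (length(cand) == 0) cand <- which(assign == from)
    assign[cand[length(cand)]] <- to
    sizes <- tabulate(assign, k)
  }
  out <- lapply(seq_len(k), function(s) which(assign == s))
  names(out) <- names(fractions)
  for (s in names(out)) {
    if (sum(labels[out[[s]]] == 1) == 0) {
      warning("split '", s, "' received zero positive cases")
    }
  }
  out
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random
#' positive outscores a random negative, with ties counted one half.
#'
#' @param labels 0/1 outcomes; both classes must be present.
#' @param scores predicted scores.
#' @return AUROC in [0, 1], or \code{NA} with a warning when only one
#'   class is present.
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

subset_batch <- function(batch, idx) {
  lapply(batch, function(m) m[idx, , drop = FALSE])
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the classifier
#'
#' Minibatch optimization of the weighted binary cross-entropy with
#' Adam. Per-epoch training loss, training AUROC (estimated on a fixed
#' subsample of up to 1024 training patients) and validation AUROC are
#' recorded. The returned parameters are those of the epoch with the
#' best validation AUROC among epochs that pass the overfitting guard
#' (train minus validation AUROC at most \code{max_overfit_gap}); when
#' no epoch passes the guard, the epoch with the best validation AUROC
#' overall is used, and the final epoch if validation AUROC is never
#' defined.
#'
#' @param features a \code{feature_set} from
#'   \code{\link{prepare_features}}.
#' @param labels list with numeric 0/1 vectors \code{train},
#'   \code{validation} (and optionally \code{test}), aligned with the
#'   feature splits.
#' @param model_cfg a \code{\link{model_config}}.
#' @param train_cfg a \code{\link{train_config}}.
#' @return list with \code{params}, \code{history} (data.frame epoch /
#'   train_loss / val_auroc) and \code{best_epoch}.
#' @export
train_model <- function(features, labels, model_cfg, train_cfg) {
  train_batch <- features$splits$train
  val_batch <- features$splits$validation
  y_train <- as.numeric(labels$train)
  n_train <- length(y_train)
  stopifnot(nrow(train_batch$tokens) == n_train)

  params <- init_params(model_cfg)
  cls <- class(params)
  cfg_attr <- attr(params, "config")
  state <- adam_init(params)
  use_dropout <- model_cfg$dropout > 0

  set.seed(train_cfg$seed)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_auroc = numeric(), val_auroc = numeric())
  snapshots <- vector("list", train_cfg$epochs)
  # the guard's training AUROC is estimated on a fixed, evenly spaced
  # subsample (SE ~0.02-0.03), which is ample against a 0.10 threshold
  guard_idx <- unique(as.integer(seq(1L, n_train,
                                     length.out = min(1024L, n_train))))
  guard_batch <- subset_batch(train_batch, guard_idx)
  y_guard <- y_train[guard_idx]
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample.int(n_train)
    chunks <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    ep_loss <- 0
    for (ch in chunks) {
      res <- model_loss_grads(params, subset_batch(train_batch, ch),
                              y_train[ch], train_cfg$pos_weight,
                              training = use_dropout)
      if (!is.finite(res$loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      upd <- adam_step(params, res$grads, state, train_cfg$learning_rate)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + res$loss * length(ch)
    }
    attr(params, "config") <- cfg_attr
    class(params) <- cls
    train_auc <- suppressWarnings(
      auroc(y_guard, model_forward(params, guard_batch)))
    val_auc <- suppressWarnings(
      auroc(labels$validation, model_forward(params, val_batch)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_train,
                                         train_auroc = train_auc,
                                         val_auroc = val_auc))
    snapshots[[epoch]] <- params
  }
  best_epoch <- select_epoch(history, train_cfg$max_overfit_gap)
  list(params = snapshots[[best_epoch]], history = history,
       best_epoch = best_epoch)
}

# epoch selection: best validation AUROC among epochs passing the
# overfitting guard; plain best-validation if none passes; final epoch
# if validation AUROC is never defined
select_epoch <- function(history, max_overfit_gap) {
  ok <- !is.na(history$val_auroc)
  if (!any(ok)) return(nrow(history))
  guard <- ok & !is.na(history$train_auroc) &
    (history$train_auroc - history$val_auroc) <= max_overfit_gap
  pool <- if (any(guard)) which(guard) else which(ok)
  pool[which.max(history$val_auroc[pool])]
}

#' Evaluate the classifier on one split
#'
#' Probabilities are thresholded at \code{threshold} for accuracy,
#' precision, recall and the confusion matrix; AUROC is computed
#' threshold-free. When a denominator is zero the metric is reported as
#' 0 and flagged in \code{undefined}.
#'
#' @param params \code{model_parameters}.
#' @param batch feature batch (as in \code{\link{model_forward}}).
#' @param labels 0/1 outcomes.
#' @param threshold decision threshold.
#' @param split name recorded in the report.
#' @return An \code{eval_report}: accuracy, auroc, precision, recall,
#'   confusion (2x2 matrix), threshold, split, n, undefined (character
#'   vector of flagged metrics).
#' @export
evaluate_model <- function(params, batch, labels, threshold = 0.5,
                           split = "test") {
  probs <- model_forward(params, batch)
  report_metrics(labels, probs, threshold, split)
}

report_metrics <- function(labels, probs, threshold = 0.5, split = "test") {
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); 0
  }
  auc <- suppressWarnings(auroc(labels, probs))
  if (is.na(auc)) undefined <- c(undefined, "auroc")
  confusion <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                      dimnames = list(actual = c("negative", "positive"),
                                      predicted = c("negative", "positive")))
  structure(list(accuracy = (tp + tn) / length(labels), auroc = auc,
                 precision = precision, recall = recall,
                 confusion = confusion, threshold = threshold,
                 split = split, n = length(labels), undefined = undefined,
                 probabilities = probs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s, n=%d, threshold=%.2f>\n", x$split, x$n,
              x$threshold))
  cat(sprintf("  accuracy %.3f | AUROC %s | precision %.3f | recall %.3f\n",
              x$accuracy, ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
              x$precision, x$recall))
  print(x$confusion)
  invisible(x)
}

#' Positive-weight sweep
#'
#' Trains one model per positive-class weight with everything else
#' (splits, seeds, architecture) held fixed, and evaluates each on the
#' test split.
#'
#' @param features a \code{feature_set}.
#' @param labels per-split label list (as in \code{\link{train_model}}).
#' @param model_cfg,train_cfg configurations; \code{train_cfg$pos_weight}
#'   is overridden by each sweep value.
#' @param weights positive weights to sweep.
#' @return data.frame with columns pos_weight, accuracy, auroc,
#'   precision, recall.
#' @export
pos_weight_sweep <- function(features, labels, model_cfg, train_cfg,
                             weights = c(1.0, 3.0, 5.0)) {
  rows <- lapply(weights, function(w) {
    cfg <- train_cfg
    cfg$pos_weight <- w
    fit <- train_model(features, labels, model_cfg, cfg)
    rep <- evaluate_model(fit$params, features$splits$test, labels$test,
                          cfg$decision_threshold, split = "test")
    data.frame(pos_weight = w, accuracy = rep$accuracy, auroc = rep$auroc,
               precision = rep$precision, recall = rep$recall)
  })
  do.call(rbind, rows)
}
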