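#' Permutation feature importance
#'
#' Importance of a static feature is the drop in a base evaluation
#' metric (AUROC by default) when that feature's values are shuffled
#' across patients, breaking its relationship with the outcome. Each
#' feature is shuffled \code{repeats} times under a fixed seed; the
#' importance is the base metric minus the mean permuted metric.
#' Shuffling a constant column is the identity, so constant features
#' score exactly 0.
#'
#' @param params fitted \code{model_parameters}.
#' @param batch feature batch (must contain both classes).
#' @param labels 0/1 outcomes.
#' @param feature_names columns to assess; defaults to every column of
#'   the demographic and survey matrices.
#' @param repeats shuffles per feature.
#' @param seed RNG seed.
#' @return data.frame (class \code{importance_report}) with columns
#'   feature, importance, sd, rank, sorted by decreasing importance.
#' @export
permutation_importance <- function(params, batch, labels,
                                   feature_names = NULL, repeats = 10L,
                                   seed = 1L) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("permutation importance needs both classes present")
  }
  where <- c(stats::setNames(rep("demo", ncol(batch$demo)),
                             colnames(batch$demo)),
             stats::setNames(rep("survey", ncol(batch$survey)),
                             colnames(batch$survey)))
  if (is.null(feature_names)) feature_names <- names(where)
  missing <- setdiff(feature_names, names(where))
  if (length(missing) > 0) {
    stop("unknown feature(s): ", paste(head(missing, 5L), collapse = ", "))
  }
  # the pooled sequence vectors do not depend on static columns, so the
  # encoder runs once and only the static branches are re-evaluated per
  # permutation
  pooled <- pooled_sequence(params, batch)
  base <- auroc(labels, head_probabilities(params, pooled, batch$demo,
                                           batch$survey))
  n <- length(labels)
  set.seed(seed)
  rows <- lapply(feature_names, function(f) {
    tab <- where[[f]]
    col <- batch[[tab]][, f]
    if (length(unique(col)) == 1L) {
      # shuffling a constant column is the identity
      return(data.frame(feature = f, importance = 0, sd = 0))
    }
    drops <- vapply(seq_len(repeats), function(r) {
      demo <- batch$demo
      survey <- batch$survey
      if (tab == "demo") demo[, f] <- col[sample.int(n)]
      else survey[, f] <- col[sample.int(n)]
      base - auroc(labels, head_probabilities(params, pooled, demo, survey))
    }, numeric(1))
    data.frame(feature = f, importance = mean(drops), sd = stats::sd(drops))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Self-attention weight matrices for one sequence
#'
#' Runs the encoder in evaluation mode and returns, per layer and head,
#' the full seq_len x seq_len attention matrix. Rows of unmasked
#' (real) query positions sum to 1 over the unmasked keys; every entry
#' involving a padded position is exactly 0.
#'
#' @param params \code{model_parameters}.
#' @param sequence a \code{tokenized_sequence}.
#' @return list (per layer) of lists (per head) of matrices.
#' @export
attention_weights <- function(params, sequence) {
  config <- attr(params, "config")
  .cpp_attention(unclass(params), as_cfg_list(config),
                 as.integer(sequence$tokens),
                 as.numeric(sequence$timestamps),
                 as.logical(sequence$mask))
}

#' Strongest attention connections
#'
#' Averages the attention matrices over the heads of the final encoder
#' layer, excludes the diagonal and every pair touching a padded
#' position, and returns the k largest connections. Ties are broken by
#' (source, target) position order for determinism.
#'
#' @param attn output of \code{\link{attention_weights}} (or any list of
#'   layers of per-head matrices).
#' @param sequence the \code{tokenized_sequence} the attention was
#'   computed on.
#' @param vocab optional \code{code_vocabulary} used to name the codes;
#'   tokens without a vocabulary entry are shown as \code{<UNK>}.
#' @param k number of connections to return.
#' @return data.frame (class \code{attention_report}) with columns
#'   source_position, target_position, source_code, target_code, weight;
#'   attribute \code{"flagged"} is TRUE when fewer than k eligible pairs
#'   exist.
#' @export
top_connections <- function(attn, sequence, vocab = NULL, k = 5L) {
  heads <- attn[[length(attn)]]
  avg <- Reduce(`+`, heads) / length(heads)
  L <- nrow(avg)
  real <- which(sequence$mask)
  eligible <- expand.grid(source = real, target = real)
  eligible <- eligible[eligible$source != eligible$target, , drop = FALSE]
  w <- avg[as.matrix(eligible)]
  ord <- order(-w, eligible$source, eligible$target)
  n_take <- min(k, length(ord))
  flagged <- n_take < k
  take <- ord[seq_len(n_take)]
  code_name <- function(pos) {
    tok <- sequence$tokens[pos]
    if (is.null(vocab)) return(as.character(tok))
    nm <- names(vocab$token_of)[match(tok, vocab$token_of)]
    ifelse(is.na(nm), "<UNK>", nm)
  }
  out <- data.frame(source_position = eligible$source[take],
                    target_position = eligible$target[take],
                    source_code = vapply(eligible$source[take], code_name,
                                         character(1)),
                    target_code = vapply(eligible$target[take], code_name,
                                         character(1)),
                    weight = w[take],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  class(out) <- c("attention_report", "data.frame")
  out
}
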