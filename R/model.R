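#' Model configuration
#'
#' Hyperparameters of the encoder-only attention classifier. Defaults
#' follow the study settings: 4 attention heads, 2 encoder layers,
#' feedforward width 32, dropout 0.1, hidden width 4 for each static
#' branch, sequence length 128. The embedding width (32, matching the
#' feedforward dimension) and mean-over-unmasked-positions pooling are
#' this package's choices where the study is silent.
#'
#' @param vocab_size token vocabulary size including PAD and UNK.
#' @param demo_dim,survey_dim widths of the static input vectors.
#' @param d_model embedding width; must be divisible by \code{n_heads}.
#' @param n_heads,n_layers,d_ff encoder shape.
#' @param dropout dropout rate inside the encoder, in [0, 1).
#' @param time_scale days per unit of the timestamp sinusoid argument
#'   (default 30, i.e. roughly monthly resolution). Encoding the raw day
#'   offset (\code{time_scale = 1}) makes the high-frequency sinusoid
#'   components effectively unique per patient, which invites
#'   memorization; a coarser scale keeps the temporal ordering signal
#'   without the fingerprint.
#' @param demo_hidden,survey_hidden static branch widths.
#' @param seq_len fixed input sequence length.
#' @param pooling pooling strategy; only \code{"mean_masked"} is
#'   implemented.
#' @param seed seed for parameter initialization.
#' @return An object of class \code{model_config}.
#' @export
model_config <- function(vocab_size, demo_dim, survey_dim,
                         d_model = 32L, n_heads = 4L, n_layers = 2L,
                         d_ff = 32L, dropout = 0.1, time_scale = 30,
                         demo_hidden = 4L, survey_hidden = 4L,
                         seq_len = 128L, pooling = "mean_masked",
                         seed = 1L) {
  if (time_scale <= 0) stop("time_scale must be positive")
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (seq_len < 1) stop("seq_len must be positive")
  pooling <- match.arg(pooling, "mean_masked")
  structure(list(vocab_size = as.integer(vocab_size),
                 demo_dim = as.integer(demo_dim),
                 survey_dim = as.integer(survey_dim),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                 dropout = dropout, time_scale = as.numeric(time_scale),
                 demo_hidden = as.integer(demo_hidden),
                 survey_hidden = as.integer(survey_hidden),
                 seq_len = as.integer(seq_len), pooling = pooling,
                 seed = as.integer(seed)),
            class = "model_config")
}

runif_mat <- function(nr, nc, fan_in) {
  a <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -a, a), nr, nc)
}

#' Initialize model parameters
#'
#' Uniform initialization scaled by layer fan-in, seeded from
#' \code{config$seed}. The PAD embedding row is fixed at zero; layer-norm
#' gains start at 1 and all biases at 0.
#'
#' @param config a \code{\link{model_config}}.
#' @return Named list of parameter matrices (class
#'   \code{model_parameters}) with the config attached as attribute
#'   \code{"config"}.
#' @export
init_params <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  d <- config$d_model
  p <- list()
  p$emb <- runif_mat(config$vocab_size, d, d)
  p$emb[1L, ] <- 0  # PAD
  ones_row <- function(k) matrix(1, 1L, k)
  zeros_row <- function(k) matrix(0, 1L, k)
  for (l in seq_len(config$n_layers)) {
    pre <- paste0("l", l, "_")
    for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- runif_mat(d, d, d)
    for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- zeros_row(d)
    p[[paste0(pre, "ln1_g")]] <- ones_row(d)
    p[[paste0(pre, "ln1_b")]] <- zeros_row(d)
    p[[paste0(pre, "W1")]] <- runif_mat(d, config$d_ff, d)
    p[[paste0(pre, "b1")]] <- zeros_row(config$d_ff)
    p[[paste0(pre, "W2")]] <- runif_mat(config$d_ff, d, config$d_ff)
    p[[paste0(pre, "b2")]] <- zeros_row(d)
    p[[paste0(pre, "ln2_g")]] <- ones_row(d)
    p[[paste0(pre, "ln2_b")]] <- zeros_row(d)
  }
  p$demo_W <- runif_mat(config$demo_dim, config$demo_hidden, config$demo_dim)
  p$demo_b <- zeros_row(config$demo_hidden)
  p$survey_W <- runif_mat(config$survey_dim, config$survey_hidden,
                          config$survey_dim)
  p$survey_b <- zeros_row(config$survey_hidden)
  head_in <- d + config$demo_hidden + config$survey_hidden
  p$head_W <- runif_mat(head_in, 1L, head_in)
  p$head_b <- matrix(0, 1L, 1L)
  structure(p, config = config, class = "model_parameters")
}

#' Total number of trainable parameters
#'
#' A pure function of the configuration.
#'
#' @param config a \code{\link{model_config}}.
#' @return integer count.
#' @export
n_parameters <- function(config) {
  sum(vapply(unclass(init_params(config)), length, integer(1)))
}

as_cfg_list <- function(config) {
  config[c("d_model", "n_heads", "n_layers", "d_ff", "demo_hidden",
           "survey_hidden", "dropout", "time_scale")]
}

#' Embed one tokenized sequence
#'
#' Per position: token embedding plus a sinusoidal encoding of the
#' position index plus a sinusoidal encoding of the timestamp value
#' (days until diagnosis). \code{component} selects the full sum or one
#' of its three parts for inspection.
#'
#' @param sequence a \code{tokenized_sequence}.
#' @param params model parameters.
#' @param component one of \code{"sum"}, \code{"token"},
#'   \code{"position"}, \code{"time"}.
#' @return numeric matrix (seq_len x d_model).
#' @export
embed_sequence <- function(sequence, params,
                           component = c("sum", "token", "position", "time")) {
  component <- match.arg(component)
  config <- attr(params, "config")
  comp <- match(component, c("sum", "token", "position", "time")) - 1L
  .cpp_embed(unclass(params), as_cfg_list(config),
             as.integer(sequence$tokens), as.numeric(sequence$timestamps),
             comp)
}

#' Forward pass of the classifier
#'
#' Maps a batch of tokenized sequences plus static features to outcome
#' probabilities. Padded positions are excluded from attention and from
#' pooling; sequence and static representations are concatenated and
#' passed through the final feedforward head with a sigmoid output.
#' Patients with an empty code sequence pool to a zero vector and are
#' classified from their static branches alone.
#'
#' @param params \code{model_parameters}.
#' @param batch list with matrices \code{tokens}, \code{timestamps},
#'   \code{mask} (n x seq_len) and \code{demo}, \code{survey} (n x
#'   static dims), as produced by \code{\link{prepare_features}}.
#' @param training if TRUE, dropout is active (uses the R RNG).
#' @return numeric vector of probabilities in (0, 1).
#' @export
model_forward <- function(params, batch, training = FALSE) {
  config <- attr(params, "config")
  out <- .cpp_model_run(unclass(params), as_cfg_list(config),
                        storage_int(batch$tokens),
                        storage_num(batch$timestamps),
                        storage_lgl(batch$mask),
                        storage_num(batch$demo), storage_num(batch$survey),
                        numeric(0), 1.0, training, FALSE)
  out$probs
}

model_loss_grads <- function(params, batch, labels, pos_weight,
                             training = TRUE) {
  config <- attr(params, "config")
  .cpp_model_run(unclass(params), as_cfg_list(config),
                 storage_int(batch$tokens), storage_num(batch$timestamps),
                 storage_lgl(batch$mask), storage_num(batch$demo),
                 storage_num(batch$survey), as.numeric(labels), pos_weight,
                 training, TRUE)
}

#' Pooled sequence representations
#'
#' Mean over the unmasked encoder outputs for each patient, in
#' evaluation mode. Together with \code{\link{head_probabilities}} this
#' reproduces \code{\link{model_forward}} exactly while letting the
#' static branches be re-evaluated cheaply (used by permutation
#' importance, where only static columns change).
#'
#' @param params \code{model_parameters}.
#' @param batch feature batch.
#' @return numeric matrix (n x d_model).
#' @export
pooled_sequence <- function(params, batch) {
  config <- attr(params, "config")
  .cpp_pooled(unclass(params), as_cfg_list(config),
              storage_int(batch$tokens), storage_num(batch$timestamps),
              storage_lgl(batch$mask))
}

#' Classifier head on precomputed pooled vectors
#'
#' Applies the demographic and survey feedforward branches and the final
#' head to precomputed pooled sequence vectors.
#'
#' @param params \code{model_parameters}.
#' @param pooled matrix from \code{\link{pooled_sequence}}.
#' @param demo,survey static feature matrices.
#' @return probabilities, identical to \code{\link{model_forward}}.
#' @export
head_probabilities <- function(params, pooled, demo, survey) {
  n <- nrow(pooled)
  hd <- pmax(demo %*% params$demo_W +
               matrix(params$demo_b, n, length(params$demo_b), byrow = TRUE), 0)
  hs <- pmax(survey %*% params$survey_W +
               matrix(params$survey_b, n, length(params$survey_b),
                      byrow = TRUE), 0)
  z <- cbind(pooled, hd, hs) %*% params$head_W + params$head_b[1, 1]
  plogis(as.vector(z))
}

storage_int <- function(x) { storage.mode(x) <- "integer"; x }
storage_num <- function(x) { storage.mode(x) <- "double"; x }
storage_lgl <- function(x) { storage.mode(x) <- "logical"; x }

#' Weighted binary cross-entropy
#'
#' Mean over the batch of \code{-(w y log p + (1 - y) log(1 - p))}.
#' Probabilities are clamped to [1e-7, 1 - 1e-7] for numerical safety.
#' With \code{pos_weight = 1} this is the ordinary binary cross-entropy.
#'
#' @param probabilities predicted probabilities in (0, 1).
#' @param labels 0/1 outcomes.
#' @param pos_weight positive-class weight (> 0).
#' @return scalar loss.
#' @export
weighted_bce <- function(probabilities, labels, pos_weight = 3.0) {
  stopifnot(pos_weight > 0, length(probabilities) == length(labels),
            all(labels %in% c(0, 1)))
  p <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  mean(-(pos_weight * labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Save model parameters
#'
#' Writes a single versioned file with the configuration embedded.
#'
#' @param params \code{model_parameters}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(params, path) {
  obj <- list(format = "painattn-model", version = 1L,
              config = attr(params, "config"), params = unclass(params))
  saveRDS(obj, path)
  invisible(path)
}

#' Load model parameters
#'
#' @param path file written by \code{\link{save_model}}.
#' @param expected_config optional \code{model_config}; loading fails if
#'   the stored configuration does not match.
#' @return \code{model_parameters}.
#' @export
load_model <- function(path, expected_config = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "painattn-model")) {
    stop("not a painattn model file: ", path)
  }
  if (!is.null(expected_config) &&
      !identical(unclass(obj$config), unclass(expected_config))) {
    stop("stored model config does not match the expected config")
  }
  structure(obj$params, config = obj$config, class = "model_parameters")
}
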