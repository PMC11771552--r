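#' Build the diagnosis-code vocabulary from training timelines
#'
#' Each distinct \code{"VOCABULARY:code"} identifier occurring in the
#' pre-index sequences of the training split receives a unique integer
#' token, assigned in sorted-string order starting at 2. Tokens 0 and 1
#' are reserved for PAD and UNK respectively; the vocabulary must be
#' built from training patients only so that test-split codes unseen in
#' training map to UNK (leakage-free encoding).
#'
#' @param training_timelines non-empty list of \code{patient_timeline}s.
#' @return A \code{code_vocabulary}: list with \code{token_of} (named
#'   integer vector), \code{size} (distinct codes + 2 reserved tokens).
#' @export
build_vocabulary <- function(training_timelines) {
  if (length(training_timelines) == 0) {
    stop("cannot build a vocabulary from an empty training split")
  }
  keys <- unlist(lapply(training_timelines, function(tl) {
    code_keys(tl$pre_index_codes)
  }))
  keys <- sort(unique(keys))
  structure(list(token_of = stats::setNames(seq_along(keys) + 1L, keys),
                 size = length(keys) + 2L),
            class = "code_vocabulary")
}

#' Token for padded positions
#' @export
PAD_TOKEN <- 0L

#' Token for out-of-vocabulary codes
#' @export
UNK_TOKEN <- 1L

#' Tokenize a patient's pre-index code sequence
#'
#' Returns the variable-length (token, timestamp) series in
#' chronological order (decreasing days until diagnosis). Codes absent
#' from the vocabulary map to the UNK token.
#'
#' @param timeline a \code{patient_timeline}.
#' @param vocab a \code{code_vocabulary}.
#' @return data.frame with integer column \code{token} and numeric
#'   column \code{timestamp} (days until diagnosis).
#' @export
tokenize <- function(timeline, vocab) {
  pc <- timeline$pre_index_codes
  keys <- code_keys(pc)
  tok <- unname(vocab$token_of[keys])
  tok[is.na(tok)] <- UNK_TOKEN
  data.frame(token = as.integer(tok),
             timestamp = as.numeric(pc$days_until_diagnosis))
}

#' Pad or truncate a token series to fixed length
#'
#' Sequences longer than \code{L} keep the \code{L} most recent events
#' (smallest days-until-diagnosis, i.e. the tail of the chronological
#' series); shorter sequences are padded with PAD tokens and timestamp 0.
#'
#' @param series data.frame from \code{\link{tokenize}}.
#' @param L target length, default 128.
#' @return A \code{tokenized_sequence}: list with integer \code{tokens},
#'   numeric \code{timestamps} and logical \code{mask} (TRUE = real
#'   event), each of length \code{L}.
#' @export
pad_truncate <- function(series, L = 128L) {
  n <- nrow(series)
  if (n > L) series <- series[(n - L + 1L):n, , drop = FALSE]
  m <- nrow(series)
  structure(list(tokens = c(series$token, rep(PAD_TOKEN, L - m)),
                 timestamps = c(series$timestamp, rep(0, L - m)),
                 mask = c(rep(TRUE, m), rep(FALSE, L - m))),
            class = "tokenized_sequence")
}

#' Build static-feature schemas from the training split
#'
#' Enumerates the race and ethnicity categories and the survey
#' (question, answer) pairs observed in training, in sorted order.
#'
#' @param training_timelines list of \code{patient_timeline}s.
#' @return A \code{static_schema}: list with \code{race_levels},
#'   \code{ethnicity_levels}, \code{survey_pairs}.
#' @export
build_static_schema <- function(training_timelines) {
  race <- sort(unique(vapply(training_timelines, `[[`, character(1), "race")))
  eth <- sort(unique(vapply(training_timelines, `[[`, character(1),
                            "ethnicity")))
  pairs <- sort(unique(unlist(lapply(training_timelines, function(tl) {
    pair_keys(tl$survey_answers)
  }))))
  structure(list(race_levels = race, ethnicity_levels = eth,
                 survey_pairs = pairs),
            class = "static_schema")
}

#' Encode a patient's static features
#'
#' Age is normalized by dividing by 100; race and ethnicity become
#' one-hot blocks over the schema categories; survey answers become a
#' binary vector over the schema's (question, answer) pairs. A category
#' or pair absent from the schema yields an all-zero block.
#'
#' @param timeline a \code{patient_timeline}.
#' @param schema a \code{static_schema}.
#' @return A \code{static_features}: list with \code{age_norm},
#'   named binary vectors \code{demo_onehot} and \code{survey_onehot}.
#' @export
encode_static <- function(timeline, schema) {
  if (is.na(timeline$age_at_diagnosis) || timeline$age_at_diagnosis < 0) {
    stop("negative or missing age for patient ", timeline$patient_id)
  }
  demo <- c(stats::setNames(as.numeric(schema$race_levels == timeline$race),
                            paste0("race=", schema$race_levels)),
            stats::setNames(as.numeric(schema$ethnicity_levels ==
                                         timeline$ethnicity),
                            paste0("ethnicity=", schema$ethnicity_levels)))
  pairs <- pair_keys(timeline$survey_answers)
  survey <- stats::setNames(as.numeric(schema$survey_pairs %in% pairs),
                            paste0("survey:", schema$survey_pairs))
  structure(list(age_norm = timeline$age_at_diagnosis / 100,
                 demo_onehot = demo, survey_onehot = survey),
            class = "static_features")
}

#' Variance-threshold feature selection for binary columns
#'
#' Retains column \code{j} iff its population variance
#' \code{m_j (1 - m_j)} (with \code{m_j} the column mean) is at least
#' \code{p (1 - p)}, where \code{p} is the allowable probability of a
#' constant value. Retention is non-strict: a feature exactly at the
#' allowable constancy is kept. Fit on the training split only and
#' applied unchanged elsewhere.
#'
#' @param binary_matrix numeric matrix whose entries are all 0 or 1.
#' @param p allowable constancy probability, in (0.5, 1).
#' @return Integer vector of retained column indices.
#' @export
variance_threshold_fit <- function(binary_matrix, p) {
  stopifnot(is.matrix(binary_matrix), p > 0.5, p < 1)
  bad <- which(apply(binary_matrix, 2L, function(x) any(!(x %in% c(0, 1)))))
  if (length(bad) > 0) {
    nm <- colnames(binary_matrix)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("non-binary column(s): ", paste(head(nm, 5L), collapse = ", "))
  }
  m <- colMeans(binary_matrix)
  v <- m * (1 - m)
  # small tolerance so a column exactly at the boundary survives
  # floating-point rounding of its mean
  which(v >= p * (1 - p) - 1e-10)
}

#' Prepare model-ready features for a split cohort
#'
#' Fits the vocabulary, static schemas and variance thresholds on the
#' training split only, then encodes every split: token/timestamp/mask
#' matrices of width \code{seq_len}, a demographic matrix (normalized
#' age plus the variance-selected race/ethnicity one-hots) and a
#' variance-selected survey matrix.
#'
#' @param cohort list of \code{patient_timeline}s.
#' @param splits list with integer index vectors \code{train},
#'   \code{validation}, \code{test} (from \code{\link{split_dataset}}).
#' @param seq_len fixed sequence length, default 128.
#' @param p_demo,p_survey variance-threshold constancy parameters
#'   (defaults 0.9 and 0.8).
#' @return A \code{feature_set}: list with \code{vocab}, \code{schema},
#'   \code{selected_demo}, \code{selected_survey}, and per-split inputs
#'   (\code{tokens}, \code{timestamps}, \code{mask}, \code{demo},
#'   \code{survey} matrices).
#' @export
prepare_features <- function(cohort, splits, seq_len = 128L,
                             p_demo = 0.9, p_survey = 0.8) {
  train_tl <- cohort[splits$train]
  vocab <- build_vocabulary(train_tl)
  schema <- build_static_schema(train_tl)

  enc_all <- lapply(cohort, encode_static, schema = schema)
  demo_full <- do.call(rbind, lapply(enc_all, `[[`, "demo_onehot"))
  survey_full <- do.call(rbind, lapply(enc_all, `[[`, "survey_onehot"))
  age <- vapply(enc_all, `[[`, numeric(1), "age_norm")

  sel_demo <- variance_threshold_fit(demo_full[splits$train, , drop = FALSE],
                                     p_demo)
  sel_survey <- variance_threshold_fit(survey_full[splits$train, , drop = FALSE],
                                       p_survey)

  seqs <- lapply(cohort, function(tl) pad_truncate(tokenize(tl, vocab), seq_len))
  tokens <- do.call(rbind, lapply(seqs, `[[`, "tokens"))
  timestamps <- do.call(rbind, lapply(seqs, `[[`, "timestamps"))
  mask <- do.call(rbind, lapply(seqs, `[[`, "mask"))

  demo_in <- cbind(age_norm = age, demo_full[, sel_demo, drop = FALSE])
  survey_in <- survey_full[, sel_survey, drop = FALSE]

  per_split <- lapply(splits, function(idx) {
    list(tokens = tokens[idx, , drop = FALSE],
         timestamps = timestamps[idx, , drop = FALSE],
         mask = mask[idx, , drop = FALSE],
         demo = demo_in[idx, , drop = FALSE],
         survey = survey_in[idx, , drop = FALSE])
  })
  structure(list(vocab = vocab, schema = schema,
                 selected_demo = sel_demo, selected_survey = sel_survey,
                 demo_dim = ncol(demo_in), survey_dim = ncol(survey_in),
                 splits = per_split),
            class = "feature_set")
}

#' Serialize fitted encoders to JSON
#'
#' @param features a \code{feature_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_feature_schema <- function(features, path) {
  obj <- list(vocabulary = as.list(features$vocab$token_of),
              vocab_size = features$vocab$size,
              race_levels = features$schema$race_levels,
              ethnicity_levels = features$schema$ethnicity_levels,
              survey_pairs = features$schema$survey_pairs,
              selected_demo = features$selected_demo,
              selected_survey = features$selected_survey)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# paste0 on zero-length inputs recycles the separator into a spurious
# length-1 key; these helpers keep empty tables empty
code_keys <- function(codes) {
  if (nrow(codes) == 0) return(character(0))
  paste0(codes$vocabulary, ":", codes$code)
}

pair_keys <- function(survey) {
  if (nrow(survey) == 0) return(character(0))
  paste0(survey$question, "=", survey$answer)
}
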