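#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic breast-cancer cohort with a planted logistic
#' risk signal for chronic pain. The generator emulates the statistical
#' shape of the study data: diagnosis-code sequences with a mean length
#' of 109 codes and day-offset timestamps, age/race/ethnicity
#' demographics (age mean 57.8, sd 10.4), 81 survey question--answer
#' items, opioid exposure intervals, pain-intensity scores, and a
#' marginal outcome prevalence near 17.6%.
#'
#' The outcome is drawn from a logistic model on per-patient indicators
#' (risk-code carriage, planted survey answers, age), never from the
#' classifier's own functional form, so downstream signal recovery is a
#' fair test. Unless \code{baseline_logit} is supplied it is solved at
#' configuration time so that the marginal prevalence equals
#' \code{target_prevalence} exactly under the generative distribution
#' (indicator patterns are enumerated; age is integrated over quantiles).
#'
#' @param n_patients number of patients; default 1131, the study cohort
#'   size.
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output tables.
#' @param code_vocab_size number of distinct background diagnosis codes.
#' @param mean_seq_len mean pre-index sequence length (Poisson per
#'   patient).
#' @param risk_codes data.frame with columns \code{vocabulary},
#'   \code{code}, \code{effect} (log-odds) — codes planted in carriers'
#'   pre-index histories.
#' @param risk_code_carrier_prob probability a patient carries each risk
#'   code.
#' @param risk_survey_items data.frame with columns \code{question},
#'   \code{answer}, \code{effect}.
#' @param age_effect log-odds per decade of age, centred at 55.
#' @param target_prevalence marginal outcome prevalence the baseline is
#'   calibrated to. Default 0.176.
#' @param baseline_logit intercept of the planted logistic model; if
#'   \code{NULL} (default) it is calibrated to \code{target_prevalence}.
#' @param med_persistence probability a positive patient receives a
#'   qualifying (>3-month) opioid exposure chain.
#' @param pain_code_rate probability a positive patient receives a
#'   post-index chronic-pain diagnosis code.
#' @param exacerbation_rate probability a positive patient expresses the
#'   outcome through rising pain-intensity scores.
#' @param negative_opioid_rate probability a negative patient receives
#'   sub-threshold (non-qualifying) opioid exposures.
#' @param n_survey_questions,n_survey_answers survey grid size; answers
#'   are sampled uniformly per question.
#' @param age_mean,age_sd age distribution at diagnosis (normal,
#'   truncated to [20, 90]).
#' @param lookback_days maximum days before the index date a pre-index
#'   code can occur.
#'
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_patients = 1131L,
                       seed = 1L,
                       code_vocab_size = 600L,
                       mean_seq_len = 109,
                       risk_codes = default_risk_codes(),
                       risk_code_carrier_prob = 0.3,
                       risk_survey_items = default_risk_survey_items(),
                       age_effect = 0.5,
                       target_prevalence = 0.176,
                       baseline_logit = NULL,
                       med_persistence = 0.5,
                       pain_code_rate = 0.6,
                       exacerbation_rate = 0.3,
                       negative_opioid_rate = 0.3,
                       n_survey_questions = 81L,
                       n_survey_answers = 4L,
                       age_mean = 57.8,
                       age_sd = 10.4,
                       lookback_days = 3650L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) stop("n_patients must be >= 1")
  probs <- c(risk_code_carrier_prob, med_persistence, pain_code_rate,
             exacerbation_rate, negative_opioid_rate, target_prevalence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  effects <- c(risk_codes$effect, risk_survey_items$effect, age_effect,
               baseline_logit)
  if (any(!is.finite(effects))) stop("effects must be finite")
  if (mean_seq_len <= 0 || code_vocab_size < 1) {
    stop("mean_seq_len and code_vocab_size must be positive")
  }
  cfg <- structure(list(n_patients = n_patients, seed = as.integer(seed),
                        code_vocab_size = as.integer(code_vocab_size),
                        mean_seq_len = mean_seq_len,
                        risk_codes = risk_codes,
                        risk_code_carrier_prob = risk_code_carrier_prob,
                        risk_survey_items = risk_survey_items,
                        age_effect = age_effect,
                        target_prevalence = target_prevalence,
                        baseline_logit = baseline_logit,
                        med_persistence = med_persistence,
                        pain_code_rate = pain_code_rate,
                        exacerbation_rate = exacerbation_rate,
                        negative_opioid_rate = negative_opioid_rate,
                        n_survey_questions = as.integer(n_survey_questions),
                        n_survey_answers = as.integer(n_survey_answers),
                        age_mean = age_mean, age_sd = age_sd,
                        lookback_days = as.integer(lookback_days)),
                   class = "sim_config")
  if (is.null(cfg$baseline_logit)) {
    cfg$baseline_logit <- calibrate_baseline(cfg)
  }
  cfg
}

#' Default planted risk codes
#'
#' Six diagnosis codes given positive log-odds effects in the synthetic
#' outcome model. Chosen from code families plausibly associated with
#' chronic pain (generalized pain, depression, back pain, insomnia,
#' stress); none collides with the cohort-defining or phenotype-defining
#' prefixes.
#'
#' @return data.frame with columns vocabulary, code, effect.
#' @export
default_risk_codes <- function() {
  data.frame(
    vocabulary = c("ICD10CM", "ICD10CM", "ICD9CM", "ICD10CM", "SNOMED",
                   "ICD10CM"),
    code = c("R52.1", "F32.9", "311", "M54.5", "73595000", "G47.00"),
    effect = c(3.0, 2.5, 2.0, 1.8, 1.5, 1.2),
    stringsAsFactors = FALSE)
}

#' Default planted survey risk items
#'
#' Two question--answer pairs with positive log-odds effects; all other
#' survey answers are exchangeable noise.
#'
#' @return data.frame with columns question, answer, effect.
#' @export
default_risk_survey_items <- function() {
  data.frame(question = c("Q010", "Q033"),
             answer = c("A2", "A4"),
             effect = c(1.5, 1.0),
             stringsAsFactors = FALSE)
}

#' Planted outcome probability
#'
#' The synthetic generative model of chronic-pain risk:
#' \code{sigmoid(baseline + sum(code effects) + sum(survey effects) +
#' age_effect * (age - 55) / 10)}.
#'
#' @param code_present logical vector aligned with
#'   \code{config$risk_codes} rows.
#' @param survey_present logical vector aligned with
#'   \code{config$risk_survey_items} rows.
#' @param age age at diagnosis in years (vectorised).
#' @param config a \code{\link{sim_config}}.
#'
#' @return Outcome probability in (0, 1), deterministic given inputs.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 10, baseline_logit = 0,
#'                   risk_codes = data.frame(vocabulary = "ICD10CM",
#'                                           code = "R52.1", effect = 0),
#'                   risk_survey_items = data.frame(question = "Q010",
#'                                                  answer = "A2",
#'                                                  effect = 0),
#'                   age_effect = 0)
#' planted_risk(FALSE, FALSE, 55, cfg)  # 0.5
planted_risk <- function(code_present, survey_present, age, config) {
  stopifnot(inherits(config, "sim_config"))
  code_present <- matrix(as.numeric(code_present), ncol = nrow(config$risk_codes))
  survey_present <- matrix(as.numeric(survey_present),
                           ncol = nrow(config$risk_survey_items))
  eta <- config$baseline_logit +
    as.vector(code_present %*% config$risk_codes$effect) +
    as.vector(survey_present %*% config$risk_survey_items$effect) +
    config$age_effect * (age - 55) / 10
  plogis(eta)
}

# Solve the baseline intercept so the marginal prevalence equals the
# target exactly under the generative law: enumerate all indicator
# patterns (each risk code ~ Bernoulli(carrier prob), each survey item
# ~ Bernoulli(1/n_answers)) and integrate age over midpoint quantiles of
# the truncated normal.
calibrate_baseline <- function(config, n_age_nodes = 201L) {
  k_code <- nrow(config$risk_codes)
  k_surv <- nrow(config$risk_survey_items)
  k <- k_code + k_surv
  if (k > 16L) stop("too many planted effects to enumerate")
  effects <- c(config$risk_codes$effect, config$risk_survey_items$effect)
  p_ind <- c(rep(config$risk_code_carrier_prob, k_code),
             rep(1 / config$n_survey_answers, k_surv))
  patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
  w <- apply(patterns, 1L, function(z) prod(ifelse(z == 1, p_ind, 1 - p_ind)))
  eta_pat <- as.vector(patterns %*% effects)
  u <- (seq_len(n_age_nodes) - 0.5) / n_age_nodes
  ages <- pmin(pmax(qnorm(u, config$age_mean, config$age_sd), 20), 90)
  age_eta <- config$age_effect * (ages - 55) / 10
  marginal <- function(b) {
    sum(w * vapply(eta_pat, function(e) mean(plogis(b + e + age_eta)),
                   numeric(1))) - config$target_prevalence
  }
  uniroot(marginal, c(-20, 10), tol = 1e-10)$root
}

# Deterministic background code universe; excludes every cohort-defining,
# phenotype-defining and planted risk code by construction.
synthetic_code_universe <- function(config) {
  n <- config$code_vocab_size
  per <- ceiling(n / 3)
  i <- seq_len(per)
  univ <- data.frame(
    vocabulary = rep(c("ICD9CM", "ICD10CM", "SNOMED"), each = per),
    code = c(sprintf("7%02d.%d", i %/% 10, i %% 10),
             sprintf("X%02d.%d", i %/% 10, i %% 10),
             sprintf("%d", 10000000L + i)),
    stringsAsFactors = FALSE)
  univ <- univ[seq_len(n), , drop = FALSE]
  key <- paste(univ$vocabulary, univ$code)
  risk_key <- paste(config$risk_codes$vocabulary, config$risk_codes$code)
  univ[!(key %in% risk_key), , drop = FALSE]
}

#' Generate a synthetic OMOP-style cohort
#'
#' Produces the five raw tables (persons, condition occurrences, drug
#' exposures, surveys, pain-score measurements) for a breast-cancer
#' cohort with a planted chronic-pain risk signal. Every patient gets
#' exactly one cohort-defining breast-cancer condition at the index
#' date; pre-index diagnosis codes are sampled with Poisson length and
#' uniform day offsets before the index; outcome-positive patients
#' receive post-index evidence matching the phenotype branches sampled
#' for them (chronic-pain codes, qualifying opioid chains, or rising
#' pain scores), and negative patients may receive non-qualifying
#' opioid exposures as near-boundary noise.
#'
#' All dates are emitted as absolute ISO-8601 dates so the reader must
#' recompute day offsets. The generator's intended labels and branch
#' assignments are attached as attribute \code{"truth"} for verification
#' against the phenotype module.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{raw_cohort_tables}: a list of five
#'   data.frames (\code{persons}, \code{conditions},
#'   \code{drug_exposures}, \code{surveys}, \code{measurements}) with a
#'   \code{"truth"} attribute.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))

  age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 20), 90)
  race <- sample(c("White", "Black or African American", "Asian",
                   "More than one population", "Other"),
                 n, replace = TRUE,
                 prob = c(0.882, 0.075, 0.021, 0.011, 0.011))
  ethnicity <- sample(c("Not Hispanic or Latino", "Hispanic or Latino"),
                      n, replace = TRUE, prob = c(0.98, 0.02))
  index_date <- as.Date("2014-01-01") + sample(0:1825, n, replace = TRUE)
  birth_date <- index_date - round(age * 365.25)

  persons <- data.frame(person_id = ids,
                        birth_date = as.character(birth_date),
                        race = race, ethnicity = ethnicity,
                        stringsAsFactors = FALSE)

  # surveys: every patient answers every question; uniform answers
  nq <- config$n_survey_questions
  questions <- sprintf("Q%03d", seq_len(nq))
  answers_all <- sprintf("A%d", sample.int(config$n_survey_answers, n * nq,
                                           replace = TRUE))
  surveys <- data.frame(person_id = rep(ids, each = nq),
                        question = rep(questions, times = n),
                        answer = answers_all, stringsAsFactors = FALSE)

  # planted indicators
  k_code <- nrow(config$risk_codes)
  carrier <- matrix(runif(n * k_code) < config$risk_code_carrier_prob,
                    nrow = n)
  surv_key <- paste(surveys$question, surveys$answer)
  item_key <- paste(config$risk_survey_items$question,
                    config$risk_survey_items$answer)
  surv_ind <- vapply(item_key, function(kk) {
    hit <- surveys$person_id[surv_key == kk]
    ids %in% hit
  }, logical(n))
  surv_ind <- matrix(surv_ind, nrow = n)

  p_out <- planted_risk(carrier, surv_ind, age, config)
  y <- rbinom(n, 1L, p_out)

  # outcome branches: positives express at least one; fallback = code
  b_code <- y == 1L & runif(n) < config$pain_code_rate
  b_med <- y == 1L & runif(n) < config$med_persistence
  b_ex <- y == 1L & runif(n) < config$exacerbation_rate
  none <- y == 1L & !(b_code | b_med | b_ex)
  b_code[none] <- TRUE

  univ <- synthetic_code_universe(config)

  # pre-index background codes
  len_bg <- pmax(1L, rpois(n, config$mean_seq_len))
  tot_bg <- sum(len_bg)
  bg_pid <- rep(ids, times = len_bg)
  bg_row <- sample.int(nrow(univ), tot_bg, replace = TRUE)
  bg_days <- sample.int(config$lookback_days + 1L, tot_bg, replace = TRUE) - 1L
  conditions <- data.frame(
    person_id = bg_pid,
    vocabulary = univ$vocabulary[bg_row],
    code = univ$code[bg_row],
    event_date = as.character(rep(index_date, times = len_bg) - bg_days),
    stringsAsFactors = FALSE)

  # planted risk codes for carriers, at a random pre-index day
  carry_idx <- which(carrier, arr.ind = TRUE)
  if (nrow(carry_idx) > 0) {
    rc_days <- sample.int(config$lookback_days, nrow(carry_idx),
                          replace = TRUE)
    conditions <- rbind(conditions, data.frame(
      person_id = ids[carry_idx[, 1L]],
      vocabulary = config$risk_codes$vocabulary[carry_idx[, 2L]],
      code = config$risk_codes$code[carry_idx[, 2L]],
      event_date = as.character(index_date[carry_idx[, 1L]] - rc_days),
      stringsAsFactors = FALSE))
  }

  # cohort-defining index condition (one per patient)
  bc_is_icd9 <- runif(n) < 0.1
  bc_vocab <- ifelse(bc_is_icd9, "ICD9CM", "ICD10CM")
  bc_code <- ifelse(bc_is_icd9,
                    sample(c("170.9", "170.4"), n, replace = TRUE),
                    sample(c("C50.911", "C50.912", "C50.919", "C50.411"),
                           n, replace = TRUE))
  conditions <- rbind(conditions, data.frame(
    person_id = ids, vocabulary = bc_vocab, code = bc_code,
    event_date = as.character(index_date), stringsAsFactors = FALSE))

  # post-index background codes (never match the pain-code rules)
  len_post <- rpois(n, 5)
  tot_post <- sum(len_post)
  if (tot_post > 0) {
    post_row <- sample.int(nrow(univ), tot_post, replace = TRUE)
    post_days <- sample.int(1095L, tot_post, replace = TRUE)
    conditions <- rbind(conditions, data.frame(
      person_id = rep(ids, times = len_post),
      vocabulary = univ$vocabulary[post_row],
      code = univ$code[post_row],
      event_date = as.character(rep(index_date, times = len_post) + post_days),
      stringsAsFactors = FALSE))
  }

  # chronic-pain codes for the code branch
  pain_codes <- data.frame(
    vocabulary = c("ICD10CM", "ICD10CM", "ICD9CM", "SNOMED"),
    code = c("G89.29", "G89.4", "338.21", "82423001"),
    stringsAsFactors = FALSE)
  idx_code <- which(b_code)
  if (length(idx_code) > 0) {
    pc <- sample.int(nrow(pain_codes), length(idx_code), replace = TRUE)
    pc_days <- sample(30:1000, length(idx_code), replace = TRUE)
    conditions <- rbind(conditions, data.frame(
      person_id = ids[idx_code],
      vocabulary = pain_codes$vocabulary[pc],
      code = pain_codes$code[pc],
      event_date = as.character(index_date[idx_code] + pc_days),
      stringsAsFactors = FALSE))
  }

  # drug exposures
  meds <- pain_medication_list()
  drug_rows <- list()
  # qualifying chains (union of covered days > 90, gaps <= 90)
  for (i in which(b_med)) {
    n_iv <- sample(4:6, 1L)  # >= 4 intervals of >= 25 covered days: union > 90
    start <- sample(10:150, 1L)
    starts <- ends <- integer(n_iv)
    for (j in seq_len(n_iv)) {
      len <- sample(25:40, 1L)
      starts[j] <- start
      ends[j] <- start + len
      start <- ends[j] + sample(5:60, 1L)
    }
    drug <- paste(sample(meds, n_iv, replace = TRUE),
                  sample(c("5 MG Oral Tablet", "10 MG Oral Tablet", "HCl"),
                         n_iv, replace = TRUE))
    drug_rows[[length(drug_rows) + 1L]] <- data.frame(
      person_id = ids[i], drug = drug,
      start_date = as.character(index_date[i] + starts),
      end_date = as.character(index_date[i] + ends),
      stringsAsFactors = FALSE)
  }
  # sub-threshold exposures for noisy negatives
  for (i in which(y == 0L & runif(n) < config$negative_opioid_rate)) {
    if (runif(1) < 0.5) {
      s <- sample(10:600, 1L); len <- sample(5:60, 1L)
      starts <- s; ends <- s + len
    } else {
      s1 <- sample(10:300, 1L); l1 <- sample(5:40, 1L)
      s2 <- s1 + l1 + sample(120:250, 1L); l2 <- sample(5:40, 1L)
      starts <- c(s1, s2); ends <- c(s1 + l1, s2 + l2)
    }
    drug <- paste(sample(meds, length(starts), replace = TRUE), "Oral Tablet")
    drug_rows[[length(drug_rows) + 1L]] <- data.frame(
      person_id = ids[i], drug = drug,
      start_date = as.character(index_date[i] + starts),
      end_date = as.character(index_date[i] + ends),
      stringsAsFactors = FALSE)
  }
  drug_exposures <- if (length(drug_rows) > 0) {
    do.call(rbind, drug_rows)
  } else {
    data.frame(person_id = character(), drug = character(),
               start_date = character(), end_date = character(),
               stringsAsFactors = FALSE)
  }

  # pain scores: everyone gets a pre-index baseline; post-index scores
  # rise only for the exacerbation branch
  pre_score <- sample(2:5, n, replace = TRUE)
  pre_day <- -sample(30:365, n, replace = TRUE)
  n_post_sc <- sample(0:2, n, replace = TRUE)
  n_post_sc[b_ex] <- pmax(1L, n_post_sc[b_ex])
  meas <- list(data.frame(person_id = ids, pain_score = pre_score,
                          measurement_date = as.character(index_date + pre_day),
                          stringsAsFactors = FALSE))
  idx_ps <- rep(seq_len(n), times = n_post_sc)
  if (length(idx_ps) > 0) {
    low <- vapply(pre_score[idx_ps], function(s) sample.int(s, 1L), integer(1))
    sc_day <- sample(30:1000, length(idx_ps), replace = TRUE)
    meas[[2L]] <- data.frame(person_id = ids[idx_ps], pain_score = low,
                             measurement_date = as.character(index_date[idx_ps] + sc_day),
                             stringsAsFactors = FALSE)
  }
  idx_ex <- which(b_ex)
  if (length(idx_ex) > 0) {
    hi <- pmin(10L, pre_score[idx_ex] + sample(1:4, length(idx_ex),
                                               replace = TRUE))
    hi_day <- sample(30:1000, length(idx_ex), replace = TRUE)
    meas[[length(meas) + 1L]] <- data.frame(
      person_id = ids[idx_ex], pain_score = hi,
      measurement_date = as.character(index_date[idx_ex] + hi_day),
      stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, meas)

  tables <- structure(list(persons = persons,
                           conditions = sort_table(conditions),
                           drug_exposures = sort_table(drug_exposures),
                           surveys = sort_table(surveys),
                           measurements = sort_table(measurements)),
                      class = "raw_cohort_tables")
  attr(tables, "truth") <- data.frame(
    person_id = ids, age = age, probability = p_out, outcome = y,
    branch_code = b_code, branch_medication = b_med, branch_exacerbation = b_ex,
    stringsAsFactors = FALSE)
  tables
}

# canonical row order so equal cohorts serialize to equal bytes
sort_table <- function(df) {
  if (nrow(df) == 0) return(df)
  ord <- do.call(order, unname(as.list(df)))
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write cohort tables to a directory of CSV files
#'
#' Writes one RFC-4180 CSV per table plus a plain-text manifest of row
#' counts. Round-trips through \code{\link{read_tables}}.
#'
#' @param tables a \code{raw_cohort_tables} object.
#' @param directory output directory (created if absent).
#' @return Named integer vector of row counts (the manifest), invisibly.
#' @export
write_tables <- function(tables, directory) {
  stopifnot(inherits(tables, "raw_cohort_tables"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  files <- cohort_table_files()
  counts <- integer(0)
  for (nm in names(files)) {
    write.csv(tables[[nm]], file.path(directory, files[[nm]]),
              row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    counts[nm] <- nrow(tables[[nm]])
  }
  manifest <- file.path(directory, "manifest.txt")
  writeLines(paste0(names(counts), "=", counts), manifest)
  invisible(counts)
}

cohort_table_files <- function() {
  c(persons = "persons.csv",
    conditions = "condition_occurrences.csv",
    drug_exposures = "drug_exposures.csv",
    surveys = "surveys.csv",
    measurements = "measurements.csv")
}
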