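# hand-built timelines and small random schedule generators used across
# the test files

make_timeline <- function(patient_id = "T000001",
                          age = 57.8,
                          race = "White",
                          ethnicity = "Not Hispanic or Latino",
                          index_date = as.Date("2015-06-01"),
                          pre = NULL, post = NULL, drugs = NULL,
                          scores = NULL, survey = NULL) {
  if (is.null(pre)) {
    pre <- data.frame(vocabulary = character(), code = character(),
                      days_until_diagnosis = integer(),
                      stringsAsFactors = FALSE)
  }
  pre <- pre[order(-pre$days_until_diagnosis, pre$vocabulary, pre$code), ,
             drop = FALSE]
  if (is.null(post)) {
    post <- data.frame(vocabulary = character(), code = character(),
                       days_after_diagnosis = integer(),
                       stringsAsFactors = FALSE)
  }
  if (is.null(drugs)) {
    drugs <- data.frame(drug = character(), start_day = integer(),
                        end_day = integer(), stringsAsFactors = FALSE)
  }
  if (is.null(scores)) {
    scores <- data.frame(score = numeric(), day = integer(),
                         period = character(), stringsAsFactors = FALSE)
  }
  if (is.null(survey)) {
    survey <- data.frame(question = character(), answer = character(),
                         stringsAsFactors = FALSE)
  }
  structure(list(patient_id = patient_id, age_at_diagnosis = age,
                 race = race, ethnicity = ethnicity, index_date = index_date,
                 pre_index_codes = pre, post_index_codes = post,
                 drug_intervals = drugs, pain_scores = scores,
                 survey_answers = survey),
            class = "patient_timeline")
}

# drug-interval rows for make_timeline
opioid_intervals <- function(starts, ends, drug = "Oxycodone 5 MG Oral Tablet") {
  data.frame(drug = drug, start_day = as.integer(starts),
             end_day = as.integer(ends), stringsAsFactors = FALSE)
}

# random medication schedule with overlapping, nested and zero-length
# intervals, plus occasional non-pain drugs and pre-index starts
random_schedule_timeline <- function() {
  n <- sample(0:8, 1)
  if (n == 0) return(make_timeline())
  starts <- sample(-50:1200, n, replace = TRUE)
  lens <- sample(0:150, n, replace = TRUE)   # zero-length allowed
  drugs <- sample(c("Oxycodone HCl", "Tramadol 50 MG", "MORPHINE sulfate",
                    "Aspirin 81 MG", "Fentanyl patch"), n, replace = TRUE)
  make_timeline(drugs = data.frame(drug = drugs, start_day = starts,
                                   end_day = starts + lens,
                                   stringsAsFactors = FALSE))
}

# minimal model + batch for model-level tests
tiny_model_fixture <- function(B = 3, L = 10, seed = 7, dropout = 0) {
  cfg <- model_config(vocab_size = 12, demo_dim = 3, survey_dim = 5,
                      d_model = 8, n_heads = 2, n_layers = 2, d_ff = 6,
                      dropout = dropout, demo_hidden = 4, survey_hidden = 4,
                      seq_len = L, seed = seed)
  params <- init_params(cfg)
  set.seed(seed + 1)
  batch <- list(tokens = matrix(sample(0:11, B * L, TRUE), B, L),
                timestamps = matrix(round(runif(B * L, 0, 900)), B, L),
                mask = matrix(TRUE, B, L),
                demo = matrix(runif(B * 3), B, 3),
                survey = matrix(rbinom(B * 5, 1, 0.5), B, 5))
  if (B >= 2) {
    batch$mask[1, (L - 3):L] <- FALSE
    batch$tokens[1, (L - 3):L] <- 0L
    batch$timestamps[1, (L - 3):L] <- 0
  }
  list(cfg = cfg, params = params, batch = batch)
}

# small generated cohort shared across files (generation is cheap; the
# cache avoids repeating the extraction)
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_cohort_fixture <- function() {
  cached_fixture("small_cohort", function() {
    scfg <- sim_config(n_patients = 250, seed = 91)
    tables <- generate_cohort(scfg)
    dir <- tempfile("cohort")
    write_tables(tables, dir)
    cohort <- extract_cohort(read_tables(dir))
    labels <- derive_labels(cohort)
    list(sim_config = scfg, tables = tables, dir = dir, cohort = cohort,
         labels = labels, truth = attr(tables, "truth"))
  })
}
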