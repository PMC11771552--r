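test_that("planted risk follows the logistic model", {
  zero_codes <- default_risk_codes()
  zero_codes$effect <- 0
  zero_items <- default_risk_survey_items()
  zero_items$effect <- 0
  cfg0 <- sim_config(n_patients = 10, baseline_logit = 0,
                     risk_codes = zero_codes, risk_survey_items = zero_items,
                     age_effect = 0)
  expect_equal(planted_risk(rep(FALSE, 6), rep(FALSE, 2), 55, cfg0), 0.5)

  cfg1 <- sim_config(n_patients = 10, baseline_logit = -1.54,
                     risk_codes = zero_codes, risk_survey_items = zero_items,
                     age_effect = 0)
  expect_equal(planted_risk(rep(FALSE, 6), rep(FALSE, 2), 55, cfg1),
               plogis(-1.54), tolerance = 1e-12)
  expect_equal(plogis(-1.54), 0.176, tolerance = 0.005)

  one_code <- zero_codes
  one_code$effect[1] <- 2
  cfg2 <- sim_config(n_patients = 10, baseline_logit = -1.54,
                     risk_codes = one_code, risk_survey_items = zero_items,
                     age_effect = 0)
  expect_equal(planted_risk(c(TRUE, rep(FALSE, 5)), rep(FALSE, 2), 55, cfg2),
               plogis(0.46), tolerance = 1e-12)

  # age enters per decade centred at 55
  cfg3 <- sim_config(n_patients = 10, baseline_logit = 0,
                     risk_codes = zero_codes, risk_survey_items = zero_items,
                     age_effect = 1)
  expect_equal(planted_risk(rep(FALSE, 6), rep(FALSE, 2), 65, cfg3), plogis(1))
})

test_that("configuration is validated", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(n_patients = 10, med_persistence = 1.2),
               "probabilities")
  bad <- default_risk_codes()
  bad$effect[2] <- Inf
  expect_error(sim_config(n_patients = 10, risk_codes = bad), "finite")
})

test_that("baseline calibration hits the target prevalence in expectation", {
  cfg <- sim_config(n_patients = 10, seed = 1)
  # Monte Carlo check of the calibrated intercept, independent of the
  # enumeration used to solve it
  set.seed(404)
  nmc <- 200000
  carrier <- matrix(runif(nmc * 6) < cfg$risk_code_carrier_prob, nmc)
  survey <- matrix(runif(nmc * 2) < 1 / cfg$n_survey_answers, nmc)
  age <- pmin(pmax(rnorm(nmc, cfg$age_mean, cfg$age_sd), 20), 90)
  expect_equal(mean(planted_risk(carrier, survey, age, cfg)), 0.176,
               tolerance = 0.004)
})

test_that("generation is deterministic for identical config and seed", {
  cfg <- sim_config(n_patients = 10, seed = 7)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  for (nm in names(unclass(t1))) expect_identical(t1[[nm]], t2[[nm]])
  d1 <- tempfile(); d2 <- tempfile()
  write_tables(t1, d1); write_tables(t2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("phenotype prevalence lands near the configured target", {
  cfg <- sim_config(n_patients = 5000, seed = 11)
  tables <- generate_cohort(cfg)
  prev <- mean(attr(tables, "truth")$outcome)
  # 99% binomial interval around 0.176 at n = 5000
  expect_gte(prev, 0.14)
  expect_lte(prev, 0.21)
})

test_that("generator branch assignments agree with the derived phenotype", {
  fx <- small_cohort_fixture()
  truth <- fx$truth[match(fx$labels$patient_id, fx$truth$person_id), ]
  expect_equal(fx$labels$positive, truth$outcome == 1)
  # reported branch respects the code > medication > exacerbation precedence
  expected_branch <- ifelse(!truth$outcome, "none",
                     ifelse(truth$branch_code, "code",
                     ifelse(truth$branch_medication, "medication",
                            "exacerbation")))
  expect_equal(fx$labels$branch, expected_branch)
})

test_that("forced branch configuration produces only code evidence", {
  cfg <- sim_config(n_patients = 150, seed = 21, med_persistence = 0,
                    pain_code_rate = 1, exacerbation_rate = 0,
                    negative_opioid_rate = 0)
  tables <- generate_cohort(cfg)
  dir <- tempfile(); write_tables(tables, dir)
  cohort <- extract_cohort(read_tables(dir))
  truth <- attr(tables, "truth")
  pos_ids <- truth$person_id[truth$outcome == 1]
  expect_gt(length(pos_ids), 0)
  for (tl in cohort) {
    if (tl$patient_id %in% pos_ids) {
      expect_true(label_by_codes(tl))
      expect_false(label_by_medication(tl))
    }
  }
})

test_that("tables round-trip through CSV and the manifest counts rows", {
  fx <- small_cohort_fixture()
  counts <- write_tables(fx$tables, fx$dir)
  expect_equal(unname(counts["persons"]), 250L)
  manifest <- readLines(file.path(fx$dir, "manifest.txt"))
  expect_true(paste0("persons=", nrow(fx$tables$persons)) %in% manifest)
  back <- read_tables(fx$dir)
  for (nm in names(unclass(fx$tables))) {
    expect_equal(back[[nm]], fx$tables[[nm]], ignore_attr = TRUE)
  }
})

test_that("an empty cohort writes header-only CSVs", {
  empty <- structure(list(
    persons = data.frame(person_id = character(), birth_date = character(),
                         race = character(), ethnicity = character()),
    conditions = data.frame(person_id = character(), vocabulary = character(),
                            code = character(), event_date = character()),
    drug_exposures = data.frame(person_id = character(), drug = character(),
                                start_date = character(),
                                end_date = character()),
    surveys = data.frame(person_id = character(), question = character(),
                         answer = character()),
    measurements = data.frame(person_id = character(), pain_score = numeric(),
                              measurement_date = character())),
    class = "raw_cohort_tables")
  dir <- tempfile()
  counts <- write_tables(empty, dir)
  expect_equal(sum(counts), 0L)
  for (f in list.files(dir, pattern = "csv$")) {
    expect_length(readLines(file.path(dir, f)), 1L)
  }
})
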