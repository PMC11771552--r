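test_that("code rule matches prefixes/exact codes within the horizon", {
  post <- function(vocab, code, day) {
    data.frame(vocabulary = vocab, code = code, days_after_diagnosis = day,
               stringsAsFactors = FALSE)
  }
  expect_true(label_by_codes(make_timeline(post = post("ICD10CM", "G89.29", 30))))
  expect_false(label_by_codes(make_timeline(post = post("ICD10CM", "G89.4", 1200))))
  expect_true(label_by_codes(make_timeline(post = post("SNOMED", "82423001", 10))))
  expect_false(label_by_codes(make_timeline(post = post("SNOMED", "8242300", 10))))
  expect_true(label_by_codes(make_timeline(post = post("ICD9CM", "338.21", 100))))
  expect_false(label_by_codes(make_timeline(post = post("ICD9CM", "338.1", 100))))
  expect_false(label_by_codes(make_timeline()))
})

test_that("medication rule combines the gap and covered-day conditions", {
  # gap 20 <= 90, union 31 + 71 = 102 > 90
  expect_true(label_by_medication(
    make_timeline(drugs = opioid_intervals(c(10, 60), c(40, 130)))))
  # a single 41-day exposure is not > 90 days
  expect_false(label_by_medication(
    make_timeline(drugs = opioid_intervals(10, 50, drug = "Tramadol 50 MG"))))
  # gap 160 > 90 splits into chains of 41 and 101 days; the second
  # chain alone qualifies
  expect_true(label_by_medication(
    make_timeline(drugs = opioid_intervals(c(0, 200), c(40, 300)))))
  # same total days but split into two sub-threshold chains
  expect_false(label_by_medication(
    make_timeline(drugs = opioid_intervals(c(0, 200), c(40, 260)))))
  # non-pain medications never count
  expect_false(label_by_medication(
    make_timeline(drugs = opioid_intervals(c(10, 60), c(40, 130),
                                           drug = "Aspirin 81 MG"))))
  # pre-index exposures do not count toward the chain
  expect_false(label_by_medication(
    make_timeline(drugs = opioid_intervals(c(-200, 10), c(-80, 50)))))
})

test_that("drug matching is a case-insensitive substring match", {
  expect_true(label_by_medication(
    make_timeline(drugs = opioid_intervals(c(10, 60), c(40, 130),
                                           drug = "OXYCODONE hydrochloride 5 MG"))))
})

test_that("exacerbation rule compares post-index maximum to latest baseline", {
  scores <- function(score, day) {
    data.frame(score = score, day = day,
               period = ifelse(day <= 0, "pre", "post"),
               stringsAsFactors = FALSE)
  }
  expect_true(label_by_exacerbation(
    make_timeline(scores = scores(c(3, 7), c(-20, 100)))))
  expect_false(label_by_exacerbation(
    make_timeline(scores = scores(c(5, 5), c(-20, 100)))))
  expect_false(label_by_exacerbation(
    make_timeline(scores = scores(c(7, 8), c(30, 100)))))  # no pre baseline
  # the latest pre-index score is the baseline, not the maximum
  expect_true(label_by_exacerbation(
    make_timeline(scores = scores(c(6, 2, 4), c(-300, -10, 50)))))
  # post-horizon increases do not count
  expect_false(label_by_exacerbation(
    make_timeline(scores = scores(c(3, 9), c(-20, 1200)))))
})

test_that("derived label reports the first true branch in precedence order", {
  both <- make_timeline(
    post = data.frame(vocabulary = "ICD10CM", code = "G89.29",
                      days_after_diagnosis = 30L, stringsAsFactors = FALSE),
    drugs = opioid_intervals(c(10, 60), c(40, 130)))
  lab <- derive_label(both)
  expect_true(lab$positive)
  expect_equal(lab$branch, "code")

  med_only <- derive_label(
    make_timeline(drugs = opioid_intervals(c(10, 60), c(40, 130))))
  expect_true(med_only$positive)
  expect_equal(med_only$branch, "medication")

  none <- derive_label(make_timeline())
  expect_false(none$positive)
  expect_equal(none$branch, "none")
  expect_true(none$positive == (none$branch != "none"))
})

test_that("medication rule agrees with the day-expansion oracle", {
  expect_false(oracle_medication_label(make_timeline()))
  set.seed(515)
  for (i in seq_len(300)) {
    tl <- random_schedule_timeline()
    expect_identical(label_by_medication(tl), oracle_medication_label(tl),
                     label = sprintf("schedule %d", i))
  }
})

test_that("adding an exposure never flips a positive medication label", {
  set.seed(616)
  for (i in seq_len(100)) {
    tl <- random_schedule_timeline()
    before <- label_by_medication(tl)
    s <- sample(0:1000, 1)
    extra <- opioid_intervals(s, s + sample(0:120, 1))
    tl$drug_intervals <- rbind(tl$drug_intervals, extra)
    after <- label_by_medication(tl)
    if (before) expect_true(after)
  }
})

test_that("events beyond the follow-up horizon never change any label", {
  set.seed(717)
  for (i in seq_len(50)) {
    tl <- random_schedule_timeline()
    tl$post_index_codes <- data.frame(
      vocabulary = "ICD10CM", code = "I10", days_after_diagnosis = 40L,
      stringsAsFactors = FALSE)
    tl$pain_scores <- data.frame(score = c(4, 3), day = c(-30L, 200L),
                                 period = c("pre", "post"),
                                 stringsAsFactors = FALSE)
    before <- derive_label(tl)
    # append evidence of every kind strictly beyond 1095 days
    tl$post_index_codes <- rbind(tl$post_index_codes, data.frame(
      vocabulary = "ICD10CM", code = "G89.29", days_after_diagnosis = 1200L,
      stringsAsFactors = FALSE))
    tl$drug_intervals <- rbind(tl$drug_intervals,
                               opioid_intervals(1200, 1400))
    tl$pain_scores <- rbind(tl$pain_scores,
                            data.frame(score = 10, day = 1200L,
                                       period = "post",
                                       stringsAsFactors = FALSE))
    after <- derive_label(tl)
    expect_identical(before$positive, after$positive)
    expect_identical(before$branch, after$branch)
  }
})

test_that("zero-length and nested intervals are counted by distinct days", {
  # two one-day fills four months apart: two chains of 1 day each
  expect_false(label_by_medication(
    make_timeline(drugs = opioid_intervals(c(10, 130), c(10, 130)))))
  # nested interval does not break the chain formed by its parent
  expect_true(label_by_medication(
    make_timeline(drugs = opioid_intervals(c(0, 5, 120), c(100, 10, 130)))))
})
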