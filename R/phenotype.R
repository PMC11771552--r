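#' Chronic-pain phenotype
#'
#' The computable chronic-pain outcome within a 3-year post-diagnosis
#' horizon, combining three alternative definitions evaluated as a pure
#' OR: (1) a post-index chronic-pain diagnosis code (ICD-10-CM prefix
#' G89, ICD-9-CM prefix 338.2, or SNOMED code 82423001 exactly); (2) a
#' pain-medication exposure chain whose administrations are consecutive
#' (gaps of at most 90 days) and whose covered days exceed 90 in total;
#' (3) exacerbation: a post-index pain-intensity score strictly above the
#' latest pre-index score, when scores exist on both sides of the index.
#'
#' @name phenotype
NULL

#' Code-based chronic-pain detection
#'
#' TRUE iff any post-index diagnosis code within the follow-up horizon
#' matches a configured chronic-pain code rule.
#'
#' @param timeline a \code{patient_timeline}.
#' @param config a \code{\link{cohort_config}}.
#' @return logical.
#' @export
label_by_codes <- function(timeline, config = cohort_config()) {
  pc <- timeline$post_index_codes
  if (nrow(pc) == 0) return(FALSE)
  in_horizon <- pc$days_after_diagnosis <= config$followup_days
  any(code_matches_rule(pc$vocabulary[in_horizon], pc$code[in_horizon],
                        config$chronic_pain_code_rules))
}

# pain-medication intervals restricted to post-index days within the
# horizon: case-insensitive substring match on the configured ingredient
# list, start >= 0, end clipped to followup_days
qualifying_intervals <- function(timeline, config) {
  di <- timeline$drug_intervals
  if (nrow(di) == 0) return(di[0L, , drop = FALSE])
  pattern <- tolower(di$drug)
  is_pain <- Reduce(`|`, lapply(tolower(config$pain_medications),
                                function(m) grepl(m, pattern, fixed = TRUE)))
  di <- di[is_pain & di$start_day >= 0L &
             di$start_day <= config$followup_days, , drop = FALSE]
  if (nrow(di) == 0) return(di)
  if (any(di$end_day < di$start_day)) {
    stop("drug interval with end before start for patient ",
         timeline$patient_id)
  }
  di$end_day <- pmin(di$end_day, config$followup_days)
  di[order(di$start_day, di$end_day), , drop = FALSE]
}

#' Medication-duration chronic-pain rule
#'
#' TRUE iff some maximal chain of pain-medication exposures satisfies
#' both conditions: consecutive administration (each exposure starts at
#' most 90 days after the chain's running end) and a union of covered
#' days exceeding 90. Covered days are counted inclusively
#' (an interval from day 10 to day 40 covers 31 days) and overlaps are
#' not double-counted.
#'
#' @inheritParams label_by_codes
#' @return logical.
#' @export
label_by_medication <- function(timeline, config = cohort_config()) {
  di <- qualifying_intervals(timeline, config)
  if (nrow(di) == 0) return(FALSE)
  chain_covers(di)
}

# walk the start-sorted intervals once, splitting chains when the gap to
# the chain's running maximum end exceeds 90 days, and accumulating the
# union of covered days within each chain by interval merging
chain_covers <- function(di, max_gap = 90L, min_days = 90L) {
  n <- nrow(di)
  chain_cov <- 0L
  merge_s <- di$start_day[1L]
  merge_e <- di$end_day[1L]
  chain_max_end <- di$end_day[1L]
  for (i in seq_len(n)[-1L]) {
    s <- di$start_day[i]; e <- di$end_day[i]
    if (s - chain_max_end > max_gap) {
      # close chain
      chain_cov <- chain_cov + (merge_e - merge_s + 1L)
      if (chain_cov > min_days) return(TRUE)
      chain_cov <- 0L
      merge_s <- s; merge_e <- e; chain_max_end <- e
    } else {
      if (s > merge_e + 1L) {
        chain_cov <- chain_cov + (merge_e - merge_s + 1L)
        merge_s <- s; merge_e <- e
      } else {
        merge_e <- max(merge_e, e)
      }
      chain_max_end <- max(chain_max_end, e)
    }
  }
  chain_cov <- chain_cov + (merge_e - merge_s + 1L)
  chain_cov > min_days
}

#' Exacerbation rule
#'
#' TRUE iff pain scores exist both before and after the index date and
#' the maximum post-index score within the follow-up horizon strictly
#' exceeds the latest pre-index score (the pre-diagnosis baseline).
#'
#' @inheritParams label_by_codes
#' @return logical.
#' @export
label_by_exacerbation <- function(timeline, config = cohort_config()) {
  ps <- timeline$pain_scores
  pre <- ps[ps$period == "pre", , drop = FALSE]
  post <- ps[ps$period == "post" & ps$day <= config$followup_days, ,
             drop = FALSE]
  if (nrow(pre) == 0 || nrow(post) == 0) return(FALSE)
  latest_day <- max(pre$day)
  baseline <- max(pre$score[pre$day == latest_day])
  max(post$score) > baseline
}

#' Derive the chronic-pain label
#'
#' Positivity is the OR of the three rules; the reported branch is the
#' first TRUE rule in the order code, medication, exacerbation.
#'
#' @inheritParams label_by_codes
#' @return A \code{chronic_pain_label}: list with \code{positive},
#'   \code{branch} (one of \code{"code"}, \code{"medication"},
#'   \code{"exacerbation"}, \code{"none"}) and \code{evidence}, a
#'   data.frame of the events supporting the decision.
#' @export
derive_label <- function(timeline, config = cohort_config()) {
  if (label_by_codes(timeline, config)) {
    pc <- timeline$post_index_codes
    hit <- code_matches_rule(pc$vocabulary, pc$code,
                             config$chronic_pain_code_rules) &
      pc$days_after_diagnosis <= config$followup_days
    return(new_label(TRUE, "code", pc[hit, , drop = FALSE]))
  }
  if (label_by_medication(timeline, config)) {
    return(new_label(TRUE, "medication", qualifying_intervals(timeline, config)))
  }
  if (label_by_exacerbation(timeline, config)) {
    ps <- timeline$pain_scores
    return(new_label(TRUE, "exacerbation",
                     ps[ps$period == "post" &
                          ps$day <= config$followup_days, , drop = FALSE]))
  }
  new_label(FALSE, "none", NULL)
}

new_label <- function(positive, branch, evidence) {
  structure(list(positive = positive, branch = branch, evidence = evidence),
            class = "chronic_pain_label")
}

#' Label every patient in a cohort
#'
#' @param cohort list of \code{patient_timeline} objects.
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame with columns patient_id, positive, branch.
#' @export
derive_labels <- function(cohort, config = cohort_config()) {
  labs <- lapply(cohort, derive_label, config = config)
  data.frame(patient_id = vapply(cohort, `[[`, character(1), "patient_id"),
             positive = vapply(labs, `[[`, logical(1), "positive"),
             branch = vapply(labs, `[[`, character(1), "branch"),
             stringsAsFactors = FALSE)
}

#' Day-expansion oracle for the medication rule
#'
#' Independent re-implementation of \code{\link{label_by_medication}}:
#' expands every qualifying exposure into its set of integer days, forms
#' maximal day runs whose inter-day gaps are at most 90, and returns
#' TRUE iff some run covers more than 90 distinct days. Used to verify
#' the interval-arithmetic path.
#'
#' @inheritParams label_by_codes
#' @return logical.
#' @export
oracle_medication_label <- function(timeline, config = cohort_config()) {
  di <- qualifying_intervals(timeline, config)
  if (nrow(di) == 0) return(FALSE)
  days <- sort(unique(unlist(Map(seq.int, di$start_day, di$end_day))))
  run_sizes <- integer(0)
  run_len <- 1L
  if (length(days) > 1) {
    for (i in 2:length(days)) {
      if (days[i] - days[i - 1L] > 90L) {
        run_sizes <- c(run_sizes, run_len)
        run_len <- 1L
      } else {
        run_len <- run_len + 1L
      }
    }
  }
  run_sizes <- c(run_sizes, run_len)
  any(run_sizes > 90L)
}
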