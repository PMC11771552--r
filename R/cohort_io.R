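#' Read OMOP-style cohort tables from a directory
#'
#' Reads the five CSV tables written by \code{\link{write_tables}}
#' (persons, condition occurrences, drug exposures, surveys,
#' measurements), validates dates as ISO-8601 and reports malformed rows
#' with their row numbers.
#'
#' @param directory path containing the five CSV files.
#' @return A \code{raw_cohort_tables} object.
#' @export
read_tables <- function(directory) {
  files <- cohort_table_files()
  paths <- file.path(directory, files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing cohort table file(s): ",
         paste(files[missing], collapse = ", "))
  }
  out <- list()
  for (nm in names(files)) {
    df <- read.csv(file.path(directory, files[[nm]]),
                   colClasses = "character", fileEncoding = "UTF-8")
    out[[nm]] <- df
  }
  date_cols <- list(persons = "birth_date", conditions = "event_date",
                    drug_exposures = c("start_date", "end_date"),
                    measurements = "measurement_date")
  for (nm in names(date_cols)) {
    for (col in date_cols[[nm]]) {
      # a missing birth date is allowed (the patient is excluded later,
      # with a warning, during cohort extraction)
      validate_iso_dates(out[[nm]][[col]], files[[nm]], col,
                         allow_empty = nm == "persons")
    }
  }
  out$measurements$pain_score <- as.numeric(out$measurements$pain_score)
  bad_end <- which(as.Date(out$drug_exposures$end_date) <
                     as.Date(out$drug_exposures$start_date))
  if (length(bad_end) > 0) {
    stop("drug_exposures: end_date before start_date at row(s) ",
         paste(head(bad_end, 5L), collapse = ", "))
  }
  check_children(out)
  structure(out, class = "raw_cohort_tables")
}

validate_iso_dates <- function(x, file, col, allow_empty = FALSE) {
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x) &
    !is.na(as.Date(x, format = "%Y-%m-%d", optional = TRUE))
  if (allow_empty) ok <- ok | is.na(x) | x == ""
  if (any(!ok)) {
    bad <- which(!ok)
    stop(sprintf("%s: invalid ISO-8601 date(s) in column '%s' at row(s) %s",
                 file, col, paste(head(bad, 5L), collapse = ", ")))
  }
  invisible(TRUE)
}

check_children <- function(tables) {
  ids <- tables$persons$person_id
  for (nm in c("conditions", "drug_exposures", "surveys", "measurements")) {
    orphan <- setdiff(unique(tables[[nm]]$person_id), ids)
    if (length(orphan) > 0) {
      stop(nm, ": patient id(s) absent from persons: ",
           paste(head(orphan, 5L), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Assemble per-patient timelines for the breast-cancer cohort
#'
#' Selects patients with at least one condition matching a
#' cohort-defining code prefix, sets the index date to the earliest such
#' condition, and re-expresses all events as day offsets relative to the
#' index date. Conditions dated on the index day itself are assigned to
#' the pre-index sequence with offset 0 (they were known at diagnosis
#' time and must not leak outcome information); same-day events are
#' ordered by vocabulary then code string for deterministic sequences.
#'
#' @param tables a \code{raw_cohort_tables} object.
#' @param config a \code{\link{cohort_config}}.
#' @return List of \code{patient_timeline} objects. Patients whose birth
#'   date is missing are excluded with a warning.
#' @export
extract_cohort <- function(tables, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cond <- tables$conditions
  is_bc <- rep(FALSE, nrow(cond))
  for (v in names(config$breast_cancer_prefixes)) {
    for (pre in config$breast_cancer_prefixes[[v]]) {
      is_bc <- is_bc | (cond$vocabulary == v & startsWith(cond$code, pre))
    }
  }
  bc <- cond[is_bc, , drop = FALSE]
  if (nrow(bc) == 0) return(list())
  bc_date <- as.Date(bc$event_date)
  index_by_patient <- tapply(as.numeric(bc_date), bc$person_id, min)
  pids <- names(index_by_patient)

  persons <- tables$persons
  rownames(persons) <- persons$person_id
  bd <- persons[pids, "birth_date"]
  no_birth <- pids[!(pids %in% persons$person_id) | is.na(bd) | !nzchar(bd)]
  if (length(no_birth) > 0) {
    warning("excluding ", length(no_birth),
            " patient(s) with a cohort-defining code but no birth date: ",
            paste(head(no_birth, 5L), collapse = ", "))
    pids <- setdiff(pids, no_birth)
  }

  cond_by <- split(cond, cond$person_id)
  drug_by <- split(tables$drug_exposures, tables$drug_exposures$person_id)
  surv_by <- split(tables$surveys, tables$surveys$person_id)
  meas_by <- split(tables$measurements, tables$measurements$person_id)
  empty <- function(df) df[0L, , drop = FALSE]

  lapply(pids, function(pid) {
    index_date <- as.Date(index_by_patient[[pid]], origin = "1970-01-01")
    birth <- as.Date(persons[pid, "birth_date"])
    age <- as.numeric(index_date - birth) / 365.25

    pc <- cond_by[[pid]]
    delta <- as.integer(index_date - as.Date(pc$event_date))
    pre <- pc[delta >= 0L, , drop = FALSE]
    pre_days <- delta[delta >= 0L]
    ord <- order(-pre_days, pre$vocabulary, pre$code)
    pre_index_codes <- data.frame(vocabulary = pre$vocabulary[ord],
                                  code = pre$code[ord],
                                  days_until_diagnosis = pre_days[ord],
                                  stringsAsFactors = FALSE)
    post <- pc[delta < 0L, , drop = FALSE]
    post_days <- -delta[delta < 0L]
    ord2 <- order(post_days, post$vocabulary, post$code)
    post_index_codes <- data.frame(vocabulary = post$vocabulary[ord2],
                                   code = post$code[ord2],
                                   days_after_diagnosis = post_days[ord2],
                                   stringsAsFactors = FALSE)

    dr <- drug_by[[pid]]
    drug_intervals <- if (is.null(dr)) {
      data.frame(drug = character(), start_day = integer(),
                 end_day = integer(), stringsAsFactors = FALSE)
    } else {
      di <- data.frame(drug = dr$drug,
                       start_day = as.integer(as.Date(dr$start_date) - index_date),
                       end_day = as.integer(as.Date(dr$end_date) - index_date),
                       stringsAsFactors = FALSE)
      di[order(di$start_day, di$end_day, di$drug), , drop = FALSE]
    }

    ms <- meas_by[[pid]]
    pain_scores <- if (is.null(ms)) {
      data.frame(score = numeric(), day = integer(), period = character(),
                 stringsAsFactors = FALSE)
    } else {
      d <- as.integer(as.Date(ms$measurement_date) - index_date)
      ps <- data.frame(score = ms$pain_score, day = d,
                       period = ifelse(d <= 0L, "pre", "post"),
                       stringsAsFactors = FALSE)
      ps[order(ps$day, ps$score), , drop = FALSE]
    }

    sv <- surv_by[[pid]]
    survey_answers <- if (is.null(sv)) {
      data.frame(question = character(), answer = character(),
                 stringsAsFactors = FALSE)
    } else {
      sa <- data.frame(question = sv$question, answer = sv$answer,
                       stringsAsFactors = FALSE)
      sa[order(sa$question, sa$answer), , drop = FALSE]
    }

    structure(list(patient_id = pid,
                   age_at_diagnosis = age,
                   race = persons[pid, "race"],
                   ethnicity = persons[pid, "ethnicity"],
                   index_date = index_date,
                   pre_index_codes = pre_index_codes,
                   post_index_codes = post_index_codes,
                   drug_intervals = drug_intervals,
                   pain_scores = pain_scores,
                   survey_answers = survey_answers),
              class = "patient_timeline")
  })
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf("<patient_timeline %s: age %.1f, %d pre-index codes, %d post-index codes, %d drug intervals>\n",
              x$patient_id, x$age_at_diagnosis, nrow(x$pre_index_codes),
              nrow(x$post_index_codes), nrow(x$drug_intervals)))
  invisible(x)
}
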