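#' Cohort and phenotype configuration
#'
#' Defines how the breast-cancer cohort is identified and how the
#' chronic-pain phenotype is evaluated: the cohort-defining code prefixes
#' per vocabulary, the post-diagnosis follow-up horizon, the list of pain
#' medications for the exposure-duration rule, and the chronic-pain
#' diagnosis-code rules.
#'
#' The defaults follow the study conventions: cohort entry on the first
#' diagnosis code starting with ICD-9-CM \code{170} or ICD-10-CM
#' \code{C50}; a 3-year (1095-day) follow-up; chronic-pain codes are
#' ICD-10-CM prefix \code{G89}, ICD-9-CM prefix \code{338.2} and the
#' exact SNOMED code \code{82423001}. Note that ICD-9-CM \code{170}
#' denotes bone neoplasms in the standard coding system (breast is
#' 174/175); the literal default is kept deliberately and is
#' configurable.
#'
#' @param breast_cancer_prefixes named list mapping vocabulary to a
#'   character vector of code prefixes that define cohort entry.
#' @param followup_days integer horizon after the index date within which
#'   phenotype evidence counts. Default 1095 (3 years at 365 days).
#' @param pain_medications character vector of pain-medication ingredient
#'   names; drug exposures are matched by case-insensitive substring.
#' @param chronic_pain_code_rules named list mapping vocabulary to a list
#'   with elements \code{type} (\code{"prefix"} or \code{"exact"}) and
#'   \code{value}.
#'
#' @return An object of class \code{cohort_config}.
#' @export
#' @examples
#' cfg <- cohort_config()
#' cfg$followup_days
cohort_config <- function(breast_cancer_prefixes = list(ICD9CM = "170",
                                                        ICD10CM = "C50"),
                          followup_days = 1095L,
                          pain_medications = pain_medication_list(),
                          chronic_pain_code_rules = list(
                            ICD10CM = list(type = "prefix", value = "G89"),
                            ICD9CM  = list(type = "prefix", value = "338.2"),
                            SNOMED  = list(type = "exact",  value = "82423001"))) {
  stopifnot(length(breast_cancer_prefixes) >= 1)
  if (any(!nzchar(unlist(breast_cancer_prefixes)))) {
    stop("breast_cancer_prefixes must be non-empty strings")
  }
  followup_days <- as.integer(followup_days)
  if (is.na(followup_days) || followup_days <= 0L) {
    stop("followup_days must be a positive integer")
  }
  structure(list(breast_cancer_prefixes = breast_cancer_prefixes,
                 followup_days = followup_days,
                 pain_medications = pain_medications,
                 chronic_pain_code_rules = chronic_pain_code_rules),
            class = "cohort_config")
}

#' Pain medications used by the medication-duration rule
#'
#' The 17 opioid-class ingredients considered evidence of pain-medication
#' administration.
#'
#' @return Character vector of ingredient names.
#' @export
pain_medication_list <- function() {
  c("Buprenorphine", "Butorphanol", "Codeine", "Dihydrocodeine",
    "Fentanyl", "Hydrocodone", "Hydromorphone", "Levorphanol tartrate",
    "Meperidine hydrochloride", "Methadone", "Morphine", "Opium",
    "Oxycodone", "Oxymorphone", "Pentazocine", "Tapentadol", "Tramadol")
}

code_matches_rule <- function(vocabulary, code, rule_map) {
  out <- logical(length(code))
  for (v in names(rule_map)) {
    rule <- rule_map[[v]]
    sel <- vocabulary == v
    if (!any(sel)) next
    out[sel] <- if (rule$type == "prefix") {
      startsWith(code[sel], rule$value)
    } else {
      code[sel] == rule$value
    }
  }
  out
}
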