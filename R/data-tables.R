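# Bundled desk-scale inputs from the screener's validation campaign.
#
# validation_2x2.csv: the published 2x2 cross-classifications of the
# screener against (i) the age-appropriate cancellation test and (ii) known
# condition status, per age group.  Cell layout follows contingency_2x2():
# a = reference+/index+, b = reference+/index-, c = reference-/index+,
# d = reference-/index-; the screener is always the index test.
#
# screening_findings.csv: the per-child findings of the follow-up clinical
# assessment of the 23 flagged children from the school screening campaign
# (questionnaire score, trigger, whether clinical findings were present,
# and the three-criterion CVI checklist count; checklist blank for the six
# children in whom expert assessment excluded a visual issue).

#' Published validation 2x2 tables
#'
#' @return Data frame of the six published 2x2 tables (three age groups
#'   against the cancellation tests; three against known condition status).
#' @export
validation_tables <- function() {
  read.csv(system.file("extdata", "validation_2x2.csv", package = "cviscreen"),
           stringsAsFactors = FALSE)
}

#' Published screening follow-up findings
#'
#' @return Data frame with one row per flagged child of the screening
#'   campaign: `child`, `age`, `hvfqi_score` (11-question inventory total;
#'   NA where it could not be administered), `screen_trigger`,
#'   `findings_present`, `checklist_met` (0-3; NA for children in whom a
#'   visual issue was excluded).
#' @export
screening_findings <- function() {
  read.csv(system.file("extdata", "screening_findings.csv", package = "cviscreen"),
           stringsAsFactors = FALSE)
}

#' Full agreement/diagnostic report for a set of 2x2 tables
#'
#' For each table computes Cohen's kappa with the marginal null-variance
#' test, the Landis-Koch band, and sensitivity/specificity with Wald
#' intervals.
#'
#' @param tables Data frame in the layout of [validation_tables()].
#' @return List of per-table report blocks.
#' @export
validation_report <- function(tables = validation_tables()) {
  lapply(seq_len(nrow(tables)), function(i) {
    row <- tables[i, ]
    tab <- contingency_2x2(row$a, row$b, row$c, row$d,
                           reference = row$reference_test, index = "screener")
    kap <- cohen_kappa(tab)
    ss <- sensitivity_specificity(tab)
    list(comparison = row$comparison, age_group = row$age_group,
         reference_test = row$reference_test,
         counts = c(a = row$a, b = row$b, c = row$c, d = row$d),
         kappa = unclass(kap),
         sensitivity = unclass(ss$sensitivity),
         specificity = unclass(ss$specificity))
  })
}
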