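# Domain vocabulary: the six PrEP activities recorded on the time-and-motion
# form (side-effect treatment is folded into follow-up counselling at parse
# time) and the six HCW cadres, ordered by the salary hierarchy.

#' PrEP activity and HCW cadre vocabularies
#'
#' `prep_activities()` returns the six PrEP activity codes used throughout the
#' package; `hcw_cadres()` returns the six health-care-worker cadre codes,
#' ordered from the highest-paid (nursing sister) to the lowest-paid (peer
#' supporter) cadre.
#'
#' Initiation visits can involve `PRE_COUNSELING`, `RISK_ASSESSMENT`,
#' `ELIGIBILITY_SCREENING`, `INITIATION`, and `BLOOD_TESTING`; follow-up
#' visits involve `FOLLOWUP_COUNSELING` and `BLOOD_TESTING`.
#'
#' @return A character vector of canonical codes.
#' @export
#' @examples
#' prep_activities()
#' hcw_cadres()
prep_activities <- function() {
  c("PRE_COUNSELING", "RISK_ASSESSMENT", "ELIGIBILITY_SCREENING",
    "INITIATION", "FOLLOWUP_COUNSELING", "BLOOD_TESTING")
}

#' @rdname prep_activities
#' @export
hcw_cadres <- function() {
  c("NURSING_SISTER", "NURSE", "NURSE_ASSISTANT",
    "PHLEBOTOMIST", "HTS_COUNSELOR", "PEER_SUPPORTER")
}

#' @rdname prep_activities
#' @export
initiation_activities <- function() {
  c("PRE_COUNSELING", "RISK_ASSESSMENT", "ELIGIBILITY_SCREENING",
    "INITIATION", "BLOOD_TESTING")
}

#' @rdname prep_activities
#' @export
followup_activities <- function() {
  c("FOLLOWUP_COUNSELING", "BLOOD_TESTING")
}

# Alias recorded on the form; collapsed because no separate time coefficient
# is estimated for side-effect treatment.
.activity_aliases <- c(SIDE_EFFECT_TREATMENT = "FOLLOWUP_COUNSELING")

#' Parse and serialise activity sets
#'
#' Activity sets travel in delimited files as semicolon-joined canonical
#' tokens (e.g. `"FOLLOWUP_COUNSELING;BLOOD_TESTING"`).  `parse_activities()`
#' maps the form's side-effect-treatment token to follow-up counselling (with
#' a message) and rejects unknown tokens; `format_activities()` is its
#' inverse, emitting tokens in the canonical order.
#'
#' @param x character vector of semicolon-joined activity tokens.
#' @param quiet suppress the remapping message.
#' @return `parse_activities()`: a list of character vectors;
#'   `format_activities()`: a character vector.
#' @export
parse_activities <- function(x, quiet = FALSE) {
  out <- lapply(strsplit(as.character(x), ";", fixed = TRUE), function(tok) {
    tok <- trimws(tok)
    tok <- tok[nzchar(tok)]
    remap <- tok %in% names(.activity_aliases)
    if (any(remap) && !quiet) {
      inform("Mapped SIDE_EFFECT_TREATMENT to FOLLOWUP_COUNSELING.")
    }
    tok[remap] <- .activity_aliases[tok[remap]]
    bad <- setdiff(tok, prep_activities())
    if (length(bad) > 0) {
      abort(paste0("Unknown activity token(s): ", paste(bad, collapse = ", ")))
    }
    sort_activities(unique(tok))
  })
  out
}

#' @rdname parse_activities
#' @param sets a list of character vectors of activity codes.
#' @export
format_activities <- function(sets) {
  vapply(sets, function(a) paste(sort_activities(a), collapse = ";"),
         character(1))
}

#' @rdname parse_activities
#' @param a a character vector of activity codes.
#' @export
sort_activities <- function(a) {
  a[order(match(a, prep_activities()))]
}
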