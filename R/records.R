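# Reading, validating, consolidating and summarising time-and-motion records.
#
# One record = one HCW-client interaction: who saw whom, when the interaction
# started and ended (minute resolution), how many of those minutes were
# non-PrEP care, and which PrEP activities were performed.

.record_columns <- c("client_id", "clinic_id", "visit_date", "hcw_id",
                     "cadre", "start", "end", "nonprep_minutes",
                     "activities", "months_since_prep_start")

#' Read time-and-motion records from a delimited file
#'
#' Expects a comma-separated file with header columns `client_id, clinic_id,
#' visit_date, hcw_id, cadre, start, end, nonprep_minutes, activities,
#' months_since_prep_start`.  Dates are ISO-8601 (`YYYY-MM-DD`), clock times
#' `HH:MM` at minute resolution, and activity sets semicolon-joined canonical
#' tokens (see [parse_activities()]).  Every row is validated; offending rows
#' are reported by number.
#'
#' @param path path to a CSV file.
#' @param quiet suppress informational messages.
#' @return A tibble of validated records, one row per interaction, with
#'   `start`/`end` as integer minutes since midnight and `activities` as a
#'   list-column of activity-code vectors.
#' @seealso [write_records()], [validate_records()]
#' @export
read_records <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("Record file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(.record_columns, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Record file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  rec <- tibble(
    client_id = raw$client_id,
    clinic_id = raw$clinic_id,
    visit_date = as.Date(raw$visit_date),
    hcw_id = raw$hcw_id,
    cadre = raw$cadre,
    start = parse_clock(raw$start),
    end = parse_clock(raw$end),
    nonprep_minutes = as.numeric(raw$nonprep_minutes),
    activities = parse_activities(raw$activities, quiet = quiet),
    months_since_prep_start = as.integer(raw$months_since_prep_start)
  )
  validate_records(rec)
  rec
}

#' @rdname read_records
#' @param records a record tibble as returned by [read_records()].
#' @export
write_records <- function(records, path) {
  out <- records
  out$start <- format_clock(out$start)
  out$end <- format_clock(out$end)
  out$activities <- format_activities(out$activities)
  out$visit_date <- format(out$visit_date, "%Y-%m-%d")
  readr::write_csv(out[, .record_columns], path, progress = FALSE)
  invisible(path)
}

#' @rdname read_records
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, paste0(
        what, " in row(s) ", paste(head(rows, 5), collapse = ", "),
        if (length(rows) > 5) paste0(" (+", length(rows) - 5, " more)")))
    }
  }
  flag(is.na(records$visit_date), "unparseable visit_date")
  flag(is.na(records$start) | is.na(records$end), "unparseable clock time")
  flag(records$end < records$start, "end before start")
  flag(records$nonprep_minutes < 0, "negative nonprep_minutes")
  flag(records$nonprep_minutes > (records$end - records$start),
       "nonprep_minutes exceeding interaction length")
  flag(lengths(records$activities) == 0, "empty activity set")
  flag(!(records$cadre %in% hcw_cadres()), "unknown cadre")
  flag(records$months_since_prep_start < 0, "negative months_since_prep_start")
  if (length(problems) > 0) {
    abort(paste0("Invalid time-and-motion records: ",
                 paste(problems, collapse = "; ")))
  }
  invisible(records)
}

parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", as.character(x)))
  vapply(m, function(g) {
    if (length(g) != 3) return(NA_integer_)
    h <- as.integer(g[2]); mi <- as.integer(g[3])
    if (h > 23 || mi > 59) return(NA_integer_)
    h * 60L + mi
  }, integer(1))
}

format_clock <- function(minutes) {
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

#' PrEP minutes of an interaction
#'
#' Interaction time net of non-PrEP care: `(end - start) - nonprep_minutes`.
#'
#' @param records a validated record tibble.
#' @return numeric vector of PrEP minutes, one per record, all `>= 0`.
#' @export
prep_minutes <- function(records) {
  validate_records(records)
  as.numeric(records$end - records$start - records$nonprep_minutes)
}

#' Apply study exclusions
#'
#' Drops records inside an excluded calendar window (e.g. the first month of
#' a demonstration project, before routine care is established) and records
#' from excluded HCWs (e.g. study mentors).  The number of exclusions is
#' reported and attached as attribute `n_excluded`.
#'
#' @param records record tibble.
#' @param window `NULL` or a length-2 Date vector `c(from, to)`, inclusive.
#' @param hcw_ids character vector of HCW ids to exclude.
#' @param quiet suppress the exclusion-count message.
#' @return the filtered record tibble.
#' @export
apply_exclusions <- function(records, window = NULL, hcw_ids = character(0),
                             quiet = FALSE) {
  drop <- rep(FALSE, nrow(records))
  if (!is.null(window)) {
    window <- as.Date(window)
    stopifnot(length(window) == 2)
    drop <- drop | (records$visit_date >= window[1] &
                    records$visit_date <= window[2])
  }
  if (length(hcw_ids) > 0) drop <- drop | records$hcw_id %in% hcw_ids
  out <- records[!drop, , drop = FALSE]
  if (!quiet) inform(paste0("Excluded ", sum(drop), " of ", nrow(records),
                            " records."))
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Consolidate interactions into activity episodes
#'
#' Interactions recorded for the same client, visit and PrEP activity (the
#' same activity split across forms, or shared between HCWs) are merged into
#' one episode carrying their total PrEP time.  An interaction covering `k`
#' activities contributes its PrEP minutes evenly, `1/k` to each: the split
#' only affects episode-level accounting, never the visit total.
#'
#' @param records validated record tibble.
#' @return A tibble with one row per (client, visit date, activity):
#'   `prep_minutes`, plus list-columns `hcw_ids` and `cadres`.
#' @export
consolidate <- function(records) {
  validate_records(records)
  pm <- prep_minutes(records)
  k <- lengths(records$activities)
  long <- tibble(
    client_id = rep(records$client_id, k),
    visit_date = rep(records$visit_date, k),
    activity = unlist(records$activities),
    prep_minutes = rep(pm / k, k),
    hcw_id = rep(records$hcw_id, k),
    cadre = rep(records$cadre, k)
  )
  long %>%
    group_by(.data$client_id, .data$visit_date, .data$activity) %>%
    summarise(
      prep_minutes = sum(.data$prep_minutes),
      hcw_ids = list(unique(.data$hcw_id)),
      cadres = list(unique(.data$cadre)),
      .groups = "drop"
    ) %>%
    arrange(.data$client_id, .data$visit_date,
            match(.data$activity, prep_activities()))
}

#' Detect a workflow interruption within one visit
#'
#' A visit's workflow counts as interrupted when the client was seen by more
#' than one HCW, or by the same HCW in non-contiguous interactions (any
#' positive gap at minute resolution).
#'
#' @param interactions the records of a single (client, visit date) pair.
#' @return logical scalar.
#' @export
detect_interruption <- function(interactions) {
  if (n_distinct(interactions$hcw_id) > 1) return(TRUE)
  if (nrow(interactions) < 2) return(FALSE)
  o <- order(interactions$start, interactions$end)
  s <- interactions$start[o]
  e <- interactions$end[o]
  any(s[-1] > cummax(e[-length(e)]))
}

#' Build visit sequences from records
#'
#' Groups records by (client, visit date) into visit-level sequences: the set
#' of PrEP activities, total PrEP minutes, number of distinct HCWs, and the
#' interruption flag from [detect_interruption()].  A client's earliest
#' recorded visit is the first contact with PrEP and is classified
#' `INITIATION_VISIT` irrespective of whether PrEP initiation itself was
#' performed; all later visits are `FOLLOWUP_VISIT`.  A follow-up visit whose
#' activities are exclusively initiation-only ones is still classified by the
#' first-contact rule, with a warning.
#'
#' @param records validated record tibble.
#' @return A tibble with one row per visit: `client_id`, `visit_date`,
#'   `clinic_id`, `visit_class`, `activities` (list-column),
#'   `total_prep_minutes`, `n_activities` (distinct activities),
#'   `n_activity_entries` (activity mentions as recorded, before
#'   consolidation — exceeds `n_activities` when the same activity was
#'   recorded in several interactions), `n_hcws`, `cadres`, `interrupted`,
#'   `months_since_prep_start`.
#' @export
build_visits <- function(records) {
  validate_records(records)
  pm <- prep_minutes(records)
  keys <- paste(records$client_id, records$visit_date, sep = "\r")
  split_idx <- split(seq_len(nrow(records)), keys)
  rows <- lapply(split_idx, function(idx) {
    sub <- records[idx, , drop = FALSE]
    acts <- sort_activities(unique(unlist(sub$activities)))
    tibble(
      client_id = sub$client_id[1],
      visit_date = sub$visit_date[1],
      clinic_id = sub$clinic_id[1],
      activities = list(acts),
      total_prep_minutes = sum(pm[idx]),
      n_activities = length(acts),
      n_activity_entries = sum(lengths(sub$activities)),
      n_hcws = n_distinct(sub$hcw_id),
      cadres = list(sort(unique(sub$cadre))),
      interrupted = detect_interruption(sub),
      months_since_prep_start = sub$months_since_prep_start[1]
    )
  })
  visits <- bind_rows(rows) %>%
    arrange(.data$client_id, .data$visit_date) %>%
    group_by(.data$client_id) %>%
    mutate(visit_class = ifelse(row_number() == 1,
                                "INITIATION_VISIT", "FOLLOWUP_VISIT")) %>%
    ungroup()
  init_only <- setdiff(initiation_activities(), followup_activities())
  odd <- visits$visit_class == "FOLLOWUP_VISIT" &
    vapply(visits$activities, function(a) all(a %in% init_only), logical(1))
  if (any(odd)) {
    warn(paste0(sum(odd), " follow-up visit(s) contain only initiation-type ",
                "activities; classified by the first-contact rule."))
  }
  visits[, c("client_id", "visit_date", "clinic_id", "visit_class",
             "activities", "total_prep_minutes", "n_activities",
             "n_activity_entries", "n_hcws", "cadres", "interrupted",
             "months_since_prep_start")]
}

#' Summarise visit durations by activity sequence
#'
#' Per distinct activity signature (the ordered activity set of a visit):
#' count, mean, range, median and interquartile range of total PrEP minutes.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param visits a visit tibble from [build_visits()].
#' @return A tibble with columns `visit_class`, `signature`, `n`, `mean`,
#'   `min`, `max`, `median`, `iqr_low`, `iqr_high`.
#' @export
summarize_sequences <- function(visits) {
  stopifnot(nrow(visits) >= 1)
  visits %>%
    mutate(signature = format_activities(.data$activities)) %>%
    group_by(.data$visit_class, .data$signature) %>%
    summarise(
      n = n(),
      mean = mean(.data$total_prep_minutes),
      min = min(.data$total_prep_minutes),
      max = max(.data$total_prep_minutes),
      median = stats::median(.data$total_prep_minutes),
      iqr_low = unname(stats::quantile(.data$total_prep_minutes, 0.25,
                                       type = 7)),
      iqr_high = unname(stats::quantile(.data$total_prep_minutes, 0.75,
                                        type = 7)),
      .groups = "drop"
    ) %>%
    arrange(.data$visit_class, .data$signature)
}
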