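test_that("well-formed files parse and round-trip field-for-field", {
  rec <- make_records(list(
    list(client_id = "a", activities = list(c("PRE_COUNSELING",
                                              "RISK_ASSESSMENT"))),
    list(client_id = "b", start = 600L, end = 630L, nonprep_minutes = 5),
    list(client_id = "c", cadre = "HTS_COUNSELOR")
  ))
  path <- write_record_file(rec)
  got <- read_records(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$start, rec$start)
  expect_equal(got$activities, rec$activities)
  # write -> read -> write reproduces the file byte-for-byte
  path2 <- write_record_file(got)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema and invariant violations are rejected with row context", {
  rec <- make_records(list(list(start = 600L, end = 540L)))
  path <- write_record_file(make_records(list(list())))
  lines <- readLines(path)
  writeLines(gsub("clinic_id", "clinic", lines), path)
  expect_error(read_records(path), "missing column")
  expect_error(validate_records(rec), "end before start.*row\\(s\\) 1")
  rec2 <- make_records(list(list(), list(nonprep_minutes = 25)))
  expect_error(validate_records(rec2), "exceeding.*row\\(s\\) 2")
})

test_that("side-effect treatment is folded into follow-up counselling", {
  expect_message(
    out <- parse_activities("SIDE_EFFECT_TREATMENT;BLOOD_TESTING"),
    "FOLLOWUP_COUNSELING")
  expect_equal(out[[1]], c("FOLLOWUP_COUNSELING", "BLOOD_TESTING"))
  expect_error(parse_activities("NOT_A_THING"), "Unknown activity")
})

test_that("prep minutes subtract non-PrEP care, including the boundary", {
  rec <- make_records(list(
    list(start = 540L, end = 560L, nonprep_minutes = 5),
    list(start = 540L, end = 560L, nonprep_minutes = 0),
    list(start = 540L, end = 550L, nonprep_minutes = 10)
  ))
  expect_equal(prep_minutes(rec), c(15, 20, 0))
})

test_that("exclusions drop the calendar window and listed HCWs, and an empty
           config is the identity", {
  rec <- make_records(list(
    list(client_id = "a", visit_date = "2017-08-15"),
    list(client_id = "b", visit_date = "2017-10-05"),
    list(client_id = "c", visit_date = "2017-10-05", hcw_id = "mentor_1")
  ))
  out <- apply_exclusions(rec,
                          window = c("2017-08-01", "2017-08-31"),
                          hcw_ids = "mentor_1", quiet = TRUE)
  expect_equal(out$client_id, "b")
  expect_equal(attr(out, "n_excluded"), 2)
  same <- apply_exclusions(rec, quiet = TRUE)
  attr(same, "n_excluded") <- NULL
  expect_equal(as.data.frame(same), as.data.frame(rec))
})

test_that("consolidation merges same-activity records and conserves minutes", {
  rec <- make_records(list(
    list(hcw_id = "h1", start = 540L, end = 546L),
    list(hcw_id = "h2", start = 550L, end = 554L)
  ))
  eps <- consolidate(rec)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$prep_minutes, 10)
  expect_setequal(eps$hcw_ids[[1]], c("h1", "h2"))

  # different activities stay separate
  rec2 <- make_records(list(
    list(activities = list("PRE_COUNSELING")),
    list(activities = list("RISK_ASSESSMENT"), start = 560L, end = 570L)
  ))
  expect_equal(nrow(consolidate(rec2)), 2)

  # a k-activity interaction splits its minutes evenly
  rec3 <- make_records(list(
    list(activities = list(c("PRE_COUNSELING", "RISK_ASSESSMENT")),
         start = 540L, end = 550L)
  ))
  eps3 <- consolidate(rec3)
  expect_equal(eps3$prep_minutes, c(5, 5))

  # exact conservation on a synthetic batch
  sim <- generate_records(generator_config(n_visits = 60), seed = 11)
  expect_equal(sum(consolidate(sim$records)$prep_minutes),
               sum(prep_minutes(sim$records)))
})

test_that("interruption detection follows the multi-HCW / gap rule", {
  two_hcw <- make_records(list(
    list(hcw_id = "h1", start = 540L, end = 550L),
    list(hcw_id = "h2", start = 550L, end = 560L)
  ))
  expect_true(detect_interruption(two_hcw))
  contiguous <- make_records(list(list(hcw_id = "h1")))
  expect_false(detect_interruption(contiguous))
  gap <- make_records(list(
    list(hcw_id = "h1", start = 540L, end = 550L),
    list(hcw_id = "h1", start = 570L, end = 580L)
  ))
  expect_true(detect_interruption(gap))
  back_to_back <- make_records(list(
    list(hcw_id = "h1", start = 540L, end = 550L),
    list(hcw_id = "h1", start = 550L, end = 560L)
  ))
  expect_false(detect_interruption(back_to_back))
})

test_that("visits classify by first contact, irrespective of activities", {
  rec <- make_records(list(
    list(client_id = "a", visit_date = "2018-01-10",
         activities = list(c("PRE_COUNSELING", "RISK_ASSESSMENT"))),
    list(client_id = "a", visit_date = "2018-02-10",
         activities = list(c("FOLLOWUP_COUNSELING", "BLOOD_TESTING"))),
    list(client_id = "b", visit_date = "2018-03-01",
         activities = list("BLOOD_TESTING"))
  ))
  v <- build_visits(rec)
  expect_equal(v$visit_class[v$client_id == "a"],
               c("INITIATION_VISIT", "FOLLOWUP_VISIT"))
  expect_equal(v$visit_class[v$client_id == "b"], "INITIATION_VISIT")
  # every client has exactly one initiation visit
  tab <- table(v$client_id, v$visit_class)
  expect_true(all(tab[, "INITIATION_VISIT"] == 1))

  # a later visit with initiation-only activities still follows the rule
  odd <- make_records(list(
    list(client_id = "a", visit_date = "2018-01-10"),
    list(client_id = "a", visit_date = "2018-02-10",
         activities = list("INITIATION"))
  ))
  expect_warning(v2 <- build_visits(odd), "first-contact")
  expect_equal(v2$visit_class, c("INITIATION_VISIT", "FOLLOWUP_VISIT"))
})

test_that("visits record distinct activities and recorded entries separately", {
  rec <- make_records(list(
    list(hcw_id = "h1", start = 540L, end = 550L,
         activities = list("BLOOD_TESTING")),
    list(hcw_id = "h2", start = 555L, end = 560L,
         activities = list("BLOOD_TESTING"))
  ))
  v <- build_visits(rec)
  expect_equal(v$n_activities, 1)
  expect_equal(v$n_activity_entries, 2)
  expect_true(v$interrupted)
})

test_that("sequence summaries match a brute-force sort-based oracle", {
  rec <- make_records(list(
    list(client_id = "a", start = 540L, end = 550L),
    list(client_id = "b", start = 540L, end = 555L),
    list(client_id = "c", start = 540L, end = 560L)
  ))
  s <- summarize_sequences(build_visits(rec))
  expect_equal(s$n, 3)
  expect_equal(s$mean, 15)
  expect_equal(s$median, 15)
  expect_equal(s$min, 10)
  expect_equal(s$max, 20)

  single <- summarize_sequences(build_visits(make_records(list(list()))))
  expect_equal(single$mean, single$median)
  expect_equal(single$min, single$max)

  # independent recomputation from raw rows on a synthetic batch
  sim <- generate_records(generator_config(n_visits = 80), seed = 5)
  visits <- suppressWarnings(build_visits(sim$records))
  s2 <- summarize_sequences(visits)
  key <- paste(visits$visit_class, format_activities(visits$activities))
  for (i in seq_len(nrow(s2))) {
    dur <- sort(visits$total_prep_minutes[
      key == paste(s2$visit_class[i], s2$signature[i])])
    expect_equal(s2$n[i], length(dur))
    expect_equal(s2$mean[i], sum(dur) / length(dur))
    expect_equal(s2$median[i], unname(stats::quantile(dur, .5, type = 7)))
    expect_equal(s2$iqr_low[i], unname(stats::quantile(dur, .25, type = 7)))
    expect_equal(s2$iqr_high[i], unname(stats::quantile(dur, .75, type = 7)))
    expect_true(s2$min[i] <= s2$iqr_low[i] &&
                s2$iqr_low[i] <= s2$median[i] &&
                s2$median[i] <= s2$iqr_high[i] &&
                s2$iqr_high[i] <= s2$max[i])
  }
})
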