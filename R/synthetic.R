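# Seeded generator of synthetic time-and-motion records with the statistical
# structure the decomposition assumes: a visit's duration is a fixed overhead
# plus per-activity times, a per-activity economy-of-sequence reduction, an
# interruption penalty, optional experience and clinic effects, and Gaussian
# noise.  Totals are recorded at minute resolution and split into interaction
# records consistent with the interruption flag, so the full pipeline
# (consolidation, visit building, interruption detection, regression) can be
# exercised and checked against the returned ground truth.

default_signatures <- function() {
  list(
    INITIATION_VISIT = list(
      sets = list(
        c("PRE_COUNSELING"),
        c("RISK_ASSESSMENT"),
        c("ELIGIBILITY_SCREENING"),
        c("INITIATION"),
        c("PRE_COUNSELING", "RISK_ASSESSMENT"),
        c("PRE_COUNSELING", "BLOOD_TESTING"),
        c("PRE_COUNSELING", "INITIATION"),
        c("ELIGIBILITY_SCREENING", "INITIATION"),
        c("PRE_COUNSELING", "RISK_ASSESSMENT", "BLOOD_TESTING"),
        c("PRE_COUNSELING", "RISK_ASSESSMENT", "ELIGIBILITY_SCREENING"),
        c("BLOOD_TESTING", "ELIGIBILITY_SCREENING", "INITIATION"),
        c("PRE_COUNSELING", "RISK_ASSESSMENT", "BLOOD_TESTING",
          "ELIGIBILITY_SCREENING"),
        c("PRE_COUNSELING", "RISK_ASSESSMENT", "ELIGIBILITY_SCREENING",
          "INITIATION"),
        c("PRE_COUNSELING", "RISK_ASSESSMENT", "BLOOD_TESTING",
          "ELIGIBILITY_SCREENING", "INITIATION")
      ),
      weights = c(2, 2, 1, 7, 42, 1, 1, 41, 40, 18, 1, 2, 6, 9)
    ),
    FOLLOWUP_VISIT = list(
      sets = list(
        c("FOLLOWUP_COUNSELING"),
        c("FOLLOWUP_COUNSELING", "BLOOD_TESTING"),
        c("BLOOD_TESTING")
      ),
      weights = c(56, 27, 28)
    )
  )
}

#' Configuration for the synthetic record generator
#'
#' Defaults emulate the study conditions of the Eswatini demonstration
#' project: 250 visits across 6 clinics, an initiation-visit fraction of
#' 130/213, a 56% interruption rate, common activity signatures with their
#' observed frequencies, visit-total noise of 5 minutes, and true
#' coefficients equal to the published Model-2-shaped estimates.  Experience
#' and clinic effects default to zero (they belong to extended
#' specifications).
#'
#' @param n_visits number of visits to generate.
#' @param beta0 fixed time cost (minutes).
#' @param beta named vector of per-activity minutes covering
#'   [prep_activities()].
#' @param gamma_count minutes per additional activity in a sequence
#'   (typically negative: economy of sequence).
#' @param gamma_int minutes added by an interrupted workflow.
#' @param delta_exp minutes per month of clinic PrEP experience.
#' @param clinic_offsets named numeric vector of clinic-level minute offsets
#'   (names become clinic ids).
#' @param cadre_availability named list clinic id -> cadres staffed there.
#' @param noise_sd standard deviation of Gaussian noise on visit totals
#'   (minutes).
#' @param initiation_fraction fraction of visits that are initiation visits.
#' @param p_interrupt probability a visit's workflow is interrupted.
#' @param months_range integer range of months since PrEP introduction.
#' @param signatures activity-set sampler: list with `INITIATION_VISIT` and
#'   `FOLLOWUP_VISIT`, each `list(sets = , weights = )`.
#' @param p_split_activity probability that, in an interrupted visit with at
#'   least two activities, one activity spans both interactions (recording a
#'   duplicate entry, as when two HCWs join the same activity).  Interrupted
#'   single-activity visits always split their one activity.
#' @param nonprep_max maximum non-PrEP minutes added per interaction.
#' @param round_minutes record totals at minute resolution (clock times are
#'   whole minutes).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_visits = 250,
                             beta0 = 8.9,
                             beta = c(PRE_COUNSELING = 4.3,
                                      RISK_ASSESSMENT = 3.3,
                                      ELIGIBILITY_SCREENING = 3.8,
                                      INITIATION = 11,
                                      FOLLOWUP_COUNSELING = 4.7,
                                      BLOOD_TESTING = 4.0),
                             gamma_count = -1.5,
                             gamma_int = 3.4,
                             delta_exp = 0,
                             clinic_offsets = setNames(
                               rep(0, 6), paste0("clinic_", 1:6)),
                             cadre_availability = NULL,
                             noise_sd = 5,
                             initiation_fraction = 130 / 213,
                             p_interrupt = 0.56,
                             months_range = c(2L, 18L),
                             signatures = default_signatures(),
                             p_split_activity = 0.15,
                             nonprep_max = 8,
                             round_minutes = TRUE) {
  stopifnot(n_visits >= 1, noise_sd >= 0,
            initiation_fraction >= 0, initiation_fraction <= 1,
            p_interrupt >= 0, p_interrupt <= 1,
            all(prep_activities() %in% names(beta)))
  clinics <- names(clinic_offsets)
  if (is.null(cadre_availability)) {
    cadre_availability <- setNames(vector("list", length(clinics)), clinics)
    for (i in seq_along(clinics)) {
      cads <- c("NURSING_SISTER", "NURSE", "NURSE_ASSISTANT")
      if (i <= 4) cads <- c(cads, "HTS_COUNSELOR")
      if (i <= 2) cads <- c(cads, "PHLEBOTOMIST")
      if (i == 1) cads <- c(cads, "PEER_SUPPORTER")
      cadre_availability[[i]] <- cads
    }
  }
  for (vc in c("INITIATION_VISIT", "FOLLOWUP_VISIT")) {
    sig <- signatures[[vc]]
    if (is.null(sig) || length(sig$sets) == 0) {
      abort(paste0("No activity signatures enabled for ", vc, "."))
    }
    stopifnot(length(sig$sets) == length(sig$weights), all(sig$weights >= 0))
    if (sum(sig$weights) <= 0) {
      abort(paste0("All signature weights are zero for ", vc, "."))
    }
  }
  structure(list(
    n_visits = n_visits, beta0 = beta0, beta = beta[prep_activities()],
    gamma_count = gamma_count, gamma_int = gamma_int, delta_exp = delta_exp,
    clinic_offsets = clinic_offsets,
    cadre_availability = cadre_availability,
    noise_sd = noise_sd, initiation_fraction = initiation_fraction,
    p_interrupt = p_interrupt, months_range = as.integer(months_range),
    signatures = signatures, p_split_activity = p_split_activity,
    nonprep_max = nonprep_max, round_minutes = round_minutes
  ), class = "generator_config")
}

sample_signature <- function(sig) {
  sig$sets[[sample.int(length(sig$sets), 1, prob = sig$weights)]]
}

#' Generate synthetic time-and-motion records
#'
#' Draws visits (class, clinic, activity signature, interruption status,
#' experience month), computes each visit's total PrEP time from the
#' generating coefficients plus Gaussian noise (resampled until the total is
#' at least 1 minute, then rounded to whole minutes when `round_minutes`),
#' and splits it into interaction records that reproduce the interruption
#' status exactly: interrupted visits are served by two HCWs or by one HCW
#' with a gap between interactions; uninterrupted visits by one HCW in one
#' contiguous interaction.  Non-PrEP minutes are added per interaction.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; all randomness flows from it.
#' @return list with `records` (tibble in the on-disk schema, parseable by
#'   the full pipeline) and `truth` (one row per visit: class, activities,
#'   interruption flag, realized total PrEP minutes, linear-predictor
#'   expectation, clinic, month), plus the `config`.
#' @export
generate_records <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  n <- config$n_visits
  n_init <- round(n * config$initiation_fraction)
  if (n_init == 0 && n > 0) n_init <- 1L  # follow-ups need a first contact
  n_fu <- n - n_init
  clinics <- names(config$clinic_offsets)
  study_start <- as.Date("2017-10-01")

  client_ids <- sprintf("client_%03d", seq_len(n_init))
  client_clinic <- setNames(sample(clinics, n_init, replace = TRUE),
                            client_ids)
  client_month0 <- setNames(
    sample(seq(config$months_range[1], config$months_range[2]),
           n_init, replace = TRUE), client_ids)

  visit_plan <- tibble(
    client_id = c(client_ids,
                  if (n_fu > 0) sample(client_ids, n_fu, replace = TRUE)),
    visit_class = c(rep("INITIATION_VISIT", n_init),
                    rep("FOLLOWUP_VISIT", n_fu))
  )
  # follow-up index per client orders later visits after the initiation
  visit_plan <- visit_plan %>%
    group_by(.data$client_id) %>%
    mutate(visit_no = row_number()) %>%
    ungroup()

  # per-clinic HCW pool: two HCWs per available cadre
  pool <- list()
  for (cl in clinics) {
    cads <- config$cadre_availability[[cl]]
    pool[[cl]] <- tibble(
      hcw_id = paste0("hcw_", cl, "_", seq_len(2 * length(cads))),
      cadre = rep(cads, each = 2)
    )
  }

  # accumulate plain vectors; tibbles are assembled once at the end
  nv <- nrow(visit_plan)
  rec <- list(client_id = character(0), clinic_id = character(0),
              visit_date = numeric(0), hcw_id = character(0),
              cadre = character(0), start = integer(0), end = integer(0),
              nonprep_minutes = numeric(0), activities = list(),
              months_since_prep_start = integer(0))
  push_rec <- function(cid, clinic, date, hcw, cadre, start, end, np, acts,
                       month) {
    j <- length(rec$client_id) + 1L
    rec$client_id[j] <<- cid; rec$clinic_id[j] <<- clinic
    rec$visit_date[j] <<- as.numeric(date); rec$hcw_id[j] <<- hcw
    rec$cadre[j] <<- cadre; rec$start[j] <<- as.integer(start)
    rec$end[j] <<- as.integer(end); rec$nonprep_minutes[j] <<- np
    rec$activities[[j]] <<- acts; rec$months_since_prep_start[j] <<- month
  }
  tr <- list(client_id = character(nv), visit_date = numeric(nv),
             clinic_id = character(nv), visit_class = character(nv),
             activities = vector("list", nv), total_prep_minutes = numeric(nv),
             expected_minutes = numeric(nv), n_activities = integer(nv),
             n_activity_entries = integer(nv), interrupted = logical(nv),
             months_since_prep_start = integer(nv))
  for (i in seq_len(nv)) {
    cid <- visit_plan$client_id[i]
    vclass <- visit_plan$visit_class[i]
    vno <- visit_plan$visit_no[i]
    clinic <- client_clinic[[cid]]
    month <- client_month0[[cid]] + (vno - 1L)
    date <- study_start + month * 30 + sample.int(27, 1) + (vno - 1L)
    acts <- sample_signature(config$signatures[[vclass]])
    interrupted <- runif(1) < config$p_interrupt
    # plan the interaction split first: it fixes the recorded-entry count,
    # which is what the economy-of-sequence term acts on
    a1 <- a2 <- NULL
    if (interrupted) {
      if (length(acts) >= 2) {
        cut <- sample.int(length(acts) - 1, 1)
        a1 <- acts[seq_len(cut)]; a2 <- acts[-seq_len(cut)]
        if (runif(1) < config$p_split_activity) {
          a2 <- c(a1[length(a1)], a2)  # activity continued across the break
        }
      } else {
        a1 <- acts; a2 <- acts  # one activity interrupted mid-way
      }
      n_entries <- length(a1) + length(a2)
    } else {
      n_entries <- length(acts)
    }
    mu <- config$beta0 + sum(config$beta[acts]) +
      config$gamma_count * n_entries +
      config$gamma_int * as.numeric(interrupted) +
      config$delta_exp * month +
      config$clinic_offsets[[clinic]]
    total <- mu + rnorm(1, 0, config$noise_sd)
    tries <- 0
    while (total < 1 && config$noise_sd > 0 && tries < 1000) {
      total <- mu + rnorm(1, 0, config$noise_sd)
      tries <- tries + 1
    }
    total <- max(total, 1)
    if (config$round_minutes) total <- max(1, round(total))

    p <- pool[[clinic]]
    start0 <- sample(480:780, 1)  # between 08:00 and 13:00
    nonprep <- function() sample(0:config$nonprep_max, 1)
    if (!interrupted) {
      h <- sample.int(nrow(p), 1)
      np <- nonprep()
      push_rec(cid, clinic, date, p$hcw_id[h], p$cadre[h],
               start0, start0 + total + np, np, acts, month)
    } else {
      two_hcws <- runif(1) < 0.5 && nrow(p) >= 2
      if (two_hcws) {
        h <- sample.int(nrow(p), 2)
        gap <- sample(0:5, 1)
      } else {
        h <- rep(sample.int(nrow(p), 1), 2)
        gap <- sample(1:15, 1)  # same HCW: gap >= 1 marks the interruption
      }
      t1 <- floor(total / 2); t2 <- total - t1
      np1 <- nonprep(); np2 <- nonprep()
      end1 <- start0 + t1 + np1
      start2 <- end1 + gap
      push_rec(cid, clinic, date, p$hcw_id[h[1]], p$cadre[h[1]],
               start0, end1, np1, a1, month)
      push_rec(cid, clinic, date, p$hcw_id[h[2]], p$cadre[h[2]],
               start2, start2 + t2 + np2, np2, a2, month)
    }
    tr$client_id[i] <- cid; tr$visit_date[i] <- as.numeric(date)
    tr$clinic_id[i] <- clinic; tr$visit_class[i] <- vclass
    tr$activities[[i]] <- sort_activities(acts)
    tr$total_prep_minutes[i] <- total; tr$expected_minutes[i] <- mu
    tr$n_activities[i] <- length(acts); tr$n_activity_entries[i] <- n_entries
    tr$interrupted[i] <- interrupted; tr$months_since_prep_start[i] <- month
  }
  rec$visit_date <- as.Date(rec$visit_date, origin = "1970-01-01")
  records <- as_tibble(rec)
  validate_records(records)
  tr$visit_date <- as.Date(tr$visit_date, origin = "1970-01-01")
  truth <- as_tibble(tr) %>%
    arrange(.data$client_id, .data$visit_date)
  list(records = records, truth = truth, config = config, seed = seed)
}

#' Round-trip check of the generator against the pipeline
#'
#' Runs [generate_records()] through [build_visits()] and verifies that the
#' reconstructed activity sets, interruption flags, visit classes and total
#' PrEP minutes equal the ground-truth ledger exactly, and that episode
#' minutes from [consolidate()] conserve the recorded PrEP minutes.
#'
#' @inheritParams generate_records
#' @return list with `ok` (logical), `n_visits`, and mismatch counts per
#'   checked field.
#' @export
roundtrip_check <- function(config = generator_config(), seed = 1L) {
  sim <- generate_records(config, seed)
  visits <- suppressWarnings(build_visits(sim$records))
  truth <- sim$truth
  key_v <- paste(visits$client_id, visits$visit_date)
  key_t <- paste(truth$client_id, truth$visit_date)
  visits <- visits[match(key_t, key_v), ]
  mism <- list(
    activities = sum(format_activities(visits$activities) !=
                       format_activities(truth$activities)),
    interrupted = sum(visits$interrupted != truth$interrupted),
    visit_class = sum(visits$visit_class != truth$visit_class),
    entry_count = sum(visits$n_activity_entries != truth$n_activity_entries),
    minutes = sum(abs(visits$total_prep_minutes -
                        truth$total_prep_minutes) > 1e-9)
  )
  eps <- consolidate(sim$records)
  conservation <- abs(sum(eps$prep_minutes) -
                        sum(prep_minutes(sim$records))) < 1e-9
  list(ok = all(unlist(mism) == 0) && conservation,
       n_visits = nrow(truth),
       mismatches = mism,
       minutes_conserved = conservation)
}
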