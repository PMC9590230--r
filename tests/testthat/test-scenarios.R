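ref2 <- eswatini_reference_fit("model2")
sched <- eswatini_salaries()

test_that("the built-in catalogue covers the base case and five scenarios
           with the intended assignments", {
  cat <- scenario_catalog()
  expect_equal(length(cat), 6)
  expect_true(all(cat$base$assignment == "NURSE"))
  expect_false(cat$base$interrupted)
  expect_true(all(cat$scenario_1$assignment == "NURSING_SISTER"))
  expect_equal(unname(cat$scenario_2$assignment["BLOOD_TESTING"]),
               "PHLEBOTOMIST")
  expect_equal(unname(cat$scenario_4$assignment["FOLLOWUP_COUNSELING"]),
               "NURSE_ASSISTANT")
  expect_equal(unname(cat$scenario_5$assignment["PRE_COUNSELING"]),
               "PEER_SUPPORTER")
  # task sharing scenarios derive an interrupted workflow
  for (nm in paste0("scenario_", 2:5)) {
    res <- evaluate_scenario(cat[[nm]], ref2, sched, "INITIATION_VISIT")
    expect_true(res$interrupted)
  }
  expect_error(scenario("bad", c(PRE_COUNSELING = "NURSE")), "unassigned")
  expect_error(
    scenario("bad", setNames(rep("WIZARD", 6), prep_activities())),
    "unknown cadre")
})

test_that("single-cadre scenarios collapse to the closed-form visit cost", {
  base <- evaluate_scenario(base_case_scenario(), ref2, sched,
                            "FOLLOWUP_VISIT")
  expect_equal(base$point_low, base$point_high)
  direct <- visit_cost(ref2, "NURSE", sched, visit_class = "FOLLOWUP_VISIT")
  expect_equal(base$point_low, direct$point)
  # hand arithmetic from the published process-model estimates:
  # (8.9 + 4.7 + 4.0 - 2 * 1.5) minutes at 0.16/min
  expect_equal(base$point_low, 14.6 * 0.16)
})

test_that("a mixed-cadre scenario yields the hand-computed point range", {
  res <- evaluate_scenario(scenario_catalog()$scenario_4, ref2, sched,
                           "FOLLOWUP_VISIT")
  # activities: counselling 4.7 min at 0.11, blood 4.0 min at 0.047;
  # overhead 8.9 - 2*1.5 + 3.4 = 9.3 min at the involved-cadre wage extremes
  act <- 4.7 * 0.11 + 4.0 * 0.047
  expect_equal(res$point_low, act + 9.3 * 0.047)
  expect_equal(res$point_high, act + 9.3 * 0.11)
  expect_true(res$interrupted)
})

test_that("every scenario's UI contains its point range", {
  for (scn in scenario_catalog()) {
    for (vc in c("INITIATION_VISIT", "FOLLOWUP_VISIT")) {
      res <- evaluate_scenario(scn, ref2, sched, vc)
      expect_lte(res$ui_low, res$point_low)
      expect_gte(res$ui_high, res$point_high)
      expect_lte(res$point_low, res$point_high)
    }
  }
})

test_that("the all-nursing-sister scenario dominates the nurse base case
           componentwise", {
  for (vc in c("INITIATION_VISIT", "FOLLOWUP_VISIT")) {
    base <- evaluate_scenario(base_case_scenario(), ref2, sched, vc)
    s1 <- evaluate_scenario(scenario_catalog()$scenario_1, ref2, sched, vc)
    expect_gte(s1$point_low, base$point_low)
    expect_gte(s1$point_high, base$point_high)
    expect_gte(s1$ui_high, base$ui_high)
    expect_gte(s1$ui_low, base$ui_low)
  }
})

test_that("removing the interruption penalty never increases a scenario
           cost", {
  est <- eswatini_estimates("model2")
  est$estimate[est$term == "interrupted"] <- 0
  est$ci_low[est$term == "interrupted"] <- 0
  est$ci_high[est$term == "interrupted"] <- 0
  fit0 <- fit_from_estimates(est, n = 284)
  for (scn in scenario_catalog()) {
    for (vc in c("INITIATION_VISIT", "FOLLOWUP_VISIT")) {
      with_pen <- evaluate_scenario(scn, ref2, sched, vc)
      no_pen <- evaluate_scenario(scn, fit0, sched, vc)
      expect_lte(no_pen$point_low, with_pen$point_low + 1e-12)
      expect_lte(no_pen$point_high, with_pen$point_high + 1e-12)
      expect_lte(no_pen$ui_high, with_pen$ui_high + 1e-12)
    }
  }
})

test_that("interruption costs span the cadre wage range with a floored UI", {
  ic <- interruption_cost(ref2, sched)
  expect_equal(round_cost(ic$cost_low), 0.048)      # 3.4 min at 0.014/min
  expect_equal(ic$cost_high, 3.4 * 0.26)
  expect_equal(ic$ui_low, 0.69 * 0.014)
  expect_equal(ic$ui_high, 6.0 * 0.27)
  est <- eswatini_estimates("model2")
  est[est$term == "interrupted", c("estimate", "ci_low", "ci_high")] <- 0
  ic0 <- interruption_cost(fit_from_estimates(est, 284), sched)
  expect_equal(c(ic0$cost_low, ic0$cost_high, ic0$ui_low, ic0$ui_high),
               c(0, 0, 0, 0))
  expect_error(interruption_cost(eswatini_reference_fit("model1"), sched),
               "no interruption term")
})

test_that("savings against the base case behave like interval differences", {
  base <- evaluate_scenario(base_case_scenario(), ref2, sched,
                            "FOLLOWUP_VISIT")
  self <- savings_vs_base(base, base)
  expect_equal(self$savings_low, -self$savings_high)
  expect_equal((self$savings_low + self$savings_high) / 2, 0)
  expect_true(self$ui_low <= 0 && 0 <= self$ui_high)

  s4 <- evaluate_scenario(scenario_catalog()$scenario_4, ref2, sched,
                          "FOLLOWUP_VISIT")
  sav <- savings_vs_base(s4, base)
  expect_equal(sav$savings_low, base$point_low - s4$point_high)
  expect_equal(sav$savings_high, base$point_high - s4$point_low)
  expect_equal(sav$ui_low, base$ui_low - s4$ui_high)
  expect_equal(sav$ui_high, base$ui_high - s4$ui_low)

  # all wages strictly below the nurse wage, equal times -> positive savings
  cheap <- scenario("cheap", setNames(rep("PEER_SUPPORTER", 6),
                                      prep_activities()),
                    interrupted = FALSE)
  sav2 <- savings_vs_base(
    evaluate_scenario(cheap, ref2, sched, "FOLLOWUP_VISIT"), base)
  expect_gt(sav2$savings_low, 0)

  expect_error(
    savings_vs_base(
      evaluate_scenario(base_case_scenario(), ref2, sched,
                        "INITIATION_VISIT"), base),
    "different visit classes")
})

test_that("freed nurse time spans the published attribution conventions", {
  cat <- scenario_catalog()
  # nothing shifted in the base case
  none <- freed_nurse_time(base_case_scenario(), ref2, "FOLLOWUP_VISIT")
  expect_equal(c(none$lower, none$upper), c(0, 0))
  # follow-up with counselling and blood testing shifted:
  # 4.7 + 4.0 - 2*1.5 = 5.7 minus the 3.4-min penalty at the lower end;
  # plus the 8.9-min fixed cost at the upper end
  s4 <- freed_nurse_time(cat$scenario_4, ref2, "FOLLOWUP_VISIT")
  expect_equal(s4$lower, 4.7 + 4.0 - 2 * 1.5 - 3.4)
  expect_equal(s4$upper, 4.7 + 4.0 - 2 * 1.5 + 8.9)
  # initiation under task sharing: counselling, risk assessment and blood
  s2 <- freed_nurse_time(cat$scenario_2, ref2, "INITIATION_VISIT")
  expect_equal(s2$lower, 4.3 + 3.3 + 4.0 - 3 * 1.5 - 3.4)
  expect_equal(s2$upper, 4.3 + 3.3 + 4.0 - 3 * 1.5 + 8.9)
  expect_true(s2$lower_ci_low <= s2$lower && s2$lower <= s2$lower_ci_high)

  # everything shifted without interruption equals the full predicted visit
  all_shift <- scenario("all", setNames(rep("NURSE_ASSISTANT", 6),
                                        prep_activities()),
                        interrupted = FALSE)
  freed <- freed_nurse_time(all_shift, ref2, "FOLLOWUP_VISIT")
  pred <- predict_visit(ref2, followup_activities())
  expect_equal(freed$upper, pred$expected_minutes)
  expect_equal(freed$lower, pred$expected_minutes -
                 ref2$coefficients[["constant"]])
})

test_that("the scenario table covers all scenarios and both visit classes", {
  tab <- scenario_table(ref2, sched)
  expect_equal(nrow(tab), 12)
  expect_setequal(unique(tab$visit_class),
                  c("INITIATION_VISIT", "FOLLOWUP_VISIT"))
  base_rows <- tab[tab$scenario == "Base case", ]
  expect_equal(base_rows$savings_low, c(0, 0))
  expect_true(all(tab$cost_low <= tab$cost_high))
  expect_true(all(tab$ui_low <= tab$cost_low + 1e-12))
})
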