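test_that("simulated imatinib patients never reach CR in induction", {
  traj <- simulate_patients("imatinib", test_params, n = 14, seed = 4)
  expect_true(all(traj$induction == "nonCR"))
  expect_equal(traj$n, 14)
})

test_that("certain death empties the cohort in one cycle", {
  pk <- set_params(test_params, certain_death)
  traj <- simulate_patients("imatinib", pk, n = 50, seed = 9)
  expect_true(all(traj$death_cycle == 1))
  expect_true(all(traj$states == match("DEATH", c(
    "CR_MAINT", "NONCR", "RELAPSE", paste0("HSCT_CR_Y", 1:5),
    "HSCT_CR_LATE", "HSCT_FAIL", "DEATH"))))
})

test_that("trajectories respect the transition graph", {
  traj <- simulate_patients("dasatinib", test_params, n = 400, seed = 12)
  st <- traj$states
  dead <- match("DEATH", colnames(build_transition_matrix("dasatinib")))
  for (t in seq_len(ncol(st) - 1)) {
    expect_true(all(st[st[, t] == dead, t + 1] == dead))
  }
  # transplant states only appear from the transplant cycle onward
  hsct <- 4:10
  first_hsct <- apply(st, 1, function(s) {
    w <- which(s %in% hsct)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  expect_equal(first_hsct, traj$transplant_cycle)
  # per-patient QALYs cannot exceed the elapsed time
  expect_true(all(traj$qalys <= traj$phase$elapsed + ncol(st)))
})

test_that("transition estimates are events over at-risk with exact CIs", {
  seed <- NULL
  for (s in 1:100) {
    tr <- simulate_patients("dasatinib", test_params, n = 18, seed = s)
    if (sum(tr$induction == "CR") == 3) { seed <- s; break }
  }
  expect_false(is.null(seed))
  traj <- simulate_patients("dasatinib", test_params, n = 18, seed = seed)
  est <- estimate_transition_probs(traj)
  ind <- est[est$transition == "induction_noncr", ]
  expect_equal(ind$estimate, 15 / 18)
  expect_equal(1 - ind$estimate, 0.167, tolerance = 1e-2)
  expect_true(ind$lower < 15 / 18 & 15 / 18 < ind$upper)

  # all-events transitions hit the degenerate upper bound
  pk <- set_params(test_params, certain_death)
  est1 <- estimate_transition_probs(simulate_patients("imatinib", pk,
                                                      n = 30, seed = 2))
  dcr <- est1[est1$transition == "maint_death_cr", ]
  expect_equal(dcr$estimate, 1)
  expect_equal(dcr$upper, 1)
  # nobody ever at risk post-death: relapse among CR in later cycles absent
  expect_true(all(!est1$undefined[est1$at_risk > 0]))
})

test_that("exact binomial intervals achieve nominal coverage", {
  set.seed(31)
  x <- stats::rbinom(500, 1000, 0.5)
  covered <- vapply(x, function(k) {
    ci <- stats::binom.test(k, 1000)$conf.int
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("estimates recover generating probabilities at the study size", {
  # 300 replicates of the 18-patient dasatinib cohort: the generating
  # induction probability must fall inside ~95% of exact 95% intervals
  hits <- vapply(1:300, function(s) {
    est <- estimate_transition_probs(
      simulate_patients("dasatinib", test_params, n = 18, seed = 1000 + s))
    row <- est[est$transition == "induction_noncr", ]
    row$lower <= 0.833 && 0.833 <= row$upper
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  # and convergence: estimates tighten around truth as n grows
  big <- estimate_transition_probs(
    simulate_patients("dasatinib", test_params, n = 20000, seed = 77))
  row <- big[big$transition == "induction_noncr", ]
  expect_lt(abs(row$estimate - 0.833), 0.01)
})

test_that("an immortal CR patient accrues the closed-form QALYs", {
  pk <- set_params(test_params, c(im_noncr_intensive = 0,
                                  im_relapse_maint = 0,
                                  im_death_cr_maint = 0))
  pk$settings$discount_rate <- 0
  traj <- simulate_patients("imatinib", pk, n = 1, seed = 1)
  expect_equal(traj$qalys, traj$phase$qalys + 10 * 0.88)
})

test_that("discounting never inflates simulated accruals", {
  p0 <- test_params
  p0$settings$discount_rate <- 0
  undisc <- simulate_patients("dasatinib", p0, n = 500, seed = 21)
  disc <- simulate_patients("dasatinib", test_params, n = 500, seed = 21)
  # same seed, same trajectories; only the discount weights differ
  expect_identical(undisc$states, disc$states)
  expect_true(all(disc$qalys <= undisc$qalys + 1e-12))
  expect_true(all(disc$cost <= undisc$cost + 1e-12))
})

test_that("microsimulation agrees with the cohort model at large n", {
  n <- 200000
  for (arm in c("imatinib", "dasatinib")) {
    traj <- simulate_patients(arm, test_params, n = n, seed = 100)
    mv <- microsim_value(traj)
    cohort <- run_arm(arm, test_params)
    expect_lt(abs(mv$mean_cost - cohort$total_cost), 3 * mv$se_cost)
    expect_lt(abs(mv$mean_qalys - cohort$total_qalys), 3 * mv$se_qalys)
    emp <- as.matrix(empirical_occupancy(traj)[, health_states()])
    ref <- as.matrix(cohort$trace[, health_states()])
    se <- sqrt(ref * (1 - ref) / n)
    expect_true(all(abs(emp - ref) <= 3 * se + 1e-12))
  }
})

test_that("microsimulation matches the cohort under alternative structures", {
  configs <- list(
    structure_toggles(reward_timing_start = TRUE),
    structure_toggles(half_cycle = TRUE),
    structure_toggles(group_level_cr = FALSE, other_cost_proration = TRUE,
                      drug_in_maintenance = FALSE)
  )
  for (tg in configs) {
    traj <- simulate_patients("dasatinib", test_params, n = 40000,
                              seed = 55, toggles = tg)
    mv <- microsim_value(traj)
    cohort <- run_arm("dasatinib", test_params, tg)
    expect_lt(abs(mv$mean_cost - cohort$total_cost), 3 * mv$se_cost)
    expect_lt(abs(mv$mean_qalys - cohort$total_qalys), 3 * mv$se_qalys)
  }
})

test_that("long-format export has one row per patient-cycle", {
  traj <- simulate_patients("imatinib", test_params, n = 6, seed = 3)
  df <- as.data.frame(traj)
  expect_equal(nrow(df), 6 * 11)
  expect_equal(unique(df$arm), "imatinib")
  expect_true(all(df$state[df$cycle == 0] %in% c("CR_MAINT", "NONCR")))
})
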