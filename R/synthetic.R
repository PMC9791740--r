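# Patient-level synthetic cohort generator.  It emulates the retrospective
# EMR cohort behind the decision-tree probabilities (default 32 patients:
# 14 imatinib, 18 dasatinib) and, at large n, serves as an independent
# microsimulation oracle for the cohort engine: each patient walks the same
# decision tree and Markov chain individually, so empirical occupancies and
# mean accruals must converge to the cohort trace.

.state_index <- function(nm) match(nm, .xstates)

#' Simulate patient-level trajectories
#'
#' Draws `n` patients through the induction/intensive decision tree and then
#' `horizon` annual Markov cycles, using exactly the same probabilities,
#' rewards, timing and discounting as the cohort model under the given
#' toggles.  Deterministic under a fixed seed.
#'
#' @inheritParams run_decision_tree
#' @param n Number of patients (the emulated study cohort had 14 imatinib
#'   and 18 dasatinib patients).
#' @param seed Integer seed.
#' @return A `patient_trajectories` object: list with `arm`, `induction`
#'   and `intensive` end-of-phase states per patient, `states` (n x horizon
#'   integer matrix of expanded Markov states), `transplant_cycle` and
#'   `death_cycle` (NA if the event never occurs), `cost` and `qalys`
#'   (discounted per-patient totals including the treatment phase), and the
#'   generating `params`/`toggles`.
#' @export
#' @examples
#' traj <- simulate_patients("dasatinib", n = 18, seed = 42)
#' table(traj$induction)
simulate_patients <- function(arm, params = table1_parameters(), n = 32,
                              seed = 1, toggles = structure_toggles()) {
  arm <- match_arm(arm)
  toggles <- as_toggles(toggles)
  stopifnot(n >= 1)
  set.seed(seed)

  phase <- run_decision_tree(arm, params, toggles)
  horizon <- as.integer(params$settings$horizon_years)
  r <- params$settings$discount_rate

  # Phase outcomes patient by patient.  The end-of-phase CR probability is
  # composed per patient so individual induction/intensive paths are
  # recorded; under group_level_cr the group split is applied directly.
  if (arm == "imatinib") {
    p_ind_noncr <- param_value(params, "im_noncr_induction")
    induction <- ifelse(stats::runif(n) < p_ind_noncr, "nonCR", "CR")
    p_int_noncr <- param_value(params, "im_noncr_intensive")
    intensive <- ifelse(stats::runif(n) < p_int_noncr, "nonCR", "CR")
  } else {
    p_ind_noncr <- param_value(params, "da_noncr_induction")
    induction <- ifelse(stats::runif(n) < p_ind_noncr, "nonCR", "CR")
    if (toggles[["group_level_cr"]]) {
      p_cr <- param_value(params, "da_cr_of_noncr_intensive")
      intensive <- ifelse(stats::runif(n) < p_cr, "CR", "nonCR")
    } else {
      p_stay <- param_value(params, "da_cr_stays_cr_intensive")
      p_conv <- param_value(params, "da_cr_of_noncr_intensive")
      u <- stats::runif(n)
      intensive <- ifelse(induction == "CR",
                          ifelse(u < p_stay, "CR", "nonCR"),
                          ifelse(u < p_conv, "CR", "nonCR"))
    }
  }

  M <- build_transition_matrix(arm, params)
  one_off <- attr(M, "one_off")
  cumM <- t(apply(M, 1, cumsum))
  rew <- state_rewards(arm, params, toggles)
  cvec <- rew$cost
  uvec <- rew$utility

  i_dead <- .state_index("DEATH")
  i_tx <- c(.state_index("HSCT_CR_Y1"), .state_index("HSCT_FAIL"))
  i_pretx <- c(.state_index("NONCR"), .state_index("RELAPSE"))

  state <- ifelse(intensive == "CR", .state_index("CR_MAINT"),
                  .state_index("NONCR"))
  states <- matrix(NA_integer_, n, horizon)
  transplant_cycle <- death_cycle <- rep(NA_integer_, n)
  cost <- rep(phase$cost, n)
  qalys <- rep(phase$qalys, n)

  for (t in seq_len(horizon)) {
    u <- stats::runif(n)
    cum <- cumM[state, , drop = FALSE]
    nxt <- max.col(u < cum, ties.method = "first")
    tx_now <- state %in% i_pretx & nxt %in% i_tx
    transplant_cycle[tx_now & is.na(transplant_cycle)] <- t
    death_cycle[is.na(death_cycle) & nxt == i_dead] <- t
    lump <- ifelse(tx_now, one_off[cbind(state, nxt)], 0)

    if (toggles[["half_cycle"]]) {
      wc <- (cvec[state] + cvec[nxt]) / 2
      wu <- (uvec[state] + uvec[nxt]) / 2
      tt <- t - 0.5
    } else if (toggles[["reward_timing_start"]]) {
      wc <- cvec[state]
      wu <- uvec[state]
      tt <- t - 1
    } else {
      wc <- cvec[nxt]
      wu <- uvec[nxt]
      tt <- t
    }
    d <- discount_factor(tt, r)
    cost <- cost + (wc + lump) * d
    qalys <- qalys + wu * d

    state <- nxt
    states[, t] <- state
  }

  structure(
    list(arm = arm, n = n, seed = seed,
         induction = induction, intensive = intensive,
         states = states,
         transplant_cycle = transplant_cycle, death_cycle = death_cycle,
         cost = unname(cost), qalys = unname(qalys),
         params = params, toggles = toggles, phase = phase),
    class = "patient_trajectories"
  )
}

#' @export
print.patient_trajectories <- function(x, ...) {
  cat("<patient_trajectories> ", x$n, " ", x$arm, " patients, ",
      ncol(x$states), " Markov cycles (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  deaths: %d;  transplants: %d\n",
              sum(!is.na(x$death_cycle)), sum(!is.na(x$transplant_cycle))))
  invisible(x)
}

#' Per-cycle state occupancy of simulated patients
#'
#' Empirical analogue of the cohort trace, over the reporting states.
#'
#' @param trajectories A `patient_trajectories` object.
#' @return Tibble with `cycle` and one fraction column per reporting state.
#' @export
empirical_occupancy <- function(trajectories) {
  st <- trajectories$states
  counts <- vapply(seq_along(.xstates), function(i) colSums(st == i),
                   numeric(ncol(st)))
  colnames(counts) <- .xstates
  frac <- collapse_states(counts / nrow(st))
  out <- tibble::as_tibble(as.data.frame(frac))
  tibble::add_column(out, cycle = seq_len(nrow(out)), .before = 1)
}

#' Long-format export of simulated trajectories
#'
#' @param x A `patient_trajectories` object.
#' @param ... Unused.
#' @return Data frame with one row per patient-cycle: `patient`, `arm`,
#'   `cycle` (0 = end of intensive phase), `state`.
#' @export
as.data.frame.patient_trajectories <- function(x, ...) {
  horizon <- ncol(x$states)
  start <- ifelse(x$intensive == "CR", "CR_MAINT", "NONCR")
  data.frame(
    patient = rep(seq_len(x$n), horizon + 1),
    arm = x$arm,
    cycle = rep(0:horizon, each = x$n),
    state = c(start, .xstates[as.vector(x$states)]),
    stringsAsFactors = FALSE
  )
}

#' Estimate transition probabilities from simulated trajectories
#'
#' Maximum-likelihood proportions (events / at-risk) with exact 95%
#' Clopper-Pearson intervals for the tree-phase outcomes and the main
#' maintenance-phase transitions.  Transitions with nobody at risk are
#' returned with `NA` estimates and flagged.
#'
#' @inheritParams empirical_occupancy
#' @param conf_level Confidence level of the exact intervals.
#' @return Tibble: `transition`, `events`, `at_risk`, `estimate`, `lower`,
#'   `upper`, `undefined`.
#' @export
#' @examples
#' estimate_transition_probs(simulate_patients("dasatinib", n = 18, seed = 7))
estimate_transition_probs <- function(trajectories, conf_level = 0.95) {
  tr <- trajectories
  st <- tr$states
  prev <- cbind(ifelse(tr$intensive == "CR", .state_index("CR_MAINT"),
                       .state_index("NONCR")),
                st[, -ncol(st), drop = FALSE])

  i_cr <- .state_index("CR_MAINT")
  i_nc <- .state_index("NONCR")
  i_rel <- .state_index("RELAPSE")
  i_dead <- .state_index("DEATH")
  i_tx <- c(.state_index("HSCT_CR_Y1"), .state_index("HSCT_FAIL"))

  tally <- list(
    induction_noncr = c(sum(tr$induction == "nonCR"), tr$n),
    intensive_cr = c(sum(tr$intensive == "CR"), tr$n),
    maint_relapse = {
      at <- sum(prev == i_cr)
      c(sum(prev == i_cr & st == i_rel), at)
    },
    maint_death_cr = {
      at <- sum(prev == i_cr)
      c(sum(prev == i_cr & st == i_dead), at)
    },
    maint_death_noncr = {
      at <- sum(prev %in% c(i_nc, i_rel))
      c(sum(prev %in% c(i_nc, i_rel) & st == i_dead), at)
    },
    transplant = {
      at <- sum(prev %in% c(i_nc, i_rel))
      c(sum(prev %in% c(i_nc, i_rel) & st %in% i_tx), at)
    }
  )

  rows <- lapply(names(tally), function(nm) {
    ev <- tally[[nm]][1]
    at <- tally[[nm]][2]
    if (at == 0) {
      return(tibble::tibble(transition = nm, events = ev, at_risk = at,
                            estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_, undefined = TRUE))
    }
    ci <- stats::binom.test(ev, at, conf.level = conf_level)$conf.int
    tibble::tibble(transition = nm, events = ev, at_risk = at,
                   estimate = ev / at, lower = ci[1], upper = ci[2],
                   undefined = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean discounted value of simulated patients
#'
#' Per-patient discounted cost and QALY totals averaged over the simulated
#' cohort, with Monte-Carlo standard errors.  At large `n` these must agree
#' with the matching [run_arm()] totals — the microsimulation is the
#' independent oracle for the cohort engine.
#'
#' @inheritParams empirical_occupancy
#' @return List with `mean_cost`, `se_cost`, `mean_qalys`, `se_qalys`, `n`.
#' @export
microsim_value <- function(trajectories) {
  n <- trajectories$n
  list(
    mean_cost = mean(trajectories$cost),
    se_cost = stats::sd(trajectories$cost) / sqrt(n),
    mean_qalys = mean(trajectories$qalys),
    se_qalys = stats::sd(trajectories$qalys) / sqrt(n),
    n = n
  )
}
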