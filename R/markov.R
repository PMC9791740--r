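# Annual-cycle Markov cohort engine over maintenance, relapse,
# transplantation and death.  Post-transplant CR is implemented as a tunnel
# (five one-year sub-states) so the first-5-year / later utility split is
# anchored to time since transplant, not model time.

# Reporting states (public).
.states <- c("CR_MAINT", "NONCR", "RELAPSE", "HSCT_CR_EARLY", "HSCT_CR_LATE",
             "HSCT_FAIL", "DEATH")

# Expanded internal states: the post-transplant CR tunnel years 1..5.
.xstates <- c("CR_MAINT", "NONCR", "RELAPSE",
              paste0("HSCT_CR_Y", 1:5), "HSCT_CR_LATE", "HSCT_FAIL", "DEATH")
.tunnel <- paste0("HSCT_CR_Y", 1:5)

#' Markov health states
#'
#' @return Character vector of the reporting health states: CR maintenance,
#'   non-CR, relapse, post-transplant CR (first five years), post-transplant
#'   CR (later years), failed/relapsed transplant, death.
#' @export
health_states <- function() .states

# Collapse an expanded occupancy vector or matrix onto the reporting states.
collapse_states <- function(occ) {
  if (is.matrix(occ)) {
    cbind(
      occ[, c("CR_MAINT", "NONCR", "RELAPSE"), drop = FALSE],
      HSCT_CR_EARLY = rowSums(occ[, .tunnel, drop = FALSE]),
      occ[, c("HSCT_CR_LATE", "HSCT_FAIL", "DEATH"), drop = FALSE]
    )
  } else {
    c(occ[c("CR_MAINT", "NONCR", "RELAPSE")],
      HSCT_CR_EARLY = sum(occ[.tunnel]),
      occ[c("HSCT_CR_LATE", "HSCT_FAIL", "DEATH")])
  }
}

#' Discount factor
#'
#' @param t Cycle index (years from model start), non-negative.
#' @param r Annual discount rate, non-negative.
#' @return `(1 + r)^(-t)`.
#' @export
#' @examples
#' discount_factor(10, 0.05)   # 0.6139
discount_factor <- function(t, r) {
  if (any(r < 0)) stop("negative discount rate")
  if (any(t < 0)) stop("negative cycle index")
  (1 + r)^(-t)
}

#' Build the one-cycle transition matrix for one arm
#'
#' From CR maintenance patients relapse or die at the arm-specific annual
#' probabilities and otherwise stay.  Non-CR and relapsed patients, within a
#' cycle, receive a transplant with probability 0.1 (succeeding into
#' post-transplant CR with probability 0.4, otherwise entering the failed
#' state), die with probability 0.6, or stay.  Post-transplant CR patients
#' relapse into the failed state or die; failed-transplant patients die at
#' 0.57 per year.  Death is absorbing.  The transplant entry cost is attached
#' as a per-transition one-off cost table (attribute `one_off`).
#'
#' @inheritParams run_decision_tree
#' @return A row-stochastic matrix over the expanded state space (tunnel
#'   years explicit), with attribute `one_off` holding per-transition one-off
#'   costs (CNY).
#' @export
build_transition_matrix <- function(arm, params = table1_parameters()) {
  arm <- match_arm(arm)
  pv <- function(id) param_value(params, id)
  p_rel <- if (arm == "imatinib") pv("im_relapse_maint") else pv("da_relapse_maint")
  p_dcr <- if (arm == "imatinib") pv("im_death_cr_maint") else pv("da_death_cr_maint")
  p_dnc <- pv("death_noncr_maint")
  p_tx <- pv("hsct_rate")
  p_txs <- pv("hsct_success")
  p_hrel <- pv("hsct_relapse")
  p_hdcr <- pv("hsct_death_cr")
  p_hdf <- pv("hsct_death_noncr")

  n <- length(.xstates)
  M <- matrix(0, n, n, dimnames = list(.xstates, .xstates))
  one_off <- matrix(0, n, n, dimnames = list(.xstates, .xstates))

  remainder <- function(p, from) {
    if (p < -1e-12) {
      stop("negative stay probability in state ", from,
           " (competing risks exceed 1)")
    }
    max(p, 0)
  }

  M["CR_MAINT", "RELAPSE"] <- p_rel
  M["CR_MAINT", "DEATH"] <- p_dcr
  M["CR_MAINT", "CR_MAINT"] <- remainder(1 - p_rel - p_dcr, "CR_MAINT")

  for (s in c("NONCR", "RELAPSE")) {
    M[s, "HSCT_CR_Y1"] <- p_tx * p_txs
    M[s, "HSCT_FAIL"] <- p_tx * (1 - p_txs)
    M[s, "DEATH"] <- p_dnc
    M[s, s] <- remainder(1 - p_tx - p_dnc, s)
    one_off[s, "HSCT_CR_Y1"] <- pv("cost_hsct")
    one_off[s, "HSCT_FAIL"] <- pv("cost_hsct")
  }

  post_cr <- c(.tunnel, "HSCT_CR_LATE")
  nxt <- c(.tunnel[-1], "HSCT_CR_LATE", "HSCT_CR_LATE")
  for (i in seq_along(post_cr)) {
    M[post_cr[i], "HSCT_FAIL"] <- p_hrel
    M[post_cr[i], "DEATH"] <- p_hdcr
    M[post_cr[i], nxt[i]] <- M[post_cr[i], nxt[i]] +
      remainder(1 - p_hrel - p_hdcr, post_cr[i])
  }

  M["HSCT_FAIL", "DEATH"] <- p_hdf
  M["HSCT_FAIL", "HSCT_FAIL"] <- remainder(1 - p_hdf, "HSCT_FAIL")
  M["DEATH", "DEATH"] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("internal consistency error: transition rows sum to ",
         paste(signif(rs[abs(rs - 1) > 1e-9], 10), collapse = ", "))
  }
  if (any(M < 0 | M > 1)) stop("transition probabilities outside [0, 1]")
  attr(M, "one_off") <- one_off
  M
}

#' Per-state annual rewards for one arm
#'
#' Annual state costs (CNY/year) and utilities over the expanded state
#' space.  The CR maintenance cost optionally includes the arm's annual TKI
#' drug cost; relapse shares the non-CR cost and utility; death accrues
#' nothing.
#'
#' @inheritParams run_decision_tree
#' @return List with numeric vectors `cost` and `utility` named by expanded
#'   state.
#' @export
state_rewards <- function(arm, params = table1_parameters(),
                          toggles = structure_toggles()) {
  arm <- match_arm(arm)
  toggles <- as_toggles(toggles)
  pv <- function(id) param_value(params, id)
  drug <- if (arm == "imatinib") pv("im_drug_cost") else pv("da_drug_cost")
  cr_cost <- pv("cost_cr_maint") +
    if (toggles[["drug_in_maintenance"]]) drug else 0
  cost <- c(cr_cost, pv("cost_noncr_maint"), pv("cost_noncr_maint"),
            rep(pv("cost_hsct_cr_maint"), 6), pv("cost_hsct_fail"), 0)
  utility <- c(pv("u_cr"), pv("u_noncr"), pv("u_noncr"),
               rep(pv("u_hsct_cr_early"), 5), pv("u_hsct_cr_late"),
               pv("u_hsct_fail"), 0)
  list(cost = stats::setNames(cost, .xstates),
       utility = stats::setNames(utility, .xstates))
}

#' Propagate a cohort through the Markov model
#'
#' Runs `horizon` annual cycles from the end-of-treatment-phase state
#' distribution, accruing discounted costs and QALYs.  By default rewards are
#' accrued on end-of-cycle occupancy discounted at `(1+r)^-t`; the toggles
#' select start-of-cycle accrual or a half-cycle correction.  One-off
#' transition costs (transplantation) are charged on the transitioning mass
#' in the cycle the transition occurs.  Totals include the treatment-phase
#' accruals when `initial` is a `phase_outcome`.
#'
#' @param initial A `phase_outcome` from [run_decision_tree()], or a named
#'   occupancy vector over the matrix's states (zero phase accruals).
#' @param matrix Transition matrix from [build_transition_matrix()] (or any
#'   row-stochastic matrix with matching reward names, e.g. for testing).
#' @param rewards List with `cost` and `utility` vectors named by state, as
#'   from [state_rewards()].
#' @param horizon Number of annual cycles (default from `params` is 10).
#' @param discount_rate Annual discount rate (default 0.05).
#' @param toggles A `cea_toggles`; only the timing flags are consulted.
#' @return An `arm_result`: list with `total_cost`, `total_qalys` (treatment
#'   phase + Markov, discounted), `trace` (tibble of per-cycle occupancy and
#'   accruals over the reporting states) and `phase`.
#' @export
run_cohort <- function(initial, matrix, rewards, horizon = 10,
                       discount_rate = 0.05,
                       toggles = structure_toggles()) {
  toggles <- as_toggles(toggles)
  stopifnot(horizon >= 1, horizon == round(horizon))
  states <- colnames(matrix)
  one_off <- attr(matrix, "one_off")

  if (inherits(initial, "phase_outcome")) {
    phase <- initial
    occ <- stats::setNames(numeric(length(states)), states)
    occ["CR_MAINT"] <- phase$state_distribution[["CR"]]
    occ["NONCR"] <- phase$state_distribution[["nonCR"]]
    occ["DEATH"] <- phase$state_distribution[["death"]]
  } else {
    phase <- list(cost = 0, qalys = 0, elapsed = 0)
    if (is.null(names(initial)) || !setequal(names(initial), states)) {
      stop("initial occupancy must be named by the matrix states")
    }
    occ <- initial[states]
  }
  if (abs(sum(occ) - 1) > 1e-10) stop("initial occupancy does not sum to 1")

  cvec <- rewards$cost[states]
  uvec <- rewards$utility[states]
  if (anyNA(cvec) || anyNA(uvec)) stop("rewards missing for some states")

  ncyc <- as.integer(horizon)
  occ_hist <- matrix(0, ncyc, length(states), dimnames = list(NULL, states))
  cost_cyc <- qaly_cyc <- dcost_cyc <- dqaly_cyc <- numeric(ncyc)

  for (t in seq_len(ncyc)) {
    prev <- occ
    occ <- as.numeric(prev %*% matrix)
    names(occ) <- states
    if (abs(sum(occ) - 1) > 1e-8) {
      stop("occupancy conservation violated at cycle ", t)
    }
    lump <- if (is.null(one_off)) 0 else sum((prev * matrix) * one_off)

    if (toggles[["half_cycle"]]) {
      w <- (prev + occ) / 2
      tt <- t - 0.5
    } else if (toggles[["reward_timing_start"]]) {
      w <- prev
      tt <- t - 1
    } else {
      w <- occ
      tt <- t
    }
    d <- discount_factor(tt, discount_rate)
    cost_cyc[t] <- sum(w * cvec) + lump
    qaly_cyc[t] <- sum(w * uvec)
    dcost_cyc[t] <- cost_cyc[t] * d
    dqaly_cyc[t] <- qaly_cyc[t] * d
    occ_hist[t, ] <- occ
  }

  rep_occ <- if (setequal(states, .xstates)) collapse_states(occ_hist) else occ_hist
  trace <- tibble::as_tibble(as.data.frame(rep_occ))
  trace <- tibble::add_column(trace, cycle = seq_len(ncyc), .before = 1)
  trace$cost <- cost_cyc
  trace$qalys <- qaly_cyc
  trace$disc_cost <- dcost_cyc
  trace$disc_qalys <- dqaly_cyc

  structure(
    list(
      total_cost = phase$cost + sum(dcost_cyc),
      total_qalys = phase$qalys + sum(dqaly_cyc),
      trace = trace,
      phase = phase
    ),
    class = "arm_result"
  )
}

#' Run the full pipeline (tree + Markov) for one arm
#'
#' @inheritParams run_decision_tree
#' @return An `arm_result`; see [run_cohort()].
#' @export
#' @examples
#' res <- run_arm("dasatinib")
#' res$total_qalys
run_arm <- function(arm, params = table1_parameters(),
                    toggles = structure_toggles()) {
  arm <- match_arm(arm)
  toggles <- as_toggles(toggles)
  phase <- run_decision_tree(arm, params, toggles)
  M <- build_transition_matrix(arm, params)
  rew <- state_rewards(arm, params, toggles)
  res <- run_cohort(phase, M, rew,
                    horizon = params$settings$horizon_years,
                    discount_rate = params$settings$discount_rate,
                    toggles = toggles)
  res$arm <- arm
  res
}

#' @export
print.arm_result <- function(x, ...) {
  cat("<arm_result>", if (!is.null(x$arm)) x$arm else "", "\n")
  cat(sprintf("  total cost  %12.2f CNY (discounted)\n", x$total_cost))
  cat(sprintf("  total QALYs %12.4f\n", x$total_qalys))
  invisible(x)
}
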