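# Decision tree for the treatment phase: a ~4-week induction followed by a
# ~44-week intensive chemotherapy block.  Its output (the end-of-phase
# CR/non-CR/death split plus phase costs and QALYs) seeds the Markov model.

#' Run the treatment-phase decision tree for one arm
#'
#' Propagates a cohort through induction and intensive chemotherapy.
#' Imatinib: no patient reaches CR in induction; half are in CR after the
#' intensive block.  Dasatinib: 16.7% reach CR in induction; CR patients stay
#' in CR and 87.5% of non-CR patients convert during the intensive block,
#' giving an end-of-phase CR proportion of 0.8959 by composition or 0.875 at
#' group level (see [structure_toggles()]).  No deaths occur during the
#' treatment phase (no such parameter is observed).  Costs are the per-phase
#' "other cost" amounts plus the TKI drug cost; QALYs are the elapsed phase
#' time weighted by the on-treatment (non-CR) utility.
#'
#' @param arm `"imatinib"` or `"dasatinib"`.
#' @param params A `param_set`.
#' @param toggles A `cea_toggles` configuration.
#' @return A `phase_outcome`: list with `state_distribution` (named
#'   probabilities over `CR`, `nonCR`, `death`), `cost` (CNY), `qalys`,
#'   `elapsed` (years).
#' @export
#' @examples
#' run_decision_tree("imatinib", table1_parameters(), structure_toggles())
run_decision_tree <- function(arm, params = table1_parameters(),
                              toggles = structure_toggles()) {
  arm <- match_arm(arm)
  toggles <- as_toggles(toggles)
  pv <- function(id) param_value(params, id)

  if (arm == "imatinib") {
    noncr_induction <- pv("im_noncr_induction")
    # the intensive-phase parameter is the group-level non-CR proportion
    end_cr <- 1 - pv("im_noncr_intensive")
    drug <- pv("im_drug_cost")
    other_ind <- pv("im_other_induction")
    other_int <- pv("im_other_intensive")
    dur_ind <- pv("im_dur_induction")
    dur_int <- pv("im_dur_intensive")
  } else {
    noncr_induction <- pv("da_noncr_induction")
    convert <- pv("da_cr_of_noncr_intensive")
    if (toggles[["group_level_cr"]]) {
      end_cr <- convert
    } else {
      end_cr <- (1 - noncr_induction) * pv("da_cr_stays_cr_intensive") +
        noncr_induction * convert
    }
    drug <- pv("da_drug_cost")
    other_ind <- pv("da_other_induction")
    other_int <- pv("da_other_intensive")
    dur_ind <- pv("da_dur_induction")
    dur_int <- pv("da_dur_intensive")
  }

  elapsed <- dur_ind + dur_int
  drug_cost <- if (toggles[["drug_proration_in_tree"]]) drug * elapsed else drug
  other_cost <- if (toggles[["other_cost_proration"]]) {
    other_ind * dur_ind + other_int * dur_int
  } else {
    other_ind + other_int
  }
  cost <- other_cost + drug_cost
  qalys <- elapsed * param_value(params, "u_noncr")

  if (toggles[["tree_discounting"]]) {
    df <- (1 + params$settings$discount_rate)^(-elapsed / 2)
    cost <- cost * df
    qalys <- qalys * df
  }

  dist <- c(CR = end_cr, nonCR = 1 - end_cr, death = 0)
  if (any(dist < -1e-12 | dist > 1 + 1e-12) ||
      abs(sum(dist) - 1) > 1e-12) {
    stop("decision tree produced an invalid state distribution")
  }

  structure(
    list(arm = arm, state_distribution = dist, cost = cost, qalys = qalys,
         elapsed = elapsed),
    class = "phase_outcome"
  )
}

#' @export
print.phase_outcome <- function(x, ...) {
  cat("<phase_outcome> ", x$arm, "\n", sep = "")
  cat("  end of intensive phase:",
      paste(names(x$state_distribution),
            sprintf("%.4f", x$state_distribution), collapse = ", "), "\n")
  cat(sprintf("  cost %.2f CNY, %.4f QALYs over %.4f years\n",
              x$cost, x$qalys, x$elapsed))
  invisible(x)
}
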