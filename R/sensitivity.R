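# One-way (tornado) sensitivity on the incremental net monetary benefit,
# Monte-Carlo probabilistic sensitivity analysis, and the
# cost-effectiveness acceptability curve.

inmb_at <- function(params, toggles, wtp) {
  base_case(params, toggles, wtp)$cea$inmb
}

#' One-way sensitivity of the incremental net monetary benefit
#'
#' Re-runs the full pipeline with a single parameter set to each end of its
#' plausible range (everything else at base) and records the iNMB of
#' dasatinib vs imatinib at both ends.  The pseudo-id `"discount_rate"`
#' varies the annual discount rate over 3-8%.
#'
#' @param id Parameter id, or `"discount_rate"`.
#' @inheritParams base_case
#' @return One-row tibble: `param`, `low`, `high`, `inmb_at_low`,
#'   `inmb_at_high`, `span` (absolute iNMB difference).
#' @export
one_way <- function(id, params = table1_parameters(),
                    wtp = params$settings$wtp,
                    toggles = structure_toggles()) {
  if (id == "discount_rate") {
    b <- c(low = 0.03, high = 0.08)
    at <- function(v) {
      p <- params
      p$settings$discount_rate <- v
      inmb_at(p, toggles, wtp)
    }
  } else {
    b <- parameter_bounds(params, id)
    at <- function(v) inmb_at(set_params(params, stats::setNames(v, id)),
                              toggles, wtp)
  }
  lo <- at(b[["low"]])
  hi <- at(b[["high"]])
  tibble::tibble(param = id, low = b[["low"]], high = b[["high"]],
                 inmb_at_low = lo, inmb_at_high = hi, span = abs(hi - lo))
}

#' Tornado analysis
#'
#' [one_way()] over every parameter with a non-degenerate range (plus the
#' discount rate), sorted by decreasing iNMB span.
#'
#' @param include_discount Also vary the discount rate over 3-8%.
#' @inheritParams one_way
#' @return Tibble of one-way results sorted by `span` (descending).
#' @export
tornado <- function(params = table1_parameters(),
                    wtp = params$settings$wtp,
                    toggles = structure_toggles(),
                    include_discount = TRUE) {
  ids <- params$entries$id
  keep <- vapply(ids, function(id) {
    b <- parameter_bounds(params, id)
    b[["high"]] > b[["low"]]
  }, logical(1))
  ids <- ids[keep]
  if (include_discount) ids <- c(ids, "discount_rate")
  if (length(ids) == 0) {
    return(tibble::tibble(param = character(0), low = numeric(0),
                          high = numeric(0), inmb_at_low = numeric(0),
                          inmb_at_high = numeric(0), span = numeric(0)))
  }
  rows <- lapply(ids, one_way, params = params, wtp = wtp, toggles = toggles)
  out <- do.call(rbind, rows)
  out[order(-out$span), ]
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo PSA: each draw samples every uncertain parameter
#' independently from its method-of-moments distribution (Gamma for costs,
#' Beta for probabilities and utilities; see [make_distribution()]),
#' re-evaluates the full pipeline for both arms with the shared parameters
#' using the same draw in both, and records the incremental cost and effect.
#' The discount rate is not sampled (it is varied one-way only).
#' Reproducible under a fixed seed.
#'
#' @param n Number of draws (default 1000).
#' @param seed Integer seed controlling all sampling.
#' @inheritParams make_distribution
#' @inheritParams base_case
#' @return A tibble of class `psa_samples`: `draw`, `delta_cost`,
#'   `delta_effect`, with attributes `seed`, `sd_rule`, `wtp` and `base`
#'   (the deterministic base-case `cea_result`).
#' @export
#' @examples
#' psa <- run_psa(n = 50, seed = 1)
#' prob_cost_effective(psa, 70892)
run_psa <- function(params = table1_parameters(), n = 1000, seed = 1,
                    toggles = structure_toggles(),
                    sd_rule = c("range95", "range4"),
                    wtp = params$settings$wtp) {
  stopifnot(n >= 1)
  sd_rule <- match.arg(sd_rule)
  toggles <- as_toggles(toggles)

  dists <- lapply(params$entries$id, make_distribution,
                  params = params, sd_rule = sd_rule)
  names(dists) <- params$entries$id
  uncertain <- names(dists)[vapply(dists, function(d) d$family != "fixed",
                                   logical(1))]

  set.seed(seed)
  draws <- vapply(uncertain, function(id) draw(dists[[id]], n), numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, uncertain))

  dc <- de <- numeric(n)
  for (k in seq_len(n)) {
    pk <- set_params(params, draws[k, ])
    im <- run_arm("imatinib", pk, toggles)
    da <- run_arm("dasatinib", pk, toggles)
    dc[k] <- da$total_cost - im$total_cost
    de[k] <- da$total_qalys - im$total_qalys
  }
  out <- tibble::tibble(draw = seq_len(n), delta_cost = dc, delta_effect = de)
  class(out) <- c("psa_samples", class(out))
  attr(out, "seed") <- seed
  attr(out, "sd_rule") <- sd_rule
  attr(out, "wtp") <- wtp
  attr(out, "base") <- base_case(params, toggles, wtp)$cea
  out
}

#' Probability of cost-effectiveness at a willingness-to-pay
#'
#' Fraction of PSA draws with positive incremental net monetary benefit,
#' `wtp * dE - dC > 0`.
#'
#' @param samples A `psa_samples` tibble from [run_psa()].
#' @param wtp Willingness-to-pay, CNY/QALY.
#' @return A fraction in `[0, 1]`.
#' @export
prob_cost_effective <- function(samples, wtp) {
  stopifnot(nrow(samples) > 0)
  mean(wtp * samples$delta_effect - samples$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, the fraction of PSA draws
#' in which dasatinib has positive net monetary benefit.
#'
#' @inheritParams prob_cost_effective
#' @param wtp_grid Ascending WTP grid (default 0 to 200,000 CNY/QALY in
#'   steps of 2,000).
#' @return Tibble with `wtp` and `probability_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 200000, by = 2000)) {
  if (nrow(samples) == 0) stop("empty PSA sample set")
  if (is.unsorted(wtp_grid)) stop("wtp_grid must be sorted ascending")
  tibble::tibble(
    wtp = wtp_grid,
    probability_cost_effective = vapply(wtp_grid, prob_cost_effective,
                                        numeric(1), samples = samples)
  )
}
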