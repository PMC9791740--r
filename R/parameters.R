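# Parameter registry: every model input with its base value, plausible range
# and distribution family, plus analysis settings.  This is the single source
# of truth consumed by the decision tree, the Markov engine and all
# sensitivity analyses.

.required_param_ids <- c(
  "im_noncr_induction", "im_noncr_intensive",
  "im_relapse_maint", "im_death_cr_maint",
  "da_noncr_induction", "da_cr_stays_cr_intensive", "da_cr_of_noncr_intensive",
  "da_relapse_maint", "da_death_cr_maint",
  "death_noncr_maint", "hsct_rate", "hsct_success",
  "hsct_relapse", "hsct_death_cr", "hsct_death_noncr",
  "im_drug_cost", "im_other_induction", "im_other_intensive",
  "da_drug_cost", "da_other_induction", "da_other_intensive",
  "cost_cr_maint", "cost_noncr_maint", "cost_hsct",
  "cost_hsct_cr_maint", "cost_hsct_fail",
  "im_dur_induction", "im_dur_intensive",
  "da_dur_induction", "da_dur_intensive",
  "u_cr", "u_noncr", "u_hsct_cr_early", "u_hsct_cr_late", "u_hsct_fail"
)

.default_settings <- function() {
  list(
    horizon_years = 10L,
    discount_rate = 0.05,
    wtp = 70892,
    body_surface_area = 0.8
  )
}

#' Load the model parameter table
#'
#' Reads a flat CSV with one record per model parameter (`id`, `label`,
#' `base`, `low`, `high`, `family`, `role`) and returns a validated
#' parameter set.  Probabilities and utilities must lie in `[0, 1]`, costs
#' and durations must be non-negative, and where a range is given it must
#' bracket the base value.  All ids required by the model must be present;
#' ids outside the model's vocabulary are rejected.
#'
#' @param path Path to the parameter CSV.  Defaults to the bundled table of
#'   base-case values and plausible ranges for the dasatinib-vs-imatinib
#'   comparison.
#' @param settings Named list overriding analysis settings: `horizon_years`
#'   (default 10), `discount_rate` (default 0.05), `wtp`
#'   (default 70,892 CNY/QALY) and `body_surface_area` (0.8 m^2,
#'   informational).
#' @return An object of class `param_set`: a list with `entries`
#'   (data frame of parameter records) and `settings`.
#' @export
#' @examples
#' params <- table1_parameters()
#' param_value(params, "im_drug_cost")
load_parameters <- function(path, settings = list()) {
  entries <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed_cols <- c("id", "base", "low", "high", "family", "role")
  missing_cols <- setdiff(needed_cols, names(entries))
  if (length(missing_cols) > 0) {
    stop("parameter file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"label" %in% names(entries)) entries$label <- entries$id

  unknown <- setdiff(entries$id, .required_param_ids)
  if (length(unknown) > 0) {
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "))
  }
  absent <- setdiff(.required_param_ids, entries$id)
  if (length(absent) > 0) {
    stop("missing required parameter id(s): ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(entries$id)) {
    stop("duplicate parameter id(s): ",
         paste(unique(entries$id[duplicated(entries$id)]), collapse = ", "))
  }

  base_settings <- .default_settings()
  unknown_settings <- setdiff(names(settings), names(base_settings))
  if (length(unknown_settings) > 0) {
    stop("unknown setting(s): ", paste(unknown_settings, collapse = ", "))
  }
  base_settings[names(settings)] <- settings

  params <- structure(
    list(entries = entries, settings = base_settings),
    class = "param_set"
  )
  validate_parameters(params)
  params
}

#' Bundled base-case parameter table
#'
#' Convenience loader for the parameter table shipped with the package:
#' transition probabilities, annual costs (2019 CNY), phase durations and
#' health-state utilities for the imatinib and dasatinib arms, with their
#' plausible ranges and distribution families (Beta for probabilities and
#' utilities, Gamma for costs).
#'
#' @inheritParams load_parameters
#' @return A `param_set`.
#' @export
table1_parameters <- function(settings = list()) {
  load_parameters(
    system.file("extdata", "table1_params.csv", package = "tkicea",
                mustWork = TRUE),
    settings = settings
  )
}

validate_parameters <- function(params) {
  e <- params$entries
  bad_family <- setdiff(unique(e$family), c("beta", "gamma", "fixed"))
  if (length(bad_family) > 0) {
    stop("unknown distribution family: ", paste(bad_family, collapse = ", "))
  }
  bad_role <- setdiff(unique(e$role), c("transition", "cost", "utility",
                                        "duration", "setting"))
  if (length(bad_role) > 0) {
    stop("unknown parameter role: ", paste(bad_role, collapse = ", "))
  }
  for (i in seq_len(nrow(e))) {
    rec <- e[i, ]
    if (!is.finite(rec$base)) stop("parameter '", rec$id, "': base is not finite")
    if (rec$role %in% c("transition", "utility") &&
        (rec$base < 0 || rec$base > 1)) {
      stop("parameter '", rec$id, "': value ", rec$base,
           " outside [0, 1] for a ", rec$role)
    }
    if (rec$role %in% c("cost", "duration") && rec$base < 0) {
      stop("parameter '", rec$id, "': negative ", rec$role)
    }
    has_range <- is.finite(rec$low) && is.finite(rec$high)
    if (has_range && !(rec$low <= rec$base && rec$base <= rec$high)) {
      stop("parameter '", rec$id, "': range (", rec$low, ", ", rec$high,
           ") does not bracket base ", rec$base)
    }
    if (rec$family == "fixed" && has_range &&
        !(rec$low == rec$base && rec$high == rec$base)) {
      stop("parameter '", rec$id, "': fixed family requires low = high = base")
    }
  }
  s <- params$settings
  if (s$discount_rate < 0 || s$discount_rate > 1) {
    stop("discount_rate must lie in [0, 1]")
  }
  if (s$horizon_years < 1 || s$horizon_years != round(s$horizon_years)) {
    stop("horizon_years must be a positive integer")
  }
  invisible(params)
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> ", nrow(x$entries), " parameters\n", sep = "")
  cat("  horizon: ", x$settings$horizon_years, " years;  discount: ",
      x$settings$discount_rate * 100, "%;  WTP: ",
      format(x$settings$wtp, big.mark = ","), " CNY/QALY\n", sep = "")
  roles <- table(x$entries$role)
  cat("  roles: ", paste(names(roles), roles, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

param_spec <- function(params, id) {
  hit <- match(id, params$entries$id)
  if (is.na(hit)) stop("unknown parameter id: '", id, "'")
  as.list(params$entries[hit, ])
}

#' Look up or override parameter values
#'
#' `param_value()` returns the base value of one parameter.  `set_params()`
#' returns a copy of the parameter set with the named base values replaced
#' (ranges and families are untouched), re-validated; it is the mechanism
#' behind scenario analyses and probabilistic draws.
#'
#' @param params A `param_set`.
#' @param id Parameter id (see `table1_parameters()$entries$id`).
#' @param overrides Named numeric vector of `id = value` replacements.
#' @return `param_value()`: a number.  `set_params()`: a `param_set`.
#' @export
param_value <- function(params, id) {
  param_spec(params, id)$base
}

#' @rdname param_value
#' @export
set_params <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("overrides must be a named numeric vector")
  }
  for (id in names(overrides)) {
    hit <- match(id, params$entries$id)
    if (is.na(hit)) stop("unknown parameter id: '", id, "'")
    v <- overrides[[id]]
    params$entries$base[hit] <- v
    # keep the range bracketing the new base so validation still holds
    if (is.finite(params$entries$low[hit])) {
      params$entries$low[hit] <- min(params$entries$low[hit], v)
      params$entries$high[hit] <- max(params$entries$high[hit], v)
    }
  }
  validate_parameters(params)
  params
}

#' One-way bounds for a parameter
#'
#' Returns the `(low, high)` pair used by one-way sensitivity analysis and by
#' distribution construction.  Where the source table reports a range it is
#' used as-is; otherwise bounds are generated as +/-10% of base for
#' transition probabilities and +/-20% for costs and utilities (clamped to
#' the natural support), and degenerate bounds for fixed parameters.
#'
#' @inheritParams param_value
#' @return Numeric vector `c(low, high)`.
#' @export
parameter_bounds <- function(params, id) {
  spec <- param_spec(params, id)
  if (spec$family == "fixed") {
    return(c(low = spec$base, high = spec$base))
  }
  if (is.finite(spec$low) && is.finite(spec$high)) {
    return(c(low = spec$low, high = spec$high))
  }
  amp <- if (spec$role == "transition") 0.10 else 0.20
  lo <- spec$base * (1 - amp)
  hi <- spec$base * (1 + amp)
  if (spec$role %in% c("transition", "utility")) {
    lo <- max(0, lo)
    hi <- min(1, hi)
  }
  c(low = lo, high = hi)
}

# ---- rate/probability transforms ------------------------------------------

#' Convert between cumulative and annual probabilities
#'
#' For an event with cumulative probability `P` over `T` years under a
#' constant annual hazard, the per-year probability is
#' `p = 1 - (1 - P)^(1/T)`; `cumulative_from_annual()` is the inverse,
#' `P = 1 - (1 - p)^T`.  These convert the 4-year trial survival and
#' recurrence rates into the annual Markov transition probabilities.
#'
#' @param p_cum Cumulative probability over `years`, in `[0, 1]`.
#' @param p_annual Per-year probability, in `[0, 1]`.
#' @param years Time span in years, positive.
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' annual_from_cumulative(0.3439, 4)   # 0.1
#' cumulative_from_annual(0.1, 4)      # 0.3439
annual_from_cumulative <- function(p_cum, years) {
  stopifnot(years > 0)
  if (any(p_cum < 0 | p_cum > 1)) {
    stop("cumulative probability outside [0, 1]")
  }
  -expm1(log1p(-p_cum) / years)
}

#' @rdname annual_from_cumulative
#' @export
cumulative_from_annual <- function(p_annual, years) {
  stopifnot(years > 0)
  if (any(p_annual < 0 | p_annual > 1)) {
    stop("annual probability outside [0, 1]")
  }
  -expm1(years * log1p(-p_annual))
}

# ---- distribution construction --------------------------------------------

#' Build a sampling distribution for one parameter
#'
#' Method-of-moments fit with mean equal to the base value and standard
#' deviation `(high - low) / 3.92` (the range treated as a 95% interval) or
#' `(high - low) / 4` under `sd_rule = "range4"`.  Costs use a Gamma
#' distribution, probabilities and utilities a Beta; `fixed` parameters (and
#' degenerate cases such as probabilities at 0 or 1, or zero-width ranges)
#' become point masses.  If the implied Beta variance is infeasible
#' (`sd^2 >= mean * (1 - mean)`), the SD falls back to 95% of the feasible
#' maximum with a warning.
#'
#' @inheritParams param_value
#' @param sd_rule `"range95"` (default, SD = range/3.92) or `"range4"`
#'   (SD = range/4).
#' @return An object of class `cea_distribution` with fields `family`,
#'   `mean`, `sd` and the fitted shape parameters; sample from it with
#'   [draw()].
#' @export
#' @examples
#' d <- make_distribution(table1_parameters(), "hsct_success")
#' d$mean   # 0.4
#' draw(d, 3)
make_distribution <- function(params, id, sd_rule = c("range95", "range4")) {
  sd_rule <- match.arg(sd_rule)
  spec <- param_spec(params, id)
  b <- parameter_bounds(params, id)
  divisor <- if (sd_rule == "range95") 3.92 else 4
  sd <- (b[["high"]] - b[["low"]]) / divisor
  m <- spec$base

  dist <- list(id = id, family = spec$family, mean = m, sd = sd)
  if (spec$family == "fixed" || sd == 0 ||
      (spec$family == "beta" && (m <= 0 || m >= 1))) {
    dist$family <- "fixed"
    dist$sd <- 0
  } else if (spec$family == "beta") {
    if (sd^2 >= m * (1 - m)) {
      warning("parameter '", id, "': implied Beta variance infeasible; ",
              "falling back to a narrower SD")
      sd <- 0.95 * sqrt(m * (1 - m))
      dist$sd <- sd
    }
    nu <- m * (1 - m) / sd^2 - 1
    dist$shape1 <- m * nu
    dist$shape2 <- (1 - m) * nu
  } else { # gamma
    dist$shape <- (m / sd)^2
    dist$rate <- m / sd^2
  }
  structure(dist, class = "cea_distribution")
}

#' Sample from a fitted parameter distribution
#'
#' @param dist A `cea_distribution` from [make_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw <- function(dist, n) {
  stopifnot(inherits(dist, "cea_distribution"))
  switch(dist$family,
    fixed = rep(dist$mean, n),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate)
  )
}

#' @export
print.cea_distribution <- function(x, ...) {
  cat("<cea_distribution> ", x$id, ": ", x$family,
      " (mean ", signif(x$mean, 6), ", sd ", signif(x$sd, 6), ")\n", sep = "")
  invisible(x)
}
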