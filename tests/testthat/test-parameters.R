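test_that("bundled parameter table loads with the published values", {
  expect_s3_class(test_params, "param_set")
  expect_equal(param_value(test_params, "im_drug_cost"), 104857.2)
  expect_equal(param_value(test_params, "da_drug_cost"), 51100)
  expect_equal(param_value(test_params, "u_cr"), 0.88)
  expect_equal(param_value(test_params, "da_dur_intensive"), 0.6822)
  expect_equal(test_params$settings$wtp, 70892)
  expect_equal(test_params$settings$discount_rate, 0.05)
  expect_equal(test_params$settings$horizon_years, 10)
})

test_that("parameter validation rejects malformed inputs by name", {
  missing_one <- write_edited_params(function(df) df[df$id != "hsct_rate", ])
  expect_error(load_parameters(missing_one), "hsct_rate")

  bad_prob <- write_edited_params(function(df) {
    df$base[df$id == "im_relapse_maint"] <- 1.2
    df$high[df$id == "im_relapse_maint"] <- 1.3
    df
  })
  expect_error(load_parameters(bad_prob), "im_relapse_maint")

  alien <- write_edited_params(function(df) {
    extra <- df[1, ]
    extra$id <- "not_a_model_parameter"
    rbind(df, extra)
  })
  expect_error(load_parameters(alien), "not_a_model_parameter")

  dupe <- write_edited_params(function(df) rbind(df, df[3, ]))
  expect_error(load_parameters(dupe), "duplicate")

  no_bracket <- write_edited_params(function(df) {
    df$low[df$id == "hsct_success"] <- 0.45
    df
  })
  expect_error(load_parameters(no_bracket), "hsct_success")

  expect_error(param_value(test_params, "no_such_id"), "no_such_id")
  expect_error(set_params(test_params, c(nope = 1)), "nope")
  expect_error(table1_parameters(settings = list(discount_rate = 1.5)),
               "discount_rate")
})

test_that("cumulative/annual probability transforms match hand values", {
  expect_equal(annual_from_cumulative(0, 4), 0)
  expect_equal(annual_from_cumulative(1, 4), 1)
  # 1 - 0.9^4 = 0.3439, so the annual probability recovering it is 0.1
  expect_equal(annual_from_cumulative(0.3439, 4), 0.1, tolerance = 1e-12)
  expect_equal(cumulative_from_annual(0.1, 4), 0.3439, tolerance = 1e-12)
  expect_equal(round(cumulative_from_annual(0.0537, 4), 4), 0.1981)
  expect_error(annual_from_cumulative(1.01, 4), "outside")
  expect_error(cumulative_from_annual(-0.1, 4), "outside")
})

test_that("transforms round-trip and are monotone", {
  # exact where the cumulative complement stays representable in doubles;
  # at long horizons a cumulative within 1e-10 of certainty cannot carry the
  # annual probability back at this resolution
  for (T in c(0.5, 1, 4)) {
    p <- seq(0, 1, by = 0.05)
    expect_equal(annual_from_cumulative(cumulative_from_annual(p, T), T), p,
                 tolerance = 1e-12)
  }
  p <- seq(0, 0.6, by = 0.05)
  expect_equal(annual_from_cumulative(cumulative_from_annual(p, 10), 10), p,
               tolerance = 1e-12)
  expect_identical(annual_from_cumulative(cumulative_from_annual(1, 10), 10), 1)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(cumulative_from_annual(p, 4)) > 0))
  expect_true(all(cumulative_from_annual(0.3, 1:10) ==
                    cummax(cumulative_from_annual(0.3, 1:10))))
})

test_that("annual maintenance probabilities reproduce the 4-year trial deltas", {
  # recurrence: annual 0.1000 vs 0.0537 -> 4-year cumulative gap of 14.6%
  rec <- cumulative_from_annual(0.1000, 4) - cumulative_from_annual(0.0537, 4)
  expect_equal(round(100 * rec, 1), 14.6)
  # survival: annual CR death 0.0879 vs 0.0304 -> 4-year OS gap of 19.2%
  os <- cumulative_from_annual(0.0879, 4) - cumulative_from_annual(0.0304, 4)
  expect_equal(round(100 * os, 1), 19.2)
})

test_that("one-way bounds use printed ranges or generated amplitudes", {
  expect_equal(parameter_bounds(test_params, "hsct_success"),
               c(low = 0.3, high = 0.5))
  # no printed range: +/-10% for probabilities, +/-20% for costs, clamped
  expect_equal(parameter_bounds(test_params, "im_noncr_intensive"),
               c(low = 0.45, high = 0.55))
  expect_equal(parameter_bounds(test_params, "im_noncr_induction"),
               c(low = 0.9, high = 1))
  expect_equal(parameter_bounds(test_params, "im_dur_induction"),
               c(low = 0.0795, high = 0.0795))
})

test_that("method-of-moments distributions have the requested moments", {
  d <- make_distribution(test_params, "hsct_success")
  expect_equal(d$family, "beta")
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.4, tolerance = 1e-9)
  sd_expected <- (0.5 - 0.3) / 3.92
  expect_equal(d$sd, sd_expected)
  v <- d$shape1 * d$shape2 /
    ((d$shape1 + d$shape2)^2 * (d$shape1 + d$shape2 + 1))
  expect_equal(sqrt(v), sd_expected, tolerance = 1e-9)

  g <- make_distribution(test_params, "im_drug_cost")
  expect_equal(g$family, "gamma")
  expect_equal(g$shape / g$rate, 104857.2, tolerance = 1e-9)
  expect_equal(sqrt(g$shape) / g$rate, (125828.64 - 83885.76) / 3.92,
               tolerance = 1e-9)

  g4 <- make_distribution(test_params, "im_drug_cost", sd_rule = "range4")
  expect_equal(g4$sd, (125828.64 - 83885.76) / 4)

  fx <- make_distribution(test_params, "im_dur_induction")
  expect_equal(fx$family, "fixed")
  expect_equal(draw(fx, 3), rep(0.0795, 3))

  # a probability of 1 cannot carry a Beta; degenerates to a point mass
  one <- make_distribution(test_params, "im_noncr_induction")
  expect_equal(one$family, "fixed")
  expect_equal(draw(one, 2), c(1, 1))
})

test_that("sampled means converge to the base value", {
  set.seed(11)
  x <- draw(make_distribution(test_params, "u_cr"), 1e5)
  d <- make_distribution(test_params, "u_cr")
  expect_lt(abs(mean(x) - 0.88), 3 * d$sd / sqrt(1e5))
  expect_true(all(x >= 0 & x <= 1))
  y <- draw(make_distribution(test_params, "cost_hsct"), 1e5)
  expect_true(all(y >= 0))
  dy <- make_distribution(test_params, "cost_hsct")
  expect_lt(abs(mean(y) - 250000), 3 * dy$sd / sqrt(1e5))
})

test_that("infeasible Beta variance falls back to a narrower SD with warning", {
  params <- test_params
  i <- match("u_noncr", params$entries$id)
  params$entries$base[i] <- 0.02
  params$entries$low[i] <- 0
  params$entries$high[i] <- 1
  expect_warning(d <- make_distribution(params, "u_noncr"), "narrower SD")
  expect_lt(d$sd^2, 0.02 * 0.98)
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.02, tolerance = 1e-9)
})
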