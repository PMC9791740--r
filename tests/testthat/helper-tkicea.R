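# Shared fixtures: the bundled parameter set and toggle grid, loaded once.

test_params <- table1_parameters()

# All valid toggle configurations (the two alternative timings are mutually
# exclusive), as a list of cea_toggles.
all_toggle_configs <- local({
  nms <- names(structure_toggles())
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nms)))
  names(grid) <- nms
  grid <- grid[!(grid$half_cycle & grid$reward_timing_start), ]
  lapply(seq_len(nrow(grid)), function(i) {
    do.call(structure_toggles, as.list(grid[i, ]))
  })
})

# Write a parameter CSV with edits applied, returning its path.
write_edited_params <- function(edit = identity) {
  src <- system.file("extdata", "table1_params.csv", package = "tkicea")
  df <- edit(utils::read.csv(src, stringsAsFactors = FALSE))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Stub arm result for testing incremental statistics in isolation.
stub_arm <- function(cost, qalys) {
  structure(list(total_cost = cost, total_qalys = qalys),
            class = "arm_result")
}

# Parameter overrides that make death certain within one cycle from every
# living Markov state.
certain_death <- c(
  im_relapse_maint = 0, im_death_cr_maint = 1,
  da_relapse_maint = 0, da_death_cr_maint = 1,
  hsct_rate = 0, death_noncr_maint = 1,
  hsct_relapse = 0, hsct_death_cr = 1, hsct_death_noncr = 1
)
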