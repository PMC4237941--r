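test_that("secretion is linear, skips dead/dormant cells, and hives in IC", {
  rates <- rate_config(secretion_rate = 1e-18, hived_fraction = 0.2)
  pool <- pool_state()

  out <- secrete(list(), pool, rates)
  expect_equal(out$pool$total_a, 0)

  cells <- lapply(1:10, function(k) make_cell("A", "EC", id = k))
  out <- secrete(cells, pool, rates, "EC")
  expect_equal(out$pool$total_a, 10e-18)
  expect_equal(out$secreted[["a"]], 10e-18)
  expect_equal(out$pool$total_i, 0)

  # dormant and dead cells secrete nothing
  cells[[1]]$life_state <- "DORMANT"
  cells[[2]]$life_state <- "DEAD"
  out <- secrete(cells, pool, rates, "EC")
  expect_equal(out$pool$total_a, 8e-18)

  # IC variant: hived fraction diverted to the cells' own stores
  cells <- lapply(1:10, function(k) make_cell("A", "IC", id = k))
  out <- secrete(cells, pool, rates, "IC")
  expect_equal(out$pool$total_a, 8e-18)
  expect_equal(sum(vapply(out$cells, `[[`, 0, "hived_self")), 2e-18)
  expect_equal(out$secreted[["a"]], 10e-18)
})

test_that("uptake respects receptors and conserves mass", {
  rates <- rate_config(uptake_rate = 0.01, tccr_count_scale = 0.05)
  bs <- binding_system(1e10)
  pool <- pool_state(volume = 1e-9, total_a = 1e-16, total_i = 4e-17)
  eq <- pool_equilibrium(pool, bs)

  # a cell with no receptors moves nothing
  bare <- make_cell("A", "EC")
  bare$receptors$has_iR <- FALSE
  bare$receptors$has_tccR <- FALSE
  out <- uptake(bare, pool, rates, eq = eq)
  expect_equal(out$pool$total_a, pool$total_a)
  expect_equal(out$cell$store_i, 0)

  # an A cell takes free i and complex, but never free a
  a <- make_cell("A", "EC")
  out <- uptake(a, pool, rates, eq = eq)
  expect_equal(out$cell$store_a, 0)
  expect_gt(out$cell$store_i, 0)
  expect_gt(out$cell$store_ai, 0)
  expect_equal(out$pool$total_a + out$cell$store_a + out$cell$store_ai,
               pool$total_a, tolerance = 1e-12)
  expect_equal(out$pool$total_i + out$cell$store_i + out$cell$store_ai,
               pool$total_i, tolerance = 1e-12)
})

test_that("sequential uptake clips against the remaining pool", {
  rates <- rate_config(uptake_rate = 1)   # each cell wants all of the free pool
  bs <- binding_system(1e10)
  pool <- pool_state(volume = 1e-9, total_i = 1e-18)
  eq <- pool_equilibrium(pool, bs)
  c1 <- make_cell("A", "EC", id = 1)
  c2 <- make_cell("A", "EC", id = 2)
  out1 <- uptake(c1, pool, rates, eq = eq)
  out2 <- uptake(c2, out1$pool, rates, eq = eq, remaining = out1$remaining)
  expect_equal(out1$cell$store_i, 1e-18)
  expect_equal(out2$cell$store_i, 0)          # nothing left to draw
  expect_gte(out2$pool$total_i, 0)
})

test_that("intracellular readout re-equilibrates the internalized species", {
  rates <- rate_config(endosome_volume = 1e-13)
  bs <- binding_system(1e10)

  empty <- make_cell("A", "EC")
  expect_equal(unname(intracellular_readout(empty, bs, "EC", rates)), c(0, 0))

  # one species only: no self Trefone present, the complex cannot grow
  a <- make_cell("A", "EC")
  a$store_i <- 3e-19
  ro <- intracellular_readout(a, bs, "EC", rates)
  expect_equal(ro[["partner"]], 3e-19 / 1e-13)
  expect_equal(ro[["complex"]], 0)

  # internalized complex partially dissociates in the endosome
  a$store_ai <- 2e-19
  ro <- intracellular_readout(a, bs, "EC", rates)
  oc <- oracle_pair_complex(2e-19 / 1e-13, 5e-19 / 1e-13, 1e10)
  expect_equal(ro[["complex"]], oc, tolerance = 1e-7)

  # IC variant: hived self Trefone equilibrates with internalized partner;
  # symmetric amounts reproduce the equal-totals chemistry
  i_ic <- make_cell("I", "IC")
  i_ic$hived_self <- 1e-21
  i_ic$store_a <- 1e-21
  ro <- intracellular_readout(i_ic, bs, "IC", rates)
  conc <- 1e-21 / 1e-13
  oc <- oracle_pair_complex(conc, conc, 1e10)
  expect_equal(ro[["complex"]], oc, tolerance = 1e-7)
  expect_equal(ro[["partner"]], conc - oc, tolerance = 1e-7)

  expect_error(intracellular_readout(a, bs, "EC",
                                     rate_config(endosome_volume = 1e-13)),
               NA)
  bad <- rates; bad$endosome_volume <- 0
  expect_error(intracellular_readout(a, bs, "EC", bad), "endosome_volume")
})

test_that("degradation is first-order and compounds", {
  pool <- pool_state(total_a = 1e-16, total_i = 2e-16, total_analog = 5e-17)

  out <- degrade(pool, rate_config(degradation_rate = 0))
  expect_equal(out$pool$total_a, pool$total_a)
  expect_equal(sum(out$removed), 0)

  out <- degrade(pool, rate_config(degradation_rate = 1))
  expect_equal(out$pool$total_a + out$pool$total_i + out$pool$total_analog, 0)

  d <- 0.3
  two <- degrade(degrade(pool, rate_config(degradation_rate = d))$pool,
                 rate_config(degradation_rate = d))$pool
  one <- degrade(pool,
                 rate_config(degradation_rate = 1 - (1 - d)^2))$pool
  expect_equal(two$total_a, one$total_a, tolerance = 1e-12)
  expect_equal(two$total_i, one$total_i, tolerance = 1e-12)
})

test_that("an A cell's own-species store only changes via complex internalization", {
  run <- ctc_run(small_couplet_config(seed = 2, steps = 15))
  for (cell in ctcsim:::live_cells(run$final)) {
    if (cell$cell_type == "A") {
      # all a-species content inside an A cell arrived as complex
      expect_equal(cell$store_a, 0)
    }
    if (cell$cell_type == "I") {
      expect_equal(cell$store_i, 0)
    }
  }
})

test_that("the global mass ledger closes on a mixed run", {
  cfg <- small_couplet_config(seed = 3, steps = 25,
    events = list(list(at_step = 5, kind = "ADD_TREFONE", species = "a",
                       amount = 1e-15),
                  list(at_step = 12, kind = "SINK_TREFONE", species = "i",
                       amount = 0.5)))
  run <- ctc_run(cfg)          # ctc_step() hard-errors on ledger failure
  expect_ledger_closed(run)
})
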