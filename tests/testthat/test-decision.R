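test_that("the default table is total and well-formed", {
  tbl <- default_table()
  expect_length(validate_table(tbl), 0)
  # every key resolves
  for (ty in c("A", "I", "SINGLET", "O")) {
    for (p in c("Lo", "Mid", "Hi")) {
      for (cx in c("Lo", "Mid", "Hi")) {
        expect_silent(ctcsim:::table_row(tbl, ty, p, cx))
      }
    }
  }
})

test_that("validate_table reports missing keys and zero-dwell divisions", {
  tbl <- default_table()
  drop <- tbl$rows$cell_type == "A" & tbl$rows$partner_level == "Lo" &
    tbl$rows$complex_level == "Lo"
  broken <- tbl
  broken$rows <- tbl$rows[!drop, ]
  diags <- validate_table(broken)
  expect_length(diags, 1)
  expect_match(diags, "missing key.*A Lo Lo")

  bad_dwell <- tbl
  scd <- bad_dwell$rows$prolonged_action == "SCD_SRE"
  bad_dwell$rows$dwell_required[which(scd)[1]] <- 0L
  expect_match(validate_table(bad_dwell), "dwell_required < 1", all = FALSE)

  dup <- tbl
  dup$rows <- rbind(tbl$rows, tbl$rows[1, ])
  expect_match(validate_table(dup), "unreachable duplicate", all = FALSE)
})

test_that("sustained Hi-partner stimulus fires one symmetric division per dwell window", {
  tbl <- default_table(dwell_required = 3L)
  for (ty in c("A", "I")) {
    cell <- make_cell(ty, "EC")
    fired <- integer(0)
    for (s in 1:7) {
      out <- decide(cell, "Hi", "Lo", tbl)
      cell <- out$cell
      if (out$action == "SCD_SRE") fired <- c(fired, s)
      if (out$action == "BOOST_SECRETION") expect_lt(cell$dwell_hi, 3L)
    }
    expect_equal(fired, c(3L, 6L))   # exactly once per completed window
  }
})

test_that("immediate actions are never divisions right after a dwell reset", {
  tbl <- default_table(dwell_required = 4L)
  cell <- make_cell("A", "EC")
  out <- decide(cell, "Hi", "Mid", tbl)     # dwell 1: immediate action
  expect_equal(out$action, "BOOST_SECRETION")
  out <- decide(out$cell, "Lo", "Mid", tbl) # leaves the class: reset
  expect_equal(out$cell$dwell_hi, 0L)
  out <- decide(out$cell, "Hi", "Mid", tbl)
  expect_equal(out$action, "BOOST_SECRETION")
})

test_that("Hi complex always quiesces, with apoptosis only at the extreme", {
  tbl <- default_table()
  p <- tbl$params
  for (pl in c("Lo", "Mid", "Hi")) {
    cell <- make_cell("A", "EC")
    for (s in 1:20) {
      out <- decide(cell, pl, "Hi", tbl,
                    complex_conc = p$theta_hi_complex * 2)
      cell <- out$cell
      expect_equal(out$action, "QSC")
    }
  }
  # extreme complex with Hi partner triggers apoptosis (configurable)
  cell <- make_cell("A", "EC")
  out <- decide(cell, "Hi", "Hi", tbl,
                complex_conc = p$apo_factor * p$theta_hi_complex * 1.1)
  expect_equal(out$action, "APO")
  off <- default_table(apo_enabled = FALSE)
  out <- decide(make_cell("A", "EC"), "Hi", "Hi", off,
                complex_conc = p$apo_factor * p$theta_hi_complex * 1.1)
  expect_equal(out$action, "QSC")
})

test_that("starvation escalates: AsCD, then partner-partner, then dedifferentiation", {
  tbl <- default_table(dwell_required = 2L, escalation_mult = 3L,
                       dediff_mult = 5L)
  cell <- make_cell("I", "EC")
  seen <- character(0)
  for (s in 1:11) {
    out <- decide(cell, "Lo", "Lo", tbl)
    cell <- out$cell
    seen <- c(seen, out$action)
  }
  expect_equal(seen[2], "ASCD_SELF_PARTNER")      # dwell == 2
  expect_equal(seen[6], "ASCD_PARTNER_PARTNER")   # dwell == 6 (3x)
  expect_equal(seen[10], "DEDIFF")                # dwell >= 10 (5x)
  expect_true(all(seen[c(1, 3:5, 7:9)] == "QSC"))
})

test_that("a division trigger beats dedifferentiation on the same step", {
  tbl <- default_table(dwell_required = 2L, escalation_mult = 3L,
                       dediff_mult = 3L)   # escalation and dediff coincide
  cell <- make_cell("A", "EC")
  acts <- character(0)
  for (s in 1:7) {
    out <- decide(cell, "Lo", "Lo", tbl)
    cell <- out$cell
    acts <- c(acts, out$action)
  }
  expect_equal(acts[6], "ASCD_PARTNER_PARTNER")   # division wins at the tie
  expect_equal(acts[7], "DEDIFF")
})

test_that("singlet starvation never divides or dedifferentiates", {
  tbl <- default_table(dwell_required = 2L, dediff_mult = 3L)
  cell <- make_cell("SINGLET", "EC")
  for (s in 1:12) {
    out <- decide(cell, "Lo", "Lo", tbl)
    cell <- out$cell
    expect_equal(out$action, "QSC")
  }
})

test_that("basal asymmetric division happens only in the (Mid, Mid) row", {
  never <- default_table(basal_ascd_prob = 0)
  always <- default_table(basal_ascd_prob = 1)
  set.seed(1)
  expect_equal(decide(make_cell("A", "EC"), "Mid", "Mid", never)$action, "QSC")
  expect_equal(decide(make_cell("A", "EC"), "Mid", "Mid", always)$action,
               "ASCD_SELF_PARTNER")
  expect_equal(decide(make_cell("A", "EC"), "Mid", "Lo", always)$action,
               "QSC")
  expect_equal(decide(make_cell("SINGLET", "EC"), "Mid", "Mid",
                      always)$action, "QSC")
})

test_that("dormant cells quiesce until a Hi partner signal reawakens them", {
  tbl <- default_table()
  cell <- make_cell("I", "EC", life_state = "DORMANT")
  out <- decide(cell, "Lo", "Lo", tbl)
  expect_equal(out$action, "QSC")
  expect_equal(out$cell$life_state, "DORMANT")
  out <- decide(cell, "Hi", "Lo", tbl)
  expect_equal(out$cell$life_state, "CYCLING")
})

test_that("the homeostatic fixed point yields only quiescence", {
  # equal counts, free Trefones Lo, complex Hi: the decision layer must not
  # change the population (basal AsCD probability set to zero)
  tbl <- default_table(basal_ascd_prob = 0)
  for (ty in c("A", "I")) {
    cell <- make_cell(ty, "EC")
    for (s in 1:30) {
      out <- decide(cell, "Lo", "Hi", tbl)
      cell <- out$cell
      expect_equal(out$action, "QSC")
    }
  }
})

test_that("decide is a pure function of (cell, levels, table, rng)", {
  tbl <- default_table()
  cell <- make_cell("A", "EC")
  cell$dwell_hi <- 3L
  set.seed(99); r1 <- decide(cell, "Mid", "Mid", tbl)
  set.seed(99); r2 <- decide(cell, "Mid", "Mid", tbl)
  expect_identical(r1, r2)
})

test_that("lowering one Trefone from the fixed point provokes replacement divisions", {
  # same seed, same world; the perturbed arm diverts the a-Trefone from
  # step 12 onward.  Within the next dwell windows the count of A-producing
  # decisions (A symmetric divisions + I asymmetric divisions) must strictly
  # exceed the unperturbed arm's.
  base <- small_couplet_config(seed = 5, steps = 32)
  sunk <- small_couplet_config(seed = 5, steps = 32,
    events = lapply(12:32, function(s)
      list(at_step = s, kind = "SINK_TREFONE", species = "a", amount = 0.9)))
  count_a_producing <- function(run) {
    ts <- run$timeseries
    w <- ts$step > 12
    sum(ts$act_A_SCD_SRE[w] + ts$act_I_ASCD_SELF_PARTNER[w] +
          ts$act_I_ASCD_PARTNER_PARTNER[w])
  }
  expect_gt(count_a_producing(ctc_run(sunk)),
            count_a_producing(ctc_run(base)))
})
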