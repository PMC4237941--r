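#' @title Canned scenarios
#' @name scenarios
#' @description
#' Each scenario freezes a configuration + seed reproducing one of the
#' model's narrated thought experiments, runs it, and returns a
#' `ctc_scenario_report` whose assertions encode the narrated outcome.  All
#' scenarios accept a `mirror` flag that swaps the roles of the two couplet
#' families (species, receptors and initial populations); the model is fully
#' symmetric, so every mirrored scenario must pass identically.
NULL

#' Pool-level Lo/Hi thresholds implied by a configuration
#'
#' Decision thresholds are defined on the *intracellular* readout.  At the
#' uptake/turnover steady state a pool concentration `c` maps onto a readout
#' of roughly `c * uptake_rate * volume / (store_decay_rate *
#' endosome_volume)` for the partner channel (times `tccr_count_scale` for
#' the complex channel), so the readout thresholds pull back to pool-level
#' equivalents.  Scenario assertions about the extracellular state use these
#' derived values rather than ad hoc constants.
#'
#' @param config a `ctc_config`.
#' @return Named list `free_lo`, `free_hi`, `complex_lo`, `complex_hi`
#'   (mol/L).
#' @export
pool_thresholds <- function(config) {
  r <- config$rates
  p <- config$table$params
  k_partner <- r$uptake_rate * config$initial_pool$volume /
    (r$store_decay_rate * r$endosome_volume)
  k_complex <- k_partner * r$tccr_count_scale
  list(free_lo = p$theta_lo_partner / k_partner,
       free_hi = p$theta_hi_partner / k_partner,
       complex_lo = p$theta_lo_complex / k_complex,
       complex_hi = p$theta_hi_complex / k_complex)
}

new_report <- function(scenario, seed, mirror, config, assertions,
                       observables, run = NULL, extra_runs = NULL) {
  hash <- config_hash(config)
  assertions$scenario <- scenario
  assertions$config_hash <- hash
  assertions$seed <- seed
  structure(
    list(scenario = scenario, seed = seed, mirror = mirror,
         config_hash = hash, assertions = assertions,
         observables = observables, run = run, extra_runs = extra_runs),
    class = "ctc_scenario_report"
  )
}

assert_row <- function(name, pass, detail) {
  data.frame(name = name, pass = isTRUE(pass), detail = detail,
             stringsAsFactors = FALSE)
}

#' @export
print.ctc_scenario_report <- function(x, ...) {
  cat(sprintf("Scenario '%s' (seed %d%s, config %s): %s\n",
              x$scenario, x$seed, if (x$mirror) ", mirrored" else "",
              x$config_hash,
              if (all(x$assertions$pass)) "PASS" else "FAIL"))
  for (k in seq_len(nrow(x$assertions))) {
    cat(sprintf("  [%s] %s — %s\n",
                if (x$assertions$pass[k]) "ok" else "FAIL",
                x$assertions$name[k], x$assertions$detail[k]))
  }
  invisible(x)
}

# species / cell-type role map: the "focal" family is the one the scenario
# watches (I cells responding to added a-Trefone in the reference
# orientation); mirroring swaps every role
roles <- function(mirror) {
  if (!mirror) {
    list(focal_type = "I", other_type = "A", focal_trefone = "i",
         other_trefone = "a", n_focal = "n_I", n_other = "n_A")
  } else {
    list(focal_type = "A", other_type = "I", focal_trefone = "a",
         other_trefone = "i", n_focal = "n_A", n_other = "n_I")
  }
}

# pool amount at the secretion/degradation steady state of n secreting cells
ss_pool_amount <- function(n, rates = rate_config()) {
  n * rates$secretion_rate / rates$degradation_rate
}

# homeostatic base world: equal couplet populations with the pool already at
# the secretion/degradation steady state of the initial populations
base_couplet_config <- function(seed, steps = 110L, n_a = 20, n_i = 20,
                                rates = rate_config(),
                                pool_a = ss_pool_amount(n_a, rates),
                                pool_i = ss_pool_amount(n_i, rates),
                                events = list(), binding = binding_system(),
                                table = default_table(), variant = "EC",
                                pool_extra = list()) {
  pool_args <- utils::modifyList(
    list(volume = 1e-9, total_a = pool_a, total_i = pool_i),
    pool_extra)
  sim_config(
    variant = variant, binding = binding, rates = rates,
    table = table,
    initial_cells = list(list(type = "A", n = n_a), list(type = "I", n = n_i)),
    initial_pool = do.call(pool_state, pool_args),
    steps = steps, seed = seed, events = events
  )
}

#' Homeostasis after a Trefone spike
#'
#' From the balanced fixed point (equal couplet populations, pool at steady
#' state) an excess of one Trefone is injected.  The opposite family must
#' proliferate first (it perceives partner-family excess), the population
#' ratio must return to balance by run end, and the terminal pool must show
#' a high complex with low, approximately equal free Trefones.
#'
#' @param overrides named list: `spike_amount` (mol), `spike_step`, `steps`.
#' @param seed RNG seed.
#' @param mirror swap the roles of the two families.
#' @return A `ctc_scenario_report`.
#' @export
scenario_balanced_perturbation <- function(overrides = list(), seed = 1,
                                           mirror = FALSE) {
  o <- utils::modifyList(list(spike_amount = 1e-14, spike_step = 20L,
                              steps = 110L), overrides)
  r <- roles(mirror)
  config <- base_couplet_config(
    seed, steps = o$steps,
    events = list(list(at_step = o$spike_step, kind = "ADD_TREFONE",
                       species = r$other_trefone, amount = o$spike_amount)))
  run <- ctc_run(config)
  ts <- run$timeseries
  th <- pool_thresholds(config)
  window_end <- min(o$spike_step + 3L * config$table$params$dwell_required,
                    o$steps)
  n_focal_spike <- ts[[r$n_focal]][o$spike_step]
  n_focal_window <- ts[[r$n_focal]][window_end]
  last <- ts[nrow(ts), ]
  imbalance <- abs(last$n_A - last$n_I) / max(last$n_A + last$n_I, 1L)
  fa <- last$pool_free_a
  fi <- last$pool_free_i
  free_gap <- if (fa + fi > 0) abs(fa - fi) / (fa + fi) else 0

  assertions <- rbind(
    assert_row("focal family rises within the dwell window",
               n_focal_window > n_focal_spike,
               sprintf("%s: %d -> %d (steps %d..%d)", r$focal_type,
                       n_focal_spike, n_focal_window, o$spike_step,
                       window_end)),
    assert_row("population ratio rebalances below 0.1",
               imbalance < 0.1,
               sprintf("final |N_A - N_I|/(N_A + N_I) = %.3f", imbalance)),
    assert_row("terminal Hi complex with low, near-equal free Trefones",
               last$pool_complex_ai >= th$complex_hi &&
                 fa < th$free_hi && fi < th$free_hi &&
                 last$pool_complex_ai > 10 * max(fa, fi) && free_gap < 0.5,
               sprintf("complex %.3g (Hi >= %.3g), free a %.3g / i %.3g (low < %.3g), gap %.2f",
                       last$pool_complex_ai, th$complex_hi, fa, fi,
                       th$free_hi, free_gap))
  )
  rebal <- which(abs(ts$n_A - ts$n_I) / pmax(ts$n_A + ts$n_I, 1L) < 0.1 &
                   ts$step > o$spike_step)
  new_report("balanced_perturbation", seed, mirror, config, assertions,
             observables = list(
               final_ratio = imbalance,
               time_to_rebalance = if (length(rebal) > 0)
                 ts$step[rebal[1]] - o$spike_step else NA,
               final_counts = c(A = last$n_A, I = last$n_I)),
             run = run)
}

#' Monoculture conversion
#'
#' A culture of one couplet type plus a dose of its *own* Trefone.  Cells of
#' the missing family must appear through asymmetric division, and both
#' families must persist to run end.
#'
#' @inheritParams scenario_balanced_perturbation
#' @param overrides named list: `dose` (mol of the culture's own Trefone),
#'   `steps`, `n_cells`, `starved_ascd` (set `FALSE` for the ablation
#'   control: no starvation-driven asymmetric division), `basal_ascd_prob`.
#' @return A `ctc_scenario_report`.
#' @export
scenario_monoculture_conversion <- function(overrides = list(), seed = 1,
                                            mirror = FALSE) {
  o <- utils::modifyList(list(dose = 2e-15, steps = 60L, n_cells = 20,
                              starved_ascd = TRUE, basal_ascd_prob = 0.01),
                         overrides)
  r <- roles(mirror)
  # the culture is the *other* family here: A cells + added a-Trefone in the
  # reference orientation (mirror: I cells + i-Trefone)
  culture_type <- r$other_type
  culture_trefone <- r$other_trefone
  table <- default_table(basal_ascd_prob = o$basal_ascd_prob)
  if (!o$starved_ascd) {
    starved <- table$rows$partner_level == "Lo" &
      table$rows$complex_level == "Lo"
    table$rows$prolonged_action[starved] <- "QSC"
  }
  config <- base_couplet_config(
    seed, steps = o$steps,
    n_a = if (culture_type == "A") o$n_cells else 0,
    n_i = if (culture_type == "I") o$n_cells else 0,
    pool_a = 0, pool_i = 0, table = table,
    events = if (o$dose > 0)
      list(list(at_step = 1L, kind = "ADD_TREFONE",
                species = culture_trefone, amount = o$dose))
    else list())
  run <- ctc_run(config)
  last <- run$timeseries[nrow(run$timeseries), ]
  n_new <- last[[r$n_focal]]
  n_culture <- last[[r$n_other]]
  assertions <- rbind(
    assert_row("missing family appears via asymmetric division",
               n_new > 0, sprintf("final %s count = %d", r$focal_type, n_new)),
    assert_row("both families persist at run end",
               n_new > 0 && n_culture > 0,
               sprintf("final counts %s=%d %s=%d", r$other_type, n_culture,
                       r$focal_type, n_new))
  )
  new_report("monoculture_conversion", seed, mirror, config, assertions,
             observables = list(final_counts = c(culture = n_culture,
                                                 converted = n_new)),
             run = run)
}

#' Low-affinity analog potency
#'
#' Two matched runs dose an equal amount of either the genuine partner
#' Trefone or its low-complex-affinity analog into a monoculture whose own
#' Trefone is present.  The genuine dose is largely sequestered into the
#' complex (high complex readout, vanishing free signal); the analog escapes
#' sequestration, so the cells read a *low* complex — interpreted as partner
#' deficiency — and divide more.  Cumulative symmetric divisions in the
#' analog arm must be at least (with a genuinely weaker analog: strictly
#' greater than) the genuine-Trefone arm.
#'
#' @inheritParams scenario_balanced_perturbation
#' @param overrides named list: `dose` (mol), `ka_analog`, `steps`,
#'   `n_cells`, `dose_step`.
#' @return A `ctc_scenario_report` (`extra_runs$genuine`, `extra_runs$analog`).
#' @export
scenario_analog_potency <- function(overrides = list(), seed = 1,
                                    mirror = FALSE) {
  o <- utils::modifyList(list(dose_rate = 4e-17, ka_analog = 1e7,
                              steps = 60L, n_cells = 40, dose_start = 10L,
                              dose_end = 40L), overrides)
  r <- roles(mirror)
  mimics <- r$other_trefone           # the analog imitates the dosed Trefone
  make_run <- function(species) {
    binding <- binding_system(ka = 1e10, ka_analog = o$ka_analog,
                              analog_mimics = mimics)
    events <- list()
    if (o$dose_rate > 0) {
      for (s in seq(o$dose_start, o$dose_end)) {
        events[[length(events) + 1L]] <-
          list(at_step = s, kind = "ADD_TREFONE", species = species,
               amount = o$dose_rate)
      }
    }
    config <- base_couplet_config(
      seed, steps = o$steps, binding = binding,
      n_a = if (r$focal_type == "A") o$n_cells else 0,
      n_i = if (r$focal_type == "I") o$n_cells else 0,
      pool_a = if (r$focal_trefone == "a") ss_pool_amount(o$n_cells) else 0,
      pool_i = if (r$focal_trefone == "i") ss_pool_amount(o$n_cells) else 0,
      events = events)
    ctc_run(config)
  }
  run_genuine <- make_run(r$other_trefone)
  run_analog <- make_run("d")
  scd_genuine <- run_genuine$tallies[r$focal_type, "SCD_SRE"]
  scd_analog <- run_analog$tallies[r$focal_type, "SCD_SRE"]
  strict <- o$ka_analog < 1e10 && o$dose_rate > 0
  assertions <- assert_row(
    "analog arm divides at least as much as the genuine arm",
    if (strict) scd_analog > scd_genuine else scd_analog >= scd_genuine,
    sprintf("%s SCD_SRE decisions: analog %d vs genuine %d (ka_analog %.3g)",
            r$focal_type, scd_analog, scd_genuine, o$ka_analog))
  new_report("analog_potency", seed, mirror,
             run_genuine$config, assertions,
             observables = list(scd_genuine = scd_genuine,
                                scd_analog = scd_analog),
             run = run_analog,
             extra_runs = list(genuine = run_genuine, analog = run_analog))
}

#' Acute Trefone sink
#'
#' From the balanced fixed point, one Trefone is acutely destroyed/diverted
#' every step.  The pool complex must fall to Lo, production of the opposite
#' Trefone must decrease (its cells lose their stimulus), and the cells that
#' make the sunk Trefone must read (Hi partner, Lo complex) — their partner's
#' signal now reaches them unbound.
#'
#' @inheritParams scenario_balanced_perturbation
#' @param overrides named list: `sink_fraction` (per-step fraction removed),
#'   `sink_start`, `steps`, `sink_both` (apply the sink to both Trefones).
#' @return A `ctc_scenario_report`.
#' @export
scenario_trefone_sink <- function(overrides = list(), seed = 1,
                                  mirror = FALSE) {
  o <- utils::modifyList(list(sink_fraction = 0.9, sink_start = 20L,
                              steps = 27L, sink_both = FALSE), overrides)
  r <- roles(mirror)
  sunk <- r$other_trefone             # the a-Trefone in the reference run
  events <- list()
  if (o$sink_fraction > 0) {
    for (s in seq(o$sink_start, o$steps)) {
      events[[length(events) + 1L]] <-
        list(at_step = s, kind = "SINK_TREFONE", species = sunk,
             amount = o$sink_fraction)
      if (o$sink_both) {
        events[[length(events) + 1L]] <-
          list(at_step = s, kind = "SINK_TREFONE", species = r$focal_trefone,
               amount = o$sink_fraction)
      }
    }
  }
  config <- base_couplet_config(seed, steps = o$steps, events = events)
  run <- ctc_run(config)
  ts <- run$timeseries
  th <- pool_thresholds(config)
  last <- ts[nrow(ts), ]
  pre <- ts$step >= o$sink_start - 10L & ts$step < o$sink_start
  post <- ts$step > o$steps - 5L
  sec_col <- paste0("secreted_", r$focal_trefone)
  # per-cell secretion rate, so population growth does not mask the damping
  n_col <- r$n_focal
  rate_pre <- mean(ts[[sec_col]][pre] / pmax(ts[[n_col]][pre], 1L))
  rate_post <- mean(ts[[sec_col]][post] / pmax(ts[[n_col]][post], 1L))

  # readout of the cells producing the sunk Trefone (A cells by default)
  producers <- Filter(function(c) c$cell_type == r$other_type,
                      live_cells(run$final))
  reads <- vapply(producers, function(c) {
    lv <- discretize_readout(
      intracellular_readout(c, config$binding, config$variant, config$rates),
      config$table)
    c(lv[["partner"]] == "Hi", lv[["complex"]] == "Lo")
  }, logical(2))
  frac_hi_lo <- if (length(producers) > 0) mean(reads[1, ] & reads[2, ]) else 0

  assertions <- rbind(
    assert_row("pool complex falls to Lo",
               last$pool_complex_ai < th$complex_lo,
               sprintf("final complex %.3g < Lo threshold %.3g",
                       last$pool_complex_ai, th$complex_lo)),
    assert_row("opposite Trefone production decreases",
               rate_post < rate_pre,
               sprintf("per-cell %s secretion %.3g -> %.3g mol/step",
                       r$focal_trefone, rate_pre, rate_post)),
    assert_row("producer cells read Hi partner with Lo complex",
               frac_hi_lo >= 0.5,
               sprintf("%.0f%% of %s cells read (Hi, Lo)",
                       100 * frac_hi_lo, r$other_type))
  )
  new_report("trefone_sink", seed, mirror, config, assertions,
             observables = list(final_complex = last$pool_complex_ai,
                                secretion_rate_pre = rate_pre,
                                secretion_rate_post = rate_post,
                                frac_hi_lo = frac_hi_lo),
             run = run)
}

#' Embryonic lineage marker fractions
#'
#' Deterministic lineage with no chemistry: one original cell cleaves
#' asymmetrically (dual lineage commitment) into the two couplet types, and
#' every subsequent cleavage is symmetric self-renewal.  At the 2-, 4- and
#' 8-cell stages the fraction of blastomeres carrying the discriminating
#' partner-Trefone receptor profile (`aR+ iR-`, modelling the receptor for
#' the embryonic growth factor) must be exactly one half at every stage.
#'
#' @param first_division action of the first cleavage; the default is the
#'   asymmetric `"ASCD_DUAL_LCDF"`; `"SCD_SRE"` is the ablation control (all
#'   cells stay progenitors, no blastomere acquires the committed marker
#'   profile).
#' @param mirror count the mirrored profile (`iR+ aR-`) instead.
#' @return A `ctc_scenario_report` with observables `fractions` (named by
#'   stage) and `positive_counts`.
#' @export
scenario_blastomere_lineage <- function(first_division = "ASCD_DUAL_LCDF",
                                        mirror = FALSE) {
  zygote <- make_cell("O", "EC", id = 1L)
  cells <- divide(zygote, first_division, next_id = 2L)
  stages <- list(`2` = cells)
  for (stage in c(4L, 8L)) {
    nid <- max(vapply(cells, `[[`, 0L, "id")) + 1L
    nxt <- list()
    for (c in cells) {
      kids <- divide(c, "SCD_SRE", next_id = nid)
      nid <- nid + 2L
      nxt <- c(nxt, kids)
    }
    cells <- nxt
    stages[[as.character(stage)]] <- cells
  }
  wanted <- if (!mirror) c(has_aR = TRUE, has_iR = FALSE)
            else c(has_aR = FALSE, has_iR = TRUE)
  positive <- function(cell) {
    cell$receptors$has_aR == wanted[["has_aR"]] &&
      cell$receptors$has_iR == wanted[["has_iR"]]
  }
  counts <- vapply(stages, function(cs) sum(vapply(cs, positive, TRUE)),
                   numeric(1))
  sizes <- vapply(stages, length, numeric(1))
  fractions <- counts / sizes
  config <- sim_config(steps = 1L, seed = 1L,
                       initial_cells = list(list(type = "O", n = 1)))
  expected <- if (first_division == "ASCD_DUAL_LCDF") 0.5 else 0
  assertions <- rbind(
    assert_row("receptor-positive fraction matches the model prediction at every stage",
               all(fractions == expected),
               sprintf("positive/total: %s (predicted fraction %.2f)",
                       paste(sprintf("%d/%d", counts, sizes),
                             collapse = ", "), expected)),
    assert_row("stage fractions agree with each other",
               length(unique(fractions)) == 1L,
               paste(sprintf("%.3f", fractions), collapse = ", "))
  )
  new_report("blastomere_lineage", 1L, mirror, config, assertions,
             observables = list(fractions = fractions,
                                positive_counts = counts,
                                stage_sizes = sizes,
                                percent_positive = 100 * fractions))
}

#' Bacterial persistence: kill and regrow
#'
#' One family grows exponentially in medium rich in its partner's Trefone
#' while the other family sits dormant.  A kill event removes every
#' metabolically active cell (dormant persisters survive); fresh medium then
#' reawakens the persisters, which regrow and re-produce the killed family
#' by symmetric and asymmetric division.  A control arm without dormant
#' cells goes extinct.
#'
#' @inheritParams scenario_balanced_perturbation
#' @param overrides named list: `steps`, `kill_step`, `replace_step`,
#'   `n_growing`, `n_dormant`, `medium_amount` (mol of partner Trefone in
#'   both the initial and the replacement medium), `kill` (set `FALSE` to
#'   skip the kill event).
#' @return A `ctc_scenario_report` (`extra_runs$control` is the no-persister
#'   arm).
#' @export
scenario_persisters <- function(overrides = list(), seed = 1,
                                mirror = FALSE) {
  o <- utils::modifyList(list(steps = 70L, kill_step = 20L,
                              replace_step = 21L, n_growing = 10,
                              n_dormant = 10, medium_amount = 1e-13,
                              replace_amount = 1e-15,
                              degradation_rate = 0.1, kill = TRUE),
                         overrides)
  r <- roles(mirror)
  growing_type <- r$other_type        # A cells in the reference orientation
  dormant_type <- r$focal_type
  # initial medium feeds the growing family (partner Trefone of the growing
  # type); replacement medium feeds the reawakening persisters
  grow_food <- r$focal_trefone
  persister_food <- r$other_trefone
  make_config <- function(n_dormant) {
    events <- list()
    if (o$kill) {
      events <- list(
        list(at_step = o$kill_step, kind = "KILL_CYCLING"),
        list(at_step = o$replace_step, kind = "MEDIUM_REPLACE",
             totals = stats::setNames(
               list(o$replace_amount, 0, 0),
               c(paste0("total_", if (persister_food == "a") "a" else "i"),
                 paste0("total_", if (persister_food == "a") "i" else "a"),
                 "total_analog")))
      )
    }
    # the flask medium is cleared much more slowly than the tissue-like
    # default world, and the persisters' survival depends on the medium
    # Trefone outlasting the growth phase
    base_couplet_config(
      seed, steps = o$steps,
      rates = rate_config(degradation_rate = o$degradation_rate),
      n_a = if (growing_type == "A") o$n_growing else n_dormant,
      n_i = if (growing_type == "I") o$n_growing else n_dormant,
      pool_a = if (grow_food == "a") o$medium_amount else 0,
      pool_i = if (grow_food == "i") o$medium_amount else 0,
      events = events)
  }
  config <- make_config(o$n_dormant)
  # the dormant group is imposed on the initial cells (growth-arrested by
  # prior starvation, outside the simulated window)
  config$initial_cells <- list(
    list(type = growing_type, n = o$n_growing),
    list(type = dormant_type, n = o$n_dormant, life_state = "DORMANT"))
  run <- ctc_run(config)
  config_control <- make_config(0)
  config_control$initial_cells <- list(
    list(type = growing_type, n = o$n_growing))
  run_control <- ctc_run(config_control)

  ts <- run$timeseries
  at_kill <- ts[ts$step == o$kill_step, ]
  last <- ts[nrow(ts), ]
  live_end <- last$n_CYCLING + last$n_QUIESCENT + last$n_DORMANT
  ctrl_last <- run_control$timeseries[nrow(run_control$timeseries), ]
  ctrl_live <- ctrl_last$n_CYCLING + ctrl_last$n_QUIESCENT + ctrl_last$n_DORMANT
  grew <- ts[[paste0("n_", growing_type)]][o$kill_step - 1L] > o$n_growing

  assertions <- rbind(
    assert_row("growing family expands before the kill",
               grew,
               sprintf("%s: %d -> %d by step %d", growing_type, o$n_growing,
                       ts[[paste0("n_", growing_type)]][o$kill_step - 1L],
                       o$kill_step - 1L)),
    assert_row("only former dormant cells survive the kill",
               at_kill$n_CYCLING + at_kill$n_QUIESCENT == 0 &&
                 at_kill$n_DORMANT == o$n_dormant,
               sprintf("at step %d: cycling+quiescent %d, dormant %d",
                       o$kill_step, at_kill$n_CYCLING + at_kill$n_QUIESCENT,
                       at_kill$n_DORMANT)),
    assert_row("persisters regrow and rebuild the killed family",
               live_end > o$n_dormant &&
                 last[[paste0("n_", growing_type)]] > 0 &&
                 run$tallies[dormant_type, "SCD_SRE"] > 0 &&
                 (run$tallies[dormant_type, "ASCD_SELF_PARTNER"] +
                    run$tallies[dormant_type, "ASCD_PARTNER_PARTNER"]) > 0,
               sprintf("final live %d (%s=%d), %s SCD=%d AsCD=%d",
                       live_end, growing_type,
                       last[[paste0("n_", growing_type)]], dormant_type,
                       run$tallies[dormant_type, "SCD_SRE"],
                       run$tallies[dormant_type, "ASCD_SELF_PARTNER"] +
                         run$tallies[dormant_type, "ASCD_PARTNER_PARTNER"])),
    assert_row("no regrowth without persisters",
               !o$kill || ctrl_live == 0,
               sprintf("control arm live cells at end: %d", ctrl_live))
  )
  new_report("persisters", seed, mirror, config, assertions,
             observables = list(live_at_kill = at_kill$n_DORMANT,
                                live_end = live_end,
                                control_live_end = ctrl_live),
             run = run, extra_runs = list(control = run_control))
}

#' Singlet immune cell
#'
#' A half-couplet: singlet cells secrete an antibody-like Trefone against an
#' exogenous antigen supplied by constant inflow (no cell produces it).  The
#' perceived antibody deficiency (high antigen, low immune-complex readout)
#' drives proliferation; accumulated antibody then saturates the antigen
#' into complex, the complex readout goes Hi, and division ceases.
#'
#' @inheritParams scenario_balanced_perturbation
#' @param overrides named list: `steps`, `n_singlets`, `inflow` (mol/step),
#'   `kickstart` (mol of antigen at step 1), `ka` (set ~1 for the
#'   non-binding runaway control).
#' @return A `ctc_scenario_report`.
#' @export
scenario_singlet_immune <- function(overrides = list(), seed = 1,
                                    mirror = FALSE) {
  o <- utils::modifyList(list(steps = 55L, n_singlets = 5, inflow = 1.4e-16,
                              kickstart = 4e-16, ka = 1e10), overrides)
  # the singlet secretes the antibody into the i slot and senses the antigen
  # in the a slot; the mirror uses an A cell (secretes a, senses i) with the
  # couplet escape hatches disabled, i.e. a true half-couplet
  if (!mirror) {
    cell_type <- "SINGLET"
    antigen <- "a"
    table <- default_table()
  } else {
    cell_type <- "A"
    antigen <- "i"
    table <- default_table()
    starved <- table$rows$cell_type == "A" &
      table$rows$partner_level == "Lo" & table$rows$complex_level == "Lo"
    table$rows$prolonged_action[starved] <- "QSC"
    table$params$basal_ascd_prob <- 0
  }
  config <- sim_config(
    variant = "EC", binding = binding_system(ka = o$ka), table = table,
    rates = rate_config(),
    initial_cells = list(list(type = cell_type, n = o$n_singlets)),
    initial_pool = pool_state(volume = 1e-9, antigen_inflow_rate = o$inflow,
                              antigen_inflow_species = antigen),
    steps = o$steps, seed = seed,
    events = if (o$kickstart > 0)
      list(list(at_step = 1L, kind = "ANTIGEN_PULSE", species = antigen,
                amount = o$kickstart))
    else list())
  run <- ctc_run(config)
  ts <- run$timeseries
  th <- pool_thresholds(config)
  n_col <- paste0("n_", cell_type)
  scd_col <- paste0("act_", cell_type, "_SCD_SRE")
  tail_window <- ts$step > o$steps - 8L
  grewn <- max(ts[[n_col]]) > o$n_singlets
  plateau <- length(unique(ts[[n_col]][tail_window])) == 1L
  late_scd <- sum(ts[[scd_col]][tail_window])
  last <- ts[nrow(ts), ]
  cmplx_col <- if (antigen == "a") "pool_complex_ai" else "pool_complex_ai"
  complex_hi <- last[[cmplx_col]] >= th$complex_hi

  assertions <- rbind(
    assert_row("singlet population expands under antigen inflow",
               if (o$inflow > 0 || o$kickstart > 0) grewn else !grewn,
               sprintf("%s count: %d -> max %d", cell_type, o$n_singlets,
                       max(ts[[n_col]]))),
    assert_row("division ceases once the complex readout is Hi",
               if (o$ka >= 1e6) {
                 plateau && late_scd == 0 && complex_hi
               } else {
                 # runaway control: no complex brake, growth never stops
                 last[[n_col]] > ts[[n_col]][o$steps - 16L]
               },
               sprintf("late-window SCD decisions %d, final complex %.3g (Hi >= %.3g)",
                       late_scd, last[[cmplx_col]], th$complex_hi))
  )
  new_report("singlet_immune", seed, mirror, config, assertions,
             observables = list(max_count = max(ts[[n_col]]),
                                final_count = last[[n_col]],
                                final_complex = last[[cmplx_col]]),
             run = run)
}
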