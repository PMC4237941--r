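#' Simulation configuration
#'
#' Assembles and validates the full world description for [ctc_run()].
#'
#' @param variant `"EC"` (extracellular complex sensed by a scarce membrane
#'   receptor) or `"IC"` (complex formed intracellularly from hived-off self
#'   Trefone).
#' @param binding a [binding_system()].
#' @param rates a [rate_config()].
#' @param table a [default_table()]-shaped decision table.
#' @param initial_cells list of groups, each
#'   `list(type =, n =, life_state =)` (`life_state` optional, default
#'   `"CYCLING"`).
#' @param initial_pool a [pool_state()].
#' @param steps number of steps to simulate (>= 1).
#' @param seed integer RNG seed (mandatory: every run is reproducible).
#' @param events list of events, each
#'   `list(at_step =, kind =, species =, amount =, totals =)`; `kind` is one
#'   of `ADD_TREFONE`, `SINK_TREFONE` (amount = fraction of the species' pool
#'   total removed), `KILL_CYCLING` (kills every non-dormant live cell),
#'   `MEDIUM_REPLACE` (pool reset to `totals`, default the initial pool) and
#'   `ANTIGEN_PULSE` (exogenous addition of the `a` species).
#' @param max_cells hard safety cap on the population size.
#' @return An object of class `ctc_config`.
#' @export
sim_config <- function(variant = c("EC", "IC"), binding = binding_system(),
                       rates = rate_config(), table = default_table(),
                       initial_cells = list(list(type = "A", n = 10),
                                            list(type = "I", n = 10)),
                       initial_pool = pool_state(),
                       steps = 100L, seed = 1L, events = list(),
                       max_cells = 20000L) {
  variant <- match.arg(variant)
  config <- structure(
    list(variant = variant, binding = binding, rates = rates, table = table,
         initial_cells = initial_cells, initial_pool = initial_pool,
         steps = as.integer(steps), seed = as.integer(seed), events = events,
         max_cells = as.integer(max_cells)),
    class = "ctc_config"
  )
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop(paste(c("invalid configuration:", paste0("  - ", problems)),
               collapse = "\n"), call. = FALSE)
  }
  config
}

EVENT_KINDS <- c("ADD_TREFONE", "SINK_TREFONE", "KILL_CYCLING",
                 "MEDIUM_REPLACE", "ANTIGEN_PULSE")

#' Validate a simulation configuration
#'
#' @param config a `ctc_config` (or a bare list shaped like one).
#' @return Character vector of all violations found; empty if valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(txt) problems <<- c(problems, txt)
  if (!isTRUE(config$variant %in% c("EC", "IC"))) {
    note("variant: must be 'EC' or 'IC'")
  }
  if (!inherits(config$binding, "ctc_binding_system")) {
    note("binding: not a binding_system()")
  } else if (config$binding$ka_analog > config$binding$ka) {
    note("binding.ka_analog: analog must not bind more tightly than the couplet (ka_analog <= ka)")
  }
  if (!inherits(config$rates, "ctc_rates")) note("rates: not a rate_config()")
  if (!inherits(config$table, "ctc_decision_table")) {
    note("table: not a decision table")
  } else {
    tdiag <- validate_table(config$table)
    if (length(tdiag) > 0) {
      problems <- c(problems, paste0("table: ", tdiag))
    }
  }
  if (!is.numeric(config$steps) || config$steps < 1) {
    note("steps: must be >= 1")
  }
  if (is.null(config$seed) || is.na(config$seed)) {
    note("seed: mandatory")
  }
  for (k in seq_along(config$initial_cells)) {
    g <- config$initial_cells[[k]]
    if (!isTRUE(g$type %in% CELL_TYPES)) {
      note(sprintf("initial_cells[%d].type: unknown type", k))
    }
    if (!is.numeric(g$n) || g$n < 0) {
      note(sprintf("initial_cells[%d].n: must be >= 0", k))
    }
    if (!is.null(g$life_state) && !isTRUE(g$life_state %in% LIFE_STATES)) {
      note(sprintf("initial_cells[%d].life_state: unknown state", k))
    }
  }
  if (!inherits(config$initial_pool, "ctc_pool")) {
    note("initial_pool: not a pool_state()")
  }
  for (k in seq_along(config$events)) {
    ev <- config$events[[k]]
    if (!isTRUE(ev$kind %in% EVENT_KINDS)) {
      note(sprintf("events[%d].kind: unknown kind", k))
      next
    }
    if (!is.numeric(ev$at_step) || ev$at_step < 1 ||
        ev$at_step > config$steps) {
      note(sprintf("events[%d].at_step: outside [1, steps]", k))
    }
    if (ev$kind %in% c("ADD_TREFONE", "SINK_TREFONE")) {
      if (!isTRUE(ev$species %in% c("a", "i", "d"))) {
        note(sprintf("events[%d].species: must be 'a', 'i' or 'd'", k))
      }
      if (!is.numeric(ev$amount) || ev$amount < 0) {
        note(sprintf("events[%d].amount: must be >= 0", k))
      }
      if (ev$kind == "SINK_TREFONE" && isTRUE(ev$amount > 1)) {
        note(sprintf("events[%d].amount: sink fraction must lie in [0, 1]", k))
      }
    }
    if (ev$kind == "ANTIGEN_PULSE" &&
        (!is.numeric(ev$amount) || ev$amount < 0)) {
      note(sprintf("events[%d].amount: must be >= 0", k))
    }
  }
  problems
}

new_sim_state <- function(config) {
  cells <- list()
  id <- 0L
  for (g in config$initial_cells) {
    n <- as.integer(g$n)
    if (n <= 0) next
    ls <- g$life_state %||% "CYCLING"
    for (j in seq_len(n)) {
      id <- id + 1L
      cells[[id]] <- make_cell(g$type, config$variant, id = id,
                               life_state = ls,
                               tccr_count_scale = config$rates$tccr_count_scale)
    }
  }
  pool <- config$initial_pool
  ledger <- list(
    added = c(a = pool$total_a, i = pool$total_i, d = pool$total_analog),
    secreted = c(a = 0, i = 0, d = 0),
    degraded = c(a = 0, i = 0, d = 0)
  )
  list(step = 0L, cells = cells, next_id = id + 1L, pool = pool,
       ledger = ledger,
       tallies = matrix(0L, nrow = length(CELL_TYPES), ncol = length(ACTIONS),
                        dimnames = list(CELL_TYPES, ACTIONS)),
       rows = list())
}

ledger_check <- function(state, analog_bound = "i", tol = 1e-9) {
  for (sp in c("a", "i", "d")) {
    sources <- state$ledger$added[[sp]] + state$ledger$secreted[[sp]]
    pool_total <- switch(sp, a = state$pool$total_a, i = state$pool$total_i,
                         d = state$pool$total_analog)
    holdings <- pool_total +
      cells_species_total(state$cells, sp, analog_bound) +
      state$ledger$degraded[[sp]]
    if (abs(sources - holdings) > tol * max(sources, 1e-30)) {
      stop(sprintf(
        "mass ledger violated for species '%s' at step %d: sources %.12g != holdings %.12g",
        sp, state$step, sources, holdings), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# move a cell's internal stores to the degradation ledger (apoptosis / kill)
destroy_stores <- function(cell, ledger, analog_bound = "i") {
  for (sp in c("a", "i", "d")) {
    ledger$degraded[[sp]] <- ledger$degraded[[sp]] +
      cell_store_total(cell, sp, analog_bound)
  }
  for (f in c("store_a", "store_i", "store_d", "store_ai", "store_di",
              "hived_self")) {
    cell[[f]] <- 0
  }
  list(cell = cell, ledger = ledger)
}

apply_event <- function(state, ev, config) {
  ab <- analog_binds(config$binding)
  pool <- state$pool
  ledger <- state$ledger
  if (ev$kind == "ADD_TREFONE" || ev$kind == "ANTIGEN_PULSE") {
    sp <- if (ev$kind == "ANTIGEN_PULSE") ev$species %||% "a" else ev$species
    field <- switch(sp, a = "total_a", i = "total_i", d = "total_analog")
    pool[[field]] <- pool[[field]] + ev$amount
    ledger$added[[sp]] <- ledger$added[[sp]] + ev$amount
  } else if (ev$kind == "SINK_TREFONE") {
    field <- switch(ev$species, a = "total_a", i = "total_i",
                    d = "total_analog")
    removed <- pool[[field]] * ev$amount
    pool[[field]] <- pool[[field]] - removed
    ledger$degraded[[ev$species]] <- ledger$degraded[[ev$species]] + removed
  } else if (ev$kind == "KILL_CYCLING") {
    for (k in seq_along(state$cells)) {
      cell <- state$cells[[k]]
      if (cell$life_state %in% c("DEAD", "DORMANT")) next
      cell$life_state <- "DEAD"
      out <- destroy_stores(cell, ledger, ab)
      ledger <- out$ledger
      state$cells[[k]] <- out$cell
    }
  } else if (ev$kind == "MEDIUM_REPLACE") {
    # old medium discarded (ledgered as degraded), fresh medium added
    for (sp in c("a", "i", "d")) {
      field <- switch(sp, a = "total_a", i = "total_i", d = "total_analog")
      ledger$degraded[[sp]] <- ledger$degraded[[sp]] + pool[[field]]
    }
    totals <- ev$totals %||% list(total_a = config$initial_pool$total_a,
                                  total_i = config$initial_pool$total_i,
                                  total_analog = config$initial_pool$total_analog)
    pool$total_a <- totals$total_a %||% 0
    pool$total_i <- totals$total_i %||% 0
    pool$total_analog <- totals$total_analog %||% 0
    ledger$added[["a"]] <- ledger$added[["a"]] + pool$total_a
    ledger$added[["i"]] <- ledger$added[["i"]] + pool$total_i
    ledger$added[["d"]] <- ledger$added[["d"]] + pool$total_analog
  }
  state$pool <- pool
  state$ledger <- ledger
  state
}

record_row <- function(state, config, eq, step_tallies, secreted_step) {
  counts <- table(factor(vapply(state$cells, `[[`, "", "cell_type"),
                         levels = CELL_TYPES))
  live <- vapply(state$cells, `[[`, "", "life_state")
  alive <- live != "DEAD"
  live_counts <- table(factor(vapply(state$cells[alive], `[[`, "",
                                     "cell_type"), levels = CELL_TYPES))
  states <- table(factor(live, levels = LIFE_STATES))
  row <- c(
    list(step = state$step),
    as.list(stats::setNames(as.integer(live_counts),
                            paste0("n_", CELL_TYPES))),
    as.list(stats::setNames(as.integer(states),
                            paste0("n_", LIFE_STATES))),
    list(
      pool_free_a = eq$free_a, pool_free_i = eq$free_i,
      pool_free_d = eq$free_analog,
      pool_complex_ai = eq$complex_ai, pool_complex_di = eq$complex_di,
      total_a = state$pool$total_a, total_i = state$pool$total_i,
      total_d = state$pool$total_analog,
      secreted_a = secreted_step[["a"]], secreted_i = secreted_step[["i"]],
      degraded_a = state$ledger$degraded[["a"]],
      degraded_i = state$ledger$degraded[["i"]],
      degraded_d = state$ledger$degraded[["d"]]
    )
  )
  for (ty in c("A", "I", "SINGLET", "O")) {
    for (ac in ACTIONS) {
      row[[paste0("act_", ty, "_", ac)]] <- step_tallies[ty, ac]
    }
  }
  state$rows[[length(state$rows) + 1L]] <- row
  state
}

#' Advance the world by one step
#'
#' Phase order is fixed: secrete -> degrade (pool, then internal store
#' turnover) -> equilibrate pool -> uptake (cells in id order) -> readouts ->
#' decisions (same pool snapshot for every cell) -> divisions -> due events
#' -> ledger check -> record one trajectory row.
#'
#' @param state engine state as produced by `ctc_run`'s initializer or a
#'   previous `ctc_step`.
#' @param config a [sim_config()].
#' @return The advanced state.
#' @export
ctc_step <- function(state, config) {
  state$step <- state$step + 1L
  rates <- config$rates
  system <- config$binding
  table <- config$table

  # --- secretion -----------------------------------------------------------
  out <- secrete(state$cells, state$pool, rates, config$variant)
  state$cells <- out$cells
  state$pool <- out$pool
  state$ledger$secreted <- state$ledger$secreted + out$secreted
  secreted_step <- out$secreted

  # exogenous antigen inflow (no cell produces the antigen species)
  if (state$pool$antigen_inflow_rate > 0) {
    sp <- state$pool$antigen_inflow_species %||% "a"
    field <- if (sp == "a") "total_a" else "total_i"
    state$pool[[field]] <- state$pool[[field]] +
      state$pool$antigen_inflow_rate
    state$ledger$added[[sp]] <- state$ledger$added[[sp]] +
      state$pool$antigen_inflow_rate
  }

  # --- degradation (pool + internal turnover) ------------------------------
  out <- degrade(state$pool, rates)
  state$pool <- out$pool
  state$ledger$degraded <- state$ledger$degraded + out$removed
  for (k in seq_along(state$cells)) {
    if (state$cells[[k]]$life_state == "DEAD") next
    dec <- decay_stores(state$cells[[k]], rates$store_decay_rate,
                        analog_binds(system))
    state$cells[[k]] <- dec$cell
    state$ledger$degraded <- state$ledger$degraded + dec$removed
  }

  # --- pool equilibrium + uptake in id order -------------------------------
  eq <- pool_equilibrium(state$pool, system)
  ord <- order(vapply(state$cells, `[[`, 0L, "id"))
  remaining <- NULL
  for (k in ord) {
    out <- uptake(state$cells[[k]], state$pool, rates, eq = eq,
                  remaining = remaining)
    state$cells[[k]] <- out$cell
    state$pool <- out$pool
    remaining <- out$remaining
  }

  # --- readouts + decisions (synchronous) ----------------------------------
  step_tallies <- matrix(0L, nrow = length(CELL_TYPES),
                         ncol = length(ACTIONS),
                         dimnames = list(CELL_TYPES, ACTIONS))
  actions <- character(length(state$cells))
  for (k in ord) {
    cell <- state$cells[[k]]
    if (cell$life_state == "DEAD") {
      actions[k] <- NA_character_
      next
    }
    readout <- intracellular_readout(cell, system, config$variant, rates)
    levels <- discretize_readout(readout, table)
    dec <- decide(cell, levels[["partner"]], levels[["complex"]], table,
                  complex_conc = readout[["complex"]])
    state$cells[[k]] <- dec$cell
    actions[k] <- dec$action
    step_tallies[cell$cell_type, dec$action] <-
      step_tallies[cell$cell_type, dec$action] + 1L
  }

  # --- apply actions / divisions -------------------------------------------
  new_cells <- list()
  for (k in seq_along(state$cells)) {
    cell <- state$cells[[k]]
    act <- actions[k]
    if (is.na(act)) {                      # dead: kept for the record
      new_cells[[length(new_cells) + 1L]] <- cell
      next
    }
    if (act == "QSC") {
      starved <- cell$dwell_starved > 0L
      cell$secretion_mult <- if (starved) rates$starved_secretion_factor else 1
      if (cell$life_state != "DORMANT") cell$life_state <- "QUIESCENT"
      new_cells[[length(new_cells) + 1L]] <- cell
    } else if (act == "BOOST_SECRETION") {
      cell$secretion_mult <- 1 + rates$boost_factor
      cell$life_state <- "CYCLING"
      new_cells[[length(new_cells) + 1L]] <- cell
    } else if (act == "APO") {
      cell$life_state <- "DEAD"
      out <- destroy_stores(cell, state$ledger, analog_binds(system))
      state$ledger <- out$ledger
      new_cells[[length(new_cells) + 1L]] <- out$cell
    } else if (act == "DEDIFF") {
      new_cells[[length(new_cells) + 1L]] <-
        apply_dedifferentiation(cell, check_dwell = FALSE)
    } else {                               # a division from the catalogue
      cell$life_state <- "CYCLING"
      kids <- divide(cell, act, next_id = state$next_id)
      state$next_id <- state$next_id + length(kids)
      for (kid in kids) new_cells[[length(new_cells) + 1L]] <- kid
    }
  }
  state$cells <- new_cells
  state$tallies <- state$tallies + step_tallies
  if (sum(vapply(state$cells, function(c) c$life_state != "DEAD", TRUE)) >
      config$max_cells) {
    stop(sprintf("population exceeded max_cells (%d) at step %d",
                 config$max_cells, state$step), call. = FALSE)
  }

  # --- due events ------------------------------------------------------------
  for (ev in config$events) {
    if (isTRUE(ev$at_step == state$step)) {
      state <- apply_event(state, ev, config)
    }
  }

  ledger_check(state, analog_binds(system))
  eq_now <- pool_equilibrium(state$pool, system)
  record_row(state, config, eq_now, step_tallies, secreted_step)
}

#' Run a simulation
#'
#' Seeds the RNG once from `config$seed`, builds the initial state and
#' applies [ctc_step()] `config$steps` times.  Identical configurations give
#' byte-identical trajectories.
#'
#' @param config a [sim_config()].
#' @return An object of class `ctc_run`: `$timeseries` (one data.frame row
#'   per step), `$final` (the full final state, including every cell),
#'   `$tallies` (cumulative action counts by cell type) and `$config`.
#' @export
ctc_run <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop(paste(c("invalid configuration:", paste0("  - ", problems)),
               collapse = "\n"), call. = FALSE)
  }
  set.seed(config$seed)
  state <- new_sim_state(config)
  for (s in seq_len(config$steps)) {
    state <- ctc_step(state, config)
  }
  ts <- do.call(rbind, lapply(state$rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  structure(
    list(timeseries = ts, final = state, tallies = state$tallies,
         config = config),
    class = "ctc_run"
  )
}

#' @export
print.ctc_run <- function(x, ...) {
  last <- x$timeseries[nrow(x$timeseries), ]
  cat(sprintf("<ctc_run: %d steps, %d cells live at end (A=%d I=%d O=%d S=%d)>\n",
              nrow(x$timeseries),
              last$n_CYCLING + last$n_QUIESCENT + last$n_DORMANT,
              last$n_A, last$n_I, last$n_O, last$n_SINGLET))
  invisible(x)
}

# live (non-dead) cells of a run's final state
live_cells <- function(state) {
  Filter(function(c) c$life_state != "DEAD", state$cells)
}
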