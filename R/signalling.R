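#' Extracellular pool state
#'
#' One well-mixed extracellular compartment.  State is kept as *total*
#' amounts (mol) per species; free and bound concentrations are derived on
#' demand with [pool_equilibrium()] under the instantaneous-equilibrium
#' approximation (only the association constant is specified by the model;
#' on/off kinetics are below its resolution).
#'
#' @param volume compartment volume, L.
#' @param total_a,total_i,total_analog total amounts, mol.
#' @param antigen_inflow_rate exogenous inflow of the antigen species,
#'   mol/step (used by the singlet immune scenario, where no cell produces
#'   the antigen).
#' @param antigen_inflow_species which species the inflow supplies (`"a"` by
#'   default; `"i"` in the mirrored singlet configuration).
#' @return An object of class `ctc_pool`.
#' @export
pool_state <- function(volume = 1e-9, total_a = 0, total_i = 0,
                       total_analog = 0, antigen_inflow_rate = 0,
                       antigen_inflow_species = c("a", "i")) {
  antigen_inflow_species <- match.arg(antigen_inflow_species)
  if (!is.numeric(volume) || volume <= 0) {
    stop("'volume' must be positive", call. = FALSE)
  }
  check_nonneg(total_a, "total_a")
  check_nonneg(total_i, "total_i")
  check_nonneg(total_analog, "total_analog")
  check_nonneg(antigen_inflow_rate, "antigen_inflow_rate")
  structure(
    list(volume = volume, total_a = total_a, total_i = total_i,
         total_analog = total_analog,
         antigen_inflow_rate = antigen_inflow_rate,
         antigen_inflow_species = antigen_inflow_species),
    class = "ctc_pool"
  )
}

#' Equilibrium composition of the pool
#'
#' @param pool a [pool_state()].
#' @param system a [binding_system()].
#' @return A `ctc_equilibrium` in concentrations (mol/L).
#' @export
pool_equilibrium <- function(pool, system) {
  eq <- equilibrate_with_analog(pool$total_a / pool$volume,
                                pool$total_i / pool$volume,
                                pool$total_analog / pool$volume,
                                system)
  attr(eq, "analog_mimics") <- system$analog_mimics
  eq
}

#' Per-step rate configuration
#'
#' @param secretion_rate Trefone synthesis per live, non-dormant secreting
#'   cell, mol/step.
#' @param boost_factor relative secretion increase while a cell is in the
#'   boosted metabolic state (action `BOOST_SECRETION`), dimensionless >= 0.
#' @param uptake_rate per-step fractional clearance of the free partner
#'   Trefone by one cell's receptors, in `[0, 1]`.
#' @param tccr_count_scale default scarcity factor of the complex receptor;
#'   multiplies `uptake_rate` for complex internalization.
#' @param degradation_rate first-order per-step loss from the pool, `[0, 1]`
#'   (species-uniform; complex degrades at the same rate).
#' @param store_decay_rate first-order per-step consumption of internalized
#'   stores (signal turnover inside the cell), `[0, 1]`.
#' @param hived_fraction IC variant only: fraction of each cell's synthesis
#'   diverted to its intracellular `hived_self` store instead of the pool.
#' @param endosome_volume volume of the common intracellular compartment in
#'   which internalized species re-equilibrate, L.
#' @param starved_secretion_factor secretion multiplier while a cell sits in
#'   the starved (Lo partner, Lo complex) readout class.
#' @return An object of class `ctc_rates`.
#' @export
rate_config <- function(secretion_rate = 1e-18, boost_factor = 0.2,
                        uptake_rate = 0.005, tccr_count_scale = 0.05,
                        degradation_rate = 0.35, store_decay_rate = 0.5,
                        hived_fraction = 0.2, endosome_volume = 1e-13,
                        starved_secretion_factor = 0.8) {
  check_nonneg(secretion_rate, "secretion_rate")
  check_nonneg(boost_factor, "boost_factor")
  in_unit <- function(x, name) {
    check_nonneg(x, name)
    if (x > 1) stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  in_unit(uptake_rate, "uptake_rate")
  in_unit(tccr_count_scale, "tccr_count_scale")
  in_unit(degradation_rate, "degradation_rate")
  in_unit(store_decay_rate, "store_decay_rate")
  in_unit(hived_fraction, "hived_fraction")
  in_unit(starved_secretion_factor, "starved_secretion_factor")
  if (endosome_volume <= 0) {
    stop("'endosome_volume' must be positive", call. = FALSE)
  }
  structure(
    list(secretion_rate = secretion_rate, boost_factor = boost_factor,
         uptake_rate = uptake_rate, tccr_count_scale = tccr_count_scale,
         degradation_rate = degradation_rate,
         store_decay_rate = store_decay_rate,
         hived_fraction = hived_fraction,
         endosome_volume = endosome_volume,
         starved_secretion_factor = starved_secretion_factor),
    class = "ctc_rates"
  )
}

#' Secretion phase
#'
#' Every live, non-dormant `A` cell adds `secretion_rate * secretion_mult`
#' of the `a` species; `I` and `SINGLET` cells likewise add the `i` species;
#' `O` cells secrete neither.  In the IC variant, `hived_fraction` of each
#' cell's synthesis is diverted to its own `hived_self` store instead of the
#' pool.
#'
#' @param cells list of `ctc_cell`.
#' @param pool a [pool_state()].
#' @param config a [rate_config()].
#' @param variant `"EC"` or `"IC"`.
#' @return `list(cells, pool, secreted)` where `secreted` is the named
#'   per-species amount added this step (pool + hived, i.e. total synthesis).
#' @export
secrete <- function(cells, pool, config, variant = "EC") {
  secreted <- c(a = 0, i = 0, d = 0)
  hive <- if (identical(variant, "IC")) config$hived_fraction else 0
  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    if (cell$life_state %in% c("DEAD", "DORMANT")) next
    sp <- self_species(cell$cell_type)
    if (is.na(sp)) next
    amount <- config$secretion_rate * cell$secretion_mult
    if (amount == 0) next
    to_pool <- amount * (1 - hive)
    field <- paste0("total_", sp)
    pool[[field]] <- pool[[field]] + to_pool
    if (hive > 0) {
      cells[[k]]$hived_self <- cell$hived_self + amount * hive
    }
    secreted[[sp]] <- secreted[[sp]] + amount
  }
  list(cells = cells, pool = pool, secreted = secreted)
}

#' Receptor-mediated uptake for one cell
#'
#' Transfers mass from the pool to the cell's internal stores: a fraction
#' `uptake_rate` of the free partner-Trefone amount for each partner
#' receptor the cell carries (an `A` cell internalizes free `i` but never
#' free `a`; receptors for the `a` species also bind the analog), and
#' `uptake_rate * tccR_count_scale` of each complex amount if the cell has
#' the scarce complex receptor.  Draws are computed from the supplied
#' equilibrium snapshot (all cells see the same pre-uptake pool) and clipped
#' against `remaining` so sequential uptake never drives the pool negative.
#'
#' @param cell a `ctc_cell`.
#' @param pool a [pool_state()].
#' @param config a [rate_config()].
#' @param eq equilibrium snapshot from [pool_equilibrium()]; computed from
#'   `pool` if missing.
#' @param system a [binding_system()] (only needed when `eq` is missing).
#' @param remaining optional named amounts (mol) still available this step
#'   for `free_a`, `free_i`, `free_d`, `complex_ai`, `complex_di`.
#' @return `list(cell, pool, remaining)`.
#' @export
uptake <- function(cell, pool, config, eq = NULL, system = NULL,
                   remaining = NULL) {
  stopifnot(inherits(cell, "ctc_cell"))
  if (is.null(eq)) eq <- pool_equilibrium(pool, system)
  v <- pool$volume
  if (is.null(remaining)) {
    remaining <- c(free_a = eq$free_a * v, free_i = eq$free_i * v,
                   free_d = eq$free_analog * v,
                   complex_ai = eq$complex_ai * v,
                   complex_di = eq$complex_di * v)
  }
  if (cell$life_state == "DEAD") {
    # dormant cells keep functional receptors (they must be able to sense a
    # reawakening partner signal); only dead cells are excluded
    return(list(cell = cell, pool = pool, remaining = remaining))
  }
  u <- config$uptake_rate
  draw <- function(key, want) min(want, remaining[[key]])
  mimics <- attr(eq, "analog_mimics") %||% "a"

  took <- c(free_a = 0, free_i = 0, free_d = 0, complex_ai = 0,
            complex_di = 0)
  if (cell$receptors$has_iR) {
    took[["free_i"]] <- draw("free_i", u * eq$free_i * v)
    if (identical(mimics, "i")) {
      took[["free_d"]] <- draw("free_d", u * eq$free_analog * v)
    }
  }
  if (cell$receptors$has_aR) {
    took[["free_a"]] <- draw("free_a", u * eq$free_a * v)
    if (identical(mimics, "a")) {
      took[["free_d"]] <- draw("free_d", u * eq$free_analog * v)
    }
  }
  if (cell$receptors$has_tccR) {
    s <- u * cell$receptors$tccR_count_scale
    took[["complex_ai"]] <- draw("complex_ai", s * eq$complex_ai * v)
    took[["complex_di"]] <- draw("complex_di", s * eq$complex_di * v)
  }
  cell$store_a  <- cell$store_a  + took[["free_a"]]
  cell$store_i  <- cell$store_i  + took[["free_i"]]
  cell$store_d  <- cell$store_d  + took[["free_d"]]
  cell$store_ai <- cell$store_ai + took[["complex_ai"]]
  cell$store_di <- cell$store_di + took[["complex_di"]]
  di_from_a <- if (identical(mimics, "i")) took[["complex_di"]] else 0
  di_from_i <- if (identical(mimics, "a")) took[["complex_di"]] else 0
  pool$total_a <- max(0, pool$total_a - took[["free_a"]] -
                        took[["complex_ai"]] - di_from_a)
  pool$total_i <- max(0, pool$total_i - took[["free_i"]] -
                        took[["complex_ai"]] - di_from_i)
  pool$total_analog <- max(0, pool$total_analog - took[["free_d"]] -
                             took[["complex_di"]])
  remaining <- remaining - took
  list(cell = cell, pool = pool, remaining = remaining)
}

#' Intracellular readout of a cell
#'
#' Converts a cell's internal stores into the `(partner, complex)`
#' concentration pair on which fate decisions are based.
#'
#' EC variant: internalized species re-equilibrate in the endosome volume.
#' The totals offered to the solver are `a = store_a + store_ai`,
#' `i = store_i + store_ai + store_di`, `analog = store_d + store_di`; the
#' readout is (free partner + free analog, total complex) as concentrations.
#' The analog contributes to the perceived partner signal (it activates the
#' same receptor) and to complex with its own weak constant, so an analog
#' with `ka_analog = ka` is indistinguishable from the genuine Trefone.
#'
#' IC variant: the hived-off self store equilibrates with the internalized
#' partner Trefone (plus analog) in the same compartment; no complex was
#' internalized by receptor.
#'
#' `O` cells sense both species: the partner channel is the sum of both free
#' Trefones.
#'
#' @param cell a `ctc_cell`.
#' @param system a [binding_system()].
#' @param variant `"EC"` or `"IC"`.
#' @param config a [rate_config()] (supplies `endosome_volume`).
#' @return Named numeric `c(partner = , complex = )`, mol/L.
#' @export
intracellular_readout <- function(cell, system, variant = cell$variant,
                                  config = rate_config()) {
  stopifnot(inherits(cell, "ctc_cell"))
  v <- config$endosome_volume
  if (is.null(v) || v <= 0) {
    stop("configuration error: 'endosome_volume' must be positive",
         call. = FALSE)
  }
  if (identical(variant, "IC")) {
    # hived-off self Trefone meets the internalized partner Trefone (and any
    # analog) in the common compartment; no complex was internalized
    sp <- self_species(cell$cell_type)
    tot_a <- cell$store_a + (if (identical(sp, "a")) cell$hived_self else 0)
    tot_i <- cell$store_i + (if (identical(sp, "i")) cell$hived_self else 0)
    eq <- equilibrate_with_analog(tot_a / v, tot_i / v, cell$store_d / v,
                                  system)
    cmplx <- eq$complex_ai + eq$complex_di
    fd_as_a <- if (system$analog_mimics == "a") eq$free_analog else 0
    fd_as_i <- if (system$analog_mimics == "i") eq$free_analog else 0
    partner <- switch(cell$cell_type,
      A = eq$free_i + fd_as_i,
      I = eq$free_a + fd_as_a,
      SINGLET = eq$free_a + fd_as_a,
      O = eq$free_a + eq$free_i + eq$free_analog
    )
    return(c(partner = partner, complex = cmplx))
  }
  bound <- analog_binds(system)
  tot_a <- cell$store_a + cell$store_ai +
    (if (bound == "a") cell$store_di else 0)
  tot_i <- cell$store_i + cell$store_ai +
    (if (bound == "i") cell$store_di else 0)
  tot_d <- cell$store_d + cell$store_di
  eq <- equilibrate_with_analog(tot_a / v, tot_i / v, tot_d / v, system)
  cmplx <- eq$complex_ai + eq$complex_di
  fd_as_a <- if (system$analog_mimics == "a") eq$free_analog else 0
  fd_as_i <- if (system$analog_mimics == "i") eq$free_analog else 0
  partner <- switch(cell$cell_type,
    A = eq$free_i + fd_as_i,
    I = eq$free_a + fd_as_a,
    SINGLET = eq$free_a + fd_as_a,
    O = eq$free_a + eq$free_i + eq$free_analog
  )
  c(partner = partner, complex = cmplx)
}

#' Degradation phase
#'
#' First-order, species-uniform clearance of the pool: every total is
#' multiplied by `1 - degradation_rate`.
#'
#' @param pool a [pool_state()].
#' @param config a [rate_config()].
#' @return `list(pool, removed)` with `removed` the named per-species amounts
#'   cleared (for the degradation ledger).
#' @export
degrade <- function(pool, config) {
  d <- config$degradation_rate
  removed <- c(a = pool$total_a * d, i = pool$total_i * d,
               d = pool$total_analog * d)
  pool$total_a <- pool$total_a - removed[["a"]]
  pool$total_i <- pool$total_i - removed[["i"]]
  pool$total_analog <- pool$total_analog - removed[["d"]]
  list(pool = pool, removed = removed)
}

# Internal: first-order turnover of a cell's internalized stores.  Consumed
# signal mass is ledgered as degraded, keeping the global ledger closed.
decay_stores <- function(cell, rate, analog_bound = "i") {
  removed <- c(a = 0, i = 0, d = 0)
  if (rate <= 0) return(list(cell = cell, removed = removed))
  sp <- self_species(cell$cell_type)
  di_species <- c("d", analog_bound)
  for (f in c("store_a", "store_i", "store_d", "store_ai", "store_di",
              "hived_self")) {
    loss <- cell[[f]] * rate
    cell[[f]] <- cell[[f]] - loss
    add <- c(a = 0, i = 0, d = 0)
    add[switch(f,
               store_a = "a", store_i = "i", store_d = "d",
               store_ai = c("a", "i"), store_di = di_species,
               hived_self = if (identical(sp, "a")) "a" else "i")] <- loss
    removed <- removed + add
  }
  list(cell = cell, removed = removed)
}

# Internal: total per-species content of a list of cells (for the ledger).
cells_species_total <- function(cells, species, analog_bound = "i") {
  if (length(cells) == 0L) return(0)
  sum(vapply(cells, cell_store_total, numeric(1), species = species,
             analog_bound = analog_bound))
}
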