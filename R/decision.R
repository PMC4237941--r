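#' Default fate-decision table
#'
#' The decision table maps each cell's discretized intracellular readout
#' (`partner` level, `complex` level, each Lo/Mid/Hi) and its dwell history
#' to a catalogue action.  The default encodes the couplet homeostat:
#'
#' * **Hi partner, Lo/Mid complex** (the partner family is in excess):
#'   immediately boost metabolism/secretion; if the stimulus persists for
#'   `dwell_required` consecutive steps, divide symmetrically (`SCD_SRE`) to
#'   expand the responding family.
#' * **Lo partner, Lo complex** (starvation: the partner family is deficient
#'   or absent): quiesce with damped secretion; at `dwell_required`
#'   consecutive starved steps divide asymmetrically into self + partner
#'   (`ASCD_SELF_PARTNER`); at `escalation_mult * dwell_required` produce two
#'   partner-type cells (`ASCD_PARTNER_PARTNER`); from
#'   `dediff_mult * dwell_required` steps onward, dedifferentiate back to the
#'   lineage progenitor (`DEDIFF`).  A division trigger and the
#'   dedifferentiation threshold landing on the same step resolve in favour
#'   of division (dedifferentiation is the last resort).
#' * **any partner, Hi complex** (both families abundant): quiesce — high
#'   complex inhibits growth.  With `apo_enabled`, a cell whose complex
#'   readout exceeds `apo_factor * theta_hi_complex` while the partner
#'   channel is Hi undergoes apoptosis.
#' * **Mid, Mid**: quiescence with a per-step `basal_ascd_prob` chance of
#'   basal asymmetric division (`ASCD_SELF_PARTNER`) — there will always be
#'   some of both types present because of basal AsCD.
#' * **O cells**: dual lineage commitment (`ASCD_DUAL_LCDF`) as soon as any
#'   Trefone signal is present (dwell 1), else quiescence.
#' * **SINGLET cells**: like `I` cells for the stimulatory and inhibitory
#'   rows, but starvation never triggers asymmetric division or
#'   dedifferentiation (there is no partner cell type to produce).
#'
#' Thresholds default to multiples of `1/ka` scaled by the endosome/pool
#' geometry of the default [rate_config()]; see the package vignette for the
#' derivation.
#'
#' @param theta_lo_partner,theta_hi_partner partner-channel bin edges, mol/L.
#' @param theta_lo_complex,theta_hi_complex complex-channel bin edges, mol/L.
#' @param dwell_required consecutive steps of a stimulatory (or starved)
#'   readout before the prolonged action fires.
#' @param escalation_mult,dediff_mult multiples of `dwell_required` at which
#'   starvation escalates (see above).
#' @param basal_ascd_prob per-step probability of basal asymmetric division
#'   in the (Mid, Mid) homeostasis row.
#' @param apo_enabled,apo_factor apoptosis at extreme complex: enabled flag
#'   and multiple of `theta_hi_complex` defining "extreme".
#' @return An object of class `ctc_decision_table`: `$rows` (one row per
#'   `(cell_type, partner_level, complex_level)` key with immediate action,
#'   prolonged action and dwell requirement) and `$params`.
#' @export
default_table <- function(theta_lo_partner = 4e-7, theta_hi_partner = 1e-6,
                          theta_lo_complex = 1.8e-7, theta_hi_complex = 4.5e-7,
                          dwell_required = 8L, escalation_mult = 3L,
                          dediff_mult = 10L, basal_ascd_prob = 0.01,
                          apo_enabled = TRUE, apo_factor = 10) {
  lv <- c("Lo", "Mid", "Hi")
  grid <- expand.grid(cell_type = c("A", "I", "SINGLET", "O"),
                      partner_level = lv, complex_level = lv,
                      stringsAsFactors = FALSE)
  row_for <- function(type, p, cx) {
    if (type == "O") {
      if (p == "Lo" && cx == "Lo") {
        return(c("QSC", "QSC", 1L))
      }
      return(c("QSC", "ASCD_DUAL_LCDF", 1L))
    }
    if (cx == "Hi") return(c("QSC", "QSC", dwell_required))
    if (p == "Hi") {
      return(c("BOOST_SECRETION", "SCD_SRE", dwell_required))
    }
    if (p == "Lo" && cx == "Lo") {
      if (type == "SINGLET") return(c("QSC", "QSC", dwell_required))
      return(c("QSC", "ASCD_SELF_PARTNER", dwell_required))
    }
    c("QSC", "QSC", dwell_required)
  }
  acts <- t(mapply(row_for, grid$cell_type, grid$partner_level,
                   grid$complex_level))
  rows <- data.frame(
    cell_type = grid$cell_type,
    partner_level = grid$partner_level,
    complex_level = grid$complex_level,
    immediate_action = acts[, 1],
    prolonged_action = acts[, 2],
    dwell_required = as.integer(acts[, 3]),
    stringsAsFactors = FALSE
  )
  structure(
    list(rows = rows,
         params = list(
           theta_lo_partner = theta_lo_partner,
           theta_hi_partner = theta_hi_partner,
           theta_lo_complex = theta_lo_complex,
           theta_hi_complex = theta_hi_complex,
           dwell_required = as.integer(dwell_required),
           escalation_mult = as.integer(escalation_mult),
           dediff_mult = as.integer(dediff_mult),
           basal_ascd_prob = basal_ascd_prob,
           apo_enabled = isTRUE(apo_enabled),
           apo_factor = apo_factor)),
    class = "ctc_decision_table"
  )
}

table_row <- function(table, cell_type, partner_level, complex_level) {
  rows <- table$rows
  hit <- rows$cell_type == cell_type &
    rows$partner_level == partner_level &
    rows$complex_level == complex_level
  if (!any(hit)) {
    stop(sprintf(
      "configuration error: decision table has no row for (%s, %s, %s)",
      cell_type, partner_level, complex_level), call. = FALSE)
  }
  rows[which(hit)[1L], ]
}

#' Discretize both readout channels of a cell
#'
#' @param readout named numeric from [intracellular_readout()].
#' @param table a decision table (supplies the channel thresholds).
#' @return Named character `c(partner = , complex = )`.
#' @export
discretize_readout <- function(readout, table) {
  p <- table$params
  c(partner = discretize_level(readout[["partner"]],
                               p$theta_lo_partner, p$theta_hi_partner),
    complex = discretize_level(readout[["complex"]],
                               p$theta_lo_complex, p$theta_hi_complex))
}

#' Decide one cell's action from its discretized readout
#'
#' Updates the cell's dwell counters and returns the action the table
#' prescribes.  Dwell semantics: `dwell_hi` counts consecutive steps with a
#' Hi partner readout, `dwell_starved` consecutive (Lo, Lo) steps; entering
#' any other class resets both.  A stimulatory division (`SCD_SRE`) fires
#' when `dwell_hi >= dwell_required` and then resets the counter, so a
#' sustained stimulus produces one division per dwell window.  Starved
#' escalation fires at exact dwell marks (`dwell_required`,
#' `escalation_mult * dwell_required`) and `DEDIFF` at
#' `dediff_mult * dwell_required` or beyond.  Basal asymmetric division is
#' sampled from the current RNG stream only in the (Mid, Mid) row.  `DORMANT`
#' cells return `QSC` unless the partner channel is Hi, which reawakens them.
#'
#' @param cell a live `ctc_cell`.
#' @param partner_level,complex_level `"Lo"`, `"Mid"` or `"Hi"`.
#' @param table a [default_table()]-shaped decision table.
#' @param complex_conc raw complex readout, mol/L; needed only for the
#'   extreme-complex apoptosis trigger (skipped when `NULL`).
#' @return `list(cell = <updated cell>, action = <action name>)`.
#' @export
decide <- function(cell, partner_level, complex_level, table,
                   complex_conc = NULL) {
  stopifnot(inherits(cell, "ctc_cell"))
  if (cell$life_state == "DEAD") {
    stop("decide: cell is DEAD", call. = FALSE)
  }
  p <- table$params
  if (cell$life_state == "DORMANT") {
    if (partner_level != "Hi") {
      return(list(cell = cell, action = "QSC"))
    }
    cell$life_state <- "CYCLING"   # reawakening
  }
  row <- table_row(table, cell$cell_type, partner_level, complex_level)

  starved <- partner_level == "Lo" && complex_level == "Lo"
  # any Trefone signal at all is stimulatory for the uncommitted progenitor
  stim <- if (cell$cell_type == "O") !starved else partner_level == "Hi"
  cell$dwell_hi <- if (stim) cell$dwell_hi + 1L else 0L
  cell$dwell_starved <- if (starved) cell$dwell_starved + 1L else 0L

  # extreme complex + Hi partner: apoptosis (configurable)
  if (!is.null(complex_conc) && p$apo_enabled && stim &&
      complex_conc >= p$apo_factor * p$theta_hi_complex) {
    return(list(cell = cell, action = "APO"))
  }

  action <- row$immediate_action
  if (starved && row$prolonged_action %in% DIVISION_ACTIONS) {
    base <- row$dwell_required
    if (cell$dwell_starved >= p$dediff_mult * base &&
        cell$dwell_starved != p$escalation_mult * base) {
      action <- "DEDIFF"
    } else if (cell$dwell_starved == p$escalation_mult * base) {
      action <- "ASCD_PARTNER_PARTNER"
    } else if (cell$dwell_starved == base) {
      action <- row$prolonged_action
    }
  } else if (row$prolonged_action != row$immediate_action) {
    dwell <- if (stim) cell$dwell_hi else if (starved) cell$dwell_starved
             else max(cell$dwell_hi, cell$dwell_starved)
    if (dwell >= row$dwell_required) {
      action <- row$prolonged_action
      if (row$prolonged_action %in% DIVISION_ACTIONS) {
        if (stim) cell$dwell_hi <- 0L
        if (starved) cell$dwell_starved <- 0L
      }
    }
  }

  # basal asymmetric division keeps a trickle of both types in the
  # homeostatic (Mid, Mid) row only
  if (action == "QSC" && partner_level == "Mid" && complex_level == "Mid" &&
      cell$cell_type %in% c("A", "I") && p$basal_ascd_prob > 0) {
    if (stats::runif(1) < p$basal_ascd_prob) {
      action <- "ASCD_SELF_PARTNER"
    }
  }
  list(cell = cell, action = action)
}

#' Validate a decision table
#'
#' @param table a decision table.
#' @return A character vector of diagnostics; empty iff the table is
#'   well-formed (total over all keys, no duplicate/unreachable rows, no
#'   division action with a zero dwell requirement, probabilities in range).
#' @export
validate_table <- function(table) {
  diags <- character(0)
  lv <- c("Lo", "Mid", "Hi")
  need <- expand.grid(cell_type = c("A", "I", "SINGLET", "O"),
                      partner_level = lv, complex_level = lv,
                      stringsAsFactors = FALSE)
  keys <- function(df) paste(df$cell_type, df$partner_level, df$complex_level)
  have <- keys(table$rows)
  missing <- setdiff(keys(need), have)
  if (length(missing) > 0) {
    diags <- c(diags, sprintf("missing key: (%s)", missing))
  }
  dup <- have[duplicated(have)]
  if (length(dup) > 0) {
    diags <- c(diags, sprintf("unreachable duplicate row: (%s)", unique(dup)))
  }
  bad_dwell <- table$rows$prolonged_action %in% DIVISION_ACTIONS &
    table$rows$dwell_required < 1L
  if (any(bad_dwell)) {
    diags <- c(diags, sprintf(
      "division action %s at (%s) has dwell_required < 1",
      table$rows$prolonged_action[bad_dwell], have[bad_dwell]))
  }
  p <- table$params
  if (p$basal_ascd_prob < 0 || p$basal_ascd_prob > 1) {
    diags <- c(diags, "basal_ascd_prob outside [0, 1]")
  }
  if (!(p$theta_lo_partner < p$theta_hi_partner) ||
      !(p$theta_lo_complex < p$theta_hi_complex)) {
    diags <- c(diags, "channel thresholds must satisfy theta_lo < theta_hi")
  }
  diags
}

# serialization -------------------------------------------------------------

table_to_list <- function(table) {
  list(rows = table$rows, params = table$params)
}

table_from_list <- function(lst) {
  base <- default_table()
  params <- utils::modifyList(base$params, lapply(lst$params %||% list(),
                                                  unlist))
  params$dwell_required <- as.integer(params$dwell_required)
  params$escalation_mult <- as.integer(params$escalation_mult)
  params$dediff_mult <- as.integer(params$dediff_mult)
  params$apo_enabled <- isTRUE(as.logical(params$apo_enabled))
  for (f in c("theta_lo_partner", "theta_hi_partner", "theta_lo_complex",
              "theta_hi_complex", "basal_ascd_prob", "apo_factor")) {
    params[[f]] <- as.numeric(params[[f]])
  }
  rows <- if (is.null(lst$rows)) {
    base$rows
  } else if (is.data.frame(lst$rows)) {
    lst$rows
  } else {
    # parsed JSON: a list of one-row records
    do.call(rbind, lapply(lst$rows, function(r) {
      data.frame(cell_type = r$cell_type, partner_level = r$partner_level,
                 complex_level = r$complex_level,
                 immediate_action = r$immediate_action,
                 prolonged_action = r$prolonged_action,
                 dwell_required = as.integer(r$dwell_required),
                 stringsAsFactors = FALSE)
    }))
  }
  rows$dwell_required <- as.integer(rows$dwell_required)
  structure(list(rows = rows, params = params),
            class = "ctc_decision_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
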