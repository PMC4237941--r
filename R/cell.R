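#' @title Cell agents and the division/fate catalogue
#' @name cell-model
#' @description
#' Each agent is one cell of a Trefone couplet lineage.  The two couplet
#' types are `A` (secretes the `a` Trefone, carries the receptor for the `i`
#' Trefone) and `I` (the converse); a cell never carries the receptor for its
#' own secreted Trefone.  `O` is the original (progenitor) cell of the
#' lineage, which by repo convention carries both Trefone receptors so it can
#' respond to either signal.  `SINGLET` models the immune half-couplet: it
#' secretes an antibody-like species (the `i` slot) against an exogenous
#' antigen (the `a` slot) and carries the receptors an `I` cell would.
NULL

CELL_TYPES   <- c("O", "A", "I", "SINGLET")
LIFE_STATES  <- c("CYCLING", "QUIESCENT", "DORMANT", "DEAD")
ACTIONS <- c("BOOST_SECRETION", "SCD_SRE", "ASCD_SELF_PARTNER",
             "ASCD_PARTNER_PARTNER", "ASCD_DUAL_LCDF", "TD_SCD",
             "APO", "QSC", "DEDIFF")
DIVISION_ACTIONS <- c("SCD_SRE", "ASCD_SELF_PARTNER", "ASCD_PARTNER_PARTNER",
                      "ASCD_DUAL_LCDF", "TD_SCD")

receptor_profile_for <- function(cell_type, variant) {
  has_tccr <- identical(variant, "EC")
  switch(cell_type,
    A = list(has_aR = FALSE, has_iR = TRUE,  has_tccR = has_tccr),
    I = list(has_aR = TRUE,  has_iR = FALSE, has_tccR = has_tccr),
    O = list(has_aR = TRUE,  has_iR = TRUE,  has_tccR = has_tccr),
    SINGLET = list(has_aR = TRUE, has_iR = FALSE, has_tccR = has_tccr),
    stop(sprintf("unknown cell type '%s'", cell_type), call. = FALSE)
  )
}

#' Species secreted by / sensed by a cell type
#'
#' `A` secretes `a` and senses `i`; `I` and the immune `SINGLET` secrete `i`
#' and sense `a`; `O` secretes nothing and senses both.
#'
#' @param cell_type one of `"O"`, `"A"`, `"I"`, `"SINGLET"`.
#' @return `self_species()`: `"a"`, `"i"` or `NA`; `partner_species()`: a
#'   character vector of the species the cell's Trefone receptors bind.
#' @keywords internal
self_species <- function(cell_type) {
  switch(cell_type, A = "a", I = "i", SINGLET = "i", O = NA_character_)
}

#' @rdname self_species
#' @keywords internal
partner_species <- function(cell_type) {
  switch(cell_type, A = "i", I = "a", SINGLET = "a", O = c("a", "i"))
}

#' Create a cell agent
#'
#' @param cell_type one of `"O"`, `"A"`, `"I"`, `"SINGLET"`.
#' @param variant model variant: `"EC"` (extracellular complex sensed by a
#'   scarce membrane receptor) or `"IC"` (complex formed intracellularly from
#'   a hived-off fraction of self-synthesized Trefone; no complex receptor).
#' @param id integer identifier; ids order all deterministic iteration.
#' @param life_state initial life state, default `"CYCLING"`.
#' @param tccr_count_scale relative abundance of the complex receptor
#'   (dimensionless, <= 1; complex receptors are scarce, default 0.05).
#' @param generation lineage generation counter.
#' @return An object of class `ctc_cell`.
#' @examples
#' a <- make_cell("A", "EC")
#' marker_string(a)
#' @export
make_cell <- function(cell_type, variant = c("EC", "IC"), id = 1L,
                      life_state = "CYCLING", tccr_count_scale = 0.05,
                      generation = 0L) {
  variant <- match.arg(variant)
  if (!cell_type %in% CELL_TYPES) {
    stop(sprintf("unknown cell type '%s' (expected one of %s)",
                 cell_type, paste(CELL_TYPES, collapse = ", ")),
         call. = FALSE)
  }
  if (!life_state %in% LIFE_STATES) {
    stop(sprintf("unknown life state '%s'", life_state), call. = FALSE)
  }
  if (tccr_count_scale > 1 || tccr_count_scale < 0) {
    stop("'tccr_count_scale' must lie in [0, 1]", call. = FALSE)
  }
  receptors <- receptor_profile_for(cell_type, variant)
  receptors$tccR_count_scale <- if (receptors$has_tccR) tccr_count_scale else 0
  cell <- list(
    id = as.integer(id),
    cell_type = cell_type,
    variant = variant,
    receptors = receptors,
    # internal stores, in mol, per species; store_ai / store_di are
    # internalized complex (each unit holds one of each constituent)
    store_a = 0, store_i = 0, store_d = 0, store_ai = 0, store_di = 0,
    hived_self = 0,
    dwell_hi = 0L, dwell_starved = 0L,
    life_state = life_state,
    secretion_mult = 1,
    generation = as.integer(generation)
  )
  cell$marker_string <- render_marker_string(receptors)
  structure(cell, class = "ctc_cell")
}

render_marker_string <- function(receptors) {
  flag <- function(x) if (isTRUE(x)) "+" else "-"
  sprintf("iR%s aR%s tccR%s",
          flag(receptors$has_iR), flag(receptors$has_aR),
          flag(receptors$has_tccR))
}

#' Receptor marker string of a cell
#'
#' Renders the cell's receptor profile as the ASCII marker string used in
#' files and CLI output, e.g. an A cell is `"iR+ aR- tccR+"` (`+`/`-` stand
#' for the presence/absence glyphs used for surface-marker typing).
#'
#' @param cell a `ctc_cell`.
#' @return A character scalar.
#' @seealso [parse_marker_string()]
#' @export
marker_string <- function(cell) {
  stopifnot(inherits(cell, "ctc_cell"))
  render_marker_string(cell$receptors)
}

#' Parse a receptor marker string
#'
#' Inverse of [marker_string()]: recovers the logical receptor flags.
#'
#' @param text a marker string such as `"iR+ aR- tccR+"`.
#' @return A named list with `has_iR`, `has_aR`, `has_tccR`.
#' @export
parse_marker_string <- function(text) {
  m <- regmatches(text, regexec("^iR([+-]) aR([+-]) tccR([+-])$", text))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("not a valid marker string: '%s'", text), call. = FALSE)
  }
  list(has_iR = m[2] == "+", has_aR = m[3] == "+", has_tccR = m[4] == "+")
}

#' @export
print.ctc_cell <- function(x, ...) {
  cat(sprintf("<cell #%d %s (%s) %s gen=%d markers=\"%s\">\n",
              x$id, x$cell_type, x$variant, x$life_state, x$generation,
              x$marker_string))
  invisible(x)
}

partner_type_of <- function(cell_type) {
  switch(cell_type, A = "I", I = "A",
         stop(sprintf("cell type '%s' has no couplet partner type", cell_type),
              call. = FALSE))
}

child_of <- function(parent, cell_type, id, split = 0.5) {
  child <- make_cell(cell_type, parent$variant, id = id,
                     tccr_count_scale = if (parent$receptors$has_tccR)
                       parent$receptors$tccR_count_scale else 0.05,
                     generation = parent$generation + 1L)
  for (f in c("store_a", "store_i", "store_d", "store_ai", "store_di",
              "hived_self")) {
    child[[f]] <- parent[[f]] * split
  }
  child
}

#' Execute a division or fate action on a cell
#'
#' Applies one catalogue action and returns the resulting cells:
#' \describe{
#'   \item{SCD_SRE}{symmetric self-renewal: two copies of the parent type.}
#'   \item{ASCD_SELF_PARTNER}{asymmetric: one parent-type + one partner-type
#'     cell (an `I` cell yields `I` + `A`).}
#'   \item{ASCD_PARTNER_PARTNER}{both children are partner type; the parent
#'     type is extinguished in this division.}
#'   \item{ASCD_DUAL_LCDF}{`O` cells only: dual lineage commitment, one `A`
#'     plus one `I`.}
#'   \item{TD_SCD}{transdifferentiation with division: two partner-type cells.}
#'   \item{APO}{apoptosis: empty result, parent marked `DEAD` (internal stores
#'     are destroyed by the caller's degradation ledger, not returned to the
#'     pool).}
#'   \item{QSC / BOOST_SECRETION / DEDIFF}{single cell back (DEDIFF via
#'     [apply_dedifferentiation()]).}
#' }
#' Children get `generation = parent + 1`, zeroed dwell counters, and the
#' parent's internal stores split equally between the two.
#'
#' @param cell a live, cycling `ctc_cell`.
#' @param action one of the action names (see `Details`).
#' @param next_id integer id for the first child (the second child, if any,
#'   gets `next_id + 1`).
#' @return A list of 0, 1 or 2 `ctc_cell` objects.
#' @export
divide <- function(cell, action, next_id = cell$id * 2L) {
  stopifnot(inherits(cell, "ctc_cell"))
  if (!action %in% ACTIONS) {
    stop(sprintf("unknown action '%s'", action), call. = FALSE)
  }
  if (cell$life_state == "DEAD") {
    stop("a DEAD cell cannot take actions", call. = FALSE)
  }
  two <- function(t1, t2) {
    list(child_of(cell, t1, id = next_id),
         child_of(cell, t2, id = next_id + 1L))
  }
  switch(action,
    SCD_SRE = two(cell$cell_type, cell$cell_type),
    ASCD_SELF_PARTNER = two(cell$cell_type, partner_type_of(cell$cell_type)),
    ASCD_PARTNER_PARTNER = {
      p <- partner_type_of(cell$cell_type)
      two(p, p)
    },
    ASCD_DUAL_LCDF = {
      if (cell$cell_type != "O") {
        stop("ASCD_DUAL_LCDF is only available to O cells", call. = FALSE)
      }
      two("A", "I")
    },
    TD_SCD = {
      p <- partner_type_of(cell$cell_type)
      two(p, p)
    },
    APO = list(),
    DEDIFF = list(apply_dedifferentiation(cell, check_dwell = FALSE)),
    QSC = list(cell),
    BOOST_SECRETION = list(cell)
  )
}

#' Dedifferentiate a cell back to the lineage's original type
#'
#' A cell deprived of its partner Trefone for long enough reverts to the
#' progenitor (`O`) state: receptors are retyped, identity and generation are
#' preserved, internal stores are carried over, dwell counters reset.  An `O`
#' cell is returned unchanged.
#'
#' @param cell a `ctc_cell` whose starvation dwell has reached the configured
#'   dedifferentiation threshold.
#' @param dediff_dwell the threshold (steps); used for the contract check.
#' @param check_dwell set `FALSE` to skip the precondition (internal use by
#'   [divide()]).
#' @return A `ctc_cell` of type `O`.
#' @export
apply_dedifferentiation <- function(cell, dediff_dwell = NULL,
                                    check_dwell = !is.null(dediff_dwell)) {
  stopifnot(inherits(cell, "ctc_cell"))
  if (check_dwell && cell$dwell_starved < dediff_dwell) {
    stop(sprintf(
      "apply_dedifferentiation called below threshold (dwell %d < %d)",
      cell$dwell_starved, dediff_dwell), call. = FALSE)
  }
  if (cell$cell_type == "O") return(cell)
  o <- cell
  o$cell_type <- "O"
  o$receptors <- receptor_profile_for("O", cell$variant)
  o$receptors$tccR_count_scale <-
    if (o$receptors$has_tccR) 0.05 else 0
  o$marker_string <- render_marker_string(o$receptors)
  o$dwell_hi <- 0L
  o$dwell_starved <- 0L
  o$secretion_mult <- 1
  o
}

# per-species content of one cell's stores; store_di pairs the analog with
# whichever couplet species the analog binds ("i" in the reference
# configuration, "a" in the mirror)
cell_store_total <- function(cell, species, analog_bound = "i") {
  switch(species,
    a = cell$store_a + cell$store_ai +
      (if (identical(analog_bound, "a")) cell$store_di else 0) +
      (if (identical(self_species(cell$cell_type), "a")) cell$hived_self else 0),
    i = cell$store_i + cell$store_ai +
      (if (identical(analog_bound, "i")) cell$store_di else 0) +
      (if (identical(self_species(cell$cell_type), "i")) cell$hived_self else 0),
    d = cell$store_d + cell$store_di,
    stop("unknown species", call. = FALSE)
  )
}
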