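#' Solvation legs for one molecule/species
#'
#' Per-phase discharging (elec) and vanishing (vdW) free energies plus the
#' phase correction sets, as needed to assemble a solvation free energy
#' under models A-D. The vacuum phase never carries long-range or
#' finite-size corrections.
#'
#' @param water,cyclohexane,vacuum Each a list with elements `elec` and
#'   `vdw` ([free_energy_estimate()] or plain numbers). `vacuum` is
#'   required; solvated phases may be omitted if unused.
#' @param water_corrections,cyclohexane_corrections [correction_set()]s for
#'   the solvated phases.
#' @param dg_v_to_v Optional vacuum free-energy change converting the
#'   organic-phase neutral species into the aqueous dominant species.
#'   Default NULL = neglected (flagged downstream).
#' @return Object of class `solvation_legs`.
#' @export
solvation_legs <- function(water = NULL, cyclohexane = NULL, vacuum,
                           water_corrections = correction_set(),
                           cyclohexane_corrections = correction_set(),
                           dg_v_to_v = NULL) {
  leg <- function(x) {
    if (is.null(x)) return(NULL)
    list(elec = as_fee(x$elec), vdw = as_fee(x$vdw))
  }
  structure(list(
    water = leg(water),
    cyclohexane = leg(cyclohexane),
    vacuum = leg(vacuum),
    corrections = list(water = water_corrections,
                       cyclohexane = cyclohexane_corrections),
    dg_v_to_v = if (is.null(dg_v_to_v)) NULL else as_fee(dg_v_to_v)
  ), class = "solvation_legs")
}

# sum free_energy_estimates with signs, propagating in quadrature
combine_fee <- function(terms, signs, method = "assembled") {
  v <- sum(mapply(function(t, s) s * t$delta_g, terms, signs))
  u <- sqrt(sum(vapply(terms, function(t) t$uncertainty^2, numeric(1))))
  free_energy_estimate(v, u, method)
}

require_correction <- function(cs, term, model, phase) {
  x <- cs[[term]]
  if (is.null(x)) {
    stop(sprintf("model %s requires correction '%s' for phase %s",
                 model, term, phase))
  }
  x
}

#' Assemble a solvation free energy under models A-D
#'
#' Model A: dG = dG_solv^elec + dG_solv^vdW - (dG_vac^elec + dG_vac^vdW)
#' + dG_FUNC. Model B adds the phase's Lennard-Jones long-range correction;
#' model C further adds the polarization and summation-scheme corrections;
#' model D applies model C's additions only to charged species and is
#' otherwise identical to model B. Uncertainties are propagated in
#' quadrature across independent legs.
#'
#' @param legs A [solvation_legs()].
#' @param phase "water" or "cyclohexane".
#' @param model One of "A", "B", "C", "D".
#' @param is_charged Logical; drives the model D rule.
#' @return A [free_energy_estimate()].
#' @examples
#' legs <- solvation_legs(
#'   water = list(elec = -10, vdw = -2),
#'   vacuum = list(elec = -8, vdw = -1),
#'   water_corrections = correction_set(dg_func = 0.3))
#' solvation_free_energy(legs, "water", "A")  # -2.7
#' @export
solvation_free_energy <- function(legs, phase = c("water", "cyclohexane"),
                                  model = c("A", "B", "C", "D"),
                                  is_charged = FALSE) {
  phase <- match.arg(phase)
  model <- match.arg(model)
  pl <- legs[[phase]]
  if (is.null(pl)) stop(sprintf("no %s legs present", phase))
  vac <- legs$vacuum
  if (is.null(vac)) stop("vacuum legs required")
  cs <- legs$corrections[[phase]]
  func <- require_correction(cs, "dg_func", model, phase)

  terms <- list(pl$elec, pl$vdw, vac$elec, vac$vdw, func)
  signs <- c(1, 1, -1, -1, 1)

  if (model %in% c("B", "C") || (model == "D")) {
    ljlrc <- require_correction(cs, "dg_ljlrc", model, phase)
    terms <- c(terms, list(ljlrc)); signs <- c(signs, 1)
  }
  if (model == "C" || (model == "D" && is_charged)) {
    pol <- require_correction(cs, "dg_pol", model, phase)
    psum <- require_correction(cs, "dg_psum", model, phase)
    terms <- c(terms, list(pol, psum)); signs <- c(signs, 1, 1)
  }
  combine_fee(terms, signs)
}

#' Water-to-organic transfer free energy
#'
#' dG_transfer = dG_cyc - dG_w - dG_v_to_v, with quadrature-propagated
#' uncertainty. An absent dG_v_to_v is treated as 0 and flagged as
#' "neglected" in the `"v_to_v"` attribute of the result.
#'
#' @param dg_cyc,dg_w Solvation free energies ([free_energy_estimate()] or
#'   numbers), kcal/mol.
#' @param dg_v_to_v Optional vacuum conversion term.
#' @return A [free_energy_estimate()].
#' @export
transfer_free_energy <- function(dg_cyc, dg_w, dg_v_to_v = NULL) {
  dg_cyc <- as_fee(dg_cyc); dg_w <- as_fee(dg_w)
  terms <- list(dg_cyc, dg_w)
  signs <- c(1, -1)
  if (!is.null(dg_v_to_v)) {
    terms <- c(terms, list(as_fee(dg_v_to_v))); signs <- c(signs, -1)
  }
  out <- combine_fee(terms, signs)
  attr(out, "v_to_v") <- if (is.null(dg_v_to_v)) "neglected" else "included"
  out
}

#' Dominant-species distribution coefficient
#'
#' logD = -beta dG_transfer / ln(10); the uncertainty is scaled by the same
#' factor.
#'
#' @param dg_transfer Transfer free energy ([free_energy_estimate()] or
#'   number), kcal/mol.
#' @param state A [thermo_state()].
#' @return A list with `logd` and `uncertainty`.
#' @examples
#' logd_dominant(-1.3637)$logd  # ~ +1 at 298 K
#' @export
logd_dominant <- function(dg_transfer, state = thermo_state()) {
  state <- as_thermo_state(state)
  dg <- as_fee(dg_transfer)
  fac <- state$beta / LN10
  list(logd = -fac * dg$delta_g, uncertainty = fac * dg$uncertainty)
}
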