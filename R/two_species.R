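#' Effective pKa from a dominant-species fraction
#'
#' When an external pKa/tautomer predictor supplies the fraction f of the
#' dominant species at a given pH (possibly aggregating several coupled
#' equilibria), the conjugate pair can be described by a single effective
#' pKa. With the dominant form taken as the base (default orientation),
#' pKa_eff = pH - log10(f / (1 - f)).
#'
#' @param f_dom Fraction of the dominant species, strictly in (0, 1).
#' @param pH pH at which f_dom was predicted.
#' @param dominant_is_base Orientation flag; set FALSE when the dominant
#'   form is the acid of the pair, which flips the sign of the log term.
#' @return Effective pKa (dimensionless).
#' @examples
#' effective_pka(0.5, 7.4)      # 7.4
#' effective_pka(10 / 11, 7.4)  # 6.4
#' @export
effective_pka <- function(f_dom, pH, dominant_is_base = TRUE) {
  if (!is.finite(f_dom) || f_dom <= 0 || f_dom >= 1) {
    stop("degenerate speciation: f_dom must be strictly between 0 and 1")
  }
  s <- if (dominant_is_base) 1 else -1
  pH - s * log10(f_dom / (1 - f_dom))
}

#' Speciation fractions implied by an effective pKa
#'
#' Inverse of [effective_pka()]: the dominant-species fraction at `pH`.
#'
#' @param pka_eff Effective pKa.
#' @param pH pH.
#' @param dominant_is_base Orientation flag (see [effective_pka()]).
#' @return Fraction of the dominant species in (0, 1).
#' @export
speciation_fraction <- function(pka_eff, pH, dominant_is_base = TRUE) {
  s <- if (dominant_is_base) 1 else -1
  r <- 10^(s * (pH - pka_eff))
  r / (1 + r)
}

#' Partition coefficient from a transfer free energy
#'
#' P = exp(-beta dG_transfer) = 10^(-beta dG / ln 10), the
#' cyclohexane/water concentration ratio of a single species.
#'
#' @param dg_transfer Transfer free energy, kcal/mol.
#' @param state A [thermo_state()].
#' @return P (dimensionless, > 0).
#' @export
partition_from_transfer <- function(dg_transfer, state = thermo_state()) {
  state <- as_thermo_state(state)
  dg <- as_fee(dg_transfer)
  exp(-state$beta * dg$delta_g)
}

#' Two-species distribution coefficient
#'
#' Distribution coefficient of a conjugate acid/base pair from the two
#' partition coefficients, the effective pKa and the pH:
#' logD = log10( P_con (1 + 10^-pKa_eff / 10^-pH)^-1 +
#'               P_dom (1 + 10^-pH / 10^-pKa_eff)^-1 ).
#' The two speciation weights sum to one. The default orientation takes
#' the dominant form as the base and the conjugate form as the acid;
#' `dominant_is_base = FALSE` swaps the weight expressions.
#'
#' @param p_con Partition coefficient of the conjugate species (>= 0).
#' @param p_dom Partition coefficient of the dominant species (>= 0).
#' @param pka_eff Effective pKa of the pair.
#' @param pH pH.
#' @param dominant_is_base Orientation flag.
#' @return logD (dimensionless).
#' @export
logd_two_species <- function(p_con, p_dom, pka_eff, pH,
                             dominant_is_base = TRUE) {
  if (p_con < 0 || p_dom < 0) stop("partition coefficients must be >= 0")
  if (p_con == 0 && p_dom == 0) stop("both partition coefficients are zero")
  w_dom <- speciation_fraction(pka_eff, pH, dominant_is_base)
  w_con <- 1 - w_dom
  log10(p_con * w_con + p_dom * w_dom)
}

#' pKa-corrected partition coefficient (single conjugate species)
#'
#' The common approximation reached when the dominant (ionised) species
#' does not partition into the organic phase:
#' logD = log10( P (1 + 10^-pKa / 10^-pH)^-1 ).
#'
#' @param p_con Partition coefficient of the neutral (conjugate) species
#'   (> 0).
#' @param pka pKa of the conjugate pair.
#' @param pH pH.
#' @return logD (dimensionless).
#' @export
logd_pka_corrected <- function(p_con, pka, pH) {
  if (p_con <= 0) stop("p_con must be > 0")
  log10(p_con) - log10(1 + 10^(pH - pka))
}

#' Resolve the effective pKa for a species record
#'
#' Precedence rule: an explicit pKa_eff wins; when both an explicit value
#' and a dominant fraction are supplied and disagree by more than 0.01 pKa
#' units a warning is emitted.
#'
#' @param pka_eff Explicit effective pKa or NA/NULL.
#' @param f_dom Dominant fraction or NA/NULL.
#' @param pH pH.
#' @param dominant_is_base Orientation flag.
#' @return Effective pKa.
#' @export
resolve_pka_eff <- function(pka_eff = NULL, f_dom = NULL, pH,
                            dominant_is_base = TRUE) {
  has_pka <- !is.null(pka_eff) && !is.na(pka_eff)
  has_f <- !is.null(f_dom) && !is.na(f_dom)
  if (!has_pka && !has_f) stop("need pka_eff or f_dom")
  # a numerically saturated fraction carries no usable information, so the
  # consistency check only runs on non-degenerate fractions
  if (has_f && f_dom > 0 && f_dom < 1) {
    from_f <- effective_pka(f_dom, pH, dominant_is_base)
  } else if (!has_pka) {
    stop("degenerate speciation fraction and no explicit pka_eff")
  } else {
    has_f <- FALSE
  }
  if (has_pka) {
    if (has_f && abs(pka_eff - from_f) > 0.01) {
      warning(sprintf(
        "explicit pKa_eff (%.3f) inconsistent with fraction-derived value (%.3f); using the explicit one",
        pka_eff, from_f))
    }
    return(pka_eff)
  }
  from_f
}
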