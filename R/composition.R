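#' Mole-fraction solubility from weighed masses
#'
#' Converts a gravimetric saturation measurement to mole-fraction
#' solubility,
#' \deqn{x_e = \frac{m_1/M_1}{m_1/M_1 + m_2/M_2},}
#' where \eqn{m_1, M_1} are the mass and molar mass of the solute and
#' \eqn{m_2, M_2} those of the solvent system.
#'
#' For micellar media the single solvent term is ambiguous.  Two
#' conventions are supported: `"aqueous"` (default) folds the surfactant
#' mass into the aqueous term and uses the water molar mass for the whole
#' solvent system; `"two_component"` adds an explicit surfactant term
#' \eqn{m_s/M_s} to the denominator.  At the dilute surfactant loadings
#' typical of micellar solubility work (a few mM) the two differ by well
#' under 2%, but the choice is explicit.
#'
#' @param m1 Solute mass, g (may be 0).
#' @param M1 Solute molar mass, g/mol.
#' @param m2 Solvent (water) mass, g.
#' @param M2 Solvent molar mass, g/mol (water: 18.015).
#' @param m_s Surfactant mass, g (default 0).
#' @param M_s Surfactant molar mass, g/mol; required when
#'   `convention = "two_component"` and `m_s > 0`.
#' @param convention `"aqueous"` or `"two_component"` (see Details).
#' @return Mole fraction of solute in `[0, 1)`.
#' @examples
#' mole_fraction_from_masses(0.01, 418.57, 10, 18.015)  # 4.30e-5
#' @export
mole_fraction_from_masses <- function(m1, M1, m2, M2 = 18.015,
                                      m_s = 0, M_s = NULL,
                                      convention = c("aqueous",
                                                     "two_component")) {
  convention <- match.arg(convention)
  if (any(m1 < 0)) stop("solute mass 'm1' must be >= 0", call. = FALSE)
  if (any(m2 <= 0)) stop("solvent mass 'm2' must be > 0", call. = FALSE)
  if (any(M1 <= 0) || any(M2 <= 0))
    stop("molar masses must be > 0", call. = FALSE)
  if (any(m_s < 0)) stop("surfactant mass 'm_s' must be >= 0", call. = FALSE)
  n1 <- m1 / M1
  if (convention == "aqueous") {
    n2 <- (m2 + m_s) / M2
    n1 / (n1 + n2)
  } else {
    if (any(m_s > 0) && (is.null(M_s) || any(M_s <= 0)))
      stop("'M_s' must be supplied (and > 0) for the two-component ",
           "convention", call. = FALSE)
    ns <- if (is.null(M_s)) 0 else m_s / M_s
    n1 / (n1 + m2 / M2 + ns)
  }
}

#' Mole fraction from an assay concentration
#'
#' Converts a mass concentration of solute (as assayed in the saturated
#' supernatant, \eqn{\mu}g/mL) to mole fraction under the dilute-solution
#' assumption that the solution density equals the solvent density:
#' per mL of solution there are \eqn{c \cdot 10^{-6}/M_{solute}} mol of
#' solute and \eqn{\rho / M_{solvent}} mol of solvent.
#'
#' @param conc_ug_mL Solute concentration, \eqn{\mu}g/mL (>= 0).
#' @param M_solute Solute molar mass, g/mol.
#' @param M_solvent Solvent molar mass, g/mol (default water, 18.015).
#' @param rho_solvent Solvent density, g/mL (default 1.0).
#' @return Mole fraction in `[0, 1)`.
#' @examples
#' mole_fraction_from_concentration(1.74, 418.57)  # 7.49e-8
#' @export
mole_fraction_from_concentration <- function(conc_ug_mL, M_solute,
                                             M_solvent = 18.015,
                                             rho_solvent = 1.0) {
  if (any(conc_ug_mL < 0))
    stop("'conc_ug_mL' must be >= 0", call. = FALSE)
  if (any(M_solute <= 0) || any(M_solvent <= 0) || any(rho_solvent <= 0))
    stop("molar masses and density must be > 0", call. = FALSE)
  n1 <- conc_ug_mL * 1e-6 / M_solute
  n2 <- rho_solvent / M_solvent
  n1 / (n1 + n2)
}

#' Assay concentration from a mole fraction
#'
#' Exact algebraic inverse of [mole_fraction_from_concentration()].
#'
#' @param x Mole fraction in `[0, 1)`.
#' @inheritParams mole_fraction_from_concentration
#' @return Concentration in \eqn{\mu}g/mL.
#' @examples
#' concentration_from_mole_fraction(7.49e-8, 418.57)  # 1.74
#' @export
concentration_from_mole_fraction <- function(x, M_solute,
                                             M_solvent = 18.015,
                                             rho_solvent = 1.0) {
  if (any(x < 0) || any(x >= 1))
    stop("'x' must lie in [0, 1)", call. = FALSE)
  if (any(M_solute <= 0) || any(M_solvent <= 0) || any(rho_solvent <= 0))
    stop("molar masses and density must be > 0", call. = FALSE)
  n2 <- rho_solvent / M_solvent
  n1 <- x / (1 - x) * n2
  n1 * M_solute * 1e6
}
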