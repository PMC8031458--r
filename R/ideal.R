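#' Ideal mole-fraction solubility from fusion calorimetry
#'
#' Computes the solubility a crystalline solute would have in an ideal
#' solution, which depends only on its fusion properties:
#' \deqn{\ln x^{idl} = -\frac{\Delta H_{fus}(T_{fus}-T)}{R\,T_{fus}\,T}
#'   + \frac{\Delta C_p}{R}\left[\frac{T_{fus}-T}{T}
#'   + \ln\frac{T}{T_{fus}}\right].}
#' The first (enthalpic) term dominates; the heat-capacity term corrects
#' for the difference between the melt and solid heat capacities and
#' vanishes when \eqn{\Delta C_p = 0}.  Both terms are returned so their
#' relative magnitude can be inspected.
#'
#' @param T Absolute temperature(s), K; must satisfy
#'   \eqn{0 < T \le T_{fus}} (the melt regime is out of scope).
#' @param fusion A [fusion_properties] object.
#' @return A data frame with one row per temperature and columns `T_K`,
#'   `x_idl`, `term_enthalpic`, `term_heat_capacity`
#'   (`log(x_idl) == term_enthalpic + term_heat_capacity`).
#' @examples
#' sim <- fusion_properties(412.95, 28380, 68.72)
#' ideal_solubility(c(300.2, 310.2, 320.2), sim)$x_idl
#' # 7.17e-2  9.39e-2  1.22e-1
#' @export
ideal_solubility <- function(T, fusion) {
  stopifnot(inherits(fusion, "fusion_properties"))
  if (any(T <= 0)) stop("'T' must be positive (kelvin)", call. = FALSE)
  if (any(T > fusion$T_fus))
    stop("'T' above the melting temperature (", fusion$T_fus,
         " K): ideal-solubility expression applies only to T <= T_fus",
         call. = FALSE)
  Tf <- fusion$T_fus
  term1 <- -fusion$dH_fus * (Tf - T) / (R_GAS * Tf * T)
  term2 <- (fusion$dCp / R_GAS) * ((Tf - T) / T + log(T / Tf))
  data.frame(T_K = T,
             x_idl = exp(term1 + term2),
             term_enthalpic = term1,
             term_heat_capacity = term2)
}
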