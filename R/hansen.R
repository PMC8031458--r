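#' Total Hansen solubility parameter
#'
#' Combines the dispersion, polar and hydrogen-bonding components into the
#' total cohesive-energy parameter:
#' \deqn{\delta^2 = \delta_d^2 + \delta_p^2 + \delta_h^2.}
#' Substances with similar \eqn{\delta} tend to dissolve one another,
#' which is why the totals of drug and surfactant are compared when
#' rationalizing micellar solubilization.
#'
#' @param delta_d,delta_p,delta_h Component parameters, MPa\eqn{^{1/2}},
#'   all non-negative.  Vectorized.
#' @return Total parameter, MPa\eqn{^{1/2}}.
#' @examples
#' hansen_total(15.50, 16.00, 42.30)  # 47.8 (water)
#' @export
hansen_total <- function(delta_d, delta_p, delta_h) {
  if (any(delta_d < 0) || any(delta_p < 0) || any(delta_h < 0))
    stop("Hansen components must be non-negative", call. = FALSE)
  sqrt(delta_d^2 + delta_p^2 + delta_h^2)
}

#' Read a table of Hansen parameters
#'
#' Expects columns `substance, delta_d, delta_p, delta_h` and optionally
#' `delta_total`; when the total is absent it is computed with
#' [hansen_total()].
#'
#' @param path CSV path.
#' @return A data frame with all five columns.
#' @examples
#' h <- read_hansen_table(system.file("extdata", "hansen_parameters.csv",
#'                                    package = "soluthermo"))
#' @export
read_hansen_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  wanted <- c("substance", "delta_d", "delta_p", "delta_h")
  missing <- setdiff(wanted, names(df))
  if (length(missing))
    stop("Hansen table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(df$delta_d < 0 | df$delta_p < 0 | df$delta_h < 0))
    stop("Hansen components must be non-negative", call. = FALSE)
  if (is.null(df$delta_total))
    df$delta_total <- hansen_total(df$delta_d, df$delta_p, df$delta_h)
  df
}

#' Consistency check of stated Hansen totals
#'
#' Recomputes each record's total from its components and reports the
#' relative deviation from the stated total, flagging records whose
#' deviation exceeds `tol`.  Useful for catching transcription errors in
#' published parameter tables, where a component and the total cannot both
#' be right.
#'
#' With `digits` set, the recomputed total is first rounded to that many
#' decimal places — the comparison then asks whether the stated total is
#' the correctly rounded value, which is the natural question for a table
#' printed at fixed precision (`digits = 1` for tables printed to 0.1
#' MPa\eqn{^{1/2}}).
#'
#' @param records Data frame as returned by [read_hansen_table()], with
#'   both components and stated totals.
#' @param tol Relative tolerance above which a record is flagged.
#' @param digits Optional decimal places to round the recomputed total to
#'   before comparison (default `NULL`: no rounding).
#' @return A data frame `substance, stated, computed, rel_dev, flagged`.
#' @examples
#' h <- read_hansen_table(system.file("extdata", "hansen_parameters.csv",
#'                                    package = "soluthermo"))
#' subset(hansen_table_check(h, tol = 0.02), flagged)  # the SIM row
#' @export
hansen_table_check <- function(records, tol = 0.02, digits = NULL) {
  stopifnot(is.data.frame(records),
            all(c("delta_d", "delta_p", "delta_h", "delta_total") %in%
                  names(records)))
  computed <- hansen_total(records$delta_d, records$delta_p,
                           records$delta_h)
  if (!is.null(digits)) computed <- round(computed, digits)
  rel_dev <- abs(computed - records$delta_total) / records$delta_total
  data.frame(substance = records$substance,
             stated = records$delta_total,
             computed = computed,
             rel_dev = rel_dev,
             flagged = rel_dev > tol,
             stringsAsFactors = FALSE)
}

#' Molar solubilization capacity of a micellar solution
#'
#' Moles of drug taken up per mole of micellized surfactant, scaled to
#' mmol/mol:
#' \deqn{S_c = \frac{S_t - S_w}{C_s - CMC} \times 1000,}
#' where \eqn{S_t} is the total drug solubility in the surfactant
#' solution, \eqn{S_w} the intrinsic water solubility, \eqn{C_s} the
#' surfactant concentration and \eqn{CMC} its critical micelle
#' concentration (only surfactant above the CMC forms micelles).
#'
#' All concentrations are mol/L.  Solubilities given as mole fractions can
#' be converted first with `from_mole_fraction = TRUE`, which applies the
#' dilute aqueous limit \eqn{S \approx x \cdot 55.49} mol/L.
#'
#' CMC values must be supplied by the caller: they are surfactant- and
#' temperature-specific and no safe default exists.  `CMC = 0` (every
#' surfactant molecule micellized) is accepted but announced with a
#' warning so the assumption is never silent.
#'
#' @param S_t Total drug solubility in the micellar solution, mol/L (or
#'   mole fraction, see `from_mole_fraction`).
#' @param S_w Intrinsic water solubility of the drug, mol/L (or mole
#'   fraction).
#' @param C_s Surfactant concentration, mol/L.
#' @param CMC Critical micelle concentration, mol/L; must satisfy
#'   `C_s > CMC`.
#' @param from_mole_fraction Logical: interpret `S_t`, `S_w` as mole
#'   fractions and convert with the dilute factor 55.49 mol/L.
#' @return Solubilization capacity, mM per M (equivalently mmol/mol).
#' @examples
#' solubilization_capacity(S_t = 1.1e-3, S_w = 1e-4, C_s = 0.01, CMC = 1e-4)
#' @export
solubilization_capacity <- function(S_t, S_w, C_s, CMC = 0,
                                    from_mole_fraction = FALSE) {
  if (any(CMC < 0)) stop("'CMC' must be >= 0", call. = FALSE)
  if (any(C_s <= CMC))
    stop("'C_s' must exceed the CMC: below it no micelles exist and the ",
         "solubilization capacity is undefined", call. = FALSE)
  if (any(S_w < 0) || any(S_t < S_w))
    stop("need S_t >= S_w >= 0", call. = FALSE)
  if (isTRUE(from_mole_fraction)) {
    S_t <- S_t * 55.49
    S_w <- S_w * 55.49
  }
  if (all(CMC == 0))
    warning("CMC = 0 assumed: all surfactant treated as micellized",
            call. = FALSE)
  (S_t - S_w) / (C_s - CMC) * 1000
}
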