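#' Fusion (melting) properties of a solute
#'
#' Bundles the calorimetric quantities that determine a crystalline
#' solute's ideal solubility: the melting temperature, the enthalpy of
#' fusion, and the differential molar heat capacity between the
#' supercooled melt and the solid.  The fusion entropy
#' \eqn{\Delta S_{fus} = \Delta H_{fus} / T_{fus}} is derived on
#' construction.
#'
#' When `dCp` is not supplied it defaults to the fusion entropy, the
#' standard substitution when the heat-capacity difference has not been
#' measured directly (for simvastatin this gives 68.72 J/(mol K)).
#'
#' @param T_fus Melting temperature, K.
#' @param dH_fus Fusion enthalpy.  Interpreted in the unit named by
#'   `units`; stored internally in J/mol.
#' @param dCp Differential molar heat capacity, J/(mol K); defaults to the
#'   fusion entropy.
#' @param units Unit of `dH_fus`: `"J/mol"` (default) or `"kJ/mol"`.
#'
#' @return An object of class `"fusion_properties"` with fields `T_fus`
#'   (K), `dH_fus` (J/mol), `dCp` (J/(mol K)), `dS_fus` (J/(mol K)).
#' @examples
#' fusion_properties(T_fus = 412.95, dH_fus = 28.38, units = "kJ/mol")
#' @export
fusion_properties <- function(T_fus, dH_fus, dCp = NULL,
                              units = c("J/mol", "kJ/mol")) {
  units <- match.arg(units)
  if (!is.numeric(T_fus) || length(T_fus) != 1L || T_fus <= 0)
    stop("'T_fus' must be a single positive temperature in K", call. = FALSE)
  if (!is.numeric(dH_fus) || length(dH_fus) != 1L || dH_fus <= 0)
    stop("'dH_fus' must be a single positive enthalpy", call. = FALSE)
  if (units == "kJ/mol") dH_fus <- dH_fus * 1000
  dS_fus <- dH_fus / T_fus
  if (is.null(dCp)) dCp <- dS_fus
  if (!is.numeric(dCp) || length(dCp) != 1L || dCp < 0)
    stop("'dCp' must be a single non-negative number", call. = FALSE)
  structure(list(T_fus = T_fus, dH_fus = dH_fus, dCp = dCp,
                 dS_fus = dS_fus),
            class = "fusion_properties")
}

#' @export
print.fusion_properties <- function(x, ...) {
  cat("Fusion properties\n")
  cat(sprintf("  T_fus : %.2f K\n", x$T_fus))
  cat(sprintf("  dH_fus: %.2f kJ/mol\n", x$dH_fus / 1000))
  cat(sprintf("  dS_fus: %.2f J/(mol K)\n", x$dS_fus))
  cat(sprintf("  dCp   : %.2f J/(mol K)\n", x$dCp))
  invisible(x)
}

#' Read fusion properties from a JSON or YAML config
#'
#' The config must carry the melting temperature as `T_fus_K` and the
#' fusion enthalpy as either `dH_fus_J_mol` or `dH_fus_kJ_mol`; an
#' optional `dCp_J_mol_K` overrides the fusion-entropy default.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [fusion_properties] object.
#' @examples
#' cfg <- system.file("extdata", "simvastatin_fusion.json",
#'                    package = "soluthermo")
#' read_fusion_properties(cfg)
#' @export
read_fusion_properties <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$T_fus_K))
    stop("fusion config is missing 'T_fus_K'", call. = FALSE)
  if (!is.null(cfg$dH_fus_J_mol)) {
    dH <- cfg$dH_fus_J_mol; units <- "J/mol"
  } else if (!is.null(cfg$dH_fus_kJ_mol)) {
    dH <- cfg$dH_fus_kJ_mol; units <- "kJ/mol"
  } else {
    stop("fusion config needs 'dH_fus_J_mol' or 'dH_fus_kJ_mol'",
         call. = FALSE)
  }
  fusion_properties(T_fus = cfg$T_fus_K, dH_fus = dH,
                    dCp = cfg$dCp_J_mol_K, units = units)
}

#' Fusion entropy
#'
#' \eqn{\Delta S_{fus} = \Delta H_{fus} / T_{fus}}.
#'
#' @param dH_fus Fusion enthalpy in J/mol, or a [fusion_properties]
#'   object (in which case `T_fus` is taken from it).
#' @param T_fus Melting temperature, K.
#' @return Fusion entropy in J/(mol K).
#' @examples
#' fusion_entropy(28380, 412.95)  # 68.72
#' @export
fusion_entropy <- function(dH_fus, T_fus) {
  if (inherits(dH_fus, "fusion_properties")) {
    f <- dH_fus
    return(f$dH_fus / f$T_fus)
  }
  if (!is.numeric(T_fus) || any(T_fus <= 0))
    stop("'T_fus' must be positive", call. = FALSE)
  if (any(dH_fus < 0))
    stop("'dH_fus' must be non-negative", call. = FALSE)
  dH_fus / T_fus
}
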