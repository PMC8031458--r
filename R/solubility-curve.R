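#' Universal gas constant
#'
#' The molar gas constant used throughout the package,
#' \eqn{R = 8.314} J mol\eqn{^{-1}} K\eqn{^{-1}}.  The value is fixed at four
#' significant figures, the rounding conventional in the solubility
#' literature whose printed thermodynamic quantities this package
#' reproduces.
#'
#' @format A length-one numeric, J/(mol K).
#' @export
R_GAS <- 8.314

# temperatures below this are almost certainly Celsius entered by mistake
.T_MIN_K <- 200

#' Construct a solubility curve
#'
#' A solubility curve is the unit of analysis: one sample's mole-fraction
#' solubility \eqn{x_e} measured at two or more absolute temperatures, with
#' the identity of the solubilizing medium (pure water or a micellar
#' surfactant solution at a stated molar concentration).
#'
#' Replicate measurements at the same temperature are reduced to their
#' arithmetic mean before the curve is stored; the number of raw points
#' folded into each retained temperature is kept in the `replicates`
#' field.  Points are sorted by increasing temperature.
#'
#' @param sample_id Character label for the sample (e.g. `"20 mM M59"`).
#' @param temperatures Numeric vector of absolute temperatures in kelvin.
#'   Values below 200 K are rejected as probable Celsius entries.
#' @param x_e Numeric vector of mole-fraction solubilities, parallel to
#'   `temperatures`; each must lie strictly in (0, 1).
#' @param surfactant Character name of the surfactant, or `"water"` for the
#'   neat aqueous sample.
#' @param conc_mM Surfactant molar concentration in mmol/L (0 for water).
#'
#' @return An object of class `"solubility_curve"`: a list with fields
#'   `sample_id`, `surfactant`, `conc_mM`, `temperatures`, `x_e`,
#'   `replicates`.
#' @examples
#' solubility_curve("20 mM M59", c(300.2, 310.2, 320.2),
#'                  c(1.15e-2, 1.33e-2, 1.54e-2),
#'                  surfactant = "M59", conc_mM = 20)
#' @export
solubility_curve <- function(sample_id, temperatures, x_e,
                             surfactant = "water", conc_mM = 0) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  temperatures <- as.numeric(temperatures)
  x_e <- as.numeric(x_e)
  if (length(temperatures) != length(x_e))
    stop("'temperatures' and 'x_e' must have equal length", call. = FALSE)
  if (anyNA(temperatures) || anyNA(x_e))
    stop("missing values in temperatures or x_e for sample '", sample_id, "'",
         call. = FALSE)
  if (any(temperatures <= 0))
    stop("all temperatures must be positive (kelvin) for sample '",
         sample_id, "'", call. = FALSE)
  if (any(temperatures < .T_MIN_K))
    stop("temperature below ", .T_MIN_K,
         " K for sample '", sample_id,
         "': temperatures must be supplied in kelvin", call. = FALSE)
  if (any(x_e <= 0 | x_e >= 1))
    stop("all x_e must lie strictly in (0, 1) for sample '", sample_id, "'",
         call. = FALSE)
  if (length(conc_mM) != 1L || is.na(conc_mM) || conc_mM < 0)
    stop("'conc_mM' must be a single non-negative number", call. = FALSE)

  # collapse replicates: arithmetic mean of x_e per distinct temperature
  Tu <- sort(unique(temperatures))
  reps <- integer(length(Tu))
  xm <- numeric(length(Tu))
  for (i in seq_along(Tu)) {
    sel <- temperatures == Tu[i]
    reps[i] <- sum(sel)
    xm[i] <- mean(x_e[sel])
  }
  if (length(Tu) < 2L)
    stop("a solubility curve needs at least 2 distinct temperatures ",
         "(sample '", sample_id, "')", call. = FALSE)

  structure(
    list(sample_id = sample_id,
         surfactant = as.character(surfactant),
         conc_mM = as.numeric(conc_mM),
         temperatures = Tu,
         x_e = xm,
         replicates = reps),
    class = "solubility_curve")
}

#' @export
print.solubility_curve <- function(x, ...) {
  cat("Solubility curve: ", x$sample_id, "\n", sep = "")
  cat("  medium: ", if (identical(x$surfactant, "water")) "water" else
    paste0(format(x$conc_mM), " mM ", x$surfactant), "\n", sep = "")
  df <- data.frame(T_K = x$temperatures,
                   x_e = signif(x$x_e, 3),
                   replicates = x$replicates)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.solubility_curve <- function(x, ...) {
  data.frame(sample_id = x$sample_id,
             surfactant = x$surfactant,
             conc_mM = x$conc_mM,
             T_K = x$temperatures,
             x_e = x$x_e,
             stringsAsFactors = FALSE)
}

#' @export
length.solubility_curve <- function(x) length(x$temperatures)

#' Read a table of solubility measurements
#'
#' Reads a CSV of saturation solubility measurements (one row per sample
#' and temperature) and groups the rows into [solubility_curve] objects.
#' The expected columns are `sample_id, surfactant, conc_mM, T_K, x_e`;
#' differently named columns can be mapped with `dialect`.  Row order in
#' the file is irrelevant: points are sorted by temperature within each
#' sample and the returned list is sorted by sample id, so the same data
#' always yield the same curves.
#'
#' @param path Path to a CSV file with a header row, `"."` decimal
#'   separator, UTF-8.
#' @param dialect Optional named character vector mapping the standard
#'   column names to those actually used in the file, e.g.
#'   `c(T_K = "temperature", x_e = "solubility")`.
#'
#' @return A named list of [solubility_curve] objects (names are sample
#'   ids, sorted).  An input with only a header yields an empty list.
#' @examples
#' path <- system.file("extdata", "simvastatin_solubility.csv",
#'                     package = "soluthermo")
#' curves <- read_solubility_table(path)
#' length(curves)  # 25
#' @export
read_solubility_table <- function(path, dialect = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  wanted <- c("sample_id", "surfactant", "conc_mM", "T_K", "x_e")
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (dialect[[std]] %in% names(df))
        names(df)[names(df) == dialect[[std]]] <- std
    }
  }
  missing <- setdiff(wanted, names(df))
  if (length(missing))
    stop("solubility table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))

  bad <- which(!is.finite(df$x_e) | df$x_e <= 0)
  if (length(bad))
    stop("non-positive or missing x_e in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$T_K) | df$T_K <= 0)
  if (length(bad))
    stop("non-positive or missing T_K in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)

  ids <- sort(unique(df$sample_id))
  curves <- lapply(ids, function(id) {
    g <- df[df$sample_id == id, , drop = FALSE]
    solubility_curve(sample_id = id,
                     temperatures = g$T_K,
                     x_e = g$x_e,
                     surfactant = g$surfactant[1L],
                     conc_mM = g$conc_mM[1L])
  })
  names(curves) <- ids
  curves
}

#' Write solubility curves back to CSV
#'
#' Inverse of [read_solubility_table()]: flattens a list of curves to the
#' standard five-column layout.  Numeric values are written with 15
#' significant digits so a read/write cycle is lossless well beyond 12
#' significant digits.
#'
#' @param curves A list of [solubility_curve] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_solubility_table <- function(curves, path) {
  if (length(curves) == 0L) {
    df <- data.frame(sample_id = character(0), surfactant = character(0),
                     conc_mM = numeric(0), T_K = numeric(0),
                     x_e = numeric(0))
  } else {
    df <- do.call(rbind, lapply(curves, as.data.frame))
  }
  write_results(df, path)
}

#' Write a flat result table to CSV
#'
#' Writes any data frame of results with enough precision (15 significant
#' digits) that numeric fields round-trip through [read_results()] to at
#' least 12 significant digits, and text fields exactly.
#'
#' @param results A data frame (or object coercible to one).
#' @param path Output path; `.json` extension selects JSON, anything else
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  rownames(results) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(results, path, digits = NA, na = "null")
  } else {
    out <- results
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) {
      ifelse(is.na(v), NA_character_,
             formatC(v, digits = 15, format = "g"))
    })
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a flat result table
#'
#' @param path CSV or JSON path written by [write_results()].
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
}
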