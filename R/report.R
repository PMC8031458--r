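#' Overall percent RMSD of a set of correlation fits
#'
#' The arithmetic mean of the per-sample percent RMSDs, the conventional
#' single-number summary of how well a correlation family describes a
#' whole solubility study.
#'
#' @param fits Non-empty list of `"solubility_fit"` objects, or a data
#'   frame with an `rmsd_pct` column.
#' @return Mean RMSD, percent.
#' @examples
#' overall_rmsd(data.frame(rmsd_pct = c(1, 3)))  # 2
#' @export
overall_rmsd <- function(fits) {
  vals <- if (is.data.frame(fits)) {
    fits$rmsd_pct
  } else {
    vapply(fits, function(f) f$rmsd_pct, numeric(1))
  }
  if (length(vals) == 0L || is.null(vals))
    stop("'fits' must be non-empty and carry rmsd_pct values",
         call. = FALSE)
  mean(vals)
}

.fit_row <- function(fit) {
  if (fit$model == "vanthoff") {
    data.frame(sample_id = fit$sample_id,
               a = fit$coefficients[["a"]],
               b = fit$coefficients[["b"]],
               r2 = fit$r2, rmsd_pct = fit$rmsd_pct, n = fit$n,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = fit$sample_id,
               A = fit$coefficients[["A"]],
               B = fit$coefficients[["B"]],
               C = fit$coefficients[["C"]],
               r2 = fit$r2, rmsd_pct = fit$rmsd_pct, n = fit$n,
               stringsAsFactors = FALSE)
  }
}

# aligned-text rendering of a numeric table: solubilities in 3-s.f.
# scientific notation, energies to 2 decimals, everything else 4 s.f.
.render_text <- function(df) {
  fmt <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (!is.numeric(v)) return(as.character(v))
    if (grepl("^x_|_x$|x_idl|x_e", nm)) sprintf("%.2e", v)
    else if (grepl("kJ|J_mol", nm)) sprintf("%.2f", v)
    else sprintf("%.4g", v)
  })
  names(fmt) <- names(df)
  out <- do.call(cbind, lapply(names(fmt), function(nm)
    format(c(nm, fmt[[nm]]), justify = "right")))
  paste(apply(out, 1, paste, collapse = "  "), collapse = "\n")
}

#' Run the full solubility-thermodynamics analysis
#'
#' Orchestrates the complete analysis of a shake-flask study: van't Hoff
#' and Apelblat correlation of every curve (with per-sample and overall
#' RMSD), apparent thermodynamic analysis at the mean harmonic
#' temperature, and the ideal-solubility profile from the solute's fusion
#' properties.  Results are written as CSV tables plus an aligned-text
#' summary with a provenance section listing every warning raised during
#' the run.  The run is deterministic: the same inputs always produce
#' byte-identical outputs.
#'
#' @param curves List of [solubility_curve] objects (e.g. from
#'   [read_solubility_table()]).
#' @param fusion A [fusion_properties] object, or `NULL` to skip the
#'   ideal-solubility table.
#' @param out_dir Output directory; created if needed.  Files written:
#'   `fits_vanthoff.csv`, `fits_apelblat.csv`, `thermodynamics.csv`,
#'   `ideal_solubility.csv`, `summary.txt`.
#' @param T_hm Mean harmonic temperature override, K; defaults to the
#'   harmonic mean of all distinct temperatures in the dataset.
#' @param models Character subset of `c("vanthoff", "apelblat")`.
#' @return Invisibly, a list of class `"solubility_report"` with elements
#'   `vanthoff`, `apelblat`, `thermo`, `ideal` (data frames),
#'   `overall_rmsd` (named numeric), `T_hm`, `provenance` (character
#'   vector of captured warnings), `files`.
#' @examples
#' curves <- read_solubility_table(
#'   system.file("extdata", "simvastatin_solubility.csv",
#'               package = "soluthermo"))
#' fus <- read_fusion_properties(
#'   system.file("extdata", "simvastatin_fusion.json",
#'               package = "soluthermo"))
#' rep <- run_full_analysis(curves, fus, out_dir = tempfile("report"))
#' rep$overall_rmsd
#' @export
run_full_analysis <- function(curves, fusion = NULL, out_dir,
                              T_hm = NULL,
                              models = c("vanthoff", "apelblat")) {
  if (length(curves) == 0L)
    stop("stage input: no solubility curves supplied", call. = FALSE)
  if (!all(vapply(curves, inherits, logical(1), "solubility_curve")))
    stop("stage input: every element of 'curves' must be a ",
         "solubility_curve", call. = FALSE)
  models <- match.arg(models, several.ok = TRUE)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  provenance <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        provenance <<- c(provenance,
                         paste0("[", stage, "] ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  all_T <- sort(unique(unlist(lapply(curves, `[[`, "temperatures"))))
  if (is.null(T_hm))
    T_hm <- collect(harmonic_mean_temperature(all_T), "thermodynamics")

  out <- list(T_hm = T_hm)
  rmsds <- c()

  if ("vanthoff" %in% models) {
    vfits <- collect(lapply(curves, fit_vant_hoff), "vanthoff-fit")
    out$vanthoff <- do.call(rbind, lapply(vfits, .fit_row))
    rownames(out$vanthoff) <- NULL
    rmsds["vanthoff"] <- overall_rmsd(vfits)
    f <- file.path(out_dir, "fits_vanthoff.csv")
    write_results(out$vanthoff, f); written <- c(written, f)
  }
  if ("apelblat" %in% models) {
    afits <- collect(lapply(curves, function(cv)
      if (length(cv) >= 3) fit_apelblat(cv) else NULL), "apelblat-fit")
    afits <- Filter(Negate(is.null), afits)
    if (length(afits)) {
      out$apelblat <- do.call(rbind, lapply(afits, .fit_row))
      rownames(out$apelblat) <- NULL
      rmsds["apelblat"] <- overall_rmsd(afits)
      f <- file.path(out_dir, "fits_apelblat.csv")
      write_results(out$apelblat, f); written <- c(written, f)
    }
  }

  thermo <- collect(
    do.call(rbind, lapply(curves, function(cv)
      as.data.frame(apparent_thermodynamics(cv, T_hm = T_hm)))),
    "thermodynamics")
  rownames(thermo) <- NULL
  out$thermo <- thermo
  f <- file.path(out_dir, "thermodynamics.csv")
  write_results(thermo, f); written <- c(written, f)

  if (!is.null(fusion)) {
    out$ideal <- collect(ideal_solubility(all_T, fusion), "ideal")
    f <- file.path(out_dir, "ideal_solubility.csv")
    write_results(out$ideal, f); written <- c(written, f)
  }

  out$overall_rmsd <- rmsds
  out$provenance <- provenance

  txt <- c("Solubility-thermodynamics analysis", "",
           sprintf("curves: %d   T_hm: %.2f K", length(curves), T_hm), "")
  if (!is.null(out$vanthoff))
    txt <- c(txt, "van't Hoff correlations (ln x = a + b/T)",
             .render_text(out$vanthoff),
             sprintf("overall RMSD: %.2f%%", rmsds["vanthoff"]), "")
  if (!is.null(out$apelblat))
    txt <- c(txt, "Apelblat correlations (ln x = A + B/T + C ln T)",
             .render_text(out$apelblat),
             sprintf("overall RMSD: %.2f%%", rmsds["apelblat"]), "")
  txt <- c(txt, "Apparent thermodynamics at T_hm",
           .render_text(out$thermo), "")
  if (!is.null(out$ideal))
    txt <- c(txt, "Ideal solubility from fusion properties",
             .render_text(out$ideal), "")
  txt <- c(txt, "Provenance",
           if (length(provenance)) provenance else "(no warnings)")
  f <- file.path(out_dir, "summary.txt")
  writeLines(txt, f); written <- c(written, f)

  out$files <- written
  ok <- TRUE
  class(out) <- "solubility_report"
  invisible(out)
}

#' @export
print.solubility_report <- function(x, ...) {
  cat("Solubility-thermodynamics report\n")
  cat(sprintf("  curves: %d, T_hm = %.2f K\n", nrow(x$thermo), x$T_hm))
  for (m in names(x$overall_rmsd))
    cat(sprintf("  %s overall RMSD: %.2f%%\n", m, x$overall_rmsd[[m]]))
  cat("  files:\n")
  for (f in x$files) cat("    ", f, "\n", sep = "")
  invisible(x)
}
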