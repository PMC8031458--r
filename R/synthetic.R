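#' Specify a synthetic shake-flask study
#'
#' Describes a simulated saturation shake-flask experiment with a known
#' temperature-solubility law: either van't Hoff truth
#' (\eqn{\ln x = a + b/T}) or Apelblat truth
#' (\eqn{\ln x = A + B/T + C\ln T}).  Measurement error is multiplicative
#' lognormal on \eqn{x} — Gaussian with standard deviation `noise_sd_ln`
#' on \eqn{\ln x} — matching the relative-uncertainty structure of
#' saturation solubility assays; the default `noise_sd_ln = 0.014`
#' corresponds to a 1.4% relative standard uncertainty.  The default
#' design is the standard one for such studies: three temperature levels
#' around body temperature, triplicate flasks per level.
#'
#' @param true_a,true_b Van't Hoff truth (intercept, slope in K).  Supply
#'   either these or the Apelblat triple.
#' @param true_A,true_B,true_C Apelblat truth.
#' @param temperatures Temperature levels, K, within (250, 400).
#' @param replicates Flasks per temperature level (>= 1).
#' @param noise_sd_ln Standard deviation of the noise on \eqn{\ln x}
#'   (>= 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `"synthetic_spec"`.
#' @examples
#' synthetic_spec(true_a = 0.19, true_b = -1398.9, seed = 1)
#' @export
synthetic_spec <- function(true_a = NULL, true_b = NULL,
                           true_A = NULL, true_B = NULL, true_C = NULL,
                           temperatures = c(300.2, 310.2, 320.2),
                           replicates = 3, noise_sd_ln = 0.014,
                           seed = NULL) {
  vh <- !is.null(true_a) && !is.null(true_b)
  apl <- !is.null(true_A) && !is.null(true_B) && !is.null(true_C)
  if (vh == apl)
    stop("supply exactly one truth: (true_a, true_b) or ",
         "(true_A, true_B, true_C)", call. = FALSE)
  if (any(temperatures <= 250) || any(temperatures >= 400))
    stop("'temperatures' must lie within (250, 400) K", call. = FALSE)
  if (noise_sd_ln < 0) stop("'noise_sd_ln' must be >= 0", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  structure(
    list(model = if (vh) "vanthoff" else "apelblat",
         true_a = true_a, true_b = true_b,
         true_A = true_A, true_B = true_B, true_C = true_C,
         temperatures = sort(as.numeric(temperatures)),
         replicates = as.integer(replicates),
         noise_sd_ln = noise_sd_ln,
         seed = seed),
    class = "synthetic_spec")
}

.true_ln_x <- function(spec, T) {
  if (spec$model == "vanthoff") spec$true_a + spec$true_b / T
  else spec$true_A + spec$true_B / T + spec$true_C * log(T)
}

#' Generate one synthetic solubility curve
#'
#' Draws a shake-flask dataset from a [synthetic_spec]: for every
#' temperature level and replicate,
#' \eqn{x = \exp(\mu(T) + \varepsilon)} with
#' \eqn{\varepsilon \sim N(0, \sigma^2_{\ln})}, then averages replicates
#' per temperature into a [solubility_curve] (the same reduction applied
#' to real replicate measurements).  With the spec's seed set, the output
#' is fully reproducible.
#'
#' @param spec A [synthetic_spec].
#' @param sample_id Label for the generated curve.
#' @return A [solubility_curve] carrying the spec in attribute `"truth"`.
#' @examples
#' spec <- synthetic_spec(true_a = 0.19, true_b = -1398.9, seed = 42)
#' fit_vant_hoff(generate_curve(spec))
#' @export
generate_curve <- function(spec, sample_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  Tv <- rep(spec$temperatures, each = spec$replicates)
  mu <- .true_ln_x(spec, Tv)
  x <- exp(mu + stats::rnorm(length(Tv), 0, spec$noise_sd_ln))
  if (any(x >= 1))
    stop("spec generates mole fractions >= 1; choose a truth with ",
         "smaller solubility", call. = FALSE)
  curve <- solubility_curve(sample_id, Tv, x)
  attr(curve, "truth") <- spec
  curve
}

#' Parameter-recovery study on synthetic data
#'
#' Repeats generate / fit / thermodynamic analysis `n_reps` times against
#' a known van't Hoff truth and summarizes how well the estimators recover
#' the generating parameters: bias, root-mean-square error and the
#' empirical standard deviation of each estimate, for the correlation
#' parameters \eqn{a, b} and the derived apparent thermodynamic quantities
#' \eqn{\Delta_{sol}H^0, \Delta_{sol}G^0, \Delta_{sol}S^0}.
#'
#' Randomness is controlled solely by the spec's seed, set once before the
#' replicate loop; each replicate then consumes fresh draws from the
#' stream.
#'
#' @param spec A [synthetic_spec] with van't Hoff truth.
#' @param n_reps Number of Monte Carlo replicates (>= 1).
#' @return An object of class `"recovery_summary"`: data frame `summary`
#'   with rows `a, b, dH, dG, dS` and columns
#'   `truth, mean_est, bias, rmse, sd`, plus `n_reps` and the spec.
#' @examples
#' spec <- synthetic_spec(true_a = 0.19, true_b = -1398.9,
#'                        noise_sd_ln = 0.01, seed = 7)
#' recovery_study(spec, n_reps = 200)
#' @export
recovery_study <- function(spec, n_reps) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$model != "vanthoff")
    stop("recovery studies are defined for van't Hoff truth", call. = FALSE)
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  inner <- spec
  inner$seed <- NULL

  T_hm <- harmonic_mean_temperature(spec$temperatures)
  truth_fit <- thermo_from_vant_hoff(c(spec$true_a, spec$true_b),
                                     T_hm = T_hm)
  truth <- c(a = spec$true_a, b = spec$true_b,
             dH = truth_fit$dH, dG = truth_fit$dG, dS = truth_fit$dS)

  est <- matrix(NA_real_, nrow = n_reps, ncol = 5,
                dimnames = list(NULL, names(truth)))
  for (i in seq_len(n_reps)) {
    curve <- generate_curve(inner, sample_id = paste0("rep", i))
    fit <- fit_vant_hoff(curve)
    th <- thermo_from_vant_hoff(fit, T_hm = T_hm)
    est[i, ] <- c(fit$coefficients[["a"]], fit$coefficients[["b"]],
                  th$dH, th$dG, th$dS)
  }
  mean_est <- colMeans(est)
  bias <- mean_est - truth
  rmse <- sqrt(colMeans(sweep(est, 2, truth)^2))
  sds <- apply(est, 2, stats::sd)
  structure(
    list(summary = data.frame(parameter = names(truth),
                              truth = unname(truth),
                              mean_est = unname(mean_est),
                              bias = unname(bias),
                              rmse = unname(rmse),
                              sd = unname(sds),
                              stringsAsFactors = FALSE),
         n_reps = n_reps,
         spec = spec),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Parameter recovery over", x$n_reps, "synthetic shake-flask studies",
      "\n(noise_sd_ln =", x$spec$noise_sd_ln,
      ", replicates =", x$spec$replicates, ")\n")
  df <- x$summary
  df[-1] <- lapply(df[-1], signif, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
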