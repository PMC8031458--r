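#' Percent root-mean-square relative deviation
#'
#' Goodness of fit between experimental and model solubilities on the
#' original (back-transformed) scale:
#' \deqn{RMSD\% = 100\sqrt{\frac{1}{N}\sum_{i=1}^{N}
#'   \left(\frac{x^{model}_i - x^e_i}{x^e_i}\right)^2}.}
#'
#' @param observed Experimental values, all strictly positive.
#' @param predicted Model values, same length.
#' @return RMSD in percent.
#' @examples
#' rmsd_percent(c(1, 1), c(1.01, 0.99))  # 1
#' @export
rmsd_percent <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L)
    stop("'observed' and 'predicted' must have equal, nonzero length",
         call. = FALSE)
  if (any(observed <= 0))
    stop("'observed' values must be strictly positive", call. = FALSE)
  100 * sqrt(mean(((predicted - observed) / observed)^2))
}

#' Coefficient of determination in log space
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} computed on the scale the model was
#' fitted in (here \eqn{\ln x}).
#'
#' @param observed_ln Observed log solubilities (length >= 2, not all
#'   identical).
#' @param fitted_ln Fitted log solubilities, same length.
#' @return \eqn{R^2} (at most 1).
#' @export
r_squared <- function(observed_ln, fitted_ln) {
  if (length(observed_ln) != length(fitted_ln) || length(observed_ln) < 2L)
    stop("need equal lengths >= 2", call. = FALSE)
  ss_tot <- sum((observed_ln - mean(observed_ln))^2)
  if (ss_tot == 0)
    stop("zero total variance: observed values are all identical",
         call. = FALSE)
  1 - sum((observed_ln - fitted_ln)^2) / ss_tot
}

# shared assembly of a fitted correlation object
.make_fit <- function(curve, coefficients, fitted_ln, model, extra = list()) {
  ln_x <- log(curve$x_e)
  obj <- c(list(
    coefficients = coefficients,
    model = model,
    n = length(curve$temperatures),
    temperatures = curve$temperatures,
    x_e = curve$x_e,
    sample_id = curve$sample_id,
    fitted_ln = fitted_ln,
    residuals_ln = ln_x - fitted_ln,
    r2 = r_squared(ln_x, fitted_ln),
    rmsd_pct = rmsd_percent(curve$x_e, exp(fitted_ln))), extra)
  class(obj) <- c(paste0(model, "_fit"), "solubility_fit")
  obj
}

#' Fit the van't Hoff correlation to a solubility curve
#'
#' Ordinary unweighted least squares of \eqn{\ln x_e} on \eqn{1/T}:
#' \deqn{\ln x = a + b/T.}
#' The slope \eqn{b} carries the apparent dissolution enthalpy
#' (\eqn{\Delta_{sol}H^0 = -R\,b}) and the intercept the entropy; see
#' [thermo_from_vant_hoff()].  \eqn{R^2} is computed in log space and the
#' percent RMSD on back-transformed solubilities ([rmsd_percent()]).
#'
#' @param curve A [solubility_curve] with at least 2 points.
#' @return An object of class `c("vanthoff_fit", "solubility_fit")` with
#'   coefficients `a` (dimensionless) and `b` (K), plus `r2`, `rmsd_pct`,
#'   `n`, `residuals_ln`.
#' @seealso [fit_apelblat()], [predict.solubility_fit()]
#' @examples
#' m59 <- solubility_curve("20 mM M59", c(300.2, 310.2, 320.2),
#'                         c(1.15e-2, 1.33e-2, 1.54e-2), "M59", 20)
#' fit <- fit_vant_hoff(m59)
#' coef(fit)          # a ~ 0.21, b ~ -1403 K
#' fit$rmsd_pct       # ~ 0.25 %
#' @export
fit_vant_hoff <- function(curve) {
  stopifnot(inherits(curve, "solubility_curve"))
  if (length(curve$temperatures) < 2L)
    stop("van't Hoff fit needs at least 2 points", call. = FALSE)
  X <- cbind(1, 1 / curve$temperatures)
  qr_X <- qr(X)
  beta <- qr.coef(qr_X, log(curve$x_e))
  coefs <- c(a = unname(beta[1]), b = unname(beta[2]))
  fitted_ln <- drop(X %*% beta)
  .make_fit(curve, coefs, fitted_ln, "vanthoff")
}

#' Fit the modified Apelblat correlation to a solubility curve
#'
#' Least squares of \eqn{\ln x_e} on the regressors
#' \eqn{\{1,\ 1/T,\ \ln T\}}:
#' \deqn{\ln x = A + B/T + C\ln T.}
#' Although often described as a nonlinear model, it is linear in its
#' parameters once written in log space, so it is solved exactly by a QR
#' factorization; three points determine the three parameters and give an
#' interpolatory fit (RMSD = 0).  Over narrow temperature spans the
#' \eqn{1/T} and \eqn{\ln T} columns are nearly collinear: when the exact
#' condition number of the design exceeds `1e10` a conditioning warning is
#' raised and recorded in the returned object.
#'
#' @param curve A [solubility_curve] with at least 3 points.
#' @return An object of class `c("apelblat_fit", "solubility_fit")` with
#'   coefficients `A`, `B` (K), `C`, plus `r2`, `rmsd_pct`, `n`,
#'   `residuals_ln`, and the logical `condition_warning`.
#' @seealso [fit_vant_hoff()]
#' @export
fit_apelblat <- function(curve) {
  stopifnot(inherits(curve, "solubility_curve"))
  if (length(curve$temperatures) < 3L)
    stop("Apelblat fit needs at least 3 points", call. = FALSE)
  Tv <- curve$temperatures
  X <- cbind(1, 1 / Tv, log(Tv))
  qr_X <- qr(X)
  if (qr_X$rank < 3L)
    stop("Apelblat design is rank deficient: 1/T and ln T are exactly ",
         "collinear for these temperatures", call. = FALSE)
  cond <- kappa(X, exact = TRUE)
  cond_warn <- cond > 1e10
  if (cond_warn)
    warning("ill-conditioned Apelblat design (condition number ",
            format(cond, digits = 3),
            "): parameters are unstable although fitted values are not",
            call. = FALSE)
  beta <- qr.coef(qr_X, log(curve$x_e))
  coefs <- c(A = unname(beta[1]), B = unname(beta[2]), C = unname(beta[3]))
  fitted_ln <- drop(X %*% beta)
  .make_fit(curve, coefs, fitted_ln, "apelblat",
            extra = list(condition_warning = cond_warn,
                         condition_number = cond))
}

#' @export
coef.solubility_fit <- function(object, ...) object$coefficients

#' @export
residuals.solubility_fit <- function(object, ...) object$residuals_ln

# evaluate a fitted correlation at arbitrary temperatures, in ln-x space
.eval_ln <- function(object, T) {
  cf <- object$coefficients
  if (object$model == "vanthoff") cf[["a"]] + cf[["b"]] / T
  else cf[["A"]] + cf[["B"]] / T + cf[["C"]] * log(T)
}

#' Predict mole-fraction solubility from a fitted correlation
#'
#' Evaluates a van't Hoff or Apelblat fit at new temperatures and
#' back-transforms to mole fraction.  Temperatures outside the fitted
#' range are extrapolations (the classic use being estimation of the
#' ambient-temperature solubility from measurements at higher
#' temperatures); they are flagged in the `"extrapolated"` attribute and
#' announced with a warning.
#'
#' @param object A fit from [fit_vant_hoff()] or [fit_apelblat()].
#' @param newdata Temperatures (K) at which to predict; defaults to the
#'   fitted temperatures.
#' @param ... Unused.
#' @return Numeric vector of predicted mole fractions, with a logical
#'   attribute `"extrapolated"`.
#' @examples
#' h2o <- solubility_curve("H2O", c(300.2, 310.2, 320.2),
#'                         c(7.57e-7, 1.29e-6, 1.94e-6))
#' fit <- fit_vant_hoff(h2o)
#' suppressWarnings(predict(fit, 298.2))  # ambient-temperature estimate
#' @export
predict.solubility_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$temperatures else as.numeric(newdata)
  if (any(T <= 0)) stop("'newdata' temperatures must be positive",
                        call. = FALSE)
  rng <- range(object$temperatures)
  extra <- T < rng[1] | T > rng[2]
  if (any(extra))
    warning("extrapolating outside the fitted temperature range [",
            rng[1], ", ", rng[2], "] K at T = ",
            paste(T[extra], collapse = ", "), call. = FALSE)
  out <- exp(.eval_ln(object, T))
  attr(out, "extrapolated") <- extra
  out
}

#' @export
print.solubility_fit <- function(x, digits = 4, ...) {
  lab <- if (x$model == "vanthoff") "van't Hoff" else "Apelblat"
  cat(lab, " correlation", if (!is.null(x$sample_id))
    paste0(" for '", x$sample_id, "'"), "\n", sep = "")
  print(signif(x$coefficients, digits))
  cat(sprintf("R2 = %.4f (ln-space), RMSD = %.2f%% (n = %d)\n",
              x$r2, x$rmsd_pct, x$n))
  invisible(x)
}

#' @export
summary.solubility_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.solubility_fit")
}

#' @export
print.summary.solubility_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  df <- data.frame(T_K = f$temperatures,
                   x_e = signif(f$x_e, 3),
                   x_fit = signif(exp(f$fitted_ln), 3),
                   resid_ln = signif(f$residuals_ln, 3))
  print(df, row.names = FALSE)
  if (isTRUE(f$condition_warning))
    cat("note: ill-conditioned design (condition number ",
        format(f$condition_number, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Diagnostic plot of a fitted solubility correlation
#'
#' Plots \eqn{\ln x_e} against \eqn{1/T} with the fitted correlation drawn
#' through the span of the data, the standard rendering of
#' temperature-solubility correlations.
#'
#' @param x A `"solubility_fit"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.solubility_fit <- function(x, ...) {
  invT <- 1 / x$temperatures
  graphics::plot(invT, log(x$x_e),
                 xlab = "1/T (1/K)", ylab = "ln x_e",
                 main = paste0(if (x$model == "vanthoff") "van't Hoff"
                               else "Apelblat", " fit",
                               if (!is.null(x$sample_id))
                                 paste0(": ", x$sample_id)),
                 ...)
  Tgrid <- seq(min(x$temperatures), max(x$temperatures), length.out = 100)
  graphics::lines(1 / Tgrid, .eval_ln(x, Tgrid))
  invisible(x)
}

#' Simulate replicate datasets from a fitted correlation
#'
#' Draws `nsim` synthetic solubility curves from the fitted model with
#' multiplicative lognormal measurement noise (Gaussian on \eqn{\ln x}),
#' the parametric-bootstrap counterpart of [generate_curve()].
#'
#' @param object A `"solubility_fit"` object.
#' @param nsim Number of replicate curves.
#' @param seed Optional integer seed.
#' @param noise_sd_ln Standard deviation of the noise on \eqn{\ln x};
#'   defaults to the residual standard deviation of the fit (0 when the
#'   fit is saturated).
#' @param ... Unused.
#' @return A list of `nsim` [solubility_curve] objects.
#' @export
simulate.solubility_fit <- function(object, nsim = 1, seed = NULL,
                                    noise_sd_ln = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd_ln)) {
    dof <- object$n - length(object$coefficients)
    noise_sd_ln <- if (dof > 0)
      sqrt(sum(object$residuals_ln^2) / dof) else 0
  }
  mu <- .eval_ln(object, object$temperatures)
  lapply(seq_len(nsim), function(i) {
    x <- exp(mu + stats::rnorm(length(mu), 0, noise_sd_ln))
    solubility_curve(paste0(object$sample_id %||% "sim", "_rep", i),
                     object$temperatures, x)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
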