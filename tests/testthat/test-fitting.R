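test_that("noiseless van't Hoff data are recovered to machine precision", {
  cv <- exact_vh_curve(1.0, -2000, c(300.2, 310.2, 320.2))
  fit <- fit_vant_hoff(cv)
  expect_equal(unname(coef(fit)), c(1.0, -2000), tolerance = 1e-10)
  expect_equal(fit$rmsd_pct, 0, tolerance = 1e-8)
  expect_equal(fit$r2, 1)
})

test_that("a two-point fit matches the closed-form interpolant", {
  cv <- solubility_curve("two", c(305, 315), c(2e-4, 5e-4))
  fit <- fit_vant_hoff(cv)
  # closed form through both points, computed independently
  expect_equal(coef(fit)[["b"]], -8803.2632064810, tolerance = 1e-8)
  expect_equal(coef(fit)[["a"]], 20.3459648626, tolerance = 1e-8)
  expect_equal(predict(fit), cv$x_e, ignore_attr = TRUE)
})

test_that("the 20 mM M59 refit reproduces the published correlation", {
  fit <- fit_vant_hoff(m59_curve())
  expect_equal(coef(fit)[["b"]], -1398.90, tolerance = 0.01)   # 1%
  expect_equal(fit$r2, 0.9996, tolerance = 5e-4)
  expect_equal(fit$rmsd_pct, 0.25, tolerance = 0.2)            # 20% rel.
})

test_that("both fitters agree with a normal-equations oracle", {
  set.seed(21)
  for (i in 1:5) {
    temps <- sort(runif(5, 295, 325))
    x <- exp(rnorm(5, -8, 0.5))
    cv <- solubility_curve(paste0("rnd", i), temps, x)

    Xv <- cbind(1, 1 / temps)
    beta_v <- solve(t(Xv) %*% Xv, t(Xv) %*% log(x))
    expect_equal(unname(coef(fit_vant_hoff(cv))), drop(beta_v),
                 tolerance = 1e-8)

    Xa <- cbind(1, 1 / temps, log(temps))
    beta_a <- solve(t(Xa) %*% Xa, t(Xa) %*% log(x))
    expect_equal(unname(coef(fit_apelblat(cv))), drop(beta_a),
                 tolerance = 1e-6)
  }
})

test_that("a three-point Apelblat fit is interpolatory", {
  fit <- fit_apelblat(m59_curve())
  expect_equal(fit$rmsd_pct, 0, tolerance = 1e-8)
  expect_true(all(abs(residuals(fit)) < 1e-10))
})

test_that("Apelblat parameters are recovered from noiseless 5-point data", {
  cv <- exact_apl_curve(-73.76, 2004.46, 10.97, seq(300, 320, 5))
  fit <- fit_apelblat(cv)
  expect_equal(coef(fit)[["A"]], -73.76, tolerance = 1e-6)
  expect_equal(coef(fit)[["B"]], 2004.46, tolerance = 1e-6)
  expect_equal(coef(fit)[["C"]], 10.97, tolerance = 1e-6)
})

test_that("fitters demand enough points and flag degenerate designs", {
  cv2 <- solubility_curve("two", c(305, 315), c(2e-4, 5e-4))
  expect_error(fit_apelblat(cv2), "at least 3")
  cv3 <- m59_curve()
  expect_false(fit_apelblat(cv3)$condition_warning)
})

test_that("rmsd_percent matches hand arithmetic and guards its domain", {
  expect_equal(rmsd_percent(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd_percent(c(1, 1), c(1.01, 0.99)), 1.0)
  expect_error(rmsd_percent(c(0, 1), c(1, 1)), "positive")
  expect_error(rmsd_percent(1:3, 1:2), "equal")
})

test_that("r_squared behaves as 1 - SS_res/SS_tot in log space", {
  obs <- log(c(1e-4, 2e-4, 4e-4))
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_error(r_squared(rep(1, 3), rep(1, 3)), "variance")
})

test_that("extrapolation to ambient temperature matches the published value", {
  th <- thermo_from_vant_hoff(c(a = 0.62, b = -4407.80), T_hm = 309.98)
  x298 <- exp(0.62 - 4407.80 / 298.2)
  expect_equal(x298, 7.08e-7, tolerance = 0.01)
  # the same number through predict() on a curve-fitted model is flagged
  fit <- fit_vant_hoff(exact_vh_curve(0.62, -4407.80,
                                      c(300.2, 310.2, 320.2)))
  expect_warning(p <- predict(fit, 298.2), "extrapolating")
  expect_equal(as.numeric(p), 7.08e-7, tolerance = 0.01)
  expect_true(attr(p, "extrapolated"))
  expect_equal(th$dH, 36.64, tolerance = 2e-3)
})

test_that("an Apelblat model with C = 0 reduces to van't Hoff", {
  cv <- m59_curve()
  vf <- fit_vant_hoff(cv)
  apl <- fit_apelblat(cv)
  apl$coefficients <- c(A = coef(vf)[["a"]], B = coef(vf)[["b"]], C = 0)
  for (T in c(280, 300.2, 333)) {
    p <- suppressWarnings(predict(apl, T))
    expect_equal(as.numeric(p), exp(coef(vf)[["a"]] + coef(vf)[["b"]] / T))
  }
})

test_that("Apelblat never fits worse than van't Hoff on the same curve", {
  set.seed(31)
  curves <- c(table1_curves()[c("H2O", "20 mM M59", "5 mM B35")],
              lapply(1:3, function(i) {
                temps <- sort(runif(4, 298, 325))
                solubility_curve(paste0("s", i), temps,
                                 exp(rnorm(4, -7, 0.3)))
              }))
  for (cv in curves) {
    expect_lte(fit_apelblat(cv)$rmsd_pct,
               fit_vant_hoff(cv)$rmsd_pct + 1e-10)
  }
})

test_that("shifting the 1/T regressor moves only the intercept", {
  cv <- m59_curve()
  fit <- fit_vant_hoff(cv)
  # refit against shifted regressor u = 1/T - c: slope must be unchanged
  shift <- 1 / 309.98
  X <- cbind(1, 1 / cv$temperatures - shift)
  beta <- qr.coef(qr(X), log(cv$x_e))
  expect_equal(beta[2], coef(fit)[["b"]], ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(beta[1], coef(fit)[["a"]] + coef(fit)[["b"]] * shift,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("every curve in the study correlates with r2 >= 0.99", {
  fits <- lapply(table1_curves(), fit_vant_hoff)
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  expect_true(all(r2 >= 0.99))
  expect_true(all(vapply(fits, `[[`, numeric(1), "rmsd_pct") >= 0))
})
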