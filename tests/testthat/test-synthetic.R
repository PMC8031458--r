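test_that("the generator is seed-deterministic", {
  spec <- synthetic_spec(true_a = 0.19, true_b = -1398.9, seed = 42)
  expect_identical(generate_curve(spec), generate_curve(spec))
  spec2 <- spec; spec2$seed <- 43
  expect_false(identical(generate_curve(spec)$x_e,
                         generate_curve(spec2)$x_e))
})

test_that("a noiseless spec reproduces the generating law exactly", {
  spec <- synthetic_spec(true_a = 0.19, true_b = -1398.90,
                         noise_sd_ln = 0, seed = 1)
  cv <- generate_curve(spec)
  # forward evaluation oracle, frozen from independent arithmetic
  expect_equal(cv$x_e, c(0.0114485361491, 0.0133042575308, 0.0153163869691),
               tolerance = 1e-9)
  fit <- fit_vant_hoff(cv)
  expect_equal(unname(coef(fit)), c(0.19, -1398.90), tolerance = 1e-9)
  expect_equal(fit$rmsd_pct, 0, tolerance = 1e-9)
})

test_that("Apelblat truth generates and is recovered the same way", {
  spec <- synthetic_spec(true_A = -73.76, true_B = 2004.46, true_C = 10.97,
                         temperatures = seq(300, 320, 5),
                         noise_sd_ln = 0, seed = 2)
  fit <- fit_apelblat(generate_curve(spec))
  expect_equal(unname(coef(fit)), c(-73.76, 2004.46, 10.97),
               tolerance = 1e-6)
})

test_that("spec validation catches impossible designs", {
  expect_error(synthetic_spec(true_a = 0.19), "exactly one truth")
  expect_error(synthetic_spec(true_a = 0.1, true_b = -2000, true_A = 1,
                              true_B = 1, true_C = 1), "exactly one truth")
  expect_error(synthetic_spec(true_a = 0, true_b = -2000,
                              temperatures = c(100, 300)), "250")
  expect_error(synthetic_spec(true_a = 0, true_b = -2000,
                              noise_sd_ln = -1), "noise")
  # a truth implying x >= 1 is rejected at generation time
  hot <- synthetic_spec(true_a = 5, true_b = -100, noise_sd_ln = 0,
                        seed = 1)
  expect_error(generate_curve(hot), ">= 1")
})

test_that("generated curves survive a round trip through the CSV layer", {
  spec <- synthetic_spec(true_a = 0.19, true_b = -1398.9, seed = 9)
  cv <- generate_curve(spec, sample_id = "synth")
  path <- tempfile(fileext = ".csv")
  write_solubility_table(list(cv), path)
  back <- read_solubility_table(path)[["synth"]]
  expect_equal(back$x_e, cv$x_e, tolerance = 1e-12)
  expect_equal(back$temperatures, cv$temperatures)
})

test_that("recovery is exact without noise and unbiased with it", {
  spec0 <- synthetic_spec(true_a = 0.19, true_b = -1398.9,
                          noise_sd_ln = 0, seed = 4)
  rs0 <- recovery_study(spec0, n_reps = 3)
  expect_true(all(abs(rs0$summary$bias) < 1e-9))
  expect_true(all(rs0$summary$rmse < 1e-9))

  spec <- synthetic_spec(true_a = 0.19, true_b = -1398.9,
                         noise_sd_ln = 0.01, replicates = 1, seed = 8)
  rs <- recovery_study(spec, n_reps = 2000)
  s <- rs$summary
  expect_true(all(s$rmse >= abs(s$bias) - 1e-12))
  # OLS slope is unbiased: the mean dH estimate sits on the truth
  # within Monte Carlo error (~4 standard errors of the mean)
  dH_row <- s[s$parameter == "dH", ]
  expect_lt(abs(dH_row$bias), 4 * dH_row$sd / sqrt(rs$n_reps))
})

test_that("the slope sd matches the closed-form OLS formula within 5%", {
  spec <- synthetic_spec(true_a = 0.19, true_b = -1398.9,
                         noise_sd_ln = 0.01, replicates = 1, seed = 12)
  rs <- recovery_study(spec, n_reps = 2000)
  z <- 1 / spec$temperatures
  sd_theory <- spec$noise_sd_ln / sqrt(sum((z - mean(z))^2))
  sd_emp <- rs$summary$sd[rs$summary$parameter == "b"]
  expect_equal(sd_emp, sd_theory, tolerance = 0.05)
})

test_that("bias and RMSE shrink monotonically along a noise ladder", {
  ladder <- c(0.05, 0.02, 0.008, 0.002)
  res <- lapply(ladder, function(sig) {
    spec <- synthetic_spec(true_a = 0.19, true_b = -1398.9,
                           noise_sd_ln = sig, replicates = 1, seed = 99)
    recovery_study(spec, n_reps = 300)$summary
  })
  for (par in c("a", "b", "dH")) {
    rmse <- vapply(res, function(s) s$rmse[s$parameter == par],
                   numeric(1))
    bias <- vapply(res, function(s) abs(s$bias[s$parameter == par]),
                   numeric(1))
    expect_true(all(diff(rmse) < 0))
    expect_true(all(diff(bias) <= 1e-12))
  }
})
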