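test_that("packaged study reads into 25 three-point curves", {
  curves <- table1_curves()
  expect_length(curves, 25)
  expect_true(all(vapply(curves, length, integer(1)) == 3L))
  expect_true(all(vapply(curves, function(cv)
    identical(cv$temperatures, c(300.2, 310.2, 320.2)), logical(1))))
  # one water sample, six surfactants at four concentrations
  surf <- vapply(curves, `[[`, character(1), "surfactant")
  expect_identical(sum(surf == "water"), 1L)
  expect_setequal(unique(surf[surf != "water"]),
                  c("T80", "T20", "M52", "M59", "B35", "B58"))
})

test_that("curve grouping is independent of input row order", {
  path <- system.file("extdata", "simvastatin_solubility.csv",
                      package = "soluthermo")
  df <- read.csv(path, stringsAsFactors = FALSE)
  shuffled <- tempfile(fileext = ".csv")
  set.seed(11)
  write.csv(df[sample(nrow(df)), ], shuffled, row.names = FALSE)
  expect_identical(read_solubility_table(shuffled), table1_curves())
})

test_that("header-only input yields an empty curve list", {
  path <- tempfile(fileext = ".csv")
  writeLines("sample_id,surfactant,conc_mM,T_K,x_e", path)
  expect_length(read_solubility_table(path), 0)
})

test_that("reader errors name the offending column or row", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,surfactant,conc_mM,T_K", "a,water,0,300"), path)
  expect_error(read_solubility_table(path), "x_e")

  writeLines(c("sample_id,surfactant,conc_mM,T_K,x_e",
               "a,water,0,300.2,1e-5",
               "a,water,0,310.2,-1e-5",
               "a,water,0,320.2,2e-5"), path)
  expect_error(read_solubility_table(path), "row\\(s\\) 2")

  # dialect maps nonstandard column names onto the schema
  writeLines(c("sample_id,surfactant,conc_mM,temperature,solubility",
               "a,water,0,300.2,1e-5", "a,water,0,310.2,2e-5"), path)
  curves <- read_solubility_table(
    path, dialect = c(T_K = "temperature", x_e = "solubility"))
  expect_length(curves, 1)
  expect_equal(curves[["a"]]$x_e, c(1e-5, 2e-5))
})

test_that("replicate rows at one temperature are averaged with a count", {
  cv <- solubility_curve("r", c(300.2, 300.2, 300.2, 310.2),
                         c(1e-4, 1.2e-4, 1.1e-4, 2e-4))
  expect_equal(cv$temperatures, c(300.2, 310.2))
  expect_equal(cv$x_e, c(mean(c(1e-4, 1.2e-4, 1.1e-4)), 2e-4))
  expect_equal(cv$replicates, c(3L, 1L))
})

test_that("curve validation rejects physically impossible inputs", {
  expect_error(solubility_curve("a", c(300), c(1e-4)), "at least 2")
  expect_error(solubility_curve("a", c(27, 37), c(1e-4, 2e-4)), "kelvin")
  expect_error(solubility_curve("a", c(300, 310), c(0, 1e-4)), "\\(0, 1\\)")
  expect_error(solubility_curve("a", c(300, 310), c(1e-4, 1.2)), "\\(0, 1\\)")
  expect_error(solubility_curve("a", c(300, 310), c(1e-4, 2e-4),
                                conc_mM = -1), "conc_mM")
  expect_error(solubility_curve("a", c(300, 310), 1e-4), "equal length")
})

test_that("solubility tables round-trip losslessly", {
  curves <- table1_curves()
  path <- tempfile(fileext = ".csv")
  write_solubility_table(curves, path)
  back <- read_solubility_table(path)
  expect_identical(names(back), names(curves))
  for (id in names(curves)) {
    expect_equal(back[[id]]$x_e, curves[[id]]$x_e, tolerance = 1e-12)
    expect_equal(back[[id]]$temperatures, curves[[id]]$temperatures)
  }
})

test_that("result tables round-trip text exactly and numerics to 12 s.f.", {
  fits <- data.frame(sample_id = c("a", "b"),
                     a = c(0.123456789012345, -2.3),
                     b = c(-1398.90123456789, -4407.8),
                     r2 = c(0.999612345678901, 0.9977),
                     rmsd_pct = c(0.25, 1.74),
                     stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_results(fits, path)
  back <- read_results(path)
  expect_identical(back$sample_id, fits$sample_id)
  for (col in c("a", "b", "r2", "rmsd_pct"))
    expect_equal(back[[col]], fits[[col]], tolerance = 1e-12)

  # empty result set gives a header-only file
  write_results(fits[0, ], path)
  expect_length(readLines(path), 1L)
  expect_identical(nrow(read_results(path)), 0L)
})
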