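test_that("rate laws satisfy their half-saturation identities", {
  expect_equal(rate("michaelis_menten", 5.6, c(Vmax = 40, Km = 5.6)), 20)
  for (h in c(1, 1.7, 2, 4))
    expect_equal(rate("allosteric_sigmoidal", 100,
                      c(Vmax = 21, S05 = 100, h = h)), 10.5)
  expect_error(rate("michaelis_menten", -1, c(Vmax = 1, Km = 1)), "negative")
  expect_error(rate("michaelis_menten", 1, c(Vmax = -1, Km = 1)), "positive")
})

test_that("substrate inhibition peaks at sqrt(Km*Ki) (calculus oracle)", {
  p <- c(Vmax = 417, Km = 0.1, Ki = 2)
  num <- stats::optimize(function(S) rate("substrate_inhibition", S, p),
                         c(1e-4, 50), maximum = TRUE)$maximum
  expect_equal(num, sqrt(p[["Km"]] * p[["Ki"]]), tolerance = 1e-4)
  # monotone laws stay monotone
  S <- seq(0.01, 50, length.out = 200)
  expect_true(all(diff(rate("michaelis_menten", S, c(Vmax = 1, Km = 2))) > 0))
  expect_true(all(diff(rate("allosteric_sigmoidal", S,
                            c(Vmax = 1, S05 = 5, h = 2))) > 0))
})

test_that("noise-free data are recovered exactly for each generating law", {
  truths <- list(
    michaelis_menten = c(Vmax = 40, Km = 5.6),
    substrate_inhibition = c(Vmax = 417, Km = 0.1, Ki = 2),
    allosteric_sigmoidal = c(Vmax = 21, S05 = 100, h = 2))
  for (mod in names(truths)) {
    sim <- make_saturation(kinetics_spec(model = mod, params = truths[[mod]],
                                         cv = 0, seed = 9))
    f <- fit_kinetics(sim$dataset, mod, seed = 9)
    expect_true(f$converged)
    expect_equal(unname(f$parameters[names(truths[[mod]])]),
                 unname(truths[[mod]]), tolerance = 1e-6)
    expect_lt(f$rss, 1e-10)
  }
})

test_that("auto selection prefers the generating model (seeded replicates)", {
  picks <- vapply(1:20, function(i) {
    sim <- make_saturation(kinetics_spec(
      model = "substrate_inhibition", params = c(Vmax = 417, Km = 0.1, Ki = 2),
      seed = 400 + i))
    fit_kinetics(sim$dataset, "auto", seed = i)$model
  }, character(1))
  expect_gte(sum(picks == "substrate_inhibition"), 19)

  picks2 <- vapply(1:20, function(i) {
    sim <- make_saturation(kinetics_spec(
      model = "allosteric_sigmoidal", params = c(Vmax = 21, S05 = 100, h = 2),
      span = c(0.2, 5), seed = 500 + i))
    fit_kinetics(sim$dataset, "auto", seed = i)$model
  }, character(1))
  expect_gte(sum(picks2 == "allosteric_sigmoidal"), 19)
})

test_that("scale equivariance: rates x c scales Vmax only", {
  sim <- make_saturation(kinetics_spec(seed = 10))
  f1 <- fit_kinetics(sim$dataset, "michaelis_menten", seed = 1)
  ds2 <- sim$dataset; ds2$rate <- ds2$rate * 3.7
  f2 <- fit_kinetics(ds2, "michaelis_menten", seed = 1)
  expect_equal(unname(f2$parameters["Vmax"]),
               3.7 * unname(f1$parameters["Vmax"]), tolerance = 1e-5)
  expect_equal(unname(f2$parameters["Km"]), unname(f1$parameters["Km"]),
               tolerance = 1e-5)
})

test_that("efficiency reproduces table-style kcat/Km values", {
  expect_equal(efficiency(c(kcat = 21, Km = 100)), 210)
  expect_equal(signif(efficiency(c(kcat = 40, Km = 5.6)), 2), 7.1e3)
  expect_equal(signif(efficiency(c(kcat = 175, Km = 1.3)), 2), 1.3e5)
  expect_error(efficiency(c(kcat = 21)), "Km")

  sim <- make_saturation(kinetics_spec(cv = 0, seed = 2))
  f <- fit_kinetics(sim$dataset, "michaelis_menten", seed = 2)
  expect_equal(efficiency(f), 40 / (5.6e-3), tolerance = 1e-5)
  # S0.5 stands in for Km on sigmoid fits
  sim2 <- make_saturation(kinetics_spec(
    model = "allosteric_sigmoidal", params = c(Vmax = 21, S05 = 100, h = 2),
    span = c(0.2, 5), cv = 0, seed = 2))
  f2 <- fit_kinetics(sim2$dataset, "allosteric_sigmoidal", seed = 2)
  expect_equal(efficiency(f2), 210, tolerance = 1e-4)
})

test_that("dataset validation enforces the contract", {
  expect_error(saturation_dataset(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "at least 5")
  expect_error(saturation_dataset(c(-1, 1, 2, 3, 4), rep(1, 5)), "positive")
  expect_error(kinetics_spec(span = c(0.5, 10), seed = 1), "span")
  expect_error(kinetics_spec(seed = 1, params = c(Vmax = 1)), "half-saturation")
})

test_that("CSV round trip preserves data and metadata", {
  sim <- make_saturation(kinetics_spec(seed = 12))
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# substrate: PYR", "# enzyme_uM: 0.5"), tmp)
  suppressWarnings(utils::write.table(sim$dataset, tmp, append = TRUE,
                                      sep = ",", row.names = FALSE))
  ds <- read_saturation_csv(tmp)
  expect_equal(ds$substrate_mM, sim$dataset$substrate_mM)
  expect_equal(attr(ds, "substrate"), "PYR")
  expect_equal(attr(ds, "enzyme_uM"), 0.5)
  # kcat = Vmax / [E] when rates are raw
  f <- fit_kinetics(ds, "michaelis_menten", seed = 1)
  expect_equal(f$kcat, unname(f$parameters["Vmax"]) / 0.5)
})

test_that("fit report files are written and parseable", {
  sim <- make_saturation(kinetics_spec(cv = 0, seed = 13))
  f <- fit_kinetics(sim$dataset, "michaelis_menten", seed = 13)
  tmp <- withr::local_tempdir()
  write_kinetic_fit(f, sim$dataset, file.path(tmp, "fit"))
  rep <- jsonlite::read_json(file.path(tmp, "fit.json"))
  expect_equal(rep$model, "michaelis_menten")
  expect_equal(rep$parameters$Km, 5.6, tolerance = 1e-5)
  curve <- utils::read.csv(file.path(tmp, "fit_curve.csv"))
  expect_equal(nrow(curve), 100)
})
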