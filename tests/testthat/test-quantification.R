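cfgDefault <- defaultQuantConfig()
attDefault <- attenuationFactors(cfgDefault)

test_that("attenuation factor obeys the exponential model and its limits", {
  # fully relaxed limit
  expect_equal(attenuationFactor(1.3, 0.11, 0, 1e6), 1, tolerance = 1e-6)
  # direct scalar evaluation as oracle
  expect_equal(attenuationFactor(1.331, 0.110, 0.035, 2.0),
               exp(-0.035 / 0.110) * (1 - exp(-2.0 / 1.331)),
               tolerance = 1e-12)
  expect_equal(attenuationFactor(1.331, 0.110, 0.035, 2.0), 0.566,
               tolerance = 1e-3)
  # saturated limit
  expect_lt(attenuationFactor(1e6, 0.1, 0.035, 2.0), 1e-5)
  # monotonicity: decreasing in TE, increasing in TR
  expect_gt(attenuationFactor(1.3, 0.11, 0.02, 2), attenuationFactor(1.3, 0.11, 0.05, 2))
  expect_gt(attenuationFactor(1.3, 0.11, 0.035, 4), attenuationFactor(1.3, 0.11, 0.035, 2))
  expect_error(attenuationFactor(-1, 0.1, 0.035, 2), "positive")
})

test_that("water attenuation defaults match direct evaluation", {
  r <- attDefault@rH2O
  expect_equal(unname(r["gm"]), exp(-0.035 / 0.110) * (1 - exp(-2 / 1.331)))
  expect_equal(unname(r["wm"]), exp(-0.035 / 0.0799) * (1 - exp(-2 / 0.832)))
  expect_equal(unname(r["csf"]), exp(-0.035 / 0.503) * (1 - exp(-2 / 4.163)))
  expect_error(attenuationFactors(cfgDefault, "NAA"), "no relaxation values")
})

test_that("molar concentration reproduces hand-evaluated examples", {
  # identity correction: pure GM, unit density and attenuation
  cfg1 <- quantConfig(densities = c(gm = 1, wm = 1, csf = 1))
  att1 <- new("AttenuationFactors", rH2O = c(gm = 1, wm = 1, csf = 1), rMet = 1)
  expect_equal(molarConcentration(1, 1, c(1, 0, 0), att1, cfg1), 55510)
  # hand evaluation of the closed form at the FSL-mean composition
  att2 <- new("AttenuationFactors",
              rH2O = c(gm = 0.566, wm = 0.587, csf = 0.356), rMet = 0.73)
  num <- 0.43 * 0.78 * 0.566 + 0.30 * 0.65 * 0.587 + 0.26 * 0.97 * 0.356
  expected <- 2e-4 * num / (0.74 * 0.73) * 55.51 * 1000
  got <- molarConcentration(2e-4, 1, c(0.43, 0.30, 0.26), att2, cfgDefault)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got, 8.10, tolerance = 2e-3)
  # degenerate cases
  expect_error(molarConcentration(1, 1, c(0, 0, 1), attDefault, cfgDefault),
               "no metabolite-bearing tissue")
  expect_error(molarConcentration(1, 0, c(0.5, 0.3, 0.2), attDefault, cfgDefault),
               "water signal")
})

test_that("correction factor matches scalar oracles at printed compositions", {
  cf <- function(f) {
    r <- attDefault@rH2O; d <- c(gm = 0.78, wm = 0.65, csf = 0.97)
    sum(f * d * r[c("gm", "wm", "csf")]) / (1 - f[3])
  }
  fsl <- c(0.43, 0.30, 0.26); spm <- c(0.56, 0.27, 0.17)
  expect_equal(correctionFactor(fsl, attDefault, cfgDefault), cf(fsl),
               tolerance = 1e-12)
  expect_equal(correctionFactor(fsl, attDefault, cfgDefault), 0.53, tolerance = 0.01)
  expect_equal(correctionFactor(spm, attDefault, cfgDefault), 0.49, tolerance = 0.01)
  # pure GM with unit constants gives exactly 1
  cfg1 <- quantConfig(densities = c(gm = 1, wm = 1, csf = 1))
  att1 <- new("AttenuationFactors", rH2O = c(gm = 1, wm = 1, csf = 1), rMet = 1)
  expect_equal(correctionFactor(c(1, 0, 0), att1, cfg1), 1)
})

test_that("quantification is scale invariant and linear in the signal", {
  f <- tissueFractions(0.45, 0.33, 0.22)
  base <- molarConcentration(2e-4, 1, f, attDefault, cfgDefault)
  for (k in c(1e-3, 1, 1e4)) {
    expect_equal(molarConcentration(2e-4 * k, k, f, attDefault, cfgDefault),
                 base, tolerance = 1e-12)
  }
  expect_equal(molarConcentration(4e-4, 1, f, attDefault, cfgDefault),
               2 * base, tolerance = 1e-12)
})

test_that("forward signal inverts quantification over random valid inputs", {
  set.seed(11)
  for (i in 1:200) {
    raw <- stats::runif(3)
    raw[3] <- raw[3] * 0.9            # keep CSF away from 1
    f <- normalizeFractions(raw + 0.05)
    att <- new("AttenuationFactors",
               rH2O = c(gm = stats::runif(1, 0.2, 0.99),
                        wm = stats::runif(1, 0.2, 0.99),
                        csf = stats::runif(1, 0.2, 0.99)),
               rMet = stats::runif(1, 0.2, 0.99))
    conc <- stats::runif(1, 0.1, 20)
    sh2o <- stats::runif(1, 10, 1e5)
    s <- forwardSignal(conc, f, att, cfgDefault, sh2o)
    expect_equal(molarConcentration(s, sh2o, f, att, cfgDefault), conc,
                 tolerance = 1e-10)
  }
  expect_equal(forwardSignal(0, tissueFractions(0.5, 0.3, 0.2), attDefault,
                             cfgDefault, 100), 0)
  expect_error(forwardSignal(7, c(0, 0, 1), attDefault, cfgDefault, 100),
               "no metabolite-bearing tissue")
  # spec-level round trip at the reported mean composition
  f <- tissueFractions(0.45, 0.33, 0.22)
  s <- forwardSignal(7.19, f, attDefault, cfgDefault, 1000)
  expect_equal(molarConcentration(s, 1000, f, attDefault, cfgDefault), 7.19,
               tolerance = 1e-10)
})

test_that("quantification config round-trips through JSON and YAML", {
  cfg <- quantConfig(teMS = 30, trMS = 1800,
                     metabT1 = c(tCr = 1.35, NAA = 1.4),
                     metabT2 = c(tCr = 0.166, NAA = 0.25))
  p <- file.path(tempdir(), "qc.json")
  writeQuantConfig(cfg, p)
  cfg2 <- readQuantConfig(p)
  expect_equal(cfg2@teS, 0.03)
  expect_equal(cfg2@trS, 1.8)
  expect_equal(cfg2@metabT1, cfg@metabT1)
  expect_equal(cfg2@waterT2, cfg@waterT2)
  # bundled default config matches the built-in defaults
  bundled <- readQuantConfig(system.file("extdata", "quant_config.json",
                                         package = "mrsq"))
  expect_equal(bundled@densities, defaultQuantConfig()@densities)
  expect_equal(bundled@teS, 0.035)
  # yaml path
  py <- file.path(tempdir(), "qc.yaml")
  writeLines(yaml::as.yaml(jsonlite::read_json(p)), py)
  cfg3 <- readQuantConfig(py)
  expect_equal(cfg3@trS, 1.8)
  # unit tags are exclusive
  expect_error(quantConfig(teMS = 35, teS = 0.035), "not both")
})

test_that("study-table quantification validates its schema", {
  study <- data.frame(participant = "P01", session = 1, method = "SPM",
                      metabolite = "tCr", s_met = 1e-4, s_h2o = 1,
                      f_gm = 0.56, f_wm = 0.27, f_csf = 0.17)
  q <- quantifyStudy(study, cfgDefault)
  expect_true("conc_mM" %in% names(q))
  expect_equal(q$conc_mM,
               molarConcentration(1e-4, 1, c(0.56, 0.27, 0.17), attDefault,
                                  cfgDefault))
  expect_error(quantifyStudy(study[setdiff(names(study), "f_csf")]),
               "f_csf")
})
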