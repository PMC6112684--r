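test_that("presets reproduce the published default parameters in seconds", {
  m <- stdp_preset("corticostriatal")
  expect_equal(m$calcium$c_pre, 7)
  expect_equal(m$calcium$c_post, 17.1)
  expect_equal(m$calcium$tau_ca, 0.018)
  expect_equal(m$calcium$delay_d, 0.010)
  expect_equal(m$tau, 165)
  expect_equal(m$rho_star, 0.5)
  expect_equal(m$sigma, 1)
  # decimal-comma value and slope row
  expect_equal(m$readout$ltp_star, 3.475)
  expect_equal(m$readout$ltd_star, 0.55)
  expect_equal(m$readout$slope, 0.7)
  ecb <- get_pathway(m, "eCB")
  expect_equal(ecb$gamma_p, 290)
  expect_equal(ecb$gamma_d, 250)
  expect_equal(ecb$theta0_p, 6)
  expect_equal(ecb$theta0_d, 13.5)
  expect_equal(ecb$mu_p, 6)
  expect_equal(ecb$mu_d, Inf)
  nmdar <- get_pathway(m, "NMDAR")
  expect_equal(nmdar$gamma_p, 50)
  expect_equal(nmdar$gamma_d, 0)  # no NMDAR-LTD mechanism
  expect_equal(nmdar$theta0_p, 5.8)
  expect_equal(nmdar$mu_p, 32)

  s2 <- stdp_preset("scenario2")
  expect_equal(s2$calcium$c_post, 15)
  expect_equal(s2$calcium$tau_ca, 0.017)
  expect_equal(s2$calcium$delay_d, 0.010)
  expect_equal(s2$tau, 280)
  expect_equal(get_pathway(s2, "A")$mu_p, 8)
  expect_equal(get_pathway(s2, "B")$gamma_d, 100)
  # scenario 3 shares the calcium parameters of scenario 2
  s3 <- stdp_preset("scenario3")
  expect_equal(s3$calcium[c("c_pre", "c_post", "tau_ca", "delay_d")],
               s2$calcium[c("c_pre", "c_post", "tau_ca", "delay_d")])
  expect_equal(get_pathway(s3, "A")$mu_p, Inf)

  ha <- stdp_preset("hebbian_asymmetric")
  expect_equal(ha$calcium$delay_d, 0.0137)
  expect_equal(ha$sigma, 2.8284)
  expect_equal(get_pathway(ha, "A")$gamma_p, 321.808)
  expect_equal(get_pathway(ha, "A")$theta0_p, 1.3)
  hs <- stdp_preset("hebbian_symmetric")
  expect_equal(hs$calcium$delay_d, 0)
  expect_equal(hs$calcium$c_pre, 2)
})

test_that("every preset passes all type invariants", {
  for (nm in c("corticostriatal", "scenario1", "scenario2", "scenario3",
               "hebbian_asymmetric", "hebbian_symmetric")) {
    m <- stdp_preset(nm)
    expect_s3_class(m, "synapse_model")
    expect_true(m$tau > 0)
    expect_true(m$rho_star > 0 && m$rho_star < 1)
    for (p in m$pathways) {
      expect_true(p$gamma_p >= 0 && p$gamma_d >= 0)
      expect_true(p$theta0_p > 0 && p$theta0_d > 0)
      expect_true(p$mu_p > 0 && p$mu_d > 0)
    }
    ro <- m$readout
    expect_true(ro$ltd_star > 0 && ro$ltd_star < 1 && ro$ltp_star > 1)
    expect_true(exp(ro$slope) > (ro$ltp_star - ro$ltd_star) / (ro$ltp_star - 1))
  }
})

test_that("unknown preset names produce an error listing the presets", {
  expect_error(stdp_preset("striatum"), "available presets.*corticostriatal")
})

test_that("config files round-trip and reject malformed input", {
  for (nm in c("corticostriatal", "scenario3", "hebbian_asymmetric")) {
    m <- stdp_preset(nm)
    f <- withr::local_tempfile(fileext = ".yaml")
    write_model_config(m, f)
    expect_equal(read_model_config(f), m)
  }
  f <- withr::local_tempfile(fileext = ".yaml")

  writeLines(c("calcium: {c_pre: 1, c_post: 1, tau_ca: 18 ms}",
               "pathways: [{name: A, gamma_p: 1, theta0_p: 1}]",
               "dynamics: {tau: 100, rho_star: 1.5, sigma: 1}",
               "readout: {ltp_star: 3, ltd_star: 0.5, slope: 1}"), f)
  expect_error(read_model_config(f), "rho_star")

  writeLines(c("calcium: {c_pre: 1, c_post: 1, tau_ca: 18 ms}",
               "pathways: [{name: A, gamma_p: 1, theta0_p: 1}]",
               "dynamics: {tau: 100, rho_star: 0.5, sigma: 1, bogus: 2}",
               "readout: {ltp_star: 3, ltd_star: 0.5, slope: 1}"), f)
  expect_error(read_model_config(f), "unknown key.*bogus")

  writeLines(c("calcium: {c_pre: 1, c_post: 1, tau_ca: 18 ms}",
               "pathways: [{name: A, gamma_p: 1, theta0_p: 1}]",
               "readout: {ltp_star: 3, ltd_star: 0.5, slope: 1}"), f)
  expect_error(read_model_config(f), "missing required field 'dynamics'|dynamics")

  expect_error(read_model_config(withr::local_tempfile()), "does not exist")
})

test_that("time-valued fields accept ms/s suffixes and inf is recognized", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("calcium: {c_pre: 1, c_post: 2, tau_ca: 18 ms, delay_d: -0.5 ms}",
               "pathways: [{name: A, gamma_p: 1, theta0_p: 1, mu_p: inf}]",
               "dynamics: {tau: 0.1 s, rho_star: 0.5, sigma: 0}",
               "readout: {ltp_star: 3, ltd_star: 0.5, slope: 1}"), f)
  m <- read_model_config(f)
  expect_equal(m$calcium$tau_ca, 0.018)
  expect_equal(m$calcium$delay_d, -0.0005)
  expect_equal(m$tau, 0.1)
  expect_equal(m$pathways[[1]]$mu_p, Inf)
  # a time suffix on a dimensionless field is rejected
  writeLines(c("calcium: {c_pre: 1 ms, c_post: 2, tau_ca: 18 ms}",
               "pathways: [{name: A, gamma_p: 1, theta0_p: 1}]",
               "dynamics: {tau: 100, rho_star: 0.5, sigma: 0}",
               "readout: {ltp_star: 3, ltd_star: 0.5, slope: 1}"), f)
  expect_error(read_model_config(f), "does not accept a time unit")
})

test_that("constructor invariants reject bad values with clear messages", {
  expect_error(calcium_params(-1, 1, 0.01), "c_pre")
  expect_error(calcium_params(1, 1, 0), "tau_ca")
  expect_error(pathway_params("A", -1, 0, 1), "gamma_p")
  expect_error(pathway_params("A", 1, 0, 0), "theta0_p")
  expect_error(readout_params(0.9, 0.5, 1), "ltp_star")
  expect_error(readout_params(3, 1.2, 1), "ltd_star")
  # slope too shallow for the coefficient closed forms
  expect_error(readout_params(10, 0.1, 0.05), "exp\\(slope\\)")
  cp <- calcium_params(1, 1, 0.01)
  pw <- pathway_params("A", 1, 0, 1)
  ro <- readout_params(3, 0.5, 1)
  expect_error(synapse_model(cp, pw, tau = 100, rho_star = 0, sigma = 1, readout = ro),
               "rho_star")
  expect_error(synapse_model(cp, list(pw, pw), tau = 100, rho_star = 0.5,
                             sigma = 1, readout = ro), "unique")
})
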