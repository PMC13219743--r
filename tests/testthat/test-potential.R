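test_that("rate fitting recovers exact lines and matches closed-form OLS", {
  t <- c(2, 4, 8, 20, 22, 24)
  f <- fit_rate(t, 0.2 * t + 1)
  expect_equal(f$R, 0.2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_true(f$qc_pass)

  conc <- c(1.1, 1.9, 4.2, 10.1, 10.9, 12.2)
  f <- fit_rate(t, conc)
  o <- oracle_ols(t, conc)
  expect_equal(f$R, o$slope, tolerance = 1e-12)
  expect_equal(f$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(f$r_squared, o$r2, tolerance = 1e-12)
})

test_that("degenerate series are flagged, bad input rejected", {
  flat <- fit_rate(c(2, 4, 8), c(3, 3, 3))
  expect_equal(flat$R, 0)
  expect_equal(flat$r_squared, 0)
  expect_false(flat$qc_pass)
  expect_equal(flat$flag, "constant_concentration")
  expect_error(fit_rate(c(2, 4), c(1, 2)), ">= 3")
  expect_error(fit_rate(c(2, 2, 4), c(1, 2, 3)), "increasing")
})

test_that("the potential formula and its identities hold", {
  pa <- nitrification_potential(0.5, V = 0.005, m = 0.0095)
  expect_equal(pa$Np, 0.5 * (0.1 + 0.005) / 0.0095 * 24)
  expect_equal(pa$Np, 132.6316, tolerance = 1e-6)
  expect_equal(nitrification_potential(0, 0.005, 0.0095)$Np, 0)
  expect_equal(nitrification_potential(1.0, 0.005, 0.0095)$Np, 2 * pa$Np)
  expect_equal(nitrification_potential(0.5, 0.005, 2 * 0.0095)$Np,
               pa$Np / 2)
  expect_error(nitrification_potential(0.5, 0.005, 0), "m")
})

test_that("background subtraction preserves sign information", {
  np <- function(x) {
    p <- nitrification_potential(1, 0, 2.4); p$Np <- x; p
  }
  expect_equal(subtract_background(np(10), np(2))$Np, 8)
  neg <- subtract_background(np(1), np(3))
  expect_equal(neg$Np, -2)
  expect_equal(neg$flag, "negative_net")
  zero <- subtract_background(np(5), np(0))
  expect_equal(zero$Np, 5)
  expect_equal(zero$flag, "zero_background")
  expect_true(zero$background_subtracted)
})

test_that("partition reproduces hand-computed percentage blocks", {
  np <- function(x) {
    p <- nitrification_potential(1, 0, 2.4); p$Np <- x; p
  }
  assays <- list(`NaClO3|NO2` = np(11.6), `NaClO3|NO3` = np(8.85),
                 `NaClO3+Sim|NO2` = np(12.4), `NaClO3+DMPP|NO2` = np(1.9),
                 `NaClO3+Sim+DMPP|NO3` = np(8.4))
  part <- partition_contributions(assays)
  tot <- 1.9 + 12.4 + 8.4
  expect_equal(unname(part$pct_scheme_I),
               100 * c(1.9, 12.4, 8.4) / tot, tolerance = 1e-12)
  # printed to one decimal these are 8.4%, 54.6%, 37.0%
  expect_equal(round(unname(part$pct_scheme_I), 1), c(8.4, 54.6, 37.0))
  expect_equal(sum(part$pct_scheme_I), 100, tolerance = 1e-9)
  expect_equal(sum(part$pct_scheme_U), 100, tolerance = 1e-9)
  expect_equal(part$delta_AB, 11.6 - (1.9 + 12.4))
  expect_equal(part$delta_C, 8.85 - 8.4)
})

test_that("equal scheme-U inputs split 50/50 and missing arms are named", {
  np <- function(x) {
    p <- nitrification_potential(1, 0, 2.4); p$Np <- x; p
  }
  assays <- list(`NaClO3|NO2` = np(5), `NaClO3|NO3` = np(5),
                 `NaClO3+Sim|NO2` = np(3), `NaClO3+DMPP|NO2` = np(1),
                 `NaClO3+Sim+DMPP|NO3` = np(2))
  part <- partition_contributions(assays)
  expect_equal(unname(part$pct_scheme_U), c(50, 50))
  expect_error(partition_contributions(assays[-5]), "comammox")
})

test_that("negative potentials are floored only inside percentages", {
  np <- function(x) {
    p <- nitrification_potential(1, 0, 2.4); p$Np <- x; p
  }
  assays <- list(`NaClO3|NO2` = np(6), `NaClO3|NO3` = np(4),
                 `NaClO3+Sim|NO2` = np(5), `NaClO3+DMPP|NO2` = np(-1),
                 `NaClO3+Sim+DMPP|NO3` = np(3))
  expect_warning(part <- partition_contributions(assays), "floored")
  expect_equal(part$Np_AOA, -1)                 # sign preserved
  expect_equal(unname(part$pct_scheme_I), 100 * c(0, 5, 3) / 8)
  expect_equal(sum(part$pct_scheme_I), 100, tolerance = 1e-9)
})

test_that("noise-free end-to-end potentials match generator truth exactly", {
  sc <- scenario_preset("CK")
  proto <- slurry_protocol(measurement_sd = 0)
  sl <- simulate_slurry_experiment(sc$guild_rates, sc$inhibitor_design,
                                   proto, seed = 1)
  res <- estimate_potentials(sl, V = proto$soil_water_volume,
                             m = proto$soil_dry_mass, ace_baseline = TRUE)
  f <- (0.1 + proto$soil_water_volume) / proto$soil_dry_mass * 24
  r <- sc$guild_rates
  expect_equal(res$partition$Np_AOA, r$aoa_rate * f, tolerance = 1e-9)
  expect_equal(res$partition$Np_AOB, r$aob_rate * f, tolerance = 1e-9)
  expect_equal(res$partition$Np_comammox_alone, r$comammox_rate * f,
               tolerance = 1e-9)
  expect_equal(res$partition$Np_AOA_plus_AOB,
               r$interaction_ab * (r$aoa_rate + r$aob_rate) * f,
               tolerance = 1e-9)
  expect_true(all(res$partition$qc))
})

test_that("additive truth yields zero interaction index", {
  r <- guild_rates(aoa_rate = 0.01, aob_rate = 0.03, comammox_rate = 0.02,
                   interaction_ab = 1, background_rate = 0.001)
  proto <- slurry_protocol(measurement_sd = 0)
  sl <- simulate_slurry_experiment(r, protocol = proto, seed = 2)
  res <- estimate_potentials(sl, V = proto$soil_water_volume,
                             m = proto$soil_dry_mass, ace_baseline = TRUE)
  expect_equal(res$partition$delta_AB, 0, tolerance = 1e-9)
  rep <- interaction_report(list(res$partition))
  expect_equal(rep$ab_interaction, "additivity")
})

test_that("interaction report classifies directions across presets", {
  run_preset <- function(preset, seed) {
    sc <- scenario_preset(preset)
    proto <- slurry_protocol(measurement_sd = 0)
    sl <- simulate_slurry_experiment(sc$guild_rates, sc$inhibitor_design,
                                     proto, seed = seed)
    res <- estimate_potentials(sl, V = proto$soil_water_volume,
                               m = proto$soil_dry_mass, ace_baseline = TRUE)
    interaction_report(list(res$partition))
  }
  wi2 <- run_preset("WI2", 3)
  expect_equal(wi2$ab_interaction, "antagonism")
  expect_gt(wi2$comammox_share_U, wi2$comammox_share_I)
  ck <- run_preset("CK", 4)
  # no coexistence boost: comammox shares agree across schemes up to the
  # antagonism-induced shrinkage of the scheme-U total
  expect_equal(ck$comammox_interaction, "additivity")
})
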