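test_that("chloride efflux percent anchors", {
  # compound plateau equal to the Triton level -> 100%
  s1 <- simulate_ise_trace(1, noise_sd_ppm = 0, tau_min = 0.3)
  expect_equal(as.numeric(chloride_efflux_percent(s1$trace)), 100,
               tolerance = 1e-6)
  # no compound-induced release -> 0%
  s0 <- simulate_ise_trace(0, noise_sd_ppm = 0)
  expect_equal(as.numeric(chloride_efflux_percent(s0$trace)), 0,
               tolerance = 1e-9)
})

test_that("efflux recovery at default noise and affine invariance", {
  s <- simulate_ise_trace(0.4, seed = 21)
  pct <- chloride_efflux_percent(s$trace)
  expect_equal(as.numeric(pct), 40, tolerance = 2 / 40)
  # gain/offset on the raw ppm signal cancels exactly
  tr <- s$trace
  tr2 <- ise_trace(tr$time_min, 3.7 * tr$chloride_ppm + 11,
                   tr$compound_time_min, tr$triton_time_min)
  expect_equal(as.numeric(chloride_efflux_percent(tr2)),
               as.numeric(pct), tolerance = 1e-9)
})

test_that("out-of-range efflux is flagged, not clipped; degenerate trace errors", {
  t <- seq(0, 15, by = 1 / 60)
  over <- ifelse(t < 2, 0, ifelse(t < 12, 120, 100))
  tr <- ise_trace(t, over)
  pct <- chloride_efflux_percent(tr)
  expect_gt(as.numeric(pct), 100)
  expect_equal(attr(pct, "flag"), "above_100")
  flat <- ise_trace(t, rep(5, length(t)))
  expect_error(chloride_efflux_percent(flat), "undefined")
})

test_that("viability percent anchors and control validation", {
  plate <- plate_readings(data.frame(
    well = sprintf("w%d", 1:5),
    role = c("blank", "blank", "triton", "triton", "compound"),
    fluorescence = c(1000, 1000, 100, 100, 550)))
  expect_equal(viability_percent(plate)$viability_percent, 50)
  plate$fluorescence[5] <- 1000   # at blank level
  expect_equal(viability_percent(plate)$viability_percent, 100)
  plate$fluorescence[5] <- 100    # at triton level
  expect_equal(viability_percent(plate)$viability_percent, 0)
  same <- plate
  same$fluorescence <- rep(5, 5)
  expect_error(viability_percent(same), "undefined")
  expect_error(plate_readings(data.frame(well = "a", role = "compound",
                                         fluorescence = 1)),
               "blank")
})

test_that("viability is invariant to plate-reader gain and offset", {
  s1 <- simulate_plate(c(0.2, 0.5, 0.9), gain = 1000, offset = 50, seed = 4)
  s2 <- simulate_plate(c(0.2, 0.5, 0.9), gain = 7, offset = -300, seed = 4)
  expect_equal(viability_percent(s1$plate)$viability_percent,
               viability_percent(s2$plate)$viability_percent,
               tolerance = 1e-9)
})

test_that("rescue percent anchors and scale invariance", {
  g <- growth_table(data.frame(
    strain = c("WT", "WT", "mutant", "mutant"),
    compound = c("vehicle", "vehicle", "cmpd", "cmpd"),
    dose = c(0, 0, 10, 10), replicate = c(1, 2, 1, 2),
    od600 = c(1.0, 1.0, 1.0, 1.0)))
  rs <- rescue_percent(g)
  expect_equal(rs$by_dose$percent_of_wt, 100)
  # common OD multiplier cancels
  g2 <- g; g2$od600 <- g2$od600 * 3.3
  expect_equal(rescue_percent(g2)$by_dose$percent_of_wt, 100)
  g3 <- g; g3$od600[g3$strain == "WT"] <- 0
  expect_error(rescue_percent(g3), "zero")
})

test_that("synthetic Hill-rescue table recovers the programmed maximum", {
  s <- simulate_growth_table(max_rescue = 0.52, noise_sd_od = 0, seed = 9)
  rs <- rescue_percent(s$table)
  mx <- rs$max_rescue[rs$max_rescue$compound == "cmpd", ]
  expect_equal(mx$percent_of_wt, 52, tolerance = 1e-9)
  expect_equal(mx$dose, s$truth$dose_at_max)
  # vehicle-only mutant shows the programmed basal ratio
  veh <- rs$by_dose[rs$by_dose$compound == "vehicle", ]
  expect_equal(veh$percent_of_wt, s$truth$basal_percent, tolerance = 1e-9)
  # noisy recovery stays within a couple of points
  sn <- simulate_growth_table(max_rescue = 0.52, seed = 10)
  rsn <- rescue_percent(sn$table)
  expect_equal(rsn$max_rescue$percent_of_wt[rsn$max_rescue$compound == "cmpd"],
               52, tolerance = 3 / 52)
  # matched-WT mode works on the same table
  rsm <- rescue_percent(sn$table, mode = "matched_wt")
  expect_equal(rsm$max_rescue$percent_of_wt[rsm$max_rescue$compound == "cmpd"],
               52, tolerance = 3 / 52)
})

test_that("phosphorus standard curve: recovery, round-trip, degeneracy", {
  vol <- c(0, 20, 40, 60, 80, 100, 120, 140)
  slope_true <- 0.012; int_true <- 0.03
  absb <- int_true + slope_true * vol * 0.65
  cv <- phosphorus_curve(vol, absb)
  expect_equal(cv$slope, slope_true, tolerance = 1e-9)
  expect_equal(cv$intercept, int_true, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  # a sample at a standard's absorbance returns that standard's amount
  q <- phosphorus_quantify(cv, absb[4], sample_uL = 10)
  expect_equal(q$phosphorus_nmol, 60 * 0.65, tolerance = 1e-9)
  expect_equal(q$phosphorus_mM, 60 * 0.65 / 10, tolerance = 1e-9)
  expect_false(q$extrapolated)
  # quantify(predict(x)) = x on the fitted line
  x <- 37.5
  a_pred <- cv$intercept + cv$slope * x
  expect_equal(phosphorus_quantify(cv, a_pred)$phosphorus_nmol, x,
               tolerance = 1e-9)
  expect_warning(phosphorus_quantify(cv, max(absb) + 1), "extrapolating")
  expect_error(phosphorus_curve(vol, rep(0.5, 8)), "rank-deficient")
  expect_error(phosphorus_curve(c(10, 10, 10), c(1, 2, 3)), "identical")
})

test_that("vehicle normalization", {
  expect_equal(normalize_to_vehicle(10, c(8, 12)), 1)
  expect_equal(normalize_to_vehicle(20, c(10, 10)), 2)
  expect_equal(normalize_to_vehicle(0, c(5, 5)), 0)
  expect_error(normalize_to_vehicle(1, c(0, 0)), "> 0")
})
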