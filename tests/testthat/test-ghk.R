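test_that("slope constant: paper approximation vs physical constants", {
  expect_equal(ghk_slope("paper"), 61.5)
  expect_equal(round(ghk_slope("exact", 310.15), 1), 61.5)
})

test_that("junction correction is a single subtraction", {
  expect_equal(junction_correct(10, 0), 10)
  expect_equal(junction_correct(10, 10), 0)
  expect_equal(junction_correct(-4.2, 1.3), -5.5)
  expect_error(junction_correct(NA, 1), "finite")
})

test_that("drug conductance is the treated-minus-untreated difference", {
  expect_equal(drug_conductance(5, 2), 3)
  expect_error(drug_conductance(2, 2), "invalid replicate")
  expect_error(drug_conductance(1.5, 2), "invalid replicate")
  expect_error(drug_conductance(-1, 2), "> 0")
})

test_that("circuit decomposition solves the weighted average exactly", {
  expect_equal(decompose_dilution_potential(4, 10, 2, 2), -2)
  # identical pathway potentials pass through
  expect_equal(decompose_dilution_potential(10, 10, 3, 1.7), 10)
  # dominant drug pathway: v_drug -> v_t
  expect_equal(decompose_dilution_potential(4, 10, 1e-9, 1e3), 4,
               tolerance = 1e-9)
  expect_error(decompose_dilution_potential(4, 10, 2, 0), "g_drug")
})

test_that("compose/decompose round-trips and stays a convex combination", {
  set.seed(42)
  for (i in 1:200) {
    g_frt <- runif(1, 0.1, 10); g_drug <- runif(1, 0.1, 10)
    v_frt <- runif(1, -30, 30); v_drug <- runif(1, -30, 30)
    v_t <- compose_dilution_potential(v_drug, v_frt, g_frt, g_drug)
    # convexity: v_t between the two pathway potentials
    expect_gte(v_t, min(v_frt, v_drug) - 1e-12)
    expect_lte(v_t, max(v_frt, v_drug) + 1e-12)
    expect_equal(decompose_dilution_potential(v_t, v_frt, g_frt, g_drug),
                 v_drug, tolerance = 1e-10)
  }
})

test_that("forward GHK potential: anchors and sign convention", {
  # P = 1 with equal Na/Cl on each side: numerator equals denominator
  expect_equal(ghk_potential(1, 2, 2, 1, 1), 0)
  # pure-cation pathway across a 2-fold dilution
  expect_equal(ghk_potential(0, 2, 2, 1, 1), 61.5 * log10(2))
  expect_equal(ghk_potential(0, 2, 2, 1, 1), 18.5128, tolerance = 1e-4)
  # identical baths: no potential at any P
  expect_equal(ghk_potential(7.7, 10, 9, 10, 9), 0)
  expect_error(ghk_potential(1, -1, 2, 1, 1), "activities")
  expect_error(ghk_potential(-0.5, 2, 2, 1, 1), "p_cl_na")

  # sign convention under apical dilution: cation-selective positive,
  # anion-selective negative
  a <- paper_activities()
  v_cat <- ghk_potential(0.06, a[["na_baso"]], a[["cl_baso"]],
                         a[["na_api"]], a[["cl_api"]])
  v_an <- ghk_potential(3, a[["na_baso"]], a[["cl_baso"]],
                        a[["na_api"]], a[["cl_api"]])
  expect_gt(v_cat, 0)
  expect_lt(v_an, 0)
})

test_that("GHK potential is strictly decreasing in P under apical dilution", {
  a <- paper_activities()
  p_grid <- 10^seq(-2, 2, length.out = 60)
  v <- vapply(p_grid, function(p)
    ghk_potential(p, a[["na_baso"]], a[["cl_baso"]], a[["na_api"]],
                  a[["cl_api"]]), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("closed-form inversion round-trips and matches the root-solve oracle", {
  tuples <- rand_activity_tuples(60, seed = 1)
  set.seed(2)
  ps <- 10^runif(60, -2, 2)
  slope_exact <- ghk_slope("exact")
  for (i in seq_along(tuples)) {
    a <- tuples[[i]]
    v <- ghk_potential(ps[i], a[["na_baso"]], a[["cl_baso"]], a[["na_api"]],
                       a[["cl_api"]], slope_mV = slope_exact)
    p_closed <- ghk_invert(v, a[["na_baso"]], a[["cl_baso"]], a[["na_api"]],
                           a[["cl_api"]], slope_mV = slope_exact,
                           guard_mV = 0)
    expect_equal(p_closed, ps[i], tolerance = 1e-10)
    expect_equal(p_closed, oracle_invert(v, a), tolerance = 1e-9)
  }
})

test_that("inversion anchors: symmetric zero potential and cation limit", {
  # v = 0 with symmetric per-side activity ratios gives P = 1
  expect_equal(ghk_invert(0, 100, 100, 50, 50), 1)
  # approaching the Na+ (pure cation) limit drives P to 0
  a <- paper_activities()
  lim <- nernst_limits(a[["na_baso"]], a[["cl_baso"]], a[["na_api"]],
                       a[["cl_api"]])
  p_near <- ghk_invert(lim[["na"]] - 0.2, a[["na_baso"]], a[["cl_baso"]],
                       a[["na_api"]], a[["cl_api"]], guard_mV = 0.1)
  expect_lt(p_near, 0.01)
})

test_that("potentials at or beyond the Nernstian limits are rejected with both limits named", {
  a <- paper_activities()
  lim <- nernst_limits(a[["na_baso"]], a[["cl_baso"]], a[["na_api"]],
                       a[["cl_api"]])
  err <- expect_error(
    ghk_invert(lim[["na"]] + 1, a[["na_baso"]], a[["cl_baso"]],
               a[["na_api"]], a[["cl_api"]]),
    "Nernstian limits")
  expect_match(conditionMessage(err), sprintf("%.3f", lim[["na"]]))
  expect_match(conditionMessage(err), sprintf("%.3f", lim[["cl"]]))
  # guard band: a value inside the limits but within 0.1 mV is unstable
  expect_error(
    ghk_invert(lim[["na"]] - 0.05, a[["na_baso"]], a[["cl_baso"]],
               a[["na_api"]], a[["cl_api"]], guard_mV = 0.1),
    "Nernstian")
})
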