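test_that("water condensed fraction follows the carrier-gas balance", {
  sys <- dilute_test_system(inert_ratio = 0.01)
  w <- sys$compounds$water

  # no carrier gas: total condensation whenever p_vw < p_perm
  s0 <- sys$stream; s0$inert_flow <- 0
  expect_equal(as.numeric(water_condensed_fraction(s0, 283.15, sys$compounds)), 1)

  # direct evaluation against the steam-table p_vw at 10 degC, r = 0.01
  pvw <- 1227.94
  f_expected <- 1 - 0.01 * pvw / (1500 - pvw)
  f <- water_condensed_fraction(sys$stream, 283.15, sys$compounds)
  expect_equal(as.numeric(f), f_expected, tolerance = 0.005)
  expect_identical(attr(f, "status"), "ok")

  # onset: fraction is 0 exactly where p_vw equals the inlet partial pressure
  s <- permeate_stream(1e-4, inert_flow = 1e-5, total_pressure = 1500)
  onset <- function(T_K) {
    pv <- as.numeric(vapor_pressure(w, T_K))
    pv - s$total_pressure * s$water_flow / (s$water_flow + s$inert_flow)
  }
  T_star <- uniroot(onset, c(270, 290), tol = 1e-10)$root
  expect_equal(as.numeric(water_condensed_fraction(s, T_star, sys$compounds)),
               0, tolerance = 1e-6)
  expect_gt(as.numeric(water_condensed_fraction(s, T_star - 1, sys$compounds)), 0)

  # p_vw >= p_perm: no equilibrium condensation possible
  f_hot <- water_condensed_fraction(sys$stream, 330, sys$compounds)
  expect_identical(as.numeric(f_hot), 0)
  expect_identical(attr(f_hot, "status"), "water_noncondensing")
})

test_that("aroma closed form honours its limiting cases", {
  sys <- dilute_test_system()
  s0 <- sys$stream; s0$inert_flow <- 0
  expect_equal(as.numeric(
    aroma_condensed_fraction(s0, 283.15, 1e-6, "midB", sys$compounds)), 1)
  # x = 0: iteration upper bound
  expect_equal(as.numeric(
    aroma_condensed_fraction(sys$stream, 283.15, 0, "lightA", sys$compounds)), 1)
  # volatile enough that the subtrahend exceeds 1: clamped to 0
  expect_equal(as.numeric(
    aroma_condensed_fraction(sys$stream, 283.15, 0.5, "lightA", sys$compounds)), 0)
})

test_that("single condenser solves trivial and cryogenic cases", {
  compounds <- list(water = water_compound())
  s <- permeate_stream(1e-4, total_pressure = 1500)
  res <- solve_condenser(s, condenser_spec(283.15, 1), compounds)
  expect_equal(res$condensed_fraction[["water"]], 1)
  expect_equal(res$condensate_mole_fractions[["water"]], 1)
  expect_equal(res$outlet$water_flow, 0)
  expect_identical(res$validity, "valid")

  # second-condenser limit: at 77 K every condensable condenses fully,
  # only the inert gas leaves
  sys <- dilute_test_system()
  res2 <- solve_condenser(sys$stream, condenser_spec(77.15, 2), sys$compounds)
  expect_true(all(res2$condensed_fraction == 1))
  expect_equal(res2$outlet$water_flow, 0)
  expect_true(all(res2$outlet$aroma_flows == 0))
  expect_equal(res2$outlet$inert_flow, sys$stream$inert_flow)
  expect_identical(res2$validity, "extrapolated_pv")
})

test_that("the closed-form fixed point matches the flash oracle when dilute", {
  sys <- dilute_test_system(inert_ratio = 0.02)
  for (T_K in c(268.15, 278.15, 283.15, 288.15)) {
    res <- solve_condenser(sys$stream, condenser_spec(T_K, 1), sys$compounds)
    oracle <- rr_flash(sys$stream, T_K, sys$compounds)
    # total aroma mole fraction in the condensate is deep in the dilute regime
    expect_lt(sum(res$condensate_mole_fractions) -
                res$condensate_mole_fractions[["water"]], 1e-3)
    for (nm in names(oracle)) {
      expect_equal(res$condensed_fraction[[nm]], oracle[[nm]],
                   tolerance = 0.01, label = sprintf("%s @ %.2f K", nm, T_K))
    }
  }
})

test_that("condenser results conserve every species", {
  set.seed(421)
  for (i in 1:25) {
    sys <- random_system()
    res <- solve_condenser(sys$stream, condenser_spec(runif(1, 250, 290), 1),
                           sys$compounds)
    inlet <- c(water = sys$stream$water_flow, sys$stream$aroma_flows)
    outlet <- c(water = res$outlet$water_flow, res$outlet$aroma_flows)
    condensed <- res$condensed_fraction * inlet[names(res$condensed_fraction)]
    expect_lt(max(abs(inlet - (condensed + outlet[names(inlet)])) /
                    pmax(inlet, 1e-300)), 1e-9)
    if (sum(condensed) > 0)
      expect_lt(abs(sum(res$condensate_mole_fractions) - 1), 1e-10)
  }
})

test_that("cascades chain outlets and conserve overall", {
  sys <- dilute_test_system()
  single <- solve_condenser(sys$stream, condenser_spec(283.15, 1), sys$compounds)
  cas1 <- run_cascade(sys$stream, list(condenser_spec(283.15, 1)), sys$compounds)
  expect_equal(cas1$per_condenser[[1]]$condensed_fraction,
               single$condensed_fraction)

  cas <- run_cascade(sys$stream,
                     list(condenser_spec(283.15, 1), condenser_spec(77.15, 2)),
                     sys$compounds)
  # stage 2 at 77 K captures everything stage 1 missed
  expect_true(all(cas$overall_recovery[, "vapour_out"] == 0))
  expect_lt(max(abs(rowSums(cas$overall_recovery) - 1)), 1e-9)

  # permuting two condensers at equal temperature leaves stage totals unchanged
  casA <- run_cascade(sys$stream,
                      list(condenser_spec(280, 1), condenser_spec(280, 2)),
                      sys$compounds)
  tot <- casA$overall_recovery[, 1] + casA$overall_recovery[, 2]
  expect_equal(unname(tot + casA$overall_recovery[, "vapour_out"]),
               rep(1, nrow(casA$overall_recovery)))
})

test_that("condensation curves are nonincreasing in temperature", {
  sys <- dilute_test_system()
  grid <- C_to_K(seq(-40, 20, by = 2))
  curve <- condensation_curve(sys$stream, grid, sys$compounds)
  for (nm in unique(curve$compound)) {
    f <- curve$condensed_fraction[curve$compound == nm]
    expect_true(all(diff(f) <= 1e-12), label = nm)
  }
  # a single-point grid is just a condenser solve
  one <- condensation_curve(sys$stream, 283.15, sys$compounds)
  res <- solve_condenser(sys$stream, condenser_spec(283.15, 1), sys$compounds)
  expect_equal(stats::setNames(one$condensed_fraction, one$compound)[
    names(res$condensed_fraction)], res$condensed_fraction)
})

test_that("fractions depend only on flow ratios and fall with gamma", {
  sys <- dilute_test_system()
  res <- solve_condenser(sys$stream, condenser_spec(283.15, 1), sys$compounds)

  # uniform scaling of all flows (inert included) changes nothing
  s10 <- permeate_stream(10 * sys$stream$water_flow,
                         10 * sys$stream$aroma_flows,
                         10 * sys$stream$inert_flow,
                         sys$stream$total_pressure)
  res10 <- solve_condenser(s10, condenser_spec(283.15, 1), sys$compounds)
  expect_equal(res10$condensed_fraction, res$condensed_fraction,
               tolerance = 1e-12)

  # n_inert -> 0: complete condensation of every condensable
  s0 <- sys$stream; s0$inert_flow <- 0
  res0 <- solve_condenser(s0, condenser_spec(283.15, 1), sys$compounds)
  expect_true(all(res0$condensed_fraction == 1))

  # raising gamma_inf raises the escaping tendency: condensed fraction falls
  cps <- sys$compounds
  cps$midB$gamma_inf <- cps$midB$gamma_inf * 5
  res_hi <- solve_condenser(sys$stream, condenser_spec(283.15, 1), cps)
  expect_lt(res_hi$condensed_fraction[["midB"]],
            res$condensed_fraction[["midB"]])
})

test_that("inert-ratio calibration recovers a known ratio by bisection", {
  sys <- dilute_test_system(inert_ratio = 0.013)
  res <- solve_condenser(sys$stream, condenser_spec(283.15, 1), sys$compounds)
  target <- res$condensed_fraction[["midB"]]
  cal <- calibrate_inert_ratio(sys$stream, "midB", target, 283.15,
                               sys$compounds)
  expect_equal(cal$inert_ratio, 0.013, tolerance = 1e-5)
  expect_equal(cal$achieved_fraction, target, tolerance = 1e-8)
  expect_error(
    calibrate_inert_ratio(sys$stream, "midB", 0.5, 330, sys$compounds),
    "cannot condense")
})
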