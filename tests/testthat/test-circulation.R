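p <- cvs_params()

test_that("passive chambers and vessels follow their linear laws", {
  expect_equal(passive_pressure(0, p$E_vc), 0)
  expect_equal(passive_pressure(100, 0.0107), 1.07)
  expect_equal(passive_pressure(50, 0.965), 48.25)
  expect_equal(vessel_flow(100, 2, 5.65), 98 / 5.65)
  expect_equal(vessel_flow(10, 10, 1), 0)
  expect_equal(vessel_flow(3, 9, 2), -vessel_flow(9, 3, 2))
  expect_error(vessel_flow(1, 0, 0), "resistance")
})

test_that("valves block reverse flow", {
  expect_equal(valve_flow(5, 10, 1), 0)
  expect_equal(valve_flow(11, 10, 0.5), 2)
  expect_equal(valve_flow(7, 7, 1), 0)
  expect_true(all(valve_flow(runif(50, 0, 10), runif(50, 0, 10), 0.3) >= 0))
})

test_that("the RV activation function is a periodic sum of Gaussians", {
  # near-degenerate companions isolate the first Gaussian at its center
  p1 <- cvs_params(A2 = 1e-12, A3 = 1e-12)
  expect_equal(rv_activation(p1$C1, p1), p1$A1, tolerance = 1e-6)
  # direct evaluation at the first center with all three terms
  e_direct <- 0.956 + 0.625 * exp(-225 * (0.431 - 0.328)^2) +
    0.018 * exp(-4230 * (0.431 - 0.374)^2)
  expect_equal(rv_activation(0.431, p), e_direct, tolerance = 1e-12)
  expect_gt(e_direct, 1)  # the shifted centers push the peak slightly above 1
  tt <- seq(1e-4, p$period - 1e-4, by = 1e-3)  # interior of the cycle
  e <- rv_activation(tt, p)
  expect_true(all(e > 0))
  expect_true(all(e <= p$A1 + p$A2 + p$A3))
  expect_equal(rv_activation(tt + 2 * p$period, p), e)
})

test_that("RV pressure is the activated elastance law", {
  expect_equal(rv_pressure(0.1, 0, p), 0)
  e <- rv_activation(0.2, p)
  expect_equal(rv_pressure(0.2, 10, p), e * 2.06 * 10)
  expect_equal(rv_pressure(0.2, 20, p), 2 * rv_pressure(0.2, 10, p))
})

test_that("chamber derivatives respect the loop topology", {
  s <- initial_state(p)
  d <- chamber_derivatives(0.1, s, p)
  expect_equal(sum(d$dV), 0, tolerance = 1e-12)
  d50 <- chamber_derivatives(0.1, s, p, pu_outflow = 50)
  expect_equal(sum(d50$dV), -50, tolerance = 1e-12)
  # only the pulmonary-vein equation feels the sink
  expect_equal(d50$dV[1:5], d$dV[1:5])

  # contrived all-zero-pressure rest point: every flow and derivative zero
  v0 <- p$Kv * p$L0^3 - p$f * p$Vw      # cavity volume with unstressed muscle
  rest <- c(v0, 0, 0, 0, 0, 0,
            0, 0, 0, fiber_length_from_volume(v0, p) - p$hc)
  dz <- chamber_derivatives(0.5, rest, p)  # t in the quiescent tail, Ca = 0
  expect_equal(unname(dz$pressures), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(dz$flows), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(c(dz$dV, dz$dsarc)), rep(0, 10), tolerance = 1e-8)

  expect_error(chamber_derivatives(0, replace(s, 3, -1), p), "negative")
})
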