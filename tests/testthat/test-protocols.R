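p <- cvs_params()

test_that("hemorrhage shifts loops to lower volumes and drains the loop", {
  hem <- baseline_hemorrhage()
  edv <- vapply(split(hem$loops$V, hem$loops$loop), max, numeric(1))
  expect_equal(length(edv), 8)
  expect_true(all(diff(edv) < 0))
  total_end <- sum(hem$sim$state[nrow(hem$sim$state), 1:6])
  expect_equal(total_end, p$V_total - 50 * 4.8, tolerance = 1e-2)
})

test_that("zero outflow reproduces the steady-state loop eight times", {
  ss <- baseline_steady()
  pr <- run_hemorrhage(p, outflow = 0, steady = ss)
  spread <- tapply(pr$loops$V, pr$loops$t %% p$period,
                   function(v) diff(range(v)))
  expect_lt(max(spread), 0.02)
  expect_equal(max(pr$loops$loop), 8)
})

test_that("load steps behave as preload/afterload interventions", {
  ss <- baseline_steady()
  id <- run_parameter_step(p, "E_ao", factor = 1, steady = ss)
  spread <- tapply(id$loops$V, id$loops$t %% p$period,
                   function(v) diff(range(v)))
  expect_lt(max(spread), 0.02)

  mt <- run_parameter_step(p, "R_mt", steady = ss)
  edv <- vapply(split(mt$loops$V, mt$loops$loop), max, numeric(1))
  expect_true(all(diff(edv) < 0))      # preload reduction

  rs <- run_parameter_step(p, "R_sys", steady = ss)
  last <- rs$loops[rs$loops$loop == 8, ]
  expect_gt(max(last$P), max(ss$pressures[, "P_lv"]))   # afterload: higher peak
  expect_lt(diff(range(last$V)),
            diff(range(ss$state[, "V_lv"])))            # and smaller stroke
})

test_that("isovolumic contractions are volume-clamped and monotone in volume", {
  r <- run_isovolumic(p, 20)
  expect_lt(max(abs(r$trace$V - 20)), 1e-9)
  expect_equal(r$P_dev, r$P_peak - r$P_ed)
  sw <- isovolumic_sweep(p, seq(10, 25, by = 5))
  expect_true(all(diff(sw$P_peak) > 0))
})

test_that("contractility scaling only touches the calcium peak", {
  expect_equal(with_contractility(p, 1), p)
  p2 <- with_contractility(p, 2)
  expect_equal(p2$Camax, 2.94)
  same <- setdiff(names(p), "Camax")
  expect_equal(p2[same], p[same])
  expect_gt(run_isovolumic(p2, 20)$P_peak, run_isovolumic(p, 20)$P_peak)
})

test_that("flow clamps reduce matched-volume pressure as flow rises", {
  fc <- run_flow_clamp(p, flows = c(0, 10, 20, 30, 40, 50))
  # the zero-flow member is exactly the isovolumic beat
  iso <- run_isovolumic(p, fc$V_start, duration = 0.4)
  expect_equal(fc$traces[["0"]]$P, iso$trace$P, tolerance = 1e-10)
  expect_true(all(diff(fc$samples$P_match) < 0))
  expect_lt(fc$slope, 0)
  # doubling every flow keeps the ordering monotone
  fc2 <- run_flow_clamp(p, flows = c(20, 40, 60, 80),
                        match_volume = 24.5, t_match = 0.15)
  expect_true(all(diff(fc2$samples$P_match) < 0))
})

test_that("infeasible clamps are refused", {
  expect_error(run_flow_clamp(p, flows = c(1, 2)), "t_match")
  expect_error(run_flow_clamp(p, flows = c(40, 80), duration = 0.39,
                              V_start = 12, match_volume = 11.9,
                              t_match = 0.1), "negative")
})
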