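p <- cvs_params()

test_that("an unstressed quiescent configuration is a fixed point", {
  pq <- cvs_params(Camax = 1e-12)
  v0 <- p$Kv * p$L0^3 - p$f * p$Vw
  rest <- c(v0, 0, 0, 0, 0, 0,
            0, 0, 0, fiber_length_from_volume(v0, pq) - pq$hc)
  sim <- simulate_cvs(pq, duration = 0.6, init = rest)
  drift <- apply(abs(sweep(sim$state, 2, sim$state[1, ])), 2, max)
  expect_lt(max(drift), 1e-6)
})

test_that("blood volume and troponin are conserved along 20 cycles", {
  sim <- simulate_cvs(p, duration = 20 * p$period,
                      init = baseline_steady()$state0)
  total <- rowSums(sim$state[, 1:6])
  expect_lt(max(abs(total - p$V_total)), 1e-3)
  free_t <- p$Tt - rowSums(sim$state[, c("TCa", "TCastar", "Tstar")])
  expect_true(all(free_t > -1e-6))
  expect_true(all(free_t <= p$Tt + 1e-6))
  # valve flows never negative on the output grid
  expect_true(all(sim$flows[, c("Q_mt", "Q_av", "Q_tc", "Q_pv")] >= 0))
})

test_that("the steady-state cycle shows the four phases in order", {
  ss <- baseline_steady()
  expect_true(ss$converged)
  ev <- valve_events(ss)
  key <- ev[match(c("mt_close", "av_open", "av_close", "mt_open"),
                  ev$event), ]
  expect_false(any(is.na(key$time)))
  expect_true(all(diff(key$time) > 0))
})

test_that("steady state is independent of the initial volume distribution", {
  p2 <- cvs_params()
  init_b <- initial_state(p2, V_vent = 35)
  init_b[3:6] <- c(0.4, 0.3, 0.2, 0.1) * (p2$V_total - 70)  # skewed split
  ssa <- run_to_steady_state(p2, tol = 1e-7, max_cycles = 1500)
  ssb <- run_to_steady_state(p2, tol = 1e-7, max_cycles = 1500,
                             init = init_b)
  expect_true(ssa$converged && ssb$converged)
  expect_lt(max(abs(ssa$state[, "V_lv"] - ssb$state[, "V_lv"])), 1e-3)
  expect_lt(max(abs(ssa$state0 - ssb$state0)), 0.05)
})

test_that("an already-periodic start converges immediately", {
  ss <- baseline_steady()
  again <- run_to_steady_state(p, init = ss$state0)
  expect_true(again$converged)
  expect_lte(again$n_cycles, 2)
})

test_that("loop extraction counts complete periods", {
  ss <- baseline_steady()
  sim8 <- simulate_cvs(p, 4.8, init = ss$state0)
  expect_equal(max(extract_pv_loops(sim8)$loop), 8)
  sim1 <- simulate_cvs(p, 0.6, init = ss$state0)
  l1 <- extract_pv_loops(sim1)
  expect_equal(max(l1$loop), 1)
  expect_gte(sum(l1$loop == 1), 100)
  expect_error(extract_pv_loops(simulate_cvs(p, 0.5, init = ss$state0)),
               "period")
})

test_that("refining integrator tolerances barely moves the end-systolic point", {
  ss <- baseline_steady()
  es <- function(rtol, atol) {
    sim <- simulate_cvs(p, 0.6, init = ss$state0, rtol = rtol, atol = atol)
    pts <- end_systole_points(extract_pv_loops(sim), V0 = 0)
    c(pts$Ves, pts$Pes)
  }
  a <- es(1e-6, 1e-9)
  b <- es(1e-7, 1e-10)
  expect_lt(max(abs(a - b) / abs(b)), 1e-3)
})

test_that("stroke volume equals transvalvular aortic transport", {
  ss <- baseline_steady()
  sv <- max(ss$state[, "V_lv"]) - min(ss$state[, "V_lv"])
  q <- ss$flows[, "Q_av"]
  dt <- diff(ss$time)
  transported <- sum((q[-1] + q[-length(q)]) / 2 * dt)
  expect_equal(transported, sv, tolerance = 5e-3)
})

test_that("simulations export as CSV and JSON summaries", {
  ss <- baseline_steady()
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  export_sim(ss, csv = csv, json = json)
  d <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(d), length(ss$time))
  expect_true(all(c("time", "V_lv", "P_lv", "Q_av") %in% names(d)))
  j <- jsonlite::read_json(json)
  expect_true(j$converged)
  expect_equal(j$parameters$Camax, 1.47)
})
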