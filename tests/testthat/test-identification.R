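p <- cvs_params()

test_that("direct computations reproduce the printed parameterization", {
  s1 <- step1_direct(V_ed = 26.65, rv_es = c(22.2, 45.8),
                     p_ao_mean = 100, p_vc_mean = 2.5,
                     p_pa_mean = 15, p_pu_mean = 5,
                     stroke_volume = 11.7)
  expect_equal(s1$CO, 19.5)
  expect_equal(s1$R_sys, 5.0)
  expect_equal(s1$Vw, 60.8, tolerance = 1e-3)       # close to the fitted 60.6
  expect_equal(s1$E_rv, 45.8 / 22.2)
  expect_equal(s1$R_pul, 10 / 19.5)
  # wall volume solves the spherical-shell relation exactly
  Rlv <- (3 * 26.65 / (4 * pi))^(1 / 3)
  expect_equal(26.65 + s1$Vw, 4 / 3 * pi * (Rlv + 0.9)^3, tolerance = 1e-10)
  expect_error(step1_direct(-1, c(20, 40), 100, 2.5, 15, 5, 11.7),
               "positive")
})

test_that("direct resistances scale inversely with cardiac output", {
  a <- step1_direct(26.65, c(22.2, 45.8), 100, 2.5, 15, 5,
                    stroke_volume = 11.7)
  b <- step1_direct(26.65, c(22.2, 45.8), 100, 2.5, 15, 5,
                    stroke_volume = 2 * 11.7)
  expect_equal(b$R_sys, a$R_sys / 2)
  expect_equal(b$R_pul, a$R_pul / 2)
})

test_that("cycle measurements handle synthetic inputs", {
  n <- 601
  tt <- seq(0, 0.6, length.out = n)
  mk_sim <- function(Plv, Pao, Qav, Vlv) {
    structure(list(
      time = tt,
      state = cbind(V_lv = Vlv, V_rv = Vlv, V_ao = rep(50, n),
                    V_vc = rep(100, n), V_pa = rep(20, n),
                    V_pu = rep(200, n), TCa = 0, TCastar = 0, Tstar = 0,
                    X = 1),
      pressures = cbind(P_lv = Plv, P_rv = Plv, P_ao = Pao,
                        P_vc = rep(2, n), P_pa = rep(15, n),
                        P_pu = rep(5, n)),
      flows = cbind(Q_mt = rep(1, n), Q_av = Qav, Q_sys = rep(1, n),
                    Q_tc = rep(1, n), Q_pv = rep(1, n), Q_pul = rep(1, n)),
      params = p, period = 0.6), class = "cvs_sim")
  }
  vlv <- 20 + 5 * sin(2 * pi * tt / 0.6)
  qav <- ifelse(tt > 0.1 & tt < 0.3, 10, 0)
  m <- measure_targets(mk_sim(rep(60, n), rep(100, n), qav, vlv))
  expect_equal(m$lv_pulse_pressure, 0)
  expect_equal(m$stroke_volume, 10, tolerance = 1e-4)
  expect_equal(m$mean_ventricular_volume, 20, tolerance = 1e-4)
  # no ejection -> no aortic valve events
  expect_error(measure_targets(mk_sim(rep(60, n), rep(100, n),
                                      rep(0, n), vlv)),
               "valve")
})

test_that("geometry initialization is exact at the truth and flags nonsense", {
  iso <- read_iso_targets()
  s3 <- step3_init_geometry(iso, p, maxit = 40, restarts = 0)
  expect_lt(s3$objective, 1e-6)
  expect_true(s3$converged)
  expect_equal(s3$Kv, p$Kv, tolerance = 0.01)
  expect_equal(s3$f, p$f, tolerance = 0.01)
  bad <- transform(iso, Pes = -Pes)
  expect_false(step3_init_geometry(bad, p)$converged)
})

test_that("target plumbing validates its rows", {
  tg <- read_targets()
  expect_equal(tg$stroke_volume, 11.7)
  expect_equal(tg$lv_pulse_pressure, 119)
  expect_error(hemo_targets(stroke_volume = -3), "positive")
  broken <- tg; broken$mean_rv_pressure <- NULL
  expect_error(step5_fit_pulmonary(broken, p, 7, 12, maxit = 1),
               "missing target")
})

test_that("subsystem steady cycles reproduce the closed-loop measurements", {
  ss <- baseline_steady()
  tg <- measure_targets(ss)
  ven <- venous_pressures_from_cycle(ss)
  d <- cvloop:::.subsystem_steady_cycle(
    function(p2, state) simulate_systemic(p2, ven$P_pu, ven$P_vc,
                                          duration = p2$period,
                                          init = state),
    p, c(V_lv = tg$mean_ventricular_volume,
         V_ao = tg$p_ao_at_valve_open / p$E_ao,
         cvloop:::.rest_sarcomere(
           fiber_length_from_volume(tg$mean_ventricular_volume, p), p)))
  m <- cvloop:::.measure_lv(d$time, d$P_lv, d$P_ao, d$Q_av, d$V_lv)
  for (nm in names(m))
    expect_equal(m[[nm]], tg[[nm]], tolerance = 0.01)

  dp <- cvloop:::.subsystem_steady_cycle(
    function(p2, state) simulate_pulmonary(p2, ven$P_pu, ven$P_vc,
                                           duration = p2$period,
                                           init = state),
    p, c(V_rv = 20.8, V_pa = 20 / p$E_pa))
  mp <- cvloop:::.measure_rv(dp$P_rv, dp$V_rv)
  for (nm in c("rv_pulse_pressure", "mean_rv_pressure", "stroke_volume"))
    expect_equal(mp[[nm]], tg[[nm]], tolerance = 0.01)
})
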