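p <- cvs_params()

test_that("elastic elements follow their force laws", {
  expect_equal(parallel_force(p$L0, p), 0)
  expect_equal(parallel_force(1.07, p), 140000 * 0.1^5, tolerance = 1e-10)
  expect_equal(parallel_force(0.87, p), -parallel_force(1.07, p))
  expect_equal(series_force(0, p), 0)
  expect_equal(series_force(log(2) / p$beta, p), p$alpha)
  expect_equal(series_force(-50, p), -p$alpha, tolerance = 1e-8)
  ls <- seq(-0.01, 0.05, by = 0.001)
  expect_true(all(diff(series_force(ls, p)) > 0))
})

test_that("overlap attenuates bound calcium away from optimal length", {
  expect_equal(effective_bound_calcium(5, p$La, p), 5)
  expect_equal(effective_bound_calcium(5, 1.27, p), 5 * exp(-0.2),
               tolerance = 1e-12)
  expect_equal(effective_bound_calcium(0, 1.0, p), 0)
  expect_true(all(effective_bound_calcium(5, seq(0.9, 1.4, 0.01), p) <= 5))
})

test_that("reaction rates match direct evaluation of the kinetic scheme", {
  rest <- c(TCa = 0, TCastar = 0, Tstar = 0, X = 1)
  expect_equal(unname(reaction_rates(rest, Ca = 0, L = 1, dXdt = 0, p)),
               rep(0, 6))
  s <- c(TCa = 1, TCastar = 0, Tstar = 0, X = 1)
  q <- reaction_rates(s, Ca = 0, L = p$La, dXdt = 0, p)
  expect_equal(unname(q["Qb"]), -p$Z1 * 1)     # -30 uM/s
  expect_equal(unname(q["Qa"]), p$Y2 * 1)      # 1.3 uM/s (maximal overlap)
  expect_equal(unname(q[c("Qr", "Qd", "Qd1", "Qd2")]), rep(0, 4))
  s2 <- c(TCa = 0, TCastar = 0, Tstar = 2, X = 1)
  q2 <- reaction_rates(s2, Ca = 0, L = p$La, dXdt = 0, p)
  expect_equal(unname(q2["Qd"]), 80)
  expect_equal(unname(q2["Qr"]), 0)
  # velocity-dependent detachment is nonnegative and quadratic in dX/dt
  q3 <- reaction_rates(c(TCa = 0, TCastar = 3, Tstar = 2, X = 1),
                       Ca = 0.5, L = 1.1, dXdt = -2, p)
  expect_equal(unname(q3["Qd1"]), p$Yd * 4 * 3)
  expect_equal(unname(q3["Qd2"]), p$Yd * 4 * 2)
  expect_error(reaction_rates(c(TCa = 40, TCastar = 40, Tstar = 40, X = 1),
                              0, 1, 0, p), "free troponin")
})

test_that("state derivatives vanish at rest and follow the relaxation law", {
  L <- 1.05
  rest <- c(TCa = 0, TCastar = 0, Tstar = 0, X = L - p$hc)
  expect_equal(unname(state_derivatives(rest, Ca = 0, L = L, p)), rep(0, 4))
  s <- c(TCa = 0, TCastar = 0, Tstar = 0, X = L - p$hc - 0.001)
  expect_equal(unname(state_derivatives(s, 0, L, p)["dX"]), 0.8,
               tolerance = 1e-12)
})

test_that("active force is bilinear in attached troponin and elongation", {
  expect_equal(active_force(c(0, 0, 0, 1), 1.1, p), 0)
  expect_equal(active_force(c(0, 4, 6, 1.095), 1.1, p),
               p$A * 10 * 0.005, tolerance = 1e-12)
  expect_equal(active_force(c(0, 4, 6, 1.1), 1.1, p), 0)
})

test_that("the muscle partition solves the series/parallel force balance", {
  # passive rest at total length L0: both elements unstretched
  rest0 <- c(TCa = 0, TCastar = 0, Tstar = 0, X = p$L0 - p$hc)
  mf <- solve_muscle_partition(p$L0, rest0, p)
  expect_equal(mf$L, p$L0, tolerance = 1e-9)
  expect_equal(mf$F, 0, tolerance = 1e-9)
  expect_equal(mf$Ls, 0, tolerance = 1e-9)

  # passive stretch: agree with an independent bisection oracle
  bisect <- function(Lt, ct, X) {
    g <- function(L) p$A * ct * (L - X) + p$K * (L - p$L0)^5 -
      p$alpha * expm1(p$beta * (Lt - L))
    lo <- 0.5 * p$L0; hi <- 1.5 * Lt
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-14) break
    }
    (lo + hi) / 2
  }
  rest <- c(TCa = 0, TCastar = 0, Tstar = 0, X = p$L0 - p$hc)
  mf2 <- solve_muscle_partition(1.10, rest, p)
  expect_equal(mf2$L, bisect(1.10, 0, rest[["X"]]), tolerance = 1e-9)
  expect_equal(mf2$Fb + mf2$Fp, mf2$Fs, tolerance = 1e-9)

  # 100 random physiological states
  set.seed(7)
  for (i in 1:100) {
    Lt <- runif(1, 0.95, 1.35)
    ct <- runif(1, 0, 60)
    X <- runif(1, 0.9, 1.2)
    s <- c(TCa = 0, TCastar = ct / 2, Tstar = ct / 2, X = X)
    mf <- solve_muscle_partition(Lt, s, p)
    expect_equal(mf$L, bisect(Lt, ct, X), tolerance = 1e-9)
    expect_lt(abs(mf$F - mf$Fs), 1e-8)
  }
})

test_that("quiescent muscle stays passive and force-length peaks near optimal overlap", {
  pq <- cvs_params(Camax = 1e-12)  # calcium effectively clamped to zero
  r <- run_isovolumic(pq, 20)
  expect_lt(max(abs(r$trace$P - r$trace$P[1])), 1e-6)
  expect_lt(max(p$A * (r$trace$TCastar + r$trace$Tstar) *
                  (r$trace$L - r$trace$X)), 1e-9)

  # peak developed force over one transient, as a function of clamped
  # muscle-unit length, is unimodal with its maximum near La
  Lt_grid <- seq(1.00, 1.30, by = 0.025)
  vols <- p$Kv * Lt_grid^3 - p$f * p$Vw
  fpk <- vapply(vols, function(v) {
    tr <- run_isovolumic(p, v)$trace
    max(tr$F) - tr$F[1]
  }, numeric(1))
  i <- which.max(fpk)
  expect_lt(abs(Lt_grid[i] - p$La), 0.06)
  expect_true(all(diff(fpk[1:i]) > 0))
  expect_true(all(diff(fpk[i:length(fpk)]) < 0))
})
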