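test_that("end-systole detection maximizes P/(V - V0)", {
  rect <- data.frame(t = 1:4 / 10,
                     P = c(0, 100, 100, 0),
                     V = c(10, 10, 20, 20),
                     loop = 1)
  pt <- end_systole_points(rect, V0 = 0)
  expect_equal(pt$Ves, 10)
  expect_equal(pt$Pes, 100)
  # a hugely negative V0 degenerates to max-pressure selection
  pt2 <- end_systole_points(rect, V0 = -1e12)
  expect_equal(pt2$Pes, 100)
  expect_equal(pt2$Ves, 10)  # earliest sample wins the tie
  one <- data.frame(t = 0, P = 55, V = 12, loop = 1)
  expect_equal(end_systole_points(one, 0)$Pes, 55)
  expect_error(end_systole_points(rect, V0 = 30), "V <= V0")
})

test_that("the iterative linear fit recovers exact corner geometry", {
  loops <- synthetic_corner_loops(Ees = 2, V0 = -40)
  fit <- fit_linear_espvr(loops)
  expect_true(fit$converged)
  expect_equal(fit$Ees, 2, tolerance = 1e-9)
  expect_equal(fit$V0, -40, tolerance = 1e-9)

  # brute-force grid confirms (2, -40) is the least-squares optimum over
  # the detected end-systolic points
  pts <- fit$points
  sse <- function(e, v0) sum((pts$Pes - e * (pts$Ves - v0))^2)
  grid <- expand.grid(e = seq(1.5, 2.5, by = 0.05),
                      v0 = seq(-50, -30, by = 0.5))
  grid$sse <- mapply(sse, grid$e, grid$v0)
  expect_equal(grid[which.min(grid$sse), c("e", "v0")],
               data.frame(e = 2, v0 = -40), ignore_attr = TRUE)

  # idempotence: refitting from the converged geometry changes nothing
  refit <- fit_linear_espvr(loops)
  expect_equal(coef(refit), coef(fit))
  expect_error(fit_linear_espvr(loops[loops$loop == 1, ]), "two loops")
})

test_that("the parabolic fit recovers noiseless coefficients exactly", {
  true <- c(a = -0.5, b = 6, V0prime = -5)
  Ves <- seq(8, 22, by = 2)
  Pes <- true["a"] * (Ves - true["V0prime"])^2 +
    true["b"] * (Ves - true["V0prime"])
  fit <- fit_parabolic_espvr(data.frame(Ves = Ves, Pes = Pes))
  expect_equal(fit$a, -0.5, tolerance = 1e-6)
  expect_equal(fit$b, 6, tolerance = 1e-6)
  expect_equal(fit$V0prime, -5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_lt(fit$p_a, 1e-6)
  expect_equal(predict(fit, Ves), unname(Pes), tolerance = 1e-6)
})

test_that("collinear points give a zero-curvature parabola", {
  Ves <- seq(10, 24, by = 2)
  fit <- fit_parabolic_espvr(data.frame(Ves = Ves, Pes = 3 * (Ves + 12)))
  expect_lt(abs(fit$a), 1e-8)
  expect_equal(fit$b, 3, tolerance = 1e-8)
  expect_equal(fit$V0prime, -12, tolerance = 1e-6)
  expect_gt(fit$p_a, 0.99)
})

test_that("the parabola never fits worse than the line (nested models)", {
  set.seed(11)
  for (i in 1:20) {
    Ves <- sort(runif(8, 10, 30))
    Pes <- 2.5 * Ves + 20 + rnorm(8, sd = 4)
    pts <- data.frame(Ves = Ves, Pes = Pes)
    lin <- stats::lm(Pes ~ Ves, data = pts)
    par <- fit_parabolic_espvr(pts)
    expect_lte(par$rss, sum(resid(lin)^2) + 1e-8)
  }
})

test_that("curvature is recovered from noisy points over a broad preload range", {
  set.seed(101)
  true <- c(a = -0.07, b = 5.62, V0prime = -10.4)
  Ves <- seq(15, 35, length.out = 8)
  err <- replicate(500, {
    Pes <- true["a"] * (Ves - true["V0prime"])^2 +
      true["b"] * (Ves - true["V0prime"]) + rnorm(8, sd = 1)
    fit_parabolic_espvr(data.frame(Ves = Ves, Pes = Pes))$a - true["a"]
  })
  expect_lt(median(abs(err)), 0.05)
})

test_that("fit objects round-trip through the JSON writer", {
  loops <- synthetic_corner_loops()
  an <- espvr_analysis(loops)
  path <- tempfile(fileext = ".json")
  write_espvr_json(list(an$linear, an$parabolic), path)
  j <- jsonlite::read_json(path)
  expect_equal(j[[1]]$type, "linear")
  expect_equal(j[[1]]$Ees, an$linear$Ees, tolerance = 1e-12)
  expect_equal(j[[2]]$type, "parabolic")
})
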