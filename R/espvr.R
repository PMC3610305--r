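# End-systolic pressure-volume relationship (ESPVR) analysis: end-systole
# detection as the point of maximal P/(V - V0) on each loop, the classical
# iterative linear fit Pes = Ees (Ves - V0), and the nonlinear parabolic
# fit Pes = a (Ves - V0')^2 + b (Ves - V0') with a Wald test on the
# curvature.

.as_loop_df <- function(loops) {
  if (inherits(loops, "cvs_protocol")) loops <- loops$loops
  stopifnot(is.data.frame(loops), all(c("P", "V", "loop") %in% names(loops)))
  loops
}

#' End-systolic points of PV loops
#'
#' For each loop, the end-systolic point is the sample maximizing
#' `P / (V - V0)`; samples with `V <= V0` are excluded, and ties are
#' broken in favor of the earliest sample of the cycle.
#'
#' @param loops a `pv_loops` data frame (or a `cvs_protocol`).
#' @param V0 volume-axis offset (ml) used in the ratio.
#' @return data frame with columns `loop`, `Ves`, `Pes`.
#' @export
end_systole_points <- function(loops, V0 = 0) {
  loops <- .as_loop_df(loops)
  res <- lapply(split(loops, loops$loop), function(d) {
    ok <- d$V > V0
    if (!any(ok))
      stop("loop ", d$loop[1], " lies entirely at V <= V0 = ", V0)
    d <- d[ok, ]
    i <- which.max(d$P / (d$V - V0))
    data.frame(loop = d$loop[1], Ves = d$V[i], Pes = d$P[i])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Iterative linear ESPVR fit
#'
#' Fits `Pes = Ees (Ves - V0)` by the classical fixed-point scheme:
#' starting from `V0 = 0`, detect the end-systolic points at the current
#' `V0`, regress `Pes` on `Ves` by ordinary least squares, convert slope
#' and intercept to new `(Ees, V0)` estimates, and repeat until `V0`
#' changes by less than `tol`.
#'
#' @param loops a `pv_loops` data frame (or `cvs_protocol`) with at least
#'   two loops of distinct end-systolic volumes.
#' @param tol convergence tolerance on `V0` (ml).
#' @param max_iter maximum number of fixed-point iterations.
#' @return an object of class `espvr_linear`: list with `Ees` (mmHg/ml),
#'   `V0` (ml), `points` (the converged end-systolic points),
#'   `iterations`, `converged`, `fit` (the final `lm`).
#' @export
fit_linear_espvr <- function(loops, tol = 0.01, max_iter = 100) {
  loops <- .as_loop_df(loops)
  if (length(unique(loops$loop)) < 2)
    stop("need at least two loops to fit a linear ESPVR")
  V0 <- 0
  converged <- FALSE
  pts <- NULL; fit <- NULL; Ees <- NA_real_
  for (it in seq_len(max_iter)) {
    pts <- end_systole_points(loops, V0)
    if (length(unique(pts$Ves)) < 2)
      stop("degenerate regression: identical end-systolic volumes")
    fit <- stats::lm(Pes ~ Ves, data = pts)
    cf <- stats::coef(fit)
    Ees <- unname(cf[2])
    if (!is.finite(Ees) || Ees == 0)
      stop("degenerate regression: zero or undefined slope")
    V0_new <- -unname(cf[1]) / Ees
    if (!is.finite(V0_new) || V0_new >= max(loops$V)) {
      # the fixed point escaped the meaningful range (can happen on
      # strongly degenerate transients); report the last usable estimate
      break
    }
    dV0 <- abs(V0_new - V0)
    V0 <- V0_new
    if (dV0 < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("linear ESPVR iteration did not converge within ", max_iter,
            " steps")
  structure(list(Ees = Ees, V0 = V0, points = pts, iterations = it,
                 converged = converged, fit = fit),
            class = "espvr_linear")
}

#' Parabolic ESPVR fit
#'
#' Fits `Pes = a (Ves - V0')^2 + b (Ves - V0')` to end-systolic points by
#' nonlinear least squares (Levenberg-Marquardt), initialized from the
#' exact quadratic polynomial least-squares solution and guarded by a
#' deterministic multistart over jittered initializations. The curvature
#' `a` carries a Wald test (`t = a / se(a)`, `df = n - 3`, two-sided)
#' with the standard error taken from the Jacobian-based covariance at
#' the optimum. Exactly collinear points are returned as the degenerate
#' parabola `a = 0`.
#'
#' @param points data frame with columns `Ves`, `Pes` (e.g. from
#'   [end_systole_points]); at least 4 points.
#' @return an object of class `espvr_parabolic`: list with `a`
#'   (mmHg/ml^2), `b` (mmHg/ml), `V0prime` (ml), `se_a`, `t_a`, `p_a`,
#'   `df`, `rss`, `points`, `fit`.
#' @export
fit_parabolic_espvr <- function(points) {
  stopifnot(is.data.frame(points), all(c("Ves", "Pes") %in% names(points)))
  n <- nrow(points)
  if (n < 4) stop("need at least 4 end-systolic points")
  if (length(unique(points$Ves)) < 3)
    stop("need at least 3 distinct end-systolic volumes")

  # exact solution of the equivalent polynomial problem: the model family
  # {a (V - c)^2 + b (V - c)} coincides with general quadratics, so
  # polynomial OLS provides the global optimum (and the fallback for the
  # collinear degenerate case a = 0)
  qfit <- stats::lm(Pes ~ Ves + I(Ves^2), data = points)
  cf <- stats::coef(qfit)
  c0 <- unname(cf[1]); c1 <- unname(cf[2]); c2 <- unname(cf[3])

  scale_a <- max(abs(points$Pes)) / max(1, diff(range(points$Ves))^2)
  if (abs(c2) < 1e-8 * max(scale_a, 1e-8)) {
    # collinear: zero-curvature parabola through the OLS line
    lfit <- stats::lm(Pes ~ Ves, data = points)
    b <- unname(stats::coef(lfit)[2])
    V0p <- if (b != 0) -unname(stats::coef(lfit)[1]) / b else 0
    se_a <- suppressWarnings(
      summary(qfit)$coefficients["I(Ves^2)", "Std. Error"])
    t_a <- 0
    return(structure(list(a = 0, b = b, V0prime = V0p, se_a = se_a,
                          t_a = t_a,
                          p_a = 1, df = n - 3,
                          rss = sum(stats::resid(lfit)^2),
                          points = points, fit = lfit, degenerate = TRUE),
                     class = "espvr_parabolic"))
  }

  # convert polynomial coefficients to (a, b, V0'): a = c2 and V0' solves
  # a V0'^2 + c1 V0' + c0 = 0. When the unconstrained quadratic has no
  # real root it lies outside the model family and only serves to seed the
  # curvature; the line-based start then anchors (b, V0').
  lfit <- stats::lm(Pes ~ Ves, data = points)
  bl <- unname(stats::coef(lfit)[2])
  V0l <- if (bl != 0) -unname(stats::coef(lfit)[1]) / bl else mean(points$Ves)
  disc <- c1^2 - 4 * c2 * c0
  starts <- list(c(a = c2, b = bl, V0prime = V0l))
  if (disc >= 0) {
    for (V0r in (-c1 + c(1, -1) * sqrt(disc)) / (2 * c2))
      starts <- c(starts, list(c(a = c2, b = c1 + 2 * c2 * V0r,
                                 V0prime = V0r)))
  }
  # deterministic jitter multistart to guard against local minima
  for (fac in list(c(1.2, 0.8, 1.1), c(0.8, 1.2, 0.9), c(1.1, 1.1, 1.2))) {
    s <- starts[[length(starts)]] * fac
    starts <- c(starts, list(stats::setNames(s, c("a", "b", "V0prime"))))
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(Pes ~ a * (Ves - V0prime)^2 + b * (Ves - V0prime),
                        data = points, start = as.list(s),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # every curved fit failed: the constrained optimum degenerates to the
    # zero-curvature boundary of the family (the OLS line)
    se_a <- suppressWarnings(
      summary(qfit)$coefficients["I(Ves^2)", "Std. Error"])
    return(structure(list(a = 0, b = bl, V0prime = V0l, se_a = se_a,
                          t_a = 0, p_a = 1, df = n - 3,
                          rss = sum(stats::resid(lfit)^2),
                          points = points, fit = lfit, degenerate = TRUE),
                     class = "espvr_parabolic"))
  }
  fit <- best$fit
  est <- stats::coef(fit)
  # the family is doubly parameterized (the curve crosses zero at V0p and
  # at V0p - b/a with opposite slope); report the ascending crossing b > 0
  if (est[["b"]] < 0 && est[["a"]] != 0) {
    shift <- c(a = unname(est[["a"]]), b = -unname(est[["b"]]),
               V0prime = unname(est[["V0prime"]] - est[["b"]] / est[["a"]]))
    refit <- tryCatch(
      minpack.lm::nlsLM(Pes ~ a * (Ves - V0prime)^2 + b * (Ves - V0prime),
                        data = points, start = as.list(shift),
                        control = minpack.lm::nls.lm.control(maxiter = 50)),
      error = function(e) NULL)
    if (!is.null(refit) &&
        sum(stats::resid(refit)^2) <= best$rss + 1e-8) {
      fit <- refit
      best$rss <- sum(stats::resid(refit)^2)
      est <- stats::coef(fit)
    }
  }
  sm <- suppressWarnings(summary(fit))
  se_a <- sm$coefficients["a", "Std. Error"]
  t_a <- est[["a"]] / se_a
  p_a <- 2 * stats::pt(abs(t_a), df = n - 3, lower.tail = FALSE)
  structure(list(a = est[["a"]], b = est[["b"]], V0prime = est[["V0prime"]],
                 se_a = se_a, t_a = t_a, p_a = p_a, df = n - 3,
                 rss = best$rss, points = points, fit = fit,
                 degenerate = FALSE),
            class = "espvr_parabolic")
}

#' @export
print.espvr_linear <- function(x, ...) {
  cat(sprintf("Linear ESPVR: Pes = %.4g (Ves - (%.4g))\n", x$Ees, x$V0))
  cat(sprintf("  Ees = %.4g mmHg/ml, V0 = %.4g ml (%d iterations%s)\n",
              x$Ees, x$V0, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
coef.espvr_linear <- function(object, ...) {
  c(Ees = object$Ees, V0 = object$V0)
}

#' @export
predict.espvr_linear <- function(object, V, ...) {
  if (missing(V)) V <- object$points$Ves
  object$Ees * (V - object$V0)
}

#' @export
residuals.espvr_linear <- function(object, ...) {
  object$points$Pes - predict(object, object$points$Ves)
}

#' @export
print.espvr_parabolic <- function(x, ...) {
  cat(sprintf(
    "Parabolic ESPVR: Pes = %.4g (Ves - (%.4g))^2 + %.4g (Ves - (%.4g))\n",
    x$a, x$V0prime, x$b, x$V0prime))
  cat(sprintf("  curvature a = %.4g mmHg/ml^2 (se %.3g, t = %.3g, p = %.4g)\n",
              x$a, x$se_a, x$t_a, x$p_a))
  invisible(x)
}

#' @export
coef.espvr_parabolic <- function(object, ...) {
  c(a = object$a, b = object$b, V0prime = object$V0prime)
}

#' @export
predict.espvr_parabolic <- function(object, V, ...) {
  if (missing(V)) V <- object$points$Ves
  object$a * (V - object$V0prime)^2 + object$b * (V - object$V0prime)
}

#' @export
residuals.espvr_parabolic <- function(object, ...) {
  object$points$Pes - predict(object, object$points$Ves)
}

#' Plot an ESPVR fit over its end-systolic points
#' @param x an `espvr_linear` or `espvr_parabolic` object.
#' @param ... passed to `plot`.
#' @export
plot.espvr_parabolic <- function(x, ...) {
  .plot_espvr(x, ...)
}

#' @rdname plot.espvr_parabolic
#' @export
plot.espvr_linear <- function(x, ...) {
  .plot_espvr(x, ...)
}

.plot_espvr <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$Ves, pts$Pes, pch = 19,
                 xlab = "end-systolic volume (ml)",
                 ylab = "end-systolic pressure (mmHg)", ...)
  vv <- seq(min(pts$Ves), max(pts$Ves), length.out = 200)
  graphics::lines(vv, predict(x, vv), lty = 2)
  invisible(x)
}

#' Full ESPVR analysis of a set of loops
#'
#' The analysis sequence applied to every protocol: iterative linear fit
#' on all loops, end-systole detection at the converged `V0`, then the
#' parabolic fit on those points.
#'
#' @param loops a `pv_loops` data frame or `cvs_protocol`.
#' @return list with `linear` (on all loops), `points`, `parabolic`.
#' @export
espvr_analysis <- function(loops) {
  loops <- .as_loop_df(loops)
  lin <- fit_linear_espvr(loops)
  pts <- end_systole_points(loops, lin$V0)
  list(linear = lin, points = pts, parabolic = fit_parabolic_espvr(pts))
}

#' Write an ESPVR fit as JSON
#'
#' @param fits a list of ESPVR fit objects (linear or parabolic).
#' @param path output path.
#' @export
write_espvr_json <- function(fits, path) {
  enc <- function(f) {
    if (inherits(f, "espvr_linear"))
      list(type = "linear", Ees = f$Ees, V0 = f$V0,
           iterations = f$iterations, converged = f$converged)
    else if (inherits(f, "espvr_parabolic"))
      list(type = "parabolic", a = f$a, b = f$b, V0prime = f$V0prime,
           se_a = f$se_a, p_a = f$p_a)
    else stop("not an ESPVR fit object")
  }
  if (inherits(fits, "espvr_linear") || inherits(fits, "espvr_parabolic"))
    fits <- list(fits)
  jsonlite::write_json(lapply(fits, enc), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
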