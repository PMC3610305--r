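# Simulation engine: assembles the 10-dimensional state (six chamber
# volumes + four sarcomere states), integrates it with an adaptive stiff
# solver (deSolve/lsoda over the compiled right-hand side), detects
# periodic steady state cycle by cycle, and segments output into
# pressure-volume loops.

#' Default initial state of the closed loop
#'
#' Both ventricles start at the reference mean ventricular volume
#' (20.8 ml); the remaining blood volume is split among the four passive
#' chambers inversely proportional to their elastances (equal initial
#' pressures). The sarcomere starts at rest: all troponin free and the
#' cross-bridge at its equilibrium elongation. Steady-state convergence
#' erases the arbitrariness of this split.
#'
#' @param p a [cvs_params] object.
#' @param V_vent initial volume of each ventricle (ml).
#' @return named numeric state vector of length 10.
#' @export
initial_state <- function(p, V_vent = 20.8) {
  validate_params(p)
  rest <- p$V_total - 2 * V_vent
  if (rest <= 0) stop("total blood volume too small for the ventricular volumes")
  w <- 1 / c(p$E_ao, p$E_vc, p$E_pa, p$E_pu)
  Vp <- rest * w / sum(w)
  Lt <- fiber_length_from_volume(V_vent, p)
  sarc <- .rest_sarcomere(Lt, p)
  stats::setNames(c(V_vent, V_vent, Vp[1], Vp[2], Vp[3], Vp[4], sarc),
                  .state_names)
}

#' Integrate the closed-loop model
#'
#' Integrates the full 10-dimensional model with `deSolve::lsoda`
#' (adaptive, stiffness-switching), producing dense output at `dt`
#' spacing, chamber pressures and all valve/vessel flows. Time 0 of a
#' simulation is cycle time 0 (the calcium and activation drivers are
#' periodic in simulation time).
#'
#' @param p a [cvs_params] object.
#' @param duration simulated time (s).
#' @param init initial state (named length-10 vector); default
#'   [initial_state].
#' @param pu_outflow constant external outflow at the pulmonary veins
#'   (ml/s); protocols build piecewise-constant schedules by chaining
#'   simulations.
#' @param dt output cadence (s); at most 1 ms.
#' @param rtol,atol integrator tolerances.
#' @return an object of class `cvs_sim`: list with `time`, `state` (10-col
#'   matrix), `pressures` (6-col), `flows` (6-col), `L`, `F`, `params`,
#'   `pu_outflow`.
#' @export
simulate_cvs <- function(p, duration, init = NULL, pu_outflow = 0,
                         dt = 1e-3, rtol = 1e-6, atol = 1e-9) {
  validate_params(p)
  stopifnot(duration > 0, dt <= 1e-3 + 1e-12)
  if (is.null(init)) init <- initial_state(p)
  stopifnot(length(init) == 10)
  init <- stats::setNames(as.numeric(init), .state_names)
  times <- seq(0, duration, by = dt)
  if (utils::tail(times, 1) < duration - 1e-12)
    times <- c(times, duration)
  outnames <- c(.pressure_names, .flow_names, "L", "F")
  out <- deSolve::lsoda(
    y = init, times = times, func = "cv_derivs_full",
    parms = .parm_vector(p, qout = pu_outflow),
    dllname = "cvloop", initfunc = "cv_init",
    nout = 14, outnames = outnames,
    rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(out, "istate")[1] < 0)
    stop("integration failed (lsoda istate = ", attr(out, "istate")[1], ")")
  .as_cvs_sim(out, p, pu_outflow)
}

.as_cvs_sim <- function(out, p, pu_outflow) {
  m <- unclass(out)
  structure(list(
    time = m[, "time"],
    state = m[, .state_names, drop = FALSE],
    pressures = m[, .pressure_names, drop = FALSE],
    flows = m[, .flow_names, drop = FALSE],
    L = m[, "L"], F = m[, "F"],
    params = p, pu_outflow = pu_outflow,
    period = p$period), class = "cvs_sim")
}

# free troponin along a trajectory (conservation diagnostic)
.free_troponin <- function(sim) {
  sim$params$Tt - rowSums(sim$state[, c("TCa", "TCastar", "Tstar")])
}

#' Run to periodic steady state
#'
#' Integrates cycle by cycle and declares steady state when consecutive
#' cycle-start states agree in relative max-norm below `tol` (component
#' scales floored at 0.01 in model units so that near-zero concentrations
#' do not dominate the norm). Returns the last simulated cycle.
#'
#' @param p a [cvs_params] object.
#' @param max_cycles maximum number of cardiac cycles.
#' @param tol relative convergence threshold on cycle-start states.
#' @param init optional initial state.
#' @param dt,rtol,atol passed to [simulate_cvs].
#' @return a `cvs_sim` of one cycle (the periodic cycle when `converged`),
#'   with extra fields `converged`, `n_cycles` and `state0` (the
#'   cycle-start state).
#' @export
run_to_steady_state <- function(p, max_cycles = 500, tol = 1e-4,
                                init = NULL, dt = 1e-3,
                                rtol = 1e-6, atol = 1e-9) {
  validate_params(p)
  state <- if (is.null(init)) initial_state(p) else
    stats::setNames(as.numeric(init), .state_names)
  converged <- FALSE
  sim <- NULL
  n <- 0
  for (cyc in seq_len(max_cycles)) {
    sim <- simulate_cvs(p, duration = p$period, init = state, dt = dt,
                        rtol = rtol, atol = atol)
    n <- cyc
    new_state <- sim$state[nrow(sim$state), ]
    rel <- max(abs(new_state - state) / pmax(abs(state), 0.01))
    state <- new_state
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("no periodic steady state within ", max_cycles,
            " cycles (last relative change ", format(rel), ")")
  sim$converged <- converged
  sim$n_cycles <- n
  sim$state0 <- sim$state[1, ]
  sim
}

#' Segment a simulation into pressure-volume loops
#'
#' Splits a simulation at cycle boundaries (integer multiples of the
#' cardiac period from simulation start) into left-ventricular PV loops.
#'
#' @param sim a `cvs_sim` object covering at least one full period.
#' @return a data frame of class `pv_loops` with columns `t` (time within
#'   the simulation, s), `P` (LV pressure, mmHg), `V` (LV volume, ml) and
#'   `loop` (1-based loop index); one block of >= 100 samples per complete
#'   cycle.
#' @export
extract_pv_loops <- function(sim) {
  stopifnot(inherits(sim, "cvs_sim"))
  t <- sim$time - sim$time[1]
  period <- sim$period
  n_loops <- floor(round(max(t) / period, 8))
  if (n_loops < 1)
    stop("simulation shorter than one cardiac period: no complete loop")
  loop <- floor(round(t / period, 8)) + 1
  keep <- loop <= n_loops
  out <- data.frame(t = t[keep],
                    P = sim$pressures[keep, "P_lv"],
                    V = sim$state[keep, "V_lv"],
                    loop = loop[keep])
  class(out) <- c("pv_loops", "data.frame")
  attr(out, "period") <- period
  out
}

#' Valve event times of a cycle
#'
#' Detects openings and closures of the mitral and aortic valves from the
#' zero/nonzero transitions of the corresponding diode flows on the output
#' grid. On a normal cycle starting at the onset of contraction the
#' ordering is mitral closure, aortic opening, aortic closure, mitral
#' opening.
#'
#' @param sim a `cvs_sim` object (typically one steady-state cycle).
#' @return a data frame with columns `event` (`"mt_close"`, `"av_open"`,
#'   `"av_close"`, `"mt_open"`), `time` (s from simulation start) and
#'   `index` (row of the sample at/after the transition).
#' @export
valve_events <- function(sim) {
  stopifnot(inherits(sim, "cvs_sim"))
  trans <- function(q, type) {
    open <- q > 0
    idx <- if (type == "open") which(!open[-length(open)] & open[-1]) + 1
           else which(open[-length(open)] & !open[-1]) + 1
    idx
  }
  ev <- rbind(
    data.frame(event = "mt_close", index = trans(sim$flows[, "Q_mt"], "close")),
    data.frame(event = "mt_open",  index = trans(sim$flows[, "Q_mt"], "open")),
    data.frame(event = "av_open",  index = trans(sim$flows[, "Q_av"], "open")),
    data.frame(event = "av_close", index = trans(sim$flows[, "Q_av"], "close")))
  if (nrow(ev) == 0) return(data.frame(event = character(0),
                                       time = numeric(0), index = integer(0)))
  ev$time <- sim$time[ev$index]
  ev[order(ev$time), c("event", "time", "index")]
}

#' @export
print.cvs_sim <- function(x, ...) {
  dur <- diff(range(x$time))
  cat("Closed-loop cardiovascular simulation\n")
  cat(sprintf("  duration: %.3f s (%.1f cycles of %.2f s), %d samples\n",
              dur, dur / x$period, x$period, length(x$time)))
  if (!is.null(x$converged))
    cat(sprintf("  steady state: %s after %d cycle(s)\n",
                if (x$converged) "converged" else "NOT converged", x$n_cycles))
  rng <- function(v) sprintf("[%.1f, %.1f]", min(v), max(v))
  cat("  P_lv (mmHg):", rng(x$pressures[, "P_lv"]),
      " V_lv (ml):", rng(x$state[, "V_lv"]), "\n")
  cat("  total volume (ml):", rng(rowSums(x$state[, .chambers])), "\n")
  invisible(x)
}

#' @export
as.data.frame.cvs_sim <- function(x, ...) {
  data.frame(time = x$time, x$state, x$pressures, x$flows,
             L = x$L, F = x$F, check.names = FALSE)
}

#' Plot a simulation
#'
#' `type = "pv"` draws the left-ventricular pressure-volume trajectory;
#' `type = "time"` draws pulmonary-venous, left-ventricular and aortic
#' pressures against time.
#'
#' @param x a `cvs_sim` object.
#' @param type `"pv"` or `"time"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.cvs_sim <- function(x, type = c("pv", "time"), ...) {
  type <- match.arg(type)
  if (type == "pv") {
    graphics::plot(x$state[, "V_lv"], x$pressures[, "P_lv"], type = "l",
                   xlab = "LV volume (ml)", ylab = "LV pressure (mmHg)", ...)
  } else {
    graphics::matplot(x$time, x$pressures[, c("P_pu", "P_lv", "P_ao")],
                      type = "l", lty = 1,
                      col = c("red", "black", "blue"),
                      xlab = "time (s)", ylab = "pressure (mmHg)", ...)
    graphics::legend("topright", c("P_pu", "P_lv", "P_ao"), lty = 1,
                     col = c("red", "black", "blue"), bty = "n")
  }
  invisible(x)
}

#' Export a simulation as CSV plus a JSON run summary
#'
#' Writes one CSV row per sample (time, six volumes, six pressures, six
#' flows, muscle length and force) and a JSON summary holding the
#' parameters, convergence diagnostics and conservation checks.
#'
#' @param sim a `cvs_sim` object.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return invisibly, a list with the summary.
#' @export
export_sim <- function(sim, csv = NULL, json = NULL) {
  stopifnot(inherits(sim, "cvs_sim"))
  if (!is.null(csv))
    utils::write.csv(as.data.frame(sim), csv, row.names = FALSE)
  total <- rowSums(sim$state[, .chambers])
  summary <- list(
    parameters = stats::setNames(
      lapply(.par_order, function(nm) sim$params[[nm]]), .par_order),
    duration_s = diff(range(sim$time)),
    n_samples = length(sim$time),
    pu_outflow_ml_s = sim$pu_outflow,
    converged = sim$converged,
    n_cycles = sim$n_cycles,
    volume_drift_ml = max(total) - min(total) -
      abs(sim$pu_outflow) * diff(range(sim$time)),
    min_free_troponin_uM = min(.free_troponin(sim)))
  if (!is.null(json))
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(summary)
}
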