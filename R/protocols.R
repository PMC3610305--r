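# In-silico experiment protocols: preload reduction (atrial hemorrhage,
# mitral-resistance step), afterload increase (aortic elastance, systemic
# resistance), contractility scaling, isovolumic contractions and flow
# clamps. Loop-producing protocols start from the periodic steady state of
# the closed loop and apply the intervention at a cycle boundary.

#' Preload reduction by atrial hemorrhage
#'
#' From the periodic steady state, a constant outward flow is applied at
#' the pulmonary-vein compartment (the atria are merged with it) and the
#' model is simulated for `duration` seconds. With the defaults (50 ml/s
#' for 4.8 s, i.e. 8 cycles) the loops shift monotonically to lower
#' volumes.
#'
#' @param p a [cvs_params] object.
#' @param outflow pulmonary-vein outflow (ml/s, `>= 0`).
#' @param duration protocol duration (s); must be a positive multiple of
#'   the cardiac period.
#' @param steady optional precomputed [run_to_steady_state] result (reused
#'   across protocols to avoid re-settling).
#' @param ... passed to [run_to_steady_state].
#' @return a list of class `cvs_protocol` with elements `loops`
#'   ([extract_pv_loops] of the transient), `sim`, `steady` and `label`.
#' @export
run_hemorrhage <- function(p, outflow = 50, duration = 4.8, steady = NULL,
                           ...) {
  stopifnot(outflow >= 0)
  .check_loop_duration(duration, p$period)
  if (is.null(steady)) steady <- run_to_steady_state(p, ...)
  sim <- simulate_cvs(p, duration = duration, init = steady$state0,
                      pu_outflow = outflow)
  if (min(sim$state[, "V_pu"]) <= 0)
    stop("pulmonary-vein compartment emptied during hemorrhage; ",
         "reduce the outflow or the duration")
  structure(list(loops = extract_pv_loops(sim), sim = sim, steady = steady,
                 label = sprintf("hemorrhage %g ml/s", outflow)),
            class = "cvs_protocol")
}

#' Load step protocols
#'
#' Applies an instantaneous parameter change at a cycle boundary of the
#' periodic steady state and returns the ensuing transient loops:
#' `"R_mt"` (mitral resistance, default tenfold -- preload reduction),
#' `"E_ao"` (aortic elastance, default doubling -- afterload increase) or
#' `"R_sys"` (systemic resistance, default doubling -- afterload
#' increase).
#'
#' @param p a [cvs_params] object.
#' @param which which parameter to step.
#' @param factor multiplicative factor; default 10 for `R_mt`, 2
#'   otherwise.
#' @param duration transient duration (s), a multiple of the period.
#' @param steady optional precomputed steady state.
#' @param ... passed to [run_to_steady_state].
#' @return a `cvs_protocol` list (see [run_hemorrhage]).
#' @export
run_parameter_step <- function(p, which = c("R_mt", "E_ao", "R_sys"),
                               factor = NULL, duration = 4.8,
                               steady = NULL, ...) {
  which <- match.arg(which)
  if (is.null(factor)) factor <- if (which == "R_mt") 10 else 2
  stopifnot(factor > 0)
  .check_loop_duration(duration, p$period)
  if (is.null(steady)) steady <- run_to_steady_state(p, ...)
  p2 <- p
  p2[[which]] <- p[[which]] * factor
  attr(p2, "provenance")[[which]] <- "user"
  sim <- simulate_cvs(p2, duration = duration, init = steady$state0)
  structure(list(loops = extract_pv_loops(sim), sim = sim, steady = steady,
                 label = sprintf("%s x %g", which, factor)),
            class = "cvs_protocol")
}

.check_loop_duration <- function(duration, period) {
  k <- duration / period
  if (duration <= 0 || abs(k - round(k)) > 1e-8)
    stop("duration must be a positive multiple of the cardiac period")
}

#' @export
print.cvs_protocol <- function(x, ...) {
  cat("Protocol:", x$label, "\n")
  nl <- max(x$loops$loop)
  ed <- vapply(split(x$loops$V, x$loops$loop), max, numeric(1))
  cat(sprintf("  %d loops; end-diastolic V_lv from %.2f to %.2f ml\n",
              nl, ed[1], ed[nl]))
  invisible(x)
}

# integrate the isolated left ventricle with a prescribed volume
# trajectory (two-column matrix t, V) over [0, duration]
.simulate_isolated_lv <- function(p, vol_table, duration, dt = 1e-3,
                                  rtol = 1e-6, atol = 1e-9) {
  validate_params(p)
  Lt0 <- fiber_length_from_volume(vol_table[1, 2], p)
  init <- .rest_sarcomere(Lt0, p)
  times <- seq(0, duration, by = dt)
  out <- deSolve::lsoda(
    y = init, times = times, func = "cv_derivs_lviso",
    parms = .parm_vector(p), dllname = "cvloop", initfunc = "cv_init",
    initforc = "cv_forc_lviso", forcings = vol_table,
    fcontrol = list(method = "linear", rule = 2),
    nout = 4, outnames = c("P_lv", "L", "F", "V_lv"),
    rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(out, "istate")[1] < 0)
    stop("isolated-ventricle integration failed")
  m <- unclass(out)
  data.frame(time = m[, "time"], P = m[, "P_lv"], V = m[, "V_lv"],
             L = m[, "L"], F = m[, "F"],
             TCa = m[, "TCa"], TCastar = m[, "TCastar"],
             Tstar = m[, "Tstar"], X = m[, "X"])
}

#' Isovolumic contraction
#'
#' Simulates one calcium transient of the ventricle decoupled from the
#' circulation at a clamped cavity volume, starting from the sarcomere
#' rest state. Returns the pressure trace together with the end-diastolic
#' (passive) pressure, the peak pressure and the developed pressure
#' (peak minus passive).
#'
#' @param p a [cvs_params] object.
#' @param volume clamped cavity volume (ml), `> 0`.
#' @param duration simulated time (s), default one cardiac period.
#' @return a list of class `isovolumic` with `trace` (data frame), `V`,
#'   `P_ed`, `P_peak`, `P_dev`.
#' @export
run_isovolumic <- function(p, volume, duration = p$period) {
  stopifnot(volume > 0)
  tr <- .simulate_isolated_lv(p, cbind(c(0, duration), c(volume, volume)),
                              duration)
  structure(list(trace = tr, V = volume,
                 P_ed = tr$P[1], P_peak = max(tr$P),
                 P_dev = max(tr$P) - tr$P[1]),
            class = "isovolumic")
}

#' Isovolumic pressure-volume sweep
#'
#' Repeats [run_isovolumic] over a set of clamped volumes (the classical
#' isovolumic characterization of the ventricle, 10 to 25 ml by default).
#'
#' @param p a [cvs_params] object.
#' @param volumes clamped volumes (ml).
#' @return data frame with columns `V`, `P_ed`, `P_peak`, `P_dev`.
#' @export
isovolumic_sweep <- function(p, volumes = seq(10, 25, length.out = 16)) {
  rows <- lapply(volumes, function(v) {
    r <- run_isovolumic(p, v)
    data.frame(V = v, P_ed = r$P_ed, P_peak = r$P_peak, P_dev = r$P_dev)
  })
  do.call(rbind, rows)
}

#' Flow-clamp experiment
#'
#' Imposes linear ventricular volume ramps (constant ejection flows) on
#' the isolated ventricle and measures pressure across flows at a matched
#' volume and matched cycle time: for each clamped flow `Q` the ramp
#' onset is staggered so that the cavity passes through `match_volume`
#' exactly at `t_match`, so the activation state is identical across
#' flows and pressure differences isolate the flow effect. The slope of
#' the linear pressure-flow regression is the ventricle's internal
#' resistance (expected negative: pressure falls as ejection flow
#' rises).
#'
#' The cavity is held at `V_start` while the contraction develops from
#' rest; a flow of 0 is simulated as a pure isovolumic beat (and excluded
#' from the regression, since it never reaches the matched volume).
#'
#' @param p a [cvs_params] object.
#' @param V_start starting (end-diastolic) volume (ml).
#' @param flows clamped ejection flows (ml/s), nonnegative; at least two
#'   positive values.
#' @param match_volume volume (ml) at which pressures are compared.
#' @param t_match cycle time (s) at which every ramp crosses
#'   `match_volume`; within systole.
#' @param duration simulated time (s).
#' @return a list of class `flow_clamp` with `samples` (data frame `Q`,
#'   `onset`, `P_match`), `slope` (mmHg s/ml), `fit` (the `lm`), and
#'   `traces`.
#' @export
run_flow_clamp <- function(p, V_start = 25, flows = seq(10, 50, by = 10),
                           match_volume = V_start - 1, t_match = 0.15,
                           duration = 0.4) {
  stopifnot(V_start > 0, all(flows >= 0), t_match > 0, t_match < duration,
            match_volume > 0, match_volume < V_start)
  dV <- V_start - match_volume
  traces <- lapply(flows, function(q) {
    if (q == 0)
      return(.simulate_isolated_lv(p, cbind(c(0, duration),
                                            c(V_start, V_start)), duration))
    onset <- t_match - dV / q
    if (onset <= 0)
      stop("flow ", q, " ml/s cannot reach the matched volume by t_match; ",
           "increase t_match or reduce the volume offset")
    v_end <- V_start - q * (duration - onset)
    if (v_end < 0)
      stop("flow clamp of ", q, " ml/s drives the volume negative before ",
           duration, " s; shorten the ramp or lower the flow")
    tab <- cbind(c(0, onset, duration), c(V_start, V_start, v_end))
    .simulate_isolated_lv(p, tab, duration)
  })
  samples <- do.call(rbind, Map(function(q, tr) {
    if (q == 0) return(NULL)
    data.frame(Q = q, onset = t_match - dV / q,
               P_match = stats::approx(tr$time, tr$P, xout = t_match)$y)
  }, flows, traces))
  if (is.null(samples) || nrow(samples) < 2)
    stop("need at least two nonzero flows to fit the pressure-flow relation")
  fit <- stats::lm(P_match ~ Q, data = samples)
  structure(list(samples = samples, slope = unname(stats::coef(fit)[2]),
                 fit = fit, traces = stats::setNames(traces, flows),
                 V_start = V_start, match_volume = match_volume,
                 t_match = t_match),
            class = "flow_clamp")
}

#' @export
print.flow_clamp <- function(x, ...) {
  cat(sprintf(
    "Flow clamp from %.1f ml, matched at %.1f ml and t = %.3f s: internal resistance %.4f mmHg s/ml\n",
    x$V_start, x$match_volume, x$t_match, x$slope))
  print(x$samples, row.names = FALSE)
  invisible(x)
}
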