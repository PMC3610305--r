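# Stepwise parameter identification against reference hemodynamic targets:
# direct computations (wall volume, RV elastance, vascular resistances),
# isovolumic initialization of the ventricular geometry, then Nelder-Mead
# simplex fits of the systemic subsystem, the pulmonary subsystem and the
# venous elastances. The circulation is split for the subsystem steps by
# holding the venous pressures constant.

.target_names <- c("lv_pulse_pressure", "mean_lv_pressure",
                   "p_ao_at_valve_open", "p_ao_at_valve_close",
                   "mean_ventricular_volume", "stroke_volume",
                   "rv_pulse_pressure", "mean_rv_pressure")

#' Reference hemodynamic targets
#'
#' Builds the named target list used by the identification pipeline; the
#' defaults are the canine reference values (pressures in mmHg, volumes in
#' ml).
#'
#' @param lv_pulse_pressure,mean_lv_pressure LV pulse and mean pressure.
#' @param p_ao_at_valve_open,p_ao_at_valve_close aortic pressure at aortic
#'   valve opening/closure.
#' @param mean_ventricular_volume,stroke_volume volume targets, shared by
#'   the two ventricles.
#' @param rv_pulse_pressure,mean_rv_pressure RV pressure targets.
#' @return named list of class `hemo_targets`.
#' @export
hemo_targets <- function(lv_pulse_pressure = 119, mean_lv_pressure = 66,
                         p_ao_at_valve_open = 115,
                         p_ao_at_valve_close = 121,
                         mean_ventricular_volume = 20.8,
                         stroke_volume = 11.7,
                         rv_pulse_pressure = 45.8,
                         mean_rv_pressure = 22.9) {
  out <- list(lv_pulse_pressure = lv_pulse_pressure,
              mean_lv_pressure = mean_lv_pressure,
              p_ao_at_valve_open = p_ao_at_valve_open,
              p_ao_at_valve_close = p_ao_at_valve_close,
              mean_ventricular_volume = mean_ventricular_volume,
              stroke_volume = stroke_volume,
              rv_pulse_pressure = rv_pulse_pressure,
              mean_rv_pressure = mean_rv_pressure)
  if (any(vapply(out, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all targets must be positive numbers")
  structure(out, class = c("hemo_targets", "list"))
}

#' Read targets from a CSV fixture
#'
#' Expects columns `name` and `value` covering the eight reference rows.
#'
#' @param path CSV path; default the packaged reference table.
#' @return a `hemo_targets` list.
#' @export
read_targets <- function(path = system.file("extdata",
                                            "reference_targets.csv",
                                            package = "cvloop")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(d)))
    stop("target file needs columns 'name' and 'value'")
  missing <- setdiff(.target_names, d$name)
  if (length(missing))
    stop("missing target row(s): ", paste(missing, collapse = ", "))
  do.call(hemo_targets, as.list(stats::setNames(d$value, d$name))[.target_names])
}

#' @rdname read_targets
#' @details `read_iso_targets` reads the four-point isovolumic target table
#'   (`V`, `Pes`, `Ped`) used to initialize the ventricular geometry
#'   (step 3). The packaged default is a synthetic stand-in generated from
#'   the reference parameterization, since the manually read experimental
#'   loop points are not available; identification is therefore validated
#'   by self-consistency recovery.
#' @export
read_iso_targets <- function(path = system.file(
  "extdata", "isovolumic_targets_synthetic.csv", package = "cvloop")) {
  d <- utils::read.csv(path)
  if (!all(c("V", "Pes", "Ped") %in% names(d)))
    stop("isovolumic target file needs columns V, Pes, Ped")
  d
}

# --- cycle measurements ---------------------------------------------------

.aortic_valve_pressures <- function(time, Pao, Qav) {
  open <- Qav > 0
  n <- length(open)
  i_open <- which(!open[-n] & open[-1]) + 1
  i_close <- which(open[-n] & !open[-1]) + 1
  if (!length(i_open) || !length(i_close))
    stop("no aortic valve events: the ventricle never ejects")
  c(open = Pao[i_open[1]], close = Pao[i_close[1]])
}

.measure_lv <- function(time, Plv, Pao, Qav, Vlv) {
  # "mean" follows the reference-table convention: the midrange
  # (max + min)/2 of the cycle (the RV mean there is exactly half the RV
  # pulse pressure, and the end-diastolic volume implied by the
  # wall-volume computation is mean volume + SV/2)
  pv <- .aortic_valve_pressures(time, Pao, Qav)
  list(lv_pulse_pressure = max(Plv) - min(Plv),
       mean_lv_pressure = (max(Plv) + min(Plv)) / 2,
       p_ao_at_valve_open = unname(pv["open"]),
       p_ao_at_valve_close = unname(pv["close"]),
       mean_ventricular_volume = (max(Vlv) + min(Vlv)) / 2,
       stroke_volume = max(Vlv) - min(Vlv))
}

.measure_rv <- function(Prv, Vrv) {
  list(rv_pulse_pressure = max(Prv) - min(Prv),
       mean_rv_pressure = (max(Prv) + min(Prv)) / 2,
       mean_ventricular_volume = (max(Vrv) + min(Vrv)) / 2,
       stroke_volume = max(Vrv) - min(Vrv))
}

#' Measure the reference quantities on a periodic cycle
#'
#' Computes the eight hemodynamic reference quantities from one
#' steady-state cycle of the full model: pulse pressures as max minus min,
#' means over the cycle, aortic pressure sampled at the aortic-valve
#' opening and closure events, mean LV volume and stroke volume
#' (max minus min of LV volume).
#'
#' @param sim a one-cycle `cvs_sim` (e.g. from [run_to_steady_state]).
#' @return a `hemo_targets` list of measured values.
#' @export
measure_targets <- function(sim) {
  stopifnot(inherits(sim, "cvs_sim"))
  lv <- .measure_lv(sim$time, sim$pressures[, "P_lv"],
                    sim$pressures[, "P_ao"], sim$flows[, "Q_av"],
                    sim$state[, "V_lv"])
  rv <- .measure_rv(sim$pressures[, "P_rv"], sim$state[, "V_rv"])
  # measured values are reported as-is (degenerate inputs may yield zero
  # pulse pressures); positivity is only enforced on reference targets
  structure(c(lv, rv[c("rv_pulse_pressure", "mean_rv_pressure")]),
            class = c("hemo_targets", "list"))
}

#' Constant venous pressures for the split model
#'
#' For the subsystem identification steps the vena cava and pulmonary
#' veins become constant-pressure points. The constants are taken as the
#' mean of the ventricular pressures at the beginning and end of diastole
#' (atrioventricular valve opening and closure) on a steady-state cycle.
#'
#' @param sim a one-cycle `cvs_sim`.
#' @return list with `P_pu` and `P_vc` (mmHg).
#' @export
venous_pressures_from_cycle <- function(sim) {
  stopifnot(inherits(sim, "cvs_sim"))
  av_mean <- function(q, pvent) {
    open <- q > 0
    n <- length(open)
    i_open <- which(!open[-n] & open[-1]) + 1
    i_close <- which(open[-n] & !open[-1]) + 1
    if (!length(i_open) || !length(i_close))
      stop("no filling events on the cycle")
    mean(c(pvent[i_open[1]], pvent[i_close[1]]))
  }
  list(P_pu = av_mean(sim$flows[, "Q_mt"], sim$pressures[, "P_lv"]),
       P_vc = av_mean(sim$flows[, "Q_tc"], sim$pressures[, "P_rv"]))
}

# --- step 1: direct computations -----------------------------------------

#' Direct parameter computation from PV-loop readings
#'
#' Computes the four directly identifiable parameters. The wall volume
#' solves the spherical shell relation
#' `V_ed + Vw = 4/3 pi (R_lv + t)^3` with `R_lv = (3 V_ed / 4 pi)^(1/3)`
#' and wall thickness `t` (0.9 cm). The RV end-systolic elastance is the
#' pressure-to-volume ratio at the RV end-systolic point (the activation
#' function equals 1 there). The vascular resistances follow from the
#' systemic/pulmonary pressure drops over cardiac output, with
#' `CO = stroke volume / period`.
#'
#' @param V_ed LV end-diastolic volume (ml).
#' @param rv_es RV end-systolic point as `c(V, P)` (ml, mmHg).
#' @param p_ao_mean,p_vc_mean,p_pa_mean,p_pu_mean mean pressures (mmHg).
#' @param stroke_volume ml per beat.
#' @param period cardiac period (s).
#' @param wall_thickness cm.
#' @return list with `Vw` (ml), `E_rv` (mmHg/ml), `R_sys`, `R_pul`
#'   (mmHg s/ml) and `CO` (ml/s).
#' @export
step1_direct <- function(V_ed, rv_es, p_ao_mean, p_vc_mean,
                         p_pa_mean, p_pu_mean, stroke_volume,
                         period = 0.6, wall_thickness = 0.9) {
  vals <- c(V_ed, rv_es, p_ao_mean, p_vc_mean, p_pa_mean, p_pu_mean,
            stroke_volume, period, wall_thickness)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs to the direct computation must be positive")
  R_lv <- (3 * V_ed / (4 * pi))^(1 / 3)
  Vw <- 4 / 3 * pi * (R_lv + wall_thickness)^3 - V_ed
  CO <- stroke_volume / period
  list(Vw = Vw,
       E_rv = rv_es[2] / rv_es[1],
       R_sys = (p_ao_mean - p_vc_mean) / CO,
       R_pul = (p_pa_mean - p_pu_mean) / CO,
       CO = CO)
}

# --- split-model simulators ----------------------------------------------

#' Simulate the systemic subsystem
#'
#' Left ventricle (sarcomere model) and aorta with constant pulmonary-vein
#' and vena-cava pressures; used by identification step 4.
#'
#' @param p a [cvs_params] object.
#' @param P_pu,P_vc constant venous pressures (mmHg).
#' @param duration simulated time (s).
#' @param init optional state `(V_lv, V_ao, TCa, TCastar, Tstar, X)`.
#' @param dt,rtol,atol integration controls.
#' @return data frame with the trajectory and globals.
#' @export
simulate_systemic <- function(p, P_pu, P_vc, duration, init = NULL,
                              dt = 1e-3, rtol = 1e-6, atol = 1e-9) {
  validate_params(p)
  if (is.null(init)) {
    Vlv0 <- 20.8
    init <- c(V_lv = Vlv0, V_ao = 100 / p$E_ao,
              .rest_sarcomere(fiber_length_from_volume(Vlv0, p), p))
  }
  times <- seq(0, duration, by = dt)
  out <- deSolve::lsoda(
    y = init, times = times, func = "cv_derivs_sys",
    parms = .parm_vector(p, ppu_const = P_pu, pvc_const = P_vc),
    dllname = "cvloop", initfunc = "cv_init",
    nout = 7, outnames = c("P_lv", "P_ao", "Q_mt", "Q_av", "Q_sys",
                           "L", "F"),
    rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(out, "istate")[1] < 0) stop("systemic subsystem integration failed")
  as.data.frame(unclass(out))
}

#' Simulate the pulmonary subsystem
#'
#' Time-varying-elastance right ventricle and pulmonary artery with
#' constant vena-cava and pulmonary-vein pressures; used by step 5.
#'
#' @inheritParams simulate_systemic
#' @param init optional state `(V_rv, V_pa)`.
#' @return data frame with the trajectory and globals.
#' @export
simulate_pulmonary <- function(p, P_pu, P_vc, duration, init = NULL,
                               dt = 1e-3, rtol = 1e-6, atol = 1e-9) {
  validate_params(p)
  if (is.null(init))
    init <- c(V_rv = 20.8, V_pa = max(2 * P_pu, 10) / p$E_pa)
  times <- seq(0, duration, by = dt)
  out <- deSolve::lsoda(
    y = init, times = times, func = "cv_derivs_pulm",
    parms = .parm_vector(p, ppu_const = P_pu, pvc_const = P_vc),
    dllname = "cvloop", initfunc = "cv_init",
    nout = 5, outnames = c("P_rv", "P_pa", "Q_tc", "Q_pv", "Q_pul"),
    rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(out, "istate")[1] < 0) stop("pulmonary subsystem integration failed")
  as.data.frame(unclass(out))
}

# run a subsystem simulator cycle by cycle until the cycle-start state
# repeats; returns the last cycle
.subsystem_steady_cycle <- function(runner, p, init, max_cycles = 80,
                                    tol = 1e-4) {
  state <- init
  last <- NULL
  for (cyc in seq_len(max_cycles)) {
    d <- runner(p, state)
    last <- d
    new_state <- unlist(d[nrow(d), names(init)])
    rel <- max(abs(new_state - state) / pmax(abs(state), 0.01))
    state <- stats::setNames(as.numeric(new_state), names(init))
    if (rel < tol) break
  }
  last
}

# mean of squared relative errors over the target rows used by a step
.target_objective <- function(measured, targets, rows) {
  err <- vapply(rows, function(nm)
    (measured[[nm]] - targets[[nm]]) / targets[[nm]], numeric(1))
  mean(err^2)
}

# Nelder-Mead in log-space with optional restarts; lower/upper are
# soft bounds enforced by penalty (used to keep f inside (0, 1))
.simplex_fit <- function(par0, objective, maxit = 500, restarts = 1,
                         reltol = 1e-8) {
  obj_log <- function(theta) {
    val <- tryCatch(objective(exp(theta)), error = function(e) NA_real_)
    if (!is.finite(val)) 1e6 else val
  }
  theta <- log(par0)
  total_conv <- FALSE
  value <- NA_real_
  for (r in seq_len(restarts + 1)) {
    fit <- stats::optim(theta, obj_log, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    theta <- fit$par
    value <- fit$value
    total_conv <- fit$convergence == 0
  }
  # an objective at its numerical floor counts as converged even when the
  # iteration budget was exhausted polishing it
  list(par = stats::setNames(exp(theta), names(par0)), value = value,
       converged = total_conv || value < 1e-6)
}

# --- step 3: geometry initialization from isovolumic contractions ---------

#' Initialize ventricular geometry from isovolumic targets
#'
#' Adjusts `Kv` and `f` by simplex minimization so that the end-systolic
#' (peak) and end-diastolic (passive) pressures of simulated isovolumic
#' contractions match the four target points.
#'
#' @param targets data frame with columns `V` (ml), `Pes`, `Ped` (mmHg);
#'   four points.
#' @param p a [cvs_params] object providing every other parameter.
#' @param init starting values `c(Kv, f)`; defaults to the values in `p`.
#' @param maxit,restarts simplex controls.
#' @return list with `Kv`, `f`, `objective`, `converged`.
#' @export
step3_init_geometry <- function(targets, p, init = NULL, maxit = 300,
                                restarts = 1) {
  stopifnot(is.data.frame(targets), all(c("V", "Pes", "Ped") %in%
                                          names(targets)))
  if (any(targets$Pes <= 0))
    return(list(Kv = NA_real_, f = NA_real_, objective = Inf,
                converged = FALSE))
  if (is.null(init)) init <- c(Kv = p$Kv, f = p$f)
  # end-diastolic (passive) pressures are near zero over this volume range
  # (fifth-power parallel elasticity), so their residuals are normalized
  # by |target| + 1 mmHg rather than by a relative error
  objective <- function(par) {
    if (par[2] >= 0.95) return(1e6)
    p2 <- p; p2$Kv <- par[1]; p2$f <- par[2]
    sw <- isovolumic_sweep(p2, targets$V)
    mean(((sw$P_peak - targets$Pes) / targets$Pes)^2 +
           ((sw$P_ed - targets$Ped) / (abs(targets$Ped) + 1))^2)
  }
  fit <- .simplex_fit(init, objective, maxit = maxit, restarts = restarts)
  list(Kv = unname(fit$par["Kv"]), f = unname(fit$par["f"]),
       objective = fit$value, converged = fit$converged)
}

# --- steps 4-6: subsystem and closed-loop simplex fits --------------------

.lv_rows <- .target_names[1:6]
# step 5 matches the right-heart rows that the constant-venous-pressure
# split reproduces without bias: the RV volume LEVEL of the subsystem is
# shifted by the constant-Pvc approximation, so the shared stroke volume
# stands in for the volume rows
.rv_rows <- c("rv_pulse_pressure", "mean_rv_pressure", "stroke_volume")

#' Identification step 4: systemic subsystem
#'
#' Fits `R_mt`, `R_av`, `E_ao`, `Kv` and `f` so that the steady cycle of
#' the systemic subsystem (LV + aorta between constant venous pressures)
#' reproduces the six left-heart target rows.
#'
#' @param targets a `hemo_targets` list.
#' @param p a [cvs_params] object (starting point for all parameters).
#' @param P_pu,P_vc constant venous pressures (mmHg).
#' @param init optional named start `c(R_mt, R_av, E_ao, Kv, f)`.
#' @param maxit,restarts simplex controls.
#' @return list with the fitted parameters, `objective`, `converged` and
#'   the updated `params`.
#' @export
step4_fit_systemic <- function(targets, p, P_pu, P_vc, init = NULL,
                               maxit = 500, restarts = 1) {
  .check_targets(targets, .lv_rows)
  if (is.null(init))
    init <- c(R_mt = p$R_mt, R_av = p$R_av, E_ao = p$E_ao,
              Kv = p$Kv, f = p$f)
  runner <- function(p2, state)
    simulate_systemic(p2, P_pu, P_vc, duration = p2$period, init = state)
  objective <- function(par) {
    if (par["f"] >= 0.95) return(1e6)
    p2 <- p
    for (nm in names(par)) p2[[nm]] <- unname(par[nm])
    init0 <- c(V_lv = targets$mean_ventricular_volume,
               V_ao = targets$p_ao_at_valve_open / p2$E_ao,
               .rest_sarcomere(fiber_length_from_volume(
                 targets$mean_ventricular_volume, p2), p2))
    d <- .subsystem_steady_cycle(runner, p2, init0)
    meas <- .measure_lv(d$time, d$P_lv, d$P_ao, d$Q_av, d$V_lv)
    .target_objective(meas, targets, .lv_rows)
  }
  fit <- .simplex_fit(init, objective, maxit = maxit, restarts = restarts)
  p_out <- p
  for (nm in names(fit$par)) {
    p_out[[nm]] <- unname(fit$par[nm])
    attr(p_out, "provenance")[[nm]] <- "fitted"
  }
  c(as.list(fit$par), list(objective = fit$value, converged = fit$converged,
                           params = p_out))
}

#' Identification step 5: pulmonary subsystem
#'
#' Fits `E_rv`, `R_tc` and `R_pv` so that the steady cycle of the
#' pulmonary subsystem reproduces the right-heart target rows (RV pulse
#' and mean pressure plus the shared mean ventricular volume and stroke
#' volume).
#'
#' @inheritParams step4_fit_systemic
#' @param init optional named start `c(E_rv, R_tc, R_pv)`.
#' @return list with the fitted parameters, `objective`, `converged`,
#'   `params`.
#' @export
step5_fit_pulmonary <- function(targets, p, P_pu, P_vc, init = NULL,
                                maxit = 500, restarts = 1) {
  .check_targets(targets, .rv_rows)
  if (is.null(init))
    init <- c(E_rv = p$E_rv, R_tc = p$R_tc, R_pv = p$R_pv)
  runner <- function(p2, state)
    simulate_pulmonary(p2, P_pu, P_vc, duration = p2$period, init = state)
  objective <- function(par) {
    p2 <- p
    for (nm in names(par)) p2[[nm]] <- unname(par[nm])
    init0 <- c(V_rv = targets$mean_ventricular_volume,
               V_pa = max(2 * P_pu, 10) / p2$E_pa)
    d <- .subsystem_steady_cycle(runner, p2, init0)
    meas <- .measure_rv(d$P_rv, d$V_rv)
    .target_objective(meas, targets, .rv_rows)
  }
  fit <- .simplex_fit(init, objective, maxit = maxit, restarts = restarts)
  p_out <- p
  for (nm in names(fit$par)) {
    p_out[[nm]] <- unname(fit$par[nm])
    attr(p_out, "provenance")[[nm]] <- "fitted"
  }
  c(as.list(fit$par), list(objective = fit$value, converged = fit$converged,
                           params = p_out))
}

#' Identification step 6: venous elastances on the closed loop
#'
#' Reassembles the full closed loop (venous pressures free) and fits
#' `E_vc` and `E_pu` against the whole set of reference targets.
#'
#' @inheritParams step4_fit_systemic
#' @param init optional named start `c(E_vc, E_pu)`.
#' @param warm_start optional full-model state used to seed the
#'   steady-state search of each objective evaluation.
#' @return list with the fitted parameters, `objective`, `converged`,
#'   `params`.
#' @export
step6_fit_venous <- function(targets, p, init = NULL, warm_start = NULL,
                             maxit = 200, restarts = 1) {
  .check_targets(targets, .target_names)
  if (is.null(init)) init <- c(E_vc = p$E_vc, E_pu = p$E_pu)
  objective <- function(par) {
    p2 <- p
    for (nm in names(par)) p2[[nm]] <- unname(par[nm])
    ss <- suppressWarnings(
      run_to_steady_state(p2, max_cycles = 60, init = warm_start))
    meas <- measure_targets(ss)
    .target_objective(meas, targets, .target_names)
  }
  fit <- .simplex_fit(init, objective, maxit = maxit, restarts = restarts)
  p_out <- p
  for (nm in names(fit$par)) {
    p_out[[nm]] <- unname(fit$par[nm])
    attr(p_out, "provenance")[[nm]] <- "fitted"
  }
  c(as.list(fit$par), list(objective = fit$value, converged = fit$converged,
                           params = p_out))
}

.check_targets <- function(targets, rows) {
  missing <- rows[!vapply(rows, function(nm)
    !is.null(targets[[nm]]) && is.finite(targets[[nm]]), logical(1))]
  if (length(missing))
    stop("missing target row(s): ", paste(missing, collapse = ", "))
}

#' Run identification steps 3 to 6
#'
#' The iterative part of the identification pipeline: isovolumic
#' initialization of the geometry, systemic-subsystem fit, pulmonary
#' subsystem fit, and the closed-loop venous fit.
#'
#' @param targets a `hemo_targets` list.
#' @param p starting [cvs_params] (e.g. perturbed values).
#' @param iso_targets step-3 target points (`V`, `Pes`, `Ped`).
#' @param P_pu,P_vc constant venous pressures for the split model.
#' @param warm_start optional state seed for step 6.
#' @param maxit,restarts simplex controls (per step).
#' @return list of class `cvs_identification` with `params` (fitted set),
#'   `steps` (per-step results) and `objective` (final closed-loop value).
#' @export
identify_parameters <- function(targets, p, iso_targets, P_pu, P_vc,
                                warm_start = NULL, maxit = 500,
                                restarts = 1) {
  s3 <- step3_init_geometry(iso_targets, p, maxit = min(maxit, 300),
                            restarts = restarts)
  p3 <- p
  if (is.finite(s3$objective)) { p3$Kv <- s3$Kv; p3$f <- s3$f }
  s4 <- step4_fit_systemic(targets, p3, P_pu, P_vc, maxit = maxit,
                           restarts = restarts)
  s5 <- step5_fit_pulmonary(targets, s4$params, P_pu, P_vc, maxit = maxit,
                            restarts = restarts)
  s6 <- step6_fit_venous(targets, s5$params, warm_start = warm_start,
                         maxit = min(maxit, 200), restarts = restarts)
  structure(list(params = s6$params,
                 steps = list(step3 = s3, step4 = s4, step5 = s5,
                              step6 = s6),
                 objective = s6$objective),
            class = "cvs_identification")
}

#' @export
print.cvs_identification <- function(x, ...) {
  cat("Stepwise parameter identification\n")
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat(sprintf("  %s: objective %.3g%s\n", nm, s$objective,
                if (isTRUE(s$converged)) "" else " (not converged)"))
  }
  invisible(x)
}
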