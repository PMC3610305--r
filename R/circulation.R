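# Six-chamber closed-loop lumped circulation: left ventricle (sarcomere
# driven), right ventricle (time-varying elastance), aorta, vena cava,
# pulmonary artery and pulmonary veins, connected by the mitral, aortic,
# tricuspid and pulmonary valves (ideal diodes with resistance) and the
# systemic and pulmonary vascular beds (plain Poiseuille resistances).
# Loop topology: pu -(mt)-> lv -(av)-> ao -(sys)-> vc -(tc)-> rv -(pv)->
# pa -(pul)-> pu.

.chambers <- c("V_lv", "V_rv", "V_ao", "V_vc", "V_pa", "V_pu")
.state_names <- c(.chambers, "TCa", "TCastar", "Tstar", "X")
.pressure_names <- c("P_lv", "P_rv", "P_ao", "P_vc", "P_pa", "P_pu")
.flow_names <- c("Q_mt", "Q_av", "Q_sys", "Q_tc", "Q_pv", "Q_pul")

#' Passive chamber pressure
#'
#' Constant-elastance chamber law `P = E V`.
#'
#' @param V chamber volume (ml), `>= 0`.
#' @param E chamber elastance (mmHg/ml).
#' @return pressure (mmHg).
#' @export
passive_pressure <- function(V, E) {
  stopifnot(all(V >= 0), all(E > 0))
  E * V
}

#' Right-ventricular activation function
#'
#' Sum of three Gaussians `e(t) = sum Aj exp(-Bj (t - Cj)^2)` evaluated on
#' cycle time (`t` reduced modulo the cardiac period); strictly positive.
#'
#' @param t time (s), vectorized.
#' @param p a [cvs_params] object.
#' @return dimensionless activation, bounded above by `A1 + A2 + A3`.
#' @export
rv_activation <- function(t, p) {
  validate_params(p)
  .Call("cv_rv_act", as.double(t), .parm_vector(p), PACKAGE = "cvloop")
}

#' Right-ventricular pressure
#'
#' Time-varying-elastance law `Prv = e(t) Erv Vrv` (zero-pressure volume
#' taken as zero, so the end-diastolic relation coincides with the volume
#' axis).
#'
#' @param t time (s).
#' @param Vrv right-ventricular volume (ml), `>= 0`.
#' @param p a [cvs_params] object.
#' @return pressure (mmHg).
#' @export
rv_pressure <- function(t, Vrv, p) {
  stopifnot(all(Vrv >= 0))
  rv_activation(t, p) * p$E_rv * Vrv
}

#' Valved and plain vessel flows
#'
#' `vessel_flow` is Poiseuille's law `Q = (P_up - P_down) / R` with
#' unconstrained sign; `valve_flow` passes it through the ramp function so
#' reverse flow is clamped to zero (ideal diode in series with a
#' resistance).
#'
#' @param P_up,P_down upstream and downstream pressures (mmHg).
#' @param R hydraulic resistance (mmHg s/ml), `> 0`.
#' @return flow (ml/s); nonnegative for `valve_flow`.
#' @export
valve_flow <- function(P_up, P_down, R) {
  pmax(vessel_flow(P_up, P_down, R), 0)
}

#' @rdname valve_flow
#' @export
vessel_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("resistance must be > 0")
  (P_up - P_down) / R
}

#' Chamber volume derivatives of the closed loop
#'
#' Continuity equation `dV/dt = Qin - Qout` for the six chambers, with the
#' left-ventricular pressure supplied by the sarcomere/ventricle model, the
#' right-ventricular pressure by the time-varying elastance, and passive
#' laws elsewhere. With no external outflow the six derivatives sum to
#' zero exactly (closed loop); an external pulmonary-vein outflow (e.g.
#' hemorrhage) appears as a single sink.
#'
#' @param t time (s).
#' @param state full 10-component state
#'   `(V_lv, V_rv, V_ao, V_vc, V_pa, V_pu, TCa, TCastar, Tstar, X)`.
#' @param p a [cvs_params] object.
#' @param pu_outflow external outflow at the pulmonary veins (ml/s).
#' @return a list with `dV` (six chamber derivatives, ml/s), `dsarc` (four
#'   sarcomere derivatives), `pressures` (mmHg) and `flows` (ml/s).
#' @export
chamber_derivatives <- function(t, state, p, pu_outflow = 0) {
  stopifnot(length(state) == 10)
  if (any(state[1:6] < 0))
    stop("negative chamber volume: state is unphysical")
  out <- .Call("cv_full_rhs", as.double(t), as.double(state),
               .parm_vector(p, qout = pu_outflow), PACKAGE = "cvloop")
  list(dV = stats::setNames(out[1:6], .chambers),
       dsarc = stats::setNames(out[7:10], c("TCa", "TCastar", "Tstar", "X")),
       pressures = stats::setNames(out[11:16], .pressure_names),
       flows = stats::setNames(out[17:22], .flow_names))
}
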