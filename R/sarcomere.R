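# Equivalent half-sarcomere: four troponin states (free T, calcium-bound
# TCa, calcium-bound-attached TCa*, attached-without-calcium T*), one
# equivalent cross-bridge of elongation h = L - X relaxing towards hc, a
# parallel elastic element and a series elastic element. Forces are in
# mN/mm^2, lengths in um, concentrations in uM.

.sarc_state <- function(s) {
  stopifnot(is.numeric(s), length(s) >= 4)
  if (is.null(names(s))) names(s) <- c("TCa", "TCastar", "Tstar", "X")
  s
}

#' Passive parallel elastic force
#'
#' Fifth-power elastic law of the parallel element,
#' `Fp = K (L - L0)^5`, antisymmetric about the resting length `L0`.
#'
#' @param L half-sarcomere length (um).
#' @param p a [cvs_params] object.
#' @return force in mN/mm^2 (negative under compression).
#' @export
parallel_force <- function(L, p) {
  stopifnot(all(L > 0))
  p$K * (L - p$L0)^5
}

#' Series elastic force
#'
#' Exponential series element, `Fs = alpha (exp(beta Ls) - 1)`; strictly
#' increasing in `Ls` and bounded below by `-alpha`.
#'
#' @param Ls series-element length (um); may be negative.
#' @param p a [cvs_params] object.
#' @return force in mN/mm^2.
#' @export
series_force <- function(Ls, p) {
  p$alpha * expm1(p$beta * Ls)
}

#' Effective troponin-bound calcium
#'
#' Filament-overlap attenuation of the calcium-bound troponin pool:
#' `TCa_eff = TCa exp(-R (L - La)^2)`. Overlap is maximal at `L = La`.
#'
#' @param TCa calcium-bound troponin concentration (uM).
#' @param L half-sarcomere length (um).
#' @param p a [cvs_params] object.
#' @return effective concentration (uM), `<= TCa`.
#' @export
effective_bound_calcium <- function(TCa, L, p) {
  stopifnot(all(TCa >= 0))
  TCa * exp(-p$R * (L - p$La)^2)
}

#' Active cross-bridge force
#'
#' `Fb = A ([TCa*] + [T*]) h` with cross-bridge elongation `h = L - X`:
#' force is proportional to the attached troponin pool and to the average
#' cross-bridge strain.
#'
#' @param s sarcomere state, numeric `(TCa, TCastar, Tstar, X)`.
#' @param L half-sarcomere length (um).
#' @param p a [cvs_params] object.
#' @return force in mN/mm^2.
#' @export
active_force <- function(s, L, p) {
  s <- .sarc_state(s)
  p$A * (s[["TCastar"]] + s[["Tstar"]]) * (L - s[["X"]])
}

#' Reaction rates of the troponin/cross-bridge cycle
#'
#' The six rates of the four-state kinetic scheme at a given calcium level,
#' half-sarcomere length and shortening velocity: calcium binding/unbinding
#' (`Qb`), attachment (`Qa`), calcium release while attached (`Qr`),
#' detachment (`Qd`), and the velocity-dependent detachment fluxes
#' (`Qd1`, `Qd2`), each proportional to `(dX/dt)^2`.
#'
#' @param s sarcomere state `(TCa, TCastar, Tstar, X)` (uM, uM, uM, um).
#' @param Ca calcium concentration (uM).
#' @param L half-sarcomere length (um).
#' @param dXdt rate of change of the inextensible portion (um/s).
#' @param p a [cvs_params] object.
#' @return named numeric vector `(Qa, Qb, Qr, Qd, Qd1, Qd2)` in uM/s.
#' @export
reaction_rates <- function(s, Ca, L, dXdt, p) {
  s <- .sarc_state(s)
  TCa <- s[["TCa"]]; TCs <- s[["TCastar"]]; Ts <- s[["Tstar"]]
  Tfree <- p$Tt - TCa - TCs - Ts
  if (Tfree < -1e-6)
    stop("free troponin is negative beyond tolerance (", format(Tfree),
         " uM): inconsistent state")
  c(Qa  = p$Y2 * effective_bound_calcium(TCa, L, p) - p$Z2 * TCs,
    Qb  = p$Y1 * Ca * Tfree - p$Z1 * TCa,
    Qr  = p$Y3 * TCs - p$Z3 * Ts * Ca,
    Qd  = p$Y4 * Ts,
    Qd1 = p$Yd * dXdt^2 * TCs,
    Qd2 = p$Yd * dXdt^2 * Ts)
}

#' Time derivatives of the sarcomere state
#'
#' Kinetic balance of the three bound troponin pools plus the linear
#' cross-bridge relaxation law `dX/dt = B (L - X - hc)`. The cross-bridge
#' velocity is evaluated first (closed form) and fed into the
#' velocity-dependent detachment rates.
#'
#' @inheritParams reaction_rates
#' @return named numeric vector `(dTCa, dTCastar, dTstar, dX)`.
#' @export
state_derivatives <- function(s, Ca, L, p) {
  s <- .sarc_state(s)
  dXdt <- p$B * (L - s[["X"]] - p$hc)
  q <- reaction_rates(s, Ca, L, dXdt, p)
  c(dTCa     = unname(q["Qb"] - q["Qa"]),
    dTCastar = unname(q["Qa"] - q["Qr"] - q["Qd1"]),
    dTstar   = unname(q["Qr"] - q["Qd"] - q["Qd2"]),
    dX       = dXdt)
}

#' Series/parallel force balance of the muscle unit
#'
#' At fixed total muscle-unit length `Lt = L + Ls`, the half-sarcomere
#' length `L` satisfies the algebraic force balance
#' `Fb(L) + Fp(L) = Fs(Lt - L)`. The left side is strictly increasing in
#' `L` and the right side strictly decreasing, so the root is unique; it is
#' found by safeguarded Newton iteration (bisection fallback) within the
#' bracket `[0.5 L0, 1.5 Lt]` to an absolute force tolerance of 1e-10
#' mN/mm^2. A bracket failure signals an unphysical state and is raised as
#' an error.
#'
#' @param Lt total muscle-unit length (um), `> 0`.
#' @param s sarcomere state `(TCa, TCastar, Tstar, X)`.
#' @param p a [cvs_params] object.
#' @return a list of class `muscle_forces` with elements `L`, `Ls`, `h`,
#'   `Fp`, `Fb`, `F`, `Fs` (total force `F = Fb + Fp = Fs` to solver
#'   tolerance).
#' @export
solve_muscle_partition <- function(Lt, s, p) {
  stopifnot(Lt > 0)
  s <- .sarc_state(s)
  ct <- s[["TCastar"]] + s[["Tstar"]]
  L <- .Call("cv_solve_partition", as.double(Lt), as.double(ct),
             as.double(s[["X"]]), .parm_vector(p), PACKAGE = "cvloop")
  Fp <- parallel_force(L, p)
  Fb <- active_force(s, L, p)
  structure(list(L = L, Ls = Lt - L, h = L - s[["X"]],
                 Fp = Fp, Fb = Fb, F = Fb + Fp,
                 Fs = series_force(Lt - L, p)),
            class = "muscle_forces")
}

# rest state at a given muscle-unit length: all troponin free and the
# cross-bridge at its equilibrium elongation, X = L - hc
.rest_sarcomere <- function(Lt, p) {
  g <- function(L) parallel_force(L, p) - series_force(Lt - L, p)
  L <- stats::uniroot(g, c(0.5 * p$L0, 1.5 * Lt), tol = 1e-14)$root
  c(TCa = 0, TCastar = 0, Tstar = 0, X = L - p$hc)
}
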