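# Spherical left-ventricle geometry: half-sarcomere units are arranged on
# the circumference of a sphere whose midwall volume is Vmw = Kv * Lt^3;
# a fixed fraction f of the wall volume lies inside the midwall surface,
# Vmw - Vlv = f * Vw.

#' Muscle-unit length from ventricular volume
#'
#' Inverts the midwall-volume relation: `Lt = ((Vw f + Vlv) / Kv)^(1/3)`.
#' Strictly increasing in `Vlv`.
#'
#' @param Vlv left-ventricular cavity volume (ml), `>= 0`.
#' @param p a [cvs_params] object (uses `Kv`, `Vw`, `f`).
#' @return total muscle-unit length `Lt` (um).
#'
#' @examples
#' p <- cvs_params()
#' fiber_length_from_volume(20.8, p)
#' @export
fiber_length_from_volume <- function(Vlv, p) {
  stopifnot(all(Vlv >= 0))
  ((p$Vw * p$f + Vlv) / p$Kv)^(1 / 3)
}

#' Left-ventricular pressure from muscle force
#'
#' Thin-wall spherical conversion from total muscle force per unit area to
#' cavity pressure: the average fiber stress is `sigma = F Lt / Lr`
#' (constant muscle-unit volume), the midwall volume is `Kv Lt^3`, and
#' `Plv = 5 sigma Vw / Vmw = 5 F Vw / (Lr Kv Lt^2)`. The factor 5 embeds
#' the conversion from mN/mm^2 to mmHg (1 mN/mm^2 is about 7.5 mmHg).
#'
#' @param F total muscle force (mN/mm^2).
#' @param Lt muscle-unit length (um), `> 0`.
#' @param p a [cvs_params] object.
#' @return pressure in mmHg; linear in `F`.
#' @export
lv_pressure <- function(F, Lt, p) {
  stopifnot(all(Lt > 0))
  5 * F * p$Vw / (p$Lr * p$Kv * Lt^2)
}

#' Quasi-static ventricular pressure-volume evaluation
#'
#' Convenience composition used by the isolated-ventricle protocols and
#' tests: maps a cavity volume and sarcomere state to muscle-unit length,
#' solves the series/parallel force balance and returns the resulting
#' cavity pressure together with the muscle partition.
#'
#' @param Vlv cavity volume (ml).
#' @param s sarcomere state `(TCa, TCastar, Tstar, X)`.
#' @param p a [cvs_params] object.
#' @return list with `Plv` (mmHg), `Lt` (um) and the `muscle_forces` object.
#' @export
ventricle_pressure <- function(Vlv, s, p) {
  Lt <- fiber_length_from_volume(Vlv, p)
  mf <- solve_muscle_partition(Lt, s, p)
  list(Plv = lv_pressure(mf$F, Lt, p), Lt = Lt, forces = mf)
}
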