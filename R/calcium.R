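#' Intracellular calcium driver
#'
#' Periodic intracellular calcium concentration used as input to the
#' sarcomere model. Within each cardiac cycle the transient is built from
#' two cosine branches: a rise from 0 to `Camax` over `[0, T1]`, a return to
#' 0 over `[T1, T2]`, and zero for the remainder of the cycle. The function
#' is continuous, nonnegative, and periodic with the cardiac period; time is
#' reduced modulo the period before evaluation.
#'
#' @param t time in seconds (vectorized, `t >= 0`).
#' @param p a [cvs_params] object (only `T1`, `T2`, `Camax`, `period` are
#'   used).
#' @return calcium concentration in uM, same length as `t`.
#'
#' @examples
#' p <- cvs_params()
#' calcium_concentration(c(0, p$T1, p$T2), p)   # 0, Camax, 0
#' @export
calcium_concentration <- function(t, p) {
  validate_params(p)
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  .Call("cv_ca_conc", as.double(t), .parm_vector(p), PACKAGE = "cvloop")
}
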