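# Model parameter set: calcium driver, sarcomere kinetics and elasticity,
# spherical-ventricle geometry, lumped circulation, RV activation.
# The internal unit system is s, ml, mmHg, um, uM, mN/mm^2 throughout; the
# canonical times-to-peak/return of the calcium transient are stored in
# seconds (40.6 ms -> 0.0406 s).

# order in which parameters are packed for the compiled right-hand sides
.par_order <- c(
  "T1", "T2", "Camax", "period",
  "Y1", "Z1", "Y2", "Z2", "Y3", "Z3", "Y4", "Yd", "Tt", "B", "hc", "La", "R",
  "A", "K", "L0", "alpha", "beta",
  "Kv", "Lr", "Vw", "f",
  "E_pa", "E_pu", "E_ao", "E_vc", "E_rv",
  "R_pul", "R_sys", "R_av", "R_mt", "R_pv", "R_tc",
  "V_total",
  "A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3"
)

.default_values <- list(
  # intracellular calcium transient (s, uM)
  T1 = 0.0406, T2 = 0.1302, Camax = 1.47, period = 0.6,
  # chemical kinetics (Y1 and Z3 are bilinear rate constants, uM^-1 s^-1)
  Y1 = 39, Z1 = 30, Y2 = 1.3, Z2 = 1.3, Y3 = 30, Z3 = 1560, Y4 = 40,
  Yd = 8, Tt = 70, B = 800, hc = 0.005, La = 1.17, R = 20,
  # cross-bridge force scale, parallel and series elastic elements
  A = 1800, K = 140000, L0 = 0.97, alpha = 0.5, beta = 75,
  # force-length to pressure-volume conversion
  Kv = 29.0, Lr = 1.05, Vw = 60.6, f = 0.217,
  # hemodynamics (mmHg/ml, mmHg s/ml, ml)
  E_pa = 0.953, E_pu = 0.0302, E_ao = 0.965, E_vc = 0.0107, E_rv = 2.06,
  R_pul = 2.74, R_sys = 5.65, R_av = 0.152, R_mt = 0.0313, R_pv = 0.0269,
  R_tc = 0.459, V_total = 1500,
  # right-ventricular activation function (three Gaussians)
  A1 = 0.956, A2 = 0.625, A3 = 0.0180,
  B1 = 255, B2 = 225, B3 = 4230.0,
  C1 = 0.431, C2 = 0.328, C3 = 0.374
)

#' Model parameter set
#'
#' Builds the full parameter set of the multi-scale cardiovascular model: the
#' two-cosine intracellular calcium driver, four-state troponin/cross-bridge
#' kinetics with parallel and series elastic elements, the spherical
#' left-ventricle geometry, the six-chamber lumped circulation and the
#' Gaussian right-ventricular activation function. Defaults are the
#' reference canine parameterization; any subset can be overridden by name.
#'
#' @param ... named scalar overrides, e.g. `cvs_params(E_ao = 2 * 0.965)`.
#' @param provenance optional character tag recorded for overridden
#'   parameters (`"user"` by default; the identification pipeline uses
#'   `"fitted"`).
#'
#' @return An object of class `cvs_params`: a named list of numeric scalars
#'   with a `provenance` attribute (one of `"default"`, `"user"`, `"fitted"`
#'   per parameter).
#'
#' @examples
#' p <- cvs_params()
#' p$Camax
#' p2 <- cvs_params(R_sys = 2 * p$R_sys)
#' @export
cvs_params <- function(..., provenance = "user") {
  p <- .default_values
  prov <- stats::setNames(rep("default", length(p)), names(p))
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(dots)) {
      p[[nm]] <- as.numeric(dots[[nm]])
      prov[[nm]] <- provenance
    }
  }
  structure(p, class = "cvs_params", provenance = prov)
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model parameters: positivity of
#' rates, concentrations, lengths, elastances, resistances and volumes;
#' `0 < T1 < T2 <= period`; `0 < f < 1`; activation amplitudes in (0, 1]
#' and centers within one period.
#'
#' @param p a [cvs_params] object (or named list with the same fields).
#' @return `p`, invisibly, if valid; otherwise an error describing every
#'   violated invariant.
#' @export
validate_params <- function(p) {
  missing <- setdiff(.par_order, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  v <- vapply(.par_order, function(nm) as.numeric(p[[nm]])[1], numeric(1))
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)

  chk(all(is.finite(v)), "all parameters must be finite numbers")
  pos <- c("T1", "T2", "Camax", "period",
           "Y1", "Z1", "Y2", "Z2", "Y3", "Z3", "Y4", "Yd", "Tt", "B",
           "hc", "La", "R", "A", "K", "L0", "alpha", "beta",
           "Kv", "Lr", "Vw",
           "E_pa", "E_pu", "E_ao", "E_vc", "E_rv",
           "R_pul", "R_sys", "R_av", "R_mt", "R_pv", "R_tc",
           "V_total", "B1", "B2", "B3")
  for (nm in pos) chk(v[[nm]] > 0, paste0(nm, " must be > 0"))
  chk(v[["T1"]] < v[["T2"]], "T1 must be < T2")
  chk(v[["T2"]] <= v[["period"]], "T2 must be <= period")
  chk(v[["f"]] > 0 && v[["f"]] < 1, "f must lie in (0, 1)")
  for (nm in c("A1", "A2", "A3"))
    chk(v[[nm]] > 0 && v[[nm]] <= 1, paste0(nm, " must lie in (0, 1]"))
  for (nm in c("C1", "C2", "C3"))
    chk(v[[nm]] >= 0 && v[[nm]] < v[["period"]],
        paste0(nm, " must lie in [0, period)"))
  if (length(bad))
    stop("invalid parameter set:\n  ", paste(bad, collapse = "\n  "))
  invisible(p)
}

# pack a cvs_params into the numeric vector the compiled models expect;
# slots 48-50 carry the external pulmonary-vein outflow and, for the split
# subsystems, the constant venous pressures
.parm_vector <- function(p, qout = 0, ppu_const = 0, pvc_const = 0) {
  validate_params(p)
  c(vapply(.par_order, function(nm) as.numeric(p[[nm]])[1], numeric(1)),
    qout = as.numeric(qout), ppu_const = as.numeric(ppu_const),
    pvc_const = as.numeric(pvc_const))
}

#' Scale contractility
#'
#' Contractile state is varied by scaling the peak of the intracellular
#' calcium transient (`Camax`); every other parameter is untouched.
#'
#' @param p a [cvs_params] object.
#' @param factor positive multiplicative factor (2 doubles the calcium peak).
#' @return the modified parameter set.
#' @export
with_contractility <- function(p, factor = 2) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  p$Camax <- p$Camax * factor
  validate_params(p)
  p
}

#' @export
print.cvs_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Multi-scale cardiovascular model parameters\n")
  groups <- list(
    "calcium driver"       = c("T1", "T2", "Camax", "period"),
    "sarcomere kinetics"   = c("Y1", "Z1", "Y2", "Z2", "Y3", "Z3", "Y4",
                               "Yd", "Tt", "B", "hc", "La", "R"),
    "sarcomere elasticity" = c("A", "K", "L0", "alpha", "beta"),
    "ventricle geometry"   = c("Kv", "Lr", "Vw", "f"),
    "circulation"          = c("E_pa", "E_pu", "E_ao", "E_vc", "E_rv",
                               "R_pul", "R_sys", "R_av", "R_mt", "R_pv",
                               "R_tc", "V_total"),
    "RV activation"        = c("A1", "A2", "A3", "B1", "B2", "B3",
                               "C1", "C2", "C3")
  )
  for (g in names(groups)) {
    nm <- groups[[g]]
    vals <- vapply(nm, function(k) format(x[[k]]), character(1))
    tag <- if (!is.null(prov))
      vapply(nm, function(k) if (identical(prov[[k]], "default")) ""
             else paste0(" [", prov[[k]], "]"), character(1))
    else rep("", length(nm))
    cat("  ", g, ":\n", sep = "")
    cat(paste0("    ", format(nm, width = 8), " = ", vals, tag,
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read or write a parameter set as YAML
#'
#' The configuration format is a flat key-value YAML mapping; values
#' round-trip losslessly at 15 significant digits. `read_params("default")`
#' returns the built-in reference parameterization.
#'
#' @param path file path, or `"default"` for the built-in values.
#' @param p a [cvs_params] object.
#' @return `read_params` returns a validated [cvs_params]; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (identical(path, "default")) return(cvs_params())
  raw <- yaml::yaml.load_file(path)
  if (!is.list(raw)) stop("parameter file must be a YAML mapping")
  extra <- setdiff(names(raw), .par_order)
  if (length(extra))
    stop("unknown key(s) in parameter file: ", paste(extra, collapse = ", "))
  missing <- setdiff(.par_order, names(raw))
  if (length(missing))
    stop("missing key(s) in parameter file: ",
         paste(missing, collapse = ", "))
  p <- do.call(cvs_params, c(raw[.par_order], list(provenance = "user")))
  validate_params(p)
  p
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  validate_params(p)
  vals <- lapply(.par_order, function(nm) as.numeric(p[[nm]]))
  names(vals) <- .par_order
  txt <- yaml::as.yaml(vals, precision = 15)
  writeLines(txt, path)
  invisible(path)
}
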