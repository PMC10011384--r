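# Model parameters.
#
# The three calibration constants (D, A, T) scale atomic strengths; the
# remaining eleven free parameters weight the polar, apolar and interaction
# contributions to the hydration free energy. Defaults are the published
# values of the fitted model.

#' Strength calibration parameters
#'
#' `D` and `A` convert corrected partial charges into donor/acceptor
#' strengths; both are defined by requiring strength 1.0 for the hydrogens
#' and oxygen of an MMFF94-minimised water molecule under the reference
#' charge backend (see [calibrate_water()]). `T` is the bond reduction
#' factor attenuating neighbour charges through the alpha/beta/gamma
#' topological shells.
#'
#' @param D Donor calibration coefficient (dimensionless).
#' @param A Acceptor calibration coefficient (dimensionless).
#' @param T Bond reduction factor, strictly between 0 and 1.
#' @return An object of class `strength_params`.
#' @export
strength_params <- function(D = 63.7, A = -4.4362, T = 0.274) {
  stopifnot(is.numeric(D), is.numeric(A), is.numeric(T), length(T) == 1)
  if (!(T > 0 && T < 1)) stop("T must lie strictly between 0 and 1")
  structure(list(D = as.numeric(D), A = as.numeric(A), T = as.numeric(T)),
            class = "strength_params")
}

#' Full hydration-model parameter set
#'
#' Bundles the strength calibration with the eleven free parameters of the
#' polar (`exp_d`, `exp_a`, `g_d`, `g_a`), apolar (`g_0`, `g_s`, `g_r`,
#' `g_pi2`, `g_pi1`) and interaction (`g_i`, `F`) terms. Defaults are the
#' published fitted values; energies are in kJ/mol throughout.
#'
#' @param strength A [strength_params()] object.
#' @param exp_d,exp_a Exponents on the hydrogen / lone-pair multiplicities.
#' @param g_d,g_a Polar-term coefficients (donor, acceptor).
#' @param g_0 Apolar constant term, kJ/mol.
#' @param g_s Surface coefficient, kJ/mol/A^2.
#' @param g_r Ring-count coefficient, kJ/mol.
#' @param g_pi2,g_pi1 Coefficients for pi-orbital counts of sp1/sp2 atoms.
#' @param g_i Acceptor-acceptor interaction coefficient, kJ/mol.
#' @param F Attenuation on the third (nnn) interaction shell.
#' @return An object of class `hydration_params`.
#' @export
hydration_params <- function(strength = strength_params(),
                             exp_d = 0.50, exp_a = 0.34,
                             g_d = 0.908, g_a = -16.131,
                             g_0 = 1.884, g_s = 0.0467, g_r = -3.643,
                             g_pi2 = -1.174, g_pi1 = -1.602,
                             g_i = 4.9996, F = 0.514) {
  stopifnot(inherits(strength, "strength_params"))
  free <- list(exp_d = exp_d, exp_a = exp_a, g_d = g_d, g_a = g_a,
               g_0 = g_0, g_s = g_s, g_r = g_r, g_pi2 = g_pi2,
               g_pi1 = g_pi1, g_i = g_i, F = F)
  if (!all(vapply(free, function(x) is.numeric(x) && length(x) == 1,
                  logical(1)))) {
    stop("all free parameters must be numeric scalars")
  }
  structure(c(list(strength = strength), lapply(free, as.numeric)),
            class = "hydration_params")
}

# names of the free (fittable) parameters, in canonical order
free_param_names <- function() {
  c("exp_d", "exp_a", "g_d", "g_a", "g_0", "g_s", "g_r",
    "g_pi2", "g_pi1", "g_i", "F")
}

#' @export
print.hydration_params <- function(x, ...) {
  cat("<hydration_params>\n")
  cat(sprintf("  calibration: D = %.4g, A = %.6g, T = %.3f\n",
              x$strength$D, x$strength$A, x$strength$T))
  fp <- unlist(x[free_param_names()])
  cat("  free:", paste(sprintf("%s = %.4g", names(fp), fp),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a parameter set as a YAML config file
#'
#' The on-disk format is a flat YAML mapping with keys `D`, `A`, `T` and
#' the eleven free-parameter names, round-trippable into the predictor.
#'
#' @param params A [hydration_params()] object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a [hydration_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "hydration_params"))
  flat <- c(params$strength[c("D", "A", "T")], params[free_param_names()])
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  flat <- yaml::read_yaml(path)
  need <- c("D", "A", "T", free_param_names())
  missing <- setdiff(need, names(flat))
  if (length(missing)) {
    stop("parameter file misses keys: ", paste(missing, collapse = ", "))
  }
  do.call(hydration_params,
          c(list(strength = strength_params(flat$D, flat$A, flat$T)),
            flat[free_param_names()]))
}

# replace a subset of free parameters, returning a new set
set_free_params <- function(params, values) {
  stopifnot(inherits(params, "hydration_params"))
  bad <- setdiff(names(values), free_param_names())
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  for (nm in names(values)) params[[nm]] <- as.numeric(values[[nm]])
  params
}
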