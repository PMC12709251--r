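#' Canham-Helfrich elastic constants
#'
#' Bundles the four constants of the curvature-elastic description of the
#' bilayer.  Internally all energies are in kBT and all lengths in nm, so
#' stresses are kBT/nm^3 and tensions kBT/nm^2.
#'
#' @param k bending rigidity (kBT), must be positive; typically ~20 kBT.
#' @param kG0 intrinsic Gaussian modulus at zero tension (kBT); stability
#'   arguments place it in roughly \[-k, -0.7k\].
#' @param m bilayer spontaneous curvature (1/nm); positive means the
#'   membrane prefers to bulge toward the exterior (z > 0).
#' @param gamma mechanical membrane tension (kBT/nm^2).
#' @return an object of class `elastic_constants`.
#' @seealso [total_tension()] for the derived total tension
#'   \eqn{\Sigma = \gamma + 2 k m^2}.
#' @export
elastic_constants <- function(k = 20, kG0 = -0.7 * k, m = 0, gamma = 0) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(kG0), length(kG0) == 1L, is.finite(kG0),
            is.numeric(m), length(m) == 1L, is.finite(m),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (k <= 0) stop("bending rigidity `k` must be positive")
  structure(list(k = k, kG0 = kG0, m = m, gamma = gamma),
            class = "elastic_constants")
}

#' Total membrane tension
#'
#' The zeroth moment of the lateral stress is the total tension
#' \eqn{\Sigma = \gamma + \hat\Sigma}, where \eqn{\hat\Sigma = 2 k m^2} is
#' the spontaneous tension generated by leaflet asymmetry.  Sigma is always
#' recomputed from (gamma, k, m), never stored.
#'
#' @param params an [elastic_constants()] object.
#' @return Sigma in kBT/nm^2.
#' @export
total_tension <- function(params) {
  stopifnot(inherits(params, "elastic_constants"))
  params$gamma + 2 * params$k * params$m^2
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat("Canham-Helfrich elastic constants:\n")
  cat(sprintf("  k     = %g kBT\n", x$k))
  cat(sprintf("  kG|0  = %g kBT (kG0/k = %g)\n", x$kG0, x$kG0 / x$k))
  cat(sprintf("  m     = %g 1/nm\n", x$m))
  cat(sprintf("  gamma = %g kBT/nm^2\n", x$gamma))
  cat(sprintf("  Sigma = %g kBT/nm^2 (derived)\n", total_tension(x)))
  invisible(x)
}

#' Diffuse-interface geometry
#'
#' The interface parameter epsilon sets the width of the diffuse layer; the
#' kink reaches its limiting values to within ~3% at a distance of
#' 3*epsilon, so six epsilon are matched with the membrane thickness,
#' `lme = 6*epsilon = 5 nm` by default.  Either `lme` or `epsilon` may be
#' given; ratios lme/epsilon in \[5, 7\] are accepted (the alternative
#' convention lme = 5.73*epsilon makes the tension-correction length zD
#' exactly lme/3).
#'
#' @param lme membrane thickness in nm (default 5).
#' @param epsilon interface parameter in nm (default `lme/ratio`).
#' @param ratio thickness-to-epsilon ratio (default 6).
#' @return an object of class `interface_geometry` with fields `epsilon`
#'   and `lme`.
#' @export
interface_geometry <- function(lme = 5, epsilon = lme / ratio, ratio = 6) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (missing(lme) && !missing(epsilon)) lme <- ratio * epsilon
  r <- lme / epsilon
  if (r < 5 || r > 7)
    stop(sprintf("lme/epsilon = %.3f outside the accepted range [5, 7]", r))
  structure(list(epsilon = epsilon, lme = lme),
            class = "interface_geometry")
}

#' @export
print.interface_geometry <- function(x, ...) {
  cat(sprintf("Diffuse-interface geometry: epsilon = %g nm, lme = %g nm (lme/epsilon = %g)\n",
              x$epsilon, x$lme, x$lme / x$epsilon))
  invisible(x)
}

component_names <- c("sB2", "sB1", "sB0", "sG", "sT")

new_stress_profile <- function(z, components, units_tag = "kbt_nm3",
                               params = NULL, geom = NULL, meta = list()) {
  stopifnot(is.numeric(z), all(diff(z) > 0))
  components <- as.data.frame(components)
  stopifnot(nrow(components) == length(z))
  structure(list(z = z,
                 components = components,
                 total = rowSums(components),
                 units_tag = units_tag,
                 params = params, geom = geom, meta = meta),
            class = "stress_profile")
}

#' @export
print.stress_profile <- function(x, ...) {
  cat(sprintf("Lateral stress profile: %d points, z in [%g, %g] nm, units %s\n",
              length(x$z), min(x$z), max(x$z), x$units_tag))
  cat(sprintf("  components: %s; max |total| = %g\n",
              paste(names(x$components), collapse = ", "),
              max(abs(x$total))))
  if (!is.null(x$params)) {
    cat(sprintf("  generated from k = %g, kG0 = %g, m = %g, gamma = %g; epsilon = %g nm\n",
                x$params$k, x$params$kG0, x$params$m, x$params$gamma,
                x$geom$epsilon))
  }
  invisible(x)
}

#' @export
as.data.frame.stress_profile <- function(x, ...) {
  cbind(data.frame(z = x$z), x$components, data.frame(total = x$total))
}
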