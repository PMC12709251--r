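# Monolayer-bilayer consistency relations and the sign rules for molecule
# insertion.

#' Per-leaflet elastic constants
#'
#' @param k_m monolayer bending rigidity (kBT), positive.
#' @param m_m monolayer spontaneous curvature (1/nm).
#' @param kG_m monolayer Gaussian modulus (kBT), usually negative.
#' @param Sigma_m monolayer tension (kBT/nm^2).
#' @return an object of class `monolayer_constants`.
#' @export
monolayer_constants <- function(k_m, m_m = 0, kG_m = 0, Sigma_m = 0) {
  stopifnot(is.numeric(k_m), length(k_m) == 1L)
  if (k_m <= 0) stop("monolayer bending rigidity `k_m` must be positive")
  structure(list(k_m = k_m, m_m = m_m, kG_m = kG_m, Sigma_m = Sigma_m),
            class = "monolayer_constants")
}

#' Combine two monolayers into bilayer elastic constants
#'
#' The bilayer constants follow from the per-leaflet ones when each
#' monolayer has a neutral surface (where bending and stretching decouple)
#' at `z = +z0` (leaflet 1, outer) and `z = -z0` (leaflet 2, inner):
#' \deqn{\Sigma = \Sigma_{m1} + \Sigma_{m2}, \qquad k = k_{m1} + k_{m2},}
#' \deqn{m = \frac{k_{m1} m_{m1} - k_{m2} m_{m2}}{k_{m1}+k_{m2}}
#'   + z_0 \frac{\Sigma_{m1}-\Sigma_{m2}}{2 (k_{m1}+k_{m2})},}
#' \deqn{k_G = k_{Gm1} + k_{Gm2} - 4 z_0 (k_{m1} m_{m1} + k_{m2} m_{m2})
#'   + z_0^2 \Sigma.}
#' The first-order z0 term in m is often neglected in the literature;
#' `drop_z0_tension_term = TRUE` reproduces that variant.
#'
#' @param m1 outer-leaflet [monolayer_constants()] (z > 0).
#' @param m2 inner-leaflet [monolayer_constants()] (z < 0).
#' @param z0 neutral-plane offset from the mid-surface (nm, >= 0).
#' @param drop_z0_tension_term drop the z0*(Sigma_m1 - Sigma_m2) term in m.
#' @return list with the bilayer `params` (an [elastic_constants()], gamma
#'   back-computed as Sigma - 2km^2), `Sigma`, and `kG` (the tension-
#'   corrected Gaussian modulus; `params$kG0` holds the value the stress
#'   profile uses at zero tension).
#' @export
combine_monolayers <- function(m1, m2, z0 = 0, drop_z0_tension_term = FALSE) {
  stopifnot(inherits(m1, "monolayer_constants"),
            inherits(m2, "monolayer_constants"),
            is.numeric(z0), length(z0) == 1L, z0 >= 0)
  k <- m1$k_m + m2$k_m
  if (k <= 0) stop("combined bending rigidity must be positive")
  Sigma <- m1$Sigma_m + m2$Sigma_m
  m <- (m1$k_m * m1$m_m - m2$k_m * m2$m_m) / k
  if (!drop_z0_tension_term)
    m <- m + z0 * (m1$Sigma_m - m2$Sigma_m) / (2 * k)
  kG <- m1$kG_m + m2$kG_m - 4 * z0 * (m1$k_m * m1$m_m + m2$k_m * m2$m_m) +
    z0^2 * Sigma
  kG0 <- kG - z0^2 * Sigma
  gamma <- Sigma - 2 * k * m^2
  list(params = elastic_constants(k = k, kG0 = kG0, m = m, gamma = gamma),
       Sigma = Sigma, kG = kG, z0 = z0)
}

#' Sign rules for molecule insertion
#'
#' Mechanical consequence of the consistency relations: a shallow insertion
#' (into the headgroup region) generates a positive monolayer spontaneous
#' curvature, a deep insertion (into the chain region) a negative one.  The
#' bilayer spontaneous curvature m inherits the sign with a flip for the
#' inner leaflet, while the Gaussian modulus shifts as
#' `-4 z0 k_m * delta m_m`, i.e. opposite in sign to the monolayer curvature
#' change regardless of leaflet.
#'
#' @param leaflet "outer" or "inner".
#' @param depth "shallow" or "deep".
#' @return list with `d_m` and `d_kG`, each "+" or "-".
#' @examples
#' insertion_effect("outer", "shallow")  # m up, kG more negative
#' @export
insertion_effect <- function(leaflet = c("outer", "inner"),
                             depth = c("shallow", "deep")) {
  leaflet <- match.arg(leaflet)
  depth <- match.arg(depth)
  d_mm <- if (depth == "shallow") +1 else -1   # monolayer curvature change
  d_m <- if (leaflet == "outer") d_mm else -d_mm
  d_kG <- -d_mm                                # -4 z0 k_m d_mm, z0 > 0
  list(d_m = if (d_m > 0) "+" else "-",
       d_kG = if (d_kG > 0) "+" else "-")
}
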