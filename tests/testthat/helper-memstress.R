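# shared fixtures and independent numerical oracles

default_geom <- function() interface_geometry()

default_params <- function() {
  elastic_constants(k = 20, kG0 = -14, m = 0.1, gamma = 0.005)
}

# central finite difference of a scalar function, order 1..3, with one
# Richardson extrapolation step to kill the h^2 truncation term (needed to
# reach ~1e-8 accuracy on third derivatives without roundoff blow-up)
fd_deriv <- function(fn, x, order = 1L, h = 1e-2) {
  stencil <- function(h) {
    switch(order,
           (fn(x + h) - fn(x - h)) / (2 * h),
           (fn(x + h) - 2 * fn(x) + fn(x - h)) / h^2,
           (fn(x + 2 * h) - 2 * fn(x + h) + 2 * fn(x - h) - fn(x - 2 * h)) /
             (2 * h^3))
  }
  (4 * stencil(h / 2) - stencil(h)) / 3
}

# independent quadrature oracle (adaptive, not the package's Simpson rule)
quad_oracle <- function(fn, lower, upper, ...) {
  integrate(fn, lower, upper, rel.tol = 1e-10, abs.tol = 1e-10,
            subdivisions = 2000L, ...)$value
}

# moment of a closed-form component by the adaptive oracle; the parity
# integrands that are exactly zero make integrate() abort, so fold the
# domain to [0, inf) first: int z^i g(z) dz = int z^i [g(z) +- g(-z)] dz
moment_oracle <- function(g, i, epsilon) {
  sgn <- if (i %% 2L == 0L) 1 else -1
  quad_oracle(function(z) z^i * (g(z) + sgn * g(-z)), 0, 40 * epsilon)
}
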