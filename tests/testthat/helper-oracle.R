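# Independent quadrature oracle for the oblate-spheroid surface.
#
# Rotating x(z) = A*sqrt(1 - z^2/B^2) about the z axis gives
#   S = 2*pi * Int_{-B}^{B} x * sqrt(1 + x'(z)^2) dz
# and x*sqrt(1 + x'^2) = sqrt(x^2 + (x*x')^2) with x*x' = -A^2 z / B^2,
# so the integrand sqrt(A^2 (1 - z^2/B^2) + A^4 z^2 / B^4) is smooth on
# [-B, B] (no endpoint singularity).
oblate_surface_quadrature <- function(A, B) {
  f <- function(z) sqrt(A^2 * (1 - z^2 / B^2) + A^4 * z^2 / B^4)
  2 * pi * stats::integrate(f, -B, B, rel.tol = 1e-12, abs.tol = 0)$value
}

# Fixture rows by species substring, for printed-cell lookups.
fixture_row <- function(table, species) {
  tab <- rbc_fixture(table)
  hit <- grepl(species, tab$species, fixed = TRUE)
  stopifnot(sum(hit) == 1L)
  tab[hit, ]
}
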