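# Shared fixtures and small utilities for the suite. Surfaces are cheap to
# build, so each helper constructs on demand (no cross-test state).

ref_surfaces <- function() list(
  cylinder = make_surface("cylinder"),
  spherocylinder = make_surface("spherocylinder"),
  torus = make_surface("torus"),
  helix_tube = make_surface("helix_tube"),
  ellipsoid = make_surface("ellipsoid"),
  bulged_cylinder = make_surface("bulged_cylinder"),
  undulating_cylinder = make_surface("undulating_cylinder"),
  noncircular_cylinder = make_surface("noncircular_cylinder"))

## normalized, area-weighted L1 distance between two concentration fields on
## the same grid (1/2 sum |c1 - c2| dA with each field normalized to unit
## total); the standard discrepancy measure used throughout
l1_distance <- function(f1, f2) {
  c1 <- f1$CF / sum(f1$CF * f1$dA)
  c2 <- if (inherits(f2, "concentration_field"))
    f2$CF / sum(f2$CF * f2$dA) else f2
  sum(abs(c1 - c2) * f1$dA) / 2
}

## L1 deviation of a field from the uniform density
l1_from_uniform <- function(f) {
  u <- matrix(1 / sum(f$dA), nrow(f$CF), ncol(f$CF))
  l1_distance(f, u)
}

mreb_params <- function(...) translocation_params(...)
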