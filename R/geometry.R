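## Differential geometry on parametric surfaces: fundamental forms, shape
## operator, principal curvatures/directions, area elements and quadrature.

#' Tolerance below which a point is treated as umbilic (principal curvature
#' difference, um^-1)
#' @keywords internal
UMBILIC_TOL <- 1e-6

## Vectorized curvature computation. u, v: numeric vectors (recycled to a
## common length). Returns a list of per-point vectors/matrices:
##   k1 >= k2 (um^-1), H, K, dc = k1 - k2, umbilic flag,
##   d1, d2: unit principal directions in 3D (n x 3),
##   d1p: components of d1 in the (u, v) parameter basis (n x 2),
##   E, F, G: first fundamental form; sqrtg: area element; n_in: inward normal.
curvature_batch <- function(surface, u, v, wrap = TRUE) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  e <- sg_eval(surface, u, v, wrap = wrap)
  E <- rowSums(e$ru * e$ru)
  FF <- rowSums(e$ru * e$rv)
  G <- rowSums(e$rv * e$rv)
  detI <- E * G - FF^2
  if (any(detI <= 0))
    stop("non-regular surface point encountered (degenerate metric)")
  cr <- vcross(e$ru, e$rv)
  nin <- surface$nsign * cr / sqrt(detI)
  L <- rowSums(e$ruu * nin)
  M <- rowSums(e$ruv * nin)
  N2 <- rowSums(e$rvv * nin)
  H <- (G * L + E * N2 - 2 * FF * M) / (2 * detI)
  K <- (L * N2 - M^2) / detI
  disc <- pmax(H * H - K, 0)
  rt <- sqrt(disc)
  k1 <- H + rt
  k2 <- H - rt
  dc <- k1 - k2
  umb <- dc < UMBILIC_TOL
  ## principal direction for k1: null vector of (II - k1 I); pick the
  ## better-conditioned row of the 2x2 system
  a1 <- L - k1 * E;  b1 <- M - k1 * FF
  b2 <- M - k1 * FF; c2 <- N2 - k1 * G
  use1 <- (a1 * a1 + b1 * b1) >= (b2 * b2 + c2 * c2)
  wu <- ifelse(use1, -b1, -c2)
  wv <- ifelse(use1, a1, b2)
  bad <- (wu * wu + wv * wv) < 1e-28 | umb
  wu[bad] <- 1; wv[bad] <- 0   # arbitrary at umbilics
  d1 <- wu * e$ru + wv * e$rv
  len <- vnorm(d1)
  d1 <- d1 / len
  d1p <- cbind(wu / len, wv / len)
  d2 <- vcross(nin, d1)
  list(k1 = k1, k2 = k2, H = H, K = K, dc = dc, umbilic = umb,
       d1 = d1, d2 = d2, d1p = d1p, E = E, F = FF, G = G,
       sqrtg = sqrt(detI), n_in = nin, xyz = e$r, ru = e$ru, rv = e$rv)
}

#' Curvature data at a surface point
#'
#' Computes the shape operator from the first and second fundamental forms and
#' returns principal curvatures (k1 >= k2, in um^-1), principal directions
#' (3D unit vectors and parameter-space components), mean curvature H,
#' Gaussian curvature K, the principal-curvature difference dc = k1 - k2 and
#' an umbilic flag (dc below tolerance, where principal directions are
#' undefined). Curvatures are signed with respect to the inward normal:
#' outward-convex regions are positive.
#'
#' @param surface a [make_surface()] object.
#' @param u,v parameter coordinates of the point.
#' @return A list with fields `k1`, `k2`, `d1`, `d2`, `H`, `K`, `dc`,
#'   `umbilic`, `d1_param`, `point` (3D position).
#' @export
curvature_at <- function(surface, u, v) {
  cb <- curvature_batch(surface, u[1], v[1])
  list(k1 = cb$k1, k2 = cb$k2, d1 = drop(cb$d1), d2 = drop(cb$d2),
       H = cb$H, K = cb$K, dc = cb$dc, umbilic = cb$umbilic,
       d1_param = drop(cb$d1p), point = drop(cb$xyz))
}

#' Area element at surface points
#'
#' The metric factor sqrt(det g) (um^2 per unit parameter area), i.e. the
#' density with respect to which membrane area is measured in (u, v).
#'
#' @inheritParams curvature_at
#' @return Numeric vector of strictly positive area-element values.
#' @export
area_element <- function(surface, u, v) {
  e <- sg_eval(surface, u, v)
  E <- rowSums(e$ru * e$ru)
  FF <- rowSums(e$ru * e$rv)
  G <- rowSums(e$rv * e$rv)
  g <- E * G - FF^2
  if (any(g <= 0)) stop("non-regular surface point (degenerate metric)")
  sqrt(g)
}

#' Structured quadrature / solver grid on a surface
#'
#' Midpoint grid over the parameter domain with metric area weights. Cell
#' edges are aligned with the surface's natural break lines (e.g. the
#' cap-cylinder seams of a spherocylinder) so that discontinuous integrands
#' are not smeared across cells.
#'
#' @param surface a parametric surface.
#' @param n_u,n_v cell counts (defaults from the surface spec resolution).
#' @return List with cell-center coordinates `u`, `v`, their outer grid
#'   (`U`, `V` as vectors over all cells, column-major in u), edge vectors
#'   `u_edges`, `v_edges`, cell parameter sizes and area weights `dA`
#'   (n_u x n_v matrix).
#' @export
surface_grid <- function(surface, n_u = NULL, n_v = NULL) {
  if (is.null(n_u)) n_u <- surface$resolution[1]
  if (is.null(n_v)) n_v <- surface$resolution[2]
  d <- surface$domain
  br <- sort(unique(c(d[1], surface$breaks_u, d[2])))
  br <- br[br >= d[1] & br <= d[2]]
  seg <- diff(br)
  ncell <- pmax(1L, round(n_u * seg / sum(seg)))
  u_edges <- unique(unlist(lapply(seq_along(seg), function(i)
    seq(br[i], br[i + 1], length.out = ncell[i] + 1))))
  v_edges <- seq(d[3], d[4], length.out = n_v + 1)
  uc <- (u_edges[-1] + u_edges[-length(u_edges)]) / 2
  vc <- (v_edges[-1] + v_edges[-length(v_edges)]) / 2
  du <- diff(u_edges); dv <- diff(v_edges)
  U <- rep(uc, times = length(vc))
  V <- rep(vc, each = length(uc))
  sq <- area_element(surface, U, V)
  dA <- matrix(sq * rep(du, times = length(vc)) * rep(dv, each = length(uc)),
               nrow = length(uc))
  list(u = uc, v = vc, U = U, V = V, u_edges = u_edges, v_edges = v_edges,
       du = du, dv = dv, dA = dA, n_u = length(uc), n_v = length(vc))
}

#' Metric-weighted surface integral of a scalar field
#'
#' Midpoint quadrature of `f` over the whole surface. `f` may be a function
#' `f(u, v)` (vectorized), a function `f(curv)` taking the curvature batch
#' when `use_curvature = TRUE`, or a matrix of cell values on the given grid.
#'
#' @param surface a parametric surface.
#' @param f integrand (see Details).
#' @param n_u,n_v quadrature resolution.
#' @param use_curvature if TRUE, `f` receives the curvature batch list.
#' @return The integral (scalar).
#' @examples
#' s <- make_surface("torus")
#' surface_integral(s, function(cv) cv$K, use_curvature = TRUE)  # ~ 0
#' @export
surface_integral <- function(surface, f, n_u = 256, n_v = 128,
                             use_curvature = FALSE) {
  g <- surface_grid(surface, n_u, n_v)
  vals <- if (is.matrix(f)) {
    f
  } else if (use_curvature) {
    cb <- curvature_batch(surface, g$U, g$V)
    matrix(f(cb), nrow = g$n_u)
  } else {
    matrix(f(g$U, g$V), nrow = g$n_u)
  }
  sum(vals * g$dA)
}

#' Total surface area
#' @param surface a parametric surface.
#' @param n_u,n_v quadrature resolution.
#' @return Area in um^2.
#' @export
surface_area <- function(surface, n_u = 256, n_v = 128)
  surface_integral(surface, function(u, v) rep(1, length(u)), n_u, n_v)

#' Convert a tangent direction to a parameter-space heading angle
#'
#' Returns the angle theta, measured from the u-axis in parameter
#' coordinates, such that the surface tangent r_theta = cos(theta) r_u +
#' sin(theta) r_v points along the given 3D direction (projected onto the
#' tangent plane first). Inverse of [angle_to_direction()].
#'
#' @param surface a parametric surface.
#' @param u,v the point.
#' @param direction 3D direction vector (length-3, or n x 3 matrix).
#' @return theta in (-pi, pi].
#' @export
direction_to_angle <- function(surface, u, v, direction) {
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  e <- sg_eval(surface, u, v)
  E <- rowSums(e$ru * e$ru); FF <- rowSums(e$ru * e$rv)
  G <- rowSums(e$rv * e$rv)
  if (any(vnorm(direction) < 1e-300)) stop("zero-length direction")
  a <- rowSums(direction * e$ru)
  b <- rowSums(direction * e$rv)
  det <- E * G - FF^2
  x <- (G * a - FF * b) / det
  y <- (E * b - FF * a) / det
  atan2(y, x)
}

#' Convert a parameter-space heading angle to a unit tangent direction
#'
#' @inheritParams direction_to_angle
#' @param theta heading angle from the u-axis (rad).
#' @return Unit 3D tangent vector(s), n x 3.
#' @export
angle_to_direction <- function(surface, u, v, theta) {
  e <- sg_eval(surface, u, v)
  d <- cos(theta) * e$ru + sin(theta) * e$rv
  d / vnorm(d)
}

#' Export a surface as a legacy-ASCII VTK structured grid with curvature fields
#'
#' Writes vertex positions plus per-vertex H, K, k1, k2 scalars, suitable for
#' heat-map visualization. Optionally attaches an extra per-vertex field
#' (e.g. a concentration).
#'
#' @param surface a parametric surface.
#' @param path output file path (.vtk).
#' @param n_u,n_v vertex counts.
#' @param field optional named list with `name` and `values` (length n_u*n_v).
#' @return Invisibly, the path.
#' @export
write_surface_vtk <- function(surface, path, n_u = 96, n_v = 48,
                              field = NULL) {
  d <- surface$domain
  uu <- seq(d[1], d[2], length.out = n_u)
  vv <- seq(d[3], d[4], length.out = n_v)
  ## nudge off coordinate poles where the metric degenerates
  if (!surface$periodic[1]) {
    eps <- 1e-6 * (d[2] - d[1])
    uu[1] <- uu[1] + eps; uu[n_u] <- uu[n_u] - eps
  }
  U <- rep(uu, times = n_v); V <- rep(vv, each = n_u)
  cb <- curvature_batch(surface, U, V)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("mrebdyn surface:", surface$kind),
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", n_u, n_v),
               sprintf("POINTS %d float", n_u * n_v)), con)
  utils::write.table(format(cb$xyz, digits = 7), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POINT_DATA %d", n_u * n_v), con)
  flds <- list(H = cb$H, K = cb$K, k1 = cb$k1, k2 = cb$k2)
  if (!is.null(field)) flds[[field$name]] <- field$values
  for (nm in names(flds)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(flds[[nm]], digits = 7), con)
  }
  invisible(path)
}
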