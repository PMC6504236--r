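#' Surface specification
#'
#' Describes one of the supported parametric geometries by name plus named
#' dimensions (in micrometres) and a grid resolution. The specification is
#' validated here; [make_surface()] turns it into an evaluable surface.
#'
#' Supported kinds and their dimensions:
#' \describe{
#'   \item{plane}{`length_u`, `length_v` (treated as a flat periodic patch).}
#'   \item{cylinder}{`radius`, `length` (axially periodic).}
#'   \item{spherocylinder}{`radius`, `length` (cylindrical part; closed by
#'     hemispherical caps).}
#'   \item{torus}{`tube_radius`, `centerline_radius`.}
#'   \item{bent_rod}{as torus, plus `arc_fraction` in (0, 1]; ends reflect.}
#'   \item{helix_tube}{`tube_radius`, `helix_radius`, `pitch`, `n_turns`.}
#'   \item{ellipsoid}{`a`, `b`, `c` semi-axes (closed).}
#'   \item{bulged_cylinder}{`radius`, `length`, `bulge_amplitude`,
#'     `bulge_width` (smooth compactly supported bump at mid-length).}
#'   \item{undulating_cylinder}{`radius`, `amplitude`, `wavelength`, `length`
#'     (length should be a multiple of `wavelength`; axially periodic).}
#'   \item{noncircular_cylinder}{`a`, `b` cross-section semi-axes, `length`
#'     (zero Gaussian curvature everywhere).}
#' }
#'
#' @param kind geometry name (see Details).
#' @param ... named dimensions in micrometres (see Details).
#' @param resolution integer vector of length 2, grid cells along (u, v).
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(kind, ..., resolution = c(64L, 48L)) {
  kinds <- c("plane", "cylinder", "spherocylinder", "torus", "bent_rod",
             "helix_tube", "ellipsoid", "bulged_cylinder",
             "undulating_cylinder", "noncircular_cylinder")
  kind <- match.arg(kind, kinds)
  dims <- list(...)
  if (length(dims) == 1L && is.list(dims[[1L]]) && is.null(names(dims)[1L]))
    dims <- dims[[1L]]
  defaults <- switch(kind,
    plane = list(length_u = 2, length_v = 2),
    cylinder = list(radius = 0.5, length = 3),
    spherocylinder = list(radius = 0.5, length = 3),
    torus = list(tube_radius = 0.5, centerline_radius = 5),
    bent_rod = list(tube_radius = 0.5, centerline_radius = 5,
                    arc_fraction = 1),
    helix_tube = list(tube_radius = 0.5, helix_radius = 1.5, pitch = 4,
                      n_turns = 2),
    ellipsoid = list(a = 0.5, b = 0.5, c = 1.5),
    bulged_cylinder = list(radius = 0.5, length = 6, bulge_amplitude = 0.3,
                           bulge_width = 0.5),
    undulating_cylinder = list(radius = 0.5, amplitude = 0.2, wavelength = 2,
                               length = 4),
    noncircular_cylinder = list(a = 0.7, b = 0.35, length = 4))
  unknown <- setdiff(names(dims), names(defaults))
  if (length(unknown))
    stop("unknown dimension(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  dims <- utils::modifyList(defaults, dims)
  num <- unlist(dims[names(dims) != "arc_fraction"])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all surface dimensions must be positive and finite")
  if (kind %in% c("torus", "bent_rod") &&
      dims$tube_radius >= dims$centerline_radius)
    stop("torus tube_radius must be smaller than centerline_radius")
  if (kind == "undulating_cylinder" && dims$amplitude >= dims$radius)
    stop("undulation amplitude must be smaller than the mean radius")
  if (kind == "helix_tube" && dims$tube_radius >= dims$helix_radius)
    stop("helix tube_radius must be smaller than helix_radius")
  if (kind == "bent_rod" &&
      (dims$arc_fraction <= 0 || dims$arc_fraction > 1))
    stop("bent_rod arc_fraction must lie in (0, 1]")
  resolution <- as.integer(resolution)
  if (length(resolution) != 2L || any(resolution < 4L))
    stop("resolution must be two integers >= 4")
  structure(list(kind = kind, dims = dims, resolution = resolution),
            class = "surface_spec")
}

#' @export
print.surface_spec <- function(x, ...) {
  cat("Surface spec:", x$kind, "\n")
  cat("  dims:", paste(names(x$dims), unlist(x$dims), sep = " = ",
                       collapse = ", "), "\n")
  cat("  resolution:", paste(x$resolution, collapse = " x "), "\n")
  invisible(x)
}

## Internal constructor: assemble a parametric_surface object. `f` returns the
## map and its first/second partials at (u, v) as n x 3 matrices.
new_surface <- function(kind, dims, f, domain, periodic, wrap, outward,
                        closed = FALSE, breaks_u = NULL, resolution) {
  s <- structure(list(kind = kind, dims = dims, f = f, domain = domain,
                      periodic = periodic, wrap = wrap, closed = closed,
                      breaks_u = breaks_u, resolution = resolution,
                      nsign = 1), class = "parametric_surface")
  ## fix normal sign so curvature is computed with respect to the inward
  ## normal (outward-convex surfaces get positive principal curvatures)
  u0 <- domain[1] + 0.37 * (domain[2] - domain[1])
  v0 <- domain[3] + 0.29 * (domain[4] - domain[3])
  e <- f(u0, v0)
  cr <- vcross(e$ru, e$rv)
  out <- outward(u0, v0, e$r)
  s$nsign <- if (sum(cr * out) >= 0) -1 else 1
  s$outward <- outward
  s
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(a) sqrt(rowSums(a * a))

## Surface of revolution about the z axis: profile(u) must return a list with
## rho, drho, ddrho, z, dz, ddz (vectorized over u). v is the angle.
revolution_eval <- function(profile) {
  function(u, v) {
    p <- profile(u)
    cv <- cos(v); sv <- sin(v)
    list(r   = cbind(p$rho * cv, p$rho * sv, p$z),
         ru  = cbind(p$drho * cv, p$drho * sv, p$dz),
         rv  = cbind(-p$rho * sv, p$rho * cv, 0 * u),
         ruu = cbind(p$ddrho * cv, p$ddrho * sv, p$ddz),
         ruv = cbind(-p$drho * sv, p$drho * cv, 0 * u),
         rvv = cbind(-p$rho * cv, -p$rho * sv, 0 * u))
  }
}

wrap_mod <- function(x, lo, hi) lo + (x - lo) %% (hi - lo)

## Wrap helpers: periodic in v always (angle); u either periodic, reflecting
## (wall), or pole-reflecting (pass over a coordinate pole: u reflects and v
## gains pi, exact for surfaces of revolution).
make_wrap <- function(domain, u_mode = c("periodic", "pole", "reflect", "none")) {
  u_mode <- match.arg(u_mode)
  u0 <- domain[1]; u1 <- domain[2]; v0 <- domain[3]; v1 <- domain[4]
  function(u, v) {
    if (u_mode == "periodic") {
      u <- wrap_mod(u, u0, u1)
    } else if (u_mode %in% c("pole", "reflect")) {
      for (k in 1:2) {
        lo <- u < u0; hi <- u > u1
        if (any(lo)) {
          u[lo] <- 2 * u0 - u[lo]
          if (u_mode == "pole") v[lo] <- v[lo] + pi
        }
        if (any(hi)) {
          u[hi] <- 2 * u1 - u[hi]
          if (u_mode == "pole") v[hi] <- v[hi] + pi
        }
      }
    }
    v <- wrap_mod(v, v0, v1)
    list(u = u, v = v)
  }
}

#' Build a parametric surface from a specification
#'
#' Returns a regular parametric surface r(u, v) with analytic first and second
#' partial derivatives. By convention u is the axial/longitudinal coordinate
#' and v the circumferential/angular coordinate (radians) for all tube-like
#' surfaces. Closed surfaces carry a consistent outward orientation; principal
#' curvatures are signed with respect to the inward normal, so an
#' outward-convex sphere has positive curvature.
#'
#' @param spec a [surface_spec()], or a kind name (extra arguments are then
#'   forwarded to [surface_spec()]).
#' @param ... forwarded to [surface_spec()] when `spec` is a kind name.
#' @return An object of class `parametric_surface`.
#' @examples
#' s <- make_surface("cylinder", radius = 0.5, length = 3)
#' curvature_at(s, 1, 0)$k1   # 2 um^-1, circumferential
#' @export
make_surface <- function(spec, ...) {
  if (is.character(spec)) spec <- surface_spec(spec, ...)
  stopifnot(inherits(spec, "surface_spec"))
  d <- spec$dims
  res <- spec$resolution
  switch(spec$kind,
    plane = {
      f <- function(u, v) {
        z <- 0 * u
        list(r = cbind(u, v, z), ru = cbind(z + 1, z, z),
             rv = cbind(z, z + 1, z), ruu = cbind(z, z, z),
             ruv = cbind(z, z, z), rvv = cbind(z, z, z))
      }
      dom <- c(0, d$length_u, 0, d$length_v)
      new_surface("plane", d, f, dom, c(TRUE, TRUE),
                  make_wrap(dom, "periodic"),
                  function(u, v, r) cbind(0 * u, 0 * u, 0 * u + 1),
                  resolution = res)
    },
    cylinder = {
      R <- d$radius
      prof <- function(u) list(rho = 0 * u + R, drho = 0 * u, ddrho = 0 * u,
                               z = u, dz = 0 * u + 1, ddz = 0 * u)
      dom <- c(0, d$length, 0, 2 * pi)
      new_surface("cylinder", d, revolution_eval(prof), dom, c(TRUE, TRUE),
                  make_wrap(dom, "periodic"),
                  function(u, v, r) cbind(r[, 1], r[, 2], 0 * u),
                  resolution = res)
    },
    spherocylinder = {
      R <- d$radius; Lc <- d$length
      prof <- function(u) {
        rho <- drho <- ddrho <- z <- dz <- ddz <- numeric(length(u))
        i1 <- u < 0; i3 <- u > Lc; i2 <- !(i1 | i3)
        if (any(i1)) {
          ph <- u[i1] / R
          rho[i1] <- R * cos(ph); drho[i1] <- -sin(ph)
          ddrho[i1] <- -cos(ph) / R
          z[i1] <- R * sin(ph); dz[i1] <- cos(ph); ddz[i1] <- -sin(ph) / R
        }
        if (any(i2)) {
          rho[i2] <- R; dz[i2] <- 1; z[i2] <- u[i2]
        }
        if (any(i3)) {
          ph <- (u[i3] - Lc) / R
          rho[i3] <- R * cos(ph); drho[i3] <- -sin(ph)
          ddrho[i3] <- -cos(ph) / R
          z[i3] <- Lc + R * sin(ph); dz[i3] <- cos(ph)
          ddz[i3] <- -sin(ph) / R
        }
        list(rho = rho, drho = drho, ddrho = ddrho, z = z, dz = dz, ddz = ddz)
      }
      dom <- c(-pi * R / 2, Lc + pi * R / 2, 0, 2 * pi)
      s <- new_surface("spherocylinder", d, revolution_eval(prof), dom,
                       c(FALSE, TRUE), make_wrap(dom, "pole"),
                       function(u, v, r) cbind(r[, 1], r[, 2], 0 * u),
                       closed = TRUE, breaks_u = c(0, Lc), resolution = res)
      ## global chart inversion (cap spheres / cylinder, radial projection)
      s$invert <- function(x) {
        z <- x[, 3]
        u <- ifelse(z < 0, R * asin(pmax(-1, pmin(1, z / R))),
             ifelse(z > Lc, Lc + R * asin(pmax(-1, pmin(1, (z - Lc) / R))),
                    z))
        list(u = u, v = atan2(x[, 2], x[, 1]))
      }
      ## caps are exact spheres: used for exact near-pole stepping
      s$pole_info <- list(
        list(u_pole = dom[1], center = c(0, 0, 0), R = R,
             invert = function(x) list(u = R * asin(pmax(-1, pmin(1,
                        x[, 3] / R))), v = atan2(x[, 2], x[, 1]))),
        list(u_pole = dom[2], center = c(0, 0, Lc), R = R,
             invert = function(x) list(u = Lc + R * asin(pmax(-1, pmin(1,
                        (x[, 3] - Lc) / R))), v = atan2(x[, 2], x[, 1]))))
      s
    },
    torus = ,
    bent_rod = {
      r <- d$tube_radius; Rt <- d$centerline_radius
      af <- if (spec$kind == "bent_rod") d$arc_fraction else 1
      f <- function(u, v) {
        ps <- u / Rt
        cp <- cos(ps); sp <- sin(ps); cv <- cos(v); sv <- sin(v)
        w <- Rt + r * cv
        list(r   = cbind(w * cp, w * sp, r * sv),
             ru  = cbind(-w * sp / Rt, w * cp / Rt, 0 * u),
             rv  = cbind(-r * sv * cp, -r * sv * sp, r * cv),
             ruu = cbind(-w * cp / Rt^2, -w * sp / Rt^2, 0 * u),
             ruv = cbind(r * sv * sp / Rt, -r * sv * cp / Rt, 0 * u),
             rvv = cbind(-r * cv * cp, -r * cv * sp, -r * sv))
      }
      dom <- c(0, 2 * pi * Rt * af, 0, 2 * pi)
      umode <- if (af >= 1) "periodic" else "reflect"
      new_surface(spec$kind, d, f, dom, c(af >= 1, TRUE),
                  make_wrap(dom, umode),
                  function(u, v, r) {
                    rad <- sqrt(r[, 1]^2 + r[, 2]^2)
                    cbind(r[, 1] * (1 - Rt / rad), r[, 2] * (1 - Rt / rad),
                          r[, 3])
                  },
                  closed = (af >= 1), resolution = res)
    },
    helix_tube = {
      r <- d$tube_radius; Rh <- d$helix_radius; h <- d$pitch / (2 * pi)
      w <- sqrt(Rh^2 + h^2); kc <- Rh / w^2; tau <- h / w^2
      f <- function(u, v) {
        t <- u / w
        ct <- cos(t); st <- sin(t); cv <- cos(v); sv <- sin(v)
        Tm <- cbind(-Rh * st, Rh * ct, 0 * u + h) / w
        Nm <- cbind(-ct, -st, 0 * u)
        Bm <- cbind(h * st, -h * ct, 0 * u + Rh) / w
        cpos <- cbind(Rh * ct, Rh * st, h * t)
        a <- 1 - r * kc * cv
        list(r   = cpos + r * (Nm * cv + Bm * sv),
             ru  = a * Tm + (r * tau) * (Bm * cv - Nm * sv),
             rv  = r * (Bm * cv - Nm * sv),
             ruu = (r * tau * kc * sv) * Tm +
                   (a * kc - r * tau^2 * cv) * Nm - (r * tau^2 * sv) * Bm,
             ruv = (r * kc * sv) * Tm - (r * tau) * (Nm * cv + Bm * sv),
             rvv = -r * (Nm * cv + Bm * sv))
      }
      dom <- c(0, d$n_turns * 2 * pi * w, 0, 2 * pi)
      new_surface("helix_tube", d, f, dom, c(TRUE, TRUE),
                  make_wrap(dom, "periodic"),
                  function(u, v, r) {   # away from the local centerline point
                    t <- u / w
                    cc <- cbind(Rh * cos(t), Rh * sin(t), h * t)
                    r - cc
                  },
                  resolution = res)
    },
    ellipsoid = {
      a <- d$a; b <- d$b; cc <- d$c
      f <- function(u, v) {
        su <- sin(u); cu <- cos(u); sv <- sin(v); cv <- cos(v)
        list(r   = cbind(a * su * cv, b * su * sv, cc * cu),
             ru  = cbind(a * cu * cv, b * cu * sv, -cc * su),
             rv  = cbind(-a * su * sv, b * su * cv, 0 * u),
             ruu = cbind(-a * su * cv, -b * su * sv, -cc * cu),
             ruv = cbind(-a * cu * sv, b * cu * cv, 0 * u),
             rvv = cbind(-a * su * cv, -b * su * sv, 0 * u))
      }
      dom <- c(0, pi, 0, 2 * pi)
      s <- new_surface("ellipsoid", d, f, dom, c(FALSE, TRUE),
                       make_wrap(dom, "pole"),
                       function(u, v, r) r, closed = TRUE, resolution = res)
      ## tips: osculating spheres (exact for a sphere), for near-pole steps
      s$invert <- ell_invert <- function(x) list(
        u = atan2(sqrt((x[, 1] / a)^2 + (x[, 2] / b)^2), x[, 3] / cc),
        v = atan2(x[, 2] / b, x[, 1] / a))
      R0 <- sqrt(a * b) * sqrt(a * b) / cc   # tip osculating radius a*b/c
      s$pole_info <- list(
        list(u_pole = 0, center = c(0, 0, cc - R0), R = R0,
             invert = ell_invert),
        list(u_pole = pi, center = c(0, 0, -(cc - R0)), R = R0,
             invert = ell_invert))
      s
    },
    bulged_cylinder = {
      R <- d$radius; A <- d$bulge_amplitude; wd <- d$bulge_width
      u0 <- d$length / 2
      ## raised-cosine bump: compact support, bounded edge curvature (the
      ## curvature scale stays comparable to the bump width)
      prof <- function(u) {
        t <- (u - u0) / wd
        b <- db <- ddb <- numeric(length(u))
        i <- abs(t) < 1
        if (any(i)) {
          ti <- t[i]
          b[i] <- (1 + cos(pi * ti)) / 2
          db[i] <- -pi * sin(pi * ti) / 2
          ddb[i] <- -pi^2 * cos(pi * ti) / 2
        }
        list(rho = R + A * b, drho = A * db / wd, ddrho = A * ddb / wd^2,
             z = u, dz = 0 * u + 1, ddz = 0 * u)
      }
      dom <- c(0, d$length, 0, 2 * pi)
      new_surface("bulged_cylinder", d, revolution_eval(prof), dom,
                  c(TRUE, TRUE), make_wrap(dom, "periodic"),
                  function(u, v, r) cbind(r[, 1], r[, 2], 0 * u),
                  breaks_u = c(u0 - wd, u0 + wd), resolution = res)
    },
    undulating_cylinder = {
      R0 <- d$radius; A <- d$amplitude; lw <- d$wavelength
      k <- 2 * pi / lw
      prof <- function(u) list(rho = R0 + A * sin(k * u),
                               drho = A * k * cos(k * u),
                               ddrho = -A * k^2 * sin(k * u),
                               z = u, dz = 0 * u + 1, ddz = 0 * u)
      dom <- c(0, d$length, 0, 2 * pi)
      new_surface("undulating_cylinder", d, revolution_eval(prof), dom,
                  c(TRUE, TRUE), make_wrap(dom, "periodic"),
                  function(u, v, r) cbind(r[, 1], r[, 2], 0 * u),
                  resolution = res)
    },
    noncircular_cylinder = {
      a <- d$a; b <- d$b
      f <- function(u, v) {
        cv <- cos(v); sv <- sin(v); z <- 0 * u
        list(r   = cbind(a * cv, b * sv, u),
             ru  = cbind(z, z, z + 1),
             rv  = cbind(-a * sv, b * cv, z),
             ruu = cbind(z, z, z),
             ruv = cbind(z, z, z),
             rvv = cbind(-a * cv, -b * sv, z))
      }
      dom <- c(0, d$length, 0, 2 * pi)
      new_surface("noncircular_cylinder", d, f, dom, c(TRUE, TRUE),
                  make_wrap(dom, "periodic"),
                  function(u, v, r) cbind(r[, 1], r[, 2], 0 * u),
                  resolution = res)
    })
}

#' @export
print.parametric_surface <- function(x, ...) {
  cat("Parametric surface:", x$kind, "\n")
  cat("  dims:", paste(names(x$dims), unlist(x$dims), sep = " = ",
                       collapse = ", "), "\n")
  cat(sprintf("  domain: u in [%.4g, %.4g]%s, v in [%.4g, %.4g]%s\n",
              x$domain[1], x$domain[2], if (x$periodic[1]) " (periodic)" else "",
              x$domain[3], x$domain[4], if (x$periodic[2]) " (periodic)" else ""))
  if (x$closed) cat("  closed surface (no boundary)\n")
  cat(sprintf("  area: %.4f um^2\n", surface_area(x)))
  invisible(x)
}

## Batch evaluation of the map and its partials; points are canonicalized
## through the surface's wrap rule first unless wrap = FALSE (the analytic
## formulas tolerate modest out-of-domain excursions, used mid-step).
sg_eval <- function(surface, u, v, wrap = TRUE) {
  if (wrap) {
    p <- surface$wrap(u, v)
    u <- p$u; v <- p$v
  }
  surface$f(u, v)
}

## Numerical (central difference) partials of the map; exists to cross-check
## the analytic evaluators and as a fallback for user-defined surfaces.
sg_eval_numeric <- function(surface, u, v, rel_h = 1e-5) {
  hu <- rel_h * (surface$domain[2] - surface$domain[1])
  hv <- rel_h * (surface$domain[4] - surface$domain[3])
  r0 <- surface$f(u, v)$r
  rp <- function(du, dv) surface$f(u + du, v + dv)$r
  list(r = r0,
       ru = (rp(hu, 0) - rp(-hu, 0)) / (2 * hu),
       rv = (rp(0, hv) - rp(0, -hv)) / (2 * hv),
       ruu = (rp(hu, 0) - 2 * r0 + rp(-hu, 0)) / hu^2,
       rvv = (rp(0, hv) - 2 * r0 + rp(0, -hv)) / hv^2,
       ruv = (rp(hu, hv) - rp(hu, -hv) - rp(-hu, hv) + rp(-hu, -hv)) /
             (4 * hu * hv))
}
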