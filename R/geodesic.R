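## Safeguarded stepping primitives for the discrete flow near chart
## degeneracies (umbilic regions and coordinate poles of surfaces of
## revolution), where a straight parameter-space ray misrepresents a straight
## arc on the surface.

## Great-circle step on a (cap / osculating) sphere: from 3D point x0 on a
## sphere (center c0, radius R0), move arc length L along tangent w3.
pole_sphere_step <- function(x0, w3, c0, R0, L) {
  p <- sweep(x0, 2, c0)
  pr <- vnorm(p)
  pn <- p / pr                       # radial unit
  ## orthonormalize the tangent against the radial direction
  wt <- w3 - rowSums(w3 * pn) * pn
  wt <- wt / vnorm(wt)
  phi <- L / R0
  x1 <- sweep(R0 * (cos(phi) * pn + sin(phi) * wt), 2, c0, `+`)
  h1 <- cos(phi) * wt - sin(phi) * pn
  list(x = x1, head = h1)
}

## Shared step kernel of the discrete flow: from (u, v) move on-surface
## distance L along the tangent direction w3 (unit 3D vector in the tangent
## plane). Default: straight parameter-space ray at the angle theta
## corresponding to w3, with the step size from the arclength equation (the
## discrete flow's extrapolation in surface coordinates). Two safeguarded
## exceptions, both requiring the surface to provide a chart inversion:
##  * umbilic points with appreciable curvature (spheres, spherocylinder
##    caps): the uniform-angle rule calls for a straight arc *on the
##    surface*, which is exactly a great circle on the osculating sphere --
##    a parameter ray there distorts the invariant measure;
##  * oblique rays launched deep inside a pole zone (angular-coordinate
##    circle radius below `pole_zone` step lengths), where a straight ray
##    wraps around the pole and distorts the invariant measure: stepped on
##    the nearest pole's (osculating) sphere. Rays closely aligned with a
##    coordinate direction are left alone -- they follow curvature lines /
##    meridians exactly.
## Returns raw (unwrapped) coordinates, the 3D tangent at the end point,
## theta and the parameter-space step ell. `curv` is the curvature batch at
## the points (required for the umbilic rule).
advance_points <- function(surface, u, v, w3, L, curv = NULL,
                           pole_zone = 0.75) {
  e <- sg_eval(surface, u, v)
  E <- rowSums(e$ru * e$ru); FF <- rowSums(e$ru * e$rv)
  G <- rowSums(e$rv * e$rv)
  det <- E * G - FF^2
  a <- rowSums(w3 * e$ru); b <- rowSums(w3 * e$rv)
  x <- (G * a - FF * b) / det
  y <- (E * b - FF * a) / det
  theta <- atan2(y, x)
  n <- length(theta)
  un <- vn <- numeric(n)
  ell <- rep(NA_real_, n)
  head3 <- w3
  special <- rep(FALSE, n)
  if (!is.null(surface$invert)) {
    if (!is.null(curv)) {
      osc <- which(curv$umbilic & abs(curv$k1) > 1e-3)
      if (length(osc)) {
        ctr <- e$r[osc, , drop = FALSE] +
          curv$n_in[osc, , drop = FALSE] / curv$k1[osc]
        ## per-point osculating spheres: rotate each about its own center
        p <- e$r[osc, , drop = FALSE] - ctr
        R0 <- abs(1 / curv$k1[osc])
        pn <- p / vnorm(p)
        wt <- w3[osc, , drop = FALSE]
        wt <- wt - rowSums(wt * pn) * pn
        wt <- wt / vnorm(wt)
        phi <- L / R0
        x1 <- ctr + R0 * (cos(phi) * pn + sin(phi) * wt)
        uv <- surface$invert(x1)
        un[osc] <- uv$u; vn[osc] <- uv$v
        head3[osc, ] <- cos(phi) * wt - sin(phi) * pn
        ell[osc] <- sqrt((uv$u - u[osc])^2 + (uv$v - v[osc])^2)
        special[osc] <- TRUE
      }
    }
  }
  ray <- which(!special)
  if (length(ray)) {
    ell_r <- step_length_in_parameters(surface, u[ray], v[ray], theta[ray],
                                       L, iters = 2L)
    un[ray] <- u[ray] + ell_r * cos(theta[ray])
    vn[ray] <- v[ray] + ell_r * sin(theta[ray])
    ell[ray] <- ell_r
    if (!is.null(surface$pole_info)) {
      bad <- ray[!is.finite(ell_r) |
                   (sqrt(G[ray]) < pole_zone * L &
                      abs(cos(theta[ray])) > 0.05)]
      if (length(bad)) {
        up <- vapply(surface$pole_info, `[[`, numeric(1), "u_pole")
        near <- apply(abs(outer(u[bad], up, `-`)), 1, which.min)
        for (k in seq_along(surface$pole_info)) {
          sel <- bad[near == k]
          if (!length(sel)) next
          pi_k <- surface$pole_info[[k]]
          ps <- pole_sphere_step(e$r[sel, , drop = FALSE],
                                 w3[sel, , drop = FALSE],
                                 pi_k$center, pi_k$R, L)
          uv <- pi_k$invert(ps$x)
          un[sel] <- uv$u; vn[sel] <- uv$v
          head3[sel, ] <- ps$head
          ell[sel] <- sqrt((uv$u - u[sel])^2 + (uv$v - v[sel])^2)
        }
      }
    }
  }
  list(u = un, v = vn, head = head3, theta = theta, ell = ell)
}
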