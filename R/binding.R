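## Mechanics of filament-membrane binding: elastic energy of an intrinsically
## curved rod, Helfrich membrane energy, and the free-energy landscape over
## the binding angle obtained by coupling the rod to a Monge-gauge membrane
## patch through the biharmonic shape equation.

kBT_J <- 4.141947e-21   # J at 300 K
ATM_Pa <- 101325

#' Filament mechanical properties
#'
#' @param rf cross-sectional radius (nm).
#' @param Y Young's modulus (Pa).
#' @param kappa_s intrinsic curvature (um^-1); the filament's relaxed state.
#' @param Lf filament length (nm).
#' @return A `filament_properties` object. Internally lengths are um and
#'   energies kBT (300 K); the bending rigidity B = pi Y rf^4 / 4 is derived
#'   (kBT um).
#' @export
filament_properties <- function(rf = 3.5, Y = 2e9, kappa_s = 5, Lf = 250) {
  stopifnot(rf > 0, Y > 0, kappa_s > 0, Lf > 0)
  rf_um <- rf * 1e-3
  Y_int <- Y / kBT_J * 1e-18           # kBT per um^3
  B <- pi * Y_int * rf_um^4 / 4        # kBT um
  structure(list(rf = rf_um, Y = Y_int, kappa_s = kappa_s, Lf = Lf * 1e-3,
                 B = B), class = "filament_properties")
}

#' Membrane mechanical properties
#'
#' Surface tension defaults to zero (lipids assumed freely recruited) and the
#' spontaneous curvature to zero.
#'
#' @param kb bending rigidity (kBT).
#' @param kt saddle-splay modulus (kBT).
#' @param Hs spontaneous curvature (um^-1).
#' @param gamma surface tension (kBT / um^2).
#' @param p pressure difference across the membrane (atm).
#' @return A `membrane_properties` object (pressure stored in kBT / um^3).
#' @export
membrane_properties <- function(kb = 20, kt = -10, Hs = 0, gamma = 0,
                                p = 20) {
  stopifnot(kb > 0)
  structure(list(kb = kb, kt = kt, Hs = Hs, gamma = gamma,
                 p = p * ATM_Pa / kBT_J * 1e-18, p_atm = p),
            class = "membrane_properties")
}

#' Elastic bending energy of a filament
#'
#' E = (pi Y rf^4 / 8) integral (kappa - kappa_s)^2 dl over the filament
#' length, for a given deformed-curvature profile.
#'
#' @param filament a [filament_properties()].
#' @param kappa deformed curvature (um^-1): a scalar (uniform) or a function
#'   of arclength on [0, Lf].
#' @return Energy in kBT (non-negative).
#' @export
filament_bending_energy <- function(filament, kappa) {
  B2 <- filament$B / 2
  if (is.function(kappa)) {
    B2 * stats::integrate(function(l) (kappa(l) - filament$kappa_s)^2,
                          0, filament$Lf)$value
  } else {
    B2 * (kappa - filament$kappa_s)^2 * filament$Lf
  }
}

#' Helfrich free energy
#'
#' Curvature-elastic free energy of a membrane patch. Two input forms are
#' supported: a closed/parametric surface (curvatures integrated with metric
#' quadrature, enclosed volume by the divergence theorem), or a Monge-gauge
#' [solve_shape_equation()] field, for which the small-gradient form
#' kb/2 integral (Delta h - Hs)^2 dA + gamma A - p integral h dA is used (the
#' saddle-splay term is a topological boundary constant at this order and is
#' omitted there).
#'
#' @param membrane a [membrane_properties()].
#' @param field a `parametric_surface` or a `deformation_field`.
#' @param n_u,n_v quadrature resolution (surface input).
#' @return Energy in kBT.
#' @export
helfrich_energy <- function(membrane, field, n_u = 192, n_v = 96) {
  if (inherits(field, "deformation_field")) {
    A <- sum(field$asm$area)
    bend <- membrane$kb / 2 *
      as.numeric(Matrix::crossprod(field$m - membrane$Hs,
                                   field$asm$M %*% (field$m - membrane$Hs)))
    return(bend + membrane$gamma * A - membrane$p * fem_volume_integral(field))
  }
  stopifnot(inherits(field, "parametric_surface"))
  g <- surface_grid(field, n_u, n_v)
  cb <- curvature_batch(field, g$U, g$V)
  dens <- membrane$kb / 2 * (2 * cb$H - membrane$Hs)^2 +
          membrane$kt / 2 * cb$K + membrane$gamma
  E <- sum(matrix(dens, nrow = g$n_u) * g$dA)
  if (field$closed && membrane$p != 0) {
    nout <- -field$nsign * vcross(cb$ru, cb$rv) / cb$sqrtg
    vol <- sum(matrix(rowSums(cb$xyz * nout) / 3, nrow = g$n_u) * g$dA)
    E <- E - membrane$p * vol
  }
  E
}

## Membrane response to a filament footprint: solve the homogeneous
## biharmonic problem with unit curvature mismatch imposed along a straight
## footprint of length Lf at the patch center, far field h = m = 0. Returns
## the elastic constant a_el (kBT um^2) and displaced-volume constant
## v_disp (um^4) such that for mismatch delta (um^-1):
##   E_mem(delta) = a_el delta^2 + p v_disp delta.
## Cached per (Lf, kb, patch settings) within a session.
.membrane_response_cache <- new.env(parent = emptyenv())

membrane_response <- function(membrane, Lf, half_width_factor = 2.5,
                              n_mesh = 61) {
  key <- paste(signif(Lf, 8), signif(membrane$kb, 8), half_width_factor,
               n_mesh, sep = "|")
  hit <- .membrane_response_cache[[key]]
  if (!is.null(hit)) return(hit)
  W <- half_width_factor * Lf
  n_mesh <- as.integer(n_mesh)
  if (n_mesh %% 2L == 0L) n_mesh <- n_mesh + 1L  # keep the y = 0 node row
  mesh <- fem_rect_mesh(c(-W, W), c(-W, W), n_mesh, n_mesh)
  on_axis <- abs(mesh$nodes[, 2]) < 1e-12
  foot <- which(on_axis & abs(mesh$nodes[, 1]) <= Lf / 2 + 1e-12)
  ## unit mismatch delta = 1: inward parabolic height profile along the
  ## footprint (zero at the tips), longitudinal curvature -1 imposed on m
  xf <- mesh$nodes[foot, 1]
  hf <- ((Lf / 2)^2 - xf^2) / 2
  fld <- solve_shape_equation(
    mesh, load = 0,
    m_bc = list(nodes = c(mesh$boundary, foot),
                values = c(rep(0, length(mesh$boundary)), rep(-1, length(foot)))),
    h_bc = list(nodes = c(mesh$boundary, foot),
                values = c(rep(0, length(mesh$boundary)), hf)))
  out <- list(a_el = membrane$kb / 2 * fem_bending_integral(fld),
              v_disp = fem_volume_integral(fld), field = fld)
  .membrane_response_cache[[key]] <- out
  out
}

#' Free-energy change of filament binding at a given angle
#'
#' For a filament bound at angle `theta` from the long axis of a cylindrical
#' membrane of radius `Rcell`, the substrate's normal curvature along the
#' filament is sin(theta)^2 / Rcell (Euler's formula). The filament's deformed
#' curvature kappa is optimized: bending the filament costs
#' (pi Y rf^4/8)(kappa - kappa_s)^2 Lf while any excess curvature
#' delta = kappa - c_n(theta) >= 0 must be accommodated by an inward membrane
#' deformation, whose elastic cost comes from the biharmonic shape equation on
#' a Monge patch and whose displaced volume does work p * integral h dA
#' against the turgor pressure. Both membrane terms are exactly quadratic /
#' linear in delta, so the optimal kappa is closed-form given the patch
#' response. Energies are relative to the unbound (relaxed filament, flat
#' reference membrane) state; a theta-independent adhesion offset per unit
#' length may be added.
#'
#' @param filament a [filament_properties()].
#' @param membrane a [membrane_properties()].
#' @param Rcell cylinder radius (um); `Inf` means a flat membrane.
#' @param theta binding angle(s) from the cylinder axis (rad).
#' @param adhesion adhesion free energy per unit length (kBT/um, negative
#'   favors binding); a constant offset.
#' @param half_width_factor patch half-width in units of Lf.
#' @param n_mesh patch mesh nodes per side.
#' @return A data.frame with columns `theta`, `deltaG` (kBT), `E_filament`,
#'   `E_membrane`, `kappa_star`.
#' @export
binding_free_energy <- function(filament, membrane, Rcell, theta,
                                adhesion = 0, half_width_factor = 2.5,
                                n_mesh = 61) {
  stopifnot(Rcell > 0)
  resp <- membrane_response(membrane, filament$Lf, half_width_factor, n_mesh)
  c_n <- if (is.infinite(Rcell)) rep(0, length(theta)) else
    sin(theta)^2 / Rcell
  BLf <- filament$B * filament$Lf
  a <- resp$a_el
  b <- membrane$p * resp$v_disp
  kappa_hat <- (BLf * filament$kappa_s + 2 * a * c_n - b) / (BLf + 2 * a)
  kappa_star <- pmax(kappa_hat, c_n)   # membrane deforms inward only
  delta <- kappa_star - c_n
  E_fil <- (filament$B / 2) * (kappa_star - filament$kappa_s)^2 * filament$Lf
  E_mem <- a * delta^2 + b * delta
  data.frame(theta = theta,
             deltaG = E_fil + E_mem + adhesion * filament$Lf,
             E_filament = E_fil, E_membrane = E_mem,
             kappa_star = kappa_star)
}

#' Scan the binding free energy over angle and locate the preferred angle
#'
#' @inheritParams binding_free_energy
#' @param n_theta grid size on [0, pi/2].
#' @return A `binding_scan` object: the energy table, the minimizing angle
#'   `theta_star`, the well depth deltaG(0) - deltaG(theta_star) (kBT), a
#'   `robust` flag (well depth exceeds 1 kBT, the thermal-fluctuation scale),
#'   and the binding `phase` label.
#' @export
binding_scan <- function(filament, membrane, Rcell, n_theta = 46,
                         adhesion = 0, half_width_factor = 2.5,
                         n_mesh = 61) {
  theta <- seq(0, pi / 2, length.out = n_theta)
  tab <- binding_free_energy(filament, membrane, Rcell, theta, adhesion,
                             half_width_factor, n_mesh)
  i <- which.min(tab$deltaG)
  depth <- tab$deltaG[1] - tab$deltaG[i]
  flat <- diff(range(tab$deltaG)) < 1e-9
  structure(list(table = tab, theta_star = if (flat) NA_real_ else theta[i],
                 well_depth = depth, robust = depth > 1, flat = flat,
                 Rcell = Rcell, phase = binding_phase(filament, membrane,
                                                      Rcell)),
            class = "binding_scan")
}

#' Preferred binding angle and well depth
#'
#' Convenience wrapper around [binding_scan()] returning the minimizing angle
#' theta* on [0, pi/2], the well depth in kBT and whether the orientation is
#' robust to thermal fluctuations (well depth > 1 kBT). On an umbilic
#' substrate (flat membrane / sphere-like, where the energy is
#' theta-independent) `theta_star` is NA.
#'
#' @inheritParams binding_scan
#' @return List with `theta_star`, `well_depth`, `robust`.
#' @export
preferred_angle <- function(filament, membrane, Rcell, n_theta = 91, ...) {
  sc <- binding_scan(filament, membrane, Rcell, n_theta = n_theta, ...)
  list(theta_star = sc$theta_star, well_depth = sc$well_depth,
       robust = sc$robust)
}

#' Classify the binding regime
#'
#' At the energy minimum (circumferential binding), the total elastic energy
#' is split between filament bending and membrane deformation. The regime is
#' `filament_bends` when the filament stores more than `threshold` of the
#' elastic energy, `membrane_bends` when the membrane does, and `both`
#' otherwise.
#'
#' @inheritParams binding_free_energy
#' @param threshold dominance fraction (default 0.8).
#' @return One of "filament_bends", "membrane_bends", "both".
#' @export
binding_phase <- function(filament, membrane, Rcell = 0.5, threshold = 0.8,
                          ...) {
  tab <- binding_free_energy(filament, membrane, Rcell, pi / 2, ...)
  tot <- tab$E_filament + tab$E_membrane
  if (tot <= 0) return("filament_bends")   # fully conforming, no cost
  frac <- tab$E_filament / tot
  if (frac >= threshold) "filament_bends"
  else if (frac <= 1 - threshold) "membrane_bends"
  else "both"
}

#' @export
print.binding_scan <- function(x, ...) {
  cat("Filament-membrane binding scan (Rcell =", x$Rcell, "um)\n")
  if (x$flat) {
    cat("  deltaG is angle-independent (umbilic/flat substrate)\n")
  } else {
    cat(sprintf("  preferred angle theta* = %.3f rad (%.1f deg)\n",
                x$theta_star, x$theta_star * 180 / pi))
    cat(sprintf("  well depth deltaG(0) - deltaG(theta*) = %.2f kBT%s\n",
                x$well_depth,
                if (x$robust) " (robust to thermal fluctuations)" else ""))
  }
  cat("  binding phase:", x$phase, "\n")
  invisible(x)
}

#' @export
plot.binding_scan <- function(x, ...) {
  graphics::plot(x$table$theta, x$table$deltaG, type = "l",
                 xlab = expression(theta ~ "(rad)"),
                 ylab = expression(Delta * G ~ "(kBT)"),
                 main = "Binding free energy vs angle", ...)
  if (!x$flat)
    graphics::abline(v = x$theta_star, lty = 2, col = "grey40")
  invisible(x)
}
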