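## Continuum (Fokker-Planck) steady state of the translocation dynamics.
## The discrete flow is a jump process in parameter coordinates; its
## Kramers-Moyal expansion gives, for the filament number density n(u, v)
## per unit *parameter* area,
##   dn/dt = -d_a(A^a n) + 1/2 d_a d_b(B^ab n) + k sqrt(g) - lambda n,
## where A is the first and B the (full) second jump moment per step. The
## Ito (moment) form matters: position-dependent step statistics produce the
## retention flux -1/2 d(B n) that concentrates filaments where angular
## spreading is slow (e.g. cylindrical bulks vs umbilic poles), which the
## Langevin simulation exhibits and a naive Fickian -D grad(rho) law misses.
## The equation is discretized as a conservative finite-volume scheme with
## upwinded advection; the concentration is C_F = n / sqrt(g).

#' Concentration field container
#'
#' Holds filament number N_F per grid cell and concentration C_F = N_F / dA
#' (filaments per um^2) on a structured surface grid, with area weights and a
#' normalization record. Produced by [simulate_ensemble()] (Langevin counts)
#' and [solve_steady_state()] (continuum solution).
#'
#' @param surface a parametric surface.
#' @param grid a [surface_grid()].
#' @param values occupancy counts or densities (n_u x n_v matrix, or vector).
#' @param params a [translocation_params()] (normalization: total filament
#'   number k A / lambda for lambda > 0, else 1).
#' @param source `"langevin"` or `"fokker_planck"`.
#' @param values_are_density if TRUE `values` is already C_F-shaped (density);
#'   otherwise it is occupancy counts.
#' @return A `concentration_field` with elements `grid`, `NF`, `CF`, `dA`,
#'   `total` and `source`.
#' @export
concentration_field <- function(surface, grid, values, params,
                                source = c("langevin", "fokker_planck"),
                                values_are_density = FALSE) {
  source <- match.arg(source)
  vals <- matrix(values, grid$n_u, grid$n_v)
  NF <- if (values_are_density) vals * grid$dA else vals
  total <- if (params$lambda > 0)
    params$k * sum(grid$dA) / params$lambda else 1
  s <- sum(NF)
  if (s <= 0) stop("empty occupancy; cannot normalize")
  NF <- NF * (total / s)
  structure(list(grid = grid, NF = NF, CF = NF / grid$dA, dA = grid$dA,
                 total = total, source = source,
                 surface_kind = surface$kind, params = params),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("Concentration field (%s) on %s grid %d x %d\n", x$source,
              x$surface_kind, x$grid$n_u, x$grid$n_v))
  cat(sprintf("  total filaments: %.6g; C_F range [%.4g, %.4g] /um^2\n",
              sum(x$NF), min(x$CF), max(x$CF)))
  invisible(x)
}

#' @export
plot.concentration_field <- function(x, ...) {
  graphics::image(x$grid$u, x$grid$v, x$CF, xlab = "u", ylab = "v",
                  main = sprintf("C_F (%s, %s)", x$surface_kind, x$source),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Jump moments of the continuum translocation limit
#'
#' Per-step first and second jump moments of the discrete flow, in parameter
#' coordinates. The drift is c = L E[cos eta] = L exp(-sigma^2/2) along the
#' largest principal direction; the second moment splits into a longitudinal
#' part L^2 E[cos^2 eta] and a transverse part L^2 E[sin^2 eta] about that
#' direction. As sigma grows toward the umbilic cap these approach the
#' isotropic uniform-angle limit (drift 0, second moment L^2/2 times the
#' inverse metric), so umbilic cells are handled continuously.
#'
#' @param surface a parametric surface.
#' @param params a [translocation_params()].
#' @param grid a [surface_grid()] (cell centers used).
#' @param u,v alternatively, explicit evaluation points.
#' @return A list of per-point fields: `Au`, `Av` (parameter-space drift
#'   components), `speed`, `B_par`, `B_perp` (second moments, um^2/step),
#'   `D_par`, `D_perp` (central diffusivities), `sigma`, `umbilic`, the
#'   parameter components `w` (drift direction) and `q` (transverse), and
#'   `sqrtg`.
#' @export
drift_diffusion_fields <- function(surface, params, grid = NULL,
                                   u = grid$U, v = grid$V) {
  cb <- curvature_batch(surface, u, v)
  sig <- noise_sigma(params, cb$dc)
  sig[cb$umbilic] <- params$sigma_max
  es <- exp(-sig^2 / 2)
  e2s <- exp(-2 * sig^2)
  speed <- params$L * es
  speed[cb$umbilic] <- 0
  Ec2 <- (1 + e2s) / 2           # E[cos^2 eta]
  Es2 <- (1 - e2s) / 2           # E[sin^2 eta]
  Ec2[cb$umbilic] <- 0.5; Es2[cb$umbilic] <- 0.5
  B_par <- params$L^2 * Ec2
  B_perp <- params$L^2 * Es2
  D_par <- (B_par - speed^2) / 2
  D_perp <- B_perp / 2
  det <- cb$E * cb$G - cb$F^2
  comp <- function(d3) {
    a <- rowSums(d3 * cb$ru); b <- rowSums(d3 * cb$rv)
    cbind((cb$G * a - cb$F * b) / det, (cb$E * b - cb$F * a) / det)
  }
  w <- cb$d1p
  q <- comp(cb$d2)
  list(Au = speed * w[, 1], Av = speed * w[, 2], speed = speed,
       B_par = B_par, B_perp = B_perp, D_par = D_par, D_perp = D_perp,
       sigma = sig, umbilic = cb$umbilic, w = w, q = q, sqrtg = cb$sqrtg)
}

## Orient the principal-direction field consistently across the grid so the
## two chirality populations are well defined: prefer positive circumferential
## (v) component, falling back to positive u component near the axis-switch.
orient_field <- function(w) {
  s <- ifelse(abs(w[, 2]) > 1e-12, sign(w[, 2]), sign(w[, 1]))
  s[s == 0] <- 1
  w * s
}

## Exact per-cell jump moments of the discrete flow, by quadrature over the
## angular noise using the same step kernel as the Langevin simulator:
## A^a = E[dx^a], B^ab = E[dx^a dx^b] per step, in parameter coordinates.
## `sgn` selects the chirality population (heading along +/- the oriented
## largest-principal-direction field). These moments include the metric-
## induced drift of the parameter chart and the pole/umbilic safeguards,
## which closed-form small-step formulas miss.
jump_moments <- function(surface, params, u, v, sgn = 1, n_gauss = 33L,
                         n_umb = 32L) {
  n <- length(u)
  cb <- curvature_batch(surface, u, v)
  sig <- pmin(noise_sigma(params, cb$dc), params$sigma_max)
  so <- ifelse(abs(cb$d1p[, 2]) > 1e-12, sign(cb$d1p[, 2]),
               sign(cb$d1p[, 1]))
  so[so == 0] <- 1
  d3 <- (sgn * so) * cb$d1
  tp3 <- vcross(cb$n_in, d3)
  span_u <- surface$domain[2] - surface$domain[1]
  span_v <- surface$domain[4] - surface$domain[3]
  Au <- Av <- Buu <- Buv <- Bvv <- numeric(n)
  accumulate <- function(idx, w3rep, wgt, curv_rep) {
    m <- length(idx); nq <- length(wgt)
    U <- rep(u[idx], times = nq); V <- rep(v[idx], times = nq)
    adv <- advance_points(surface, U, V, w3rep, params$L, curv = curv_rep,
                          pole_zone = params$pole_zone)
    du <- adv$u - U; dv2 <- adv$v - V
    if (surface$periodic[1]) du <- du - span_u * round(du / span_u)
    dv2 <- dv2 - span_v * round(dv2 / span_v)
    du <- matrix(du, m, nq); dv2 <- matrix(dv2, m, nq)
    Au[idx] <<- drop(du %*% wgt)
    Av[idx] <<- drop(dv2 %*% wgt)
    Buu[idx] <<- drop((du * du) %*% wgt)
    Buv[idx] <<- drop((du * dv2) %*% wgt)
    Bvv[idx] <<- drop((dv2 * dv2) %*% wgt)
  }
  idx <- which(!cb$umbilic)
  if (length(idx)) {
    z <- seq(-4, 4, length.out = n_gauss)
    wz <- exp(-z^2 / 2); wz <- wz / sum(wz)
    eta <- as.vector(outer(sig[idx], z))
    rep_i <- rep(idx, times = n_gauss)
    w3 <- cos(eta) * d3[rep_i, , drop = FALSE] +
          sin(eta) * tp3[rep_i, , drop = FALSE]
    accumulate(idx, w3, wz, NULL)
  }
  idx <- which(cb$umbilic)
  if (length(idx)) {
    phi <- 2 * pi * (seq_len(n_umb) - 0.5) / n_umb
    wp <- rep(1 / n_umb, n_umb)
    e1 <- cb$ru[idx, , drop = FALSE] / sqrt(cb$E[idx])
    e2r <- cb$rv[idx, , drop = FALSE] -
      (cb$F[idx] / cb$E[idx]) * cb$ru[idx, , drop = FALSE]
    e2 <- e2r / vnorm(e2r)
    rep_i <- rep(seq_along(idx), times = n_umb)
    phir <- rep(phi, each = length(idx))
    w3 <- cos(phir) * e1[rep_i, , drop = FALSE] +
          sin(phir) * e2[rep_i, , drop = FALSE]
    nq <- n_umb
    curv_rep <- list(umbilic = rep(TRUE, length(idx) * nq),
                     k1 = rep(cb$k1[idx], times = nq),
                     n_in = cb$n_in[rep(idx, times = nq), , drop = FALSE])
    accumulate(idx, w3, wp, curv_rep)
  }
  list(Au = Au, Av = Av, Buu = Buu, Buv = Buv, Bvv = Bvv,
       sqrtg = cb$sqrtg, umbilic = cb$umbilic)
}

#' Solve the steady-state Fokker-Planck equation for C_F
#'
#' Conservative finite-volume discretization of the Kramers-Moyal limit of
#' the translocation flow (see [drift_diffusion_fields()]): upwinded
#' advection along the oriented largest-principal-direction field plus the
#' Ito second-moment flux -1/2 d_b(B^ab n), with uniform-per-area source k
#' and sink lambda. The two chirality populations (drift along +d and -d)
#' are solved separately with half the source each and summed. For lambda = 0
#' (infinite processivity) the stationary transport density is computed as
#' the vanishing-turnover limit (a uniform birth rate with mean lifetime far
#' exceeding the mixing time) and renormalized to unit total.
#'
#' @param surface a parametric surface.
#' @param params a [translocation_params()].
#' @param n_u,n_v grid resolution (defaults from the surface spec).
#' @return A `concentration_field` (source `"fokker_planck"`) with attribute
#'   `residual` recording the relative discrete mass-balance defect.
#' @export
solve_steady_state <- function(surface, params, n_u = NULL, n_v = NULL) {
  g <- surface_grid(surface, n_u, n_v)
  nu <- g$n_u; nv <- g$n_v; N <- nu * nv
  idx <- function(i, j) (j - 1L) * nu + i
  dAvec <- as.vector(g$dA)
  dupar <- rep(g$du, times = nv)
  dv <- g$dv[1]
  cellpar <- dupar * dv

  per_u <- surface$periodic[1]; per_v <- surface$periodic[2]
  ip <- function(i) ifelse(i == nu, 1L, i + 1L)
  jp <- function(j) ifelse(j == nv, 1L, j + 1L)
  jm <- function(j) ifelse(j == 1L, nv, j - 1L)

  iu <- if (per_u) seq_len(nu) else seq_len(nu - 1L)
  FU <- expand.grid(i = iu, j = seq_len(nv))
  du_face <- g$u[ip(FU$i)] - g$u[FU$i]
  if (per_u && any(FU$i == nu))
    du_face[FU$i == nu] <- (g$u_edges[nu + 1L] - g$u[nu]) +
      (g$u[1L] - g$u_edges[1L])
  jv <- if (per_v) seq_len(nv) else seq_len(nv - 1L)
  FV <- expand.grid(i = seq_len(nu), j = jv)

  trips <- NULL; nt <- 0L
  add <- function(r, c, x) {
    nt <<- nt + 1L
    trips[[nt]] <<- cbind(r, c, x)
  }

  assemble <- function(mom) {
    trips <<- vector("list", 64); nt <<- 0L
    Au <- mom$Au; Av <- mom$Av
    Buu <- mom$Buu; Buv <- mom$Buv; Bvv <- mom$Bvv
    ## ---- u-faces ----
    P <- idx(FU$i, FU$j); Q <- idx(ip(FU$i), FU$j)
    Vn <- 0.5 * (Au[P] + Au[Q]) * dv
    ap <- pmax(Vn, 0); aq <- pmin(Vn, 0)
    add(P, P, -ap); add(P, Q, -aq); add(Q, P, ap); add(Q, Q, aq)
    cP <- dv * Buu[P] / (2 * du_face); cQ <- dv * Buu[Q] / (2 * du_face)
    add(P, P, -cP); add(P, Q, cQ); add(Q, P, cP); add(Q, Q, -cQ)
    jp_ok <- per_v | (FU$j < nv); jm_ok <- per_v | (FU$j > 1L)
    ok <- which(jp_ok & jm_ok)
    if (length(ok)) {
      for (s2 in list(FU$i, ip(FU$i))) {
        PJ <- idx(s2, jp(FU$j)); MJ <- idx(s2, jm(FU$j))
        cpj <- Buv[PJ] / 8; cmj <- Buv[MJ] / 8
        add(P[ok], PJ[ok], cpj[ok]); add(P[ok], MJ[ok], -cmj[ok])
        add(Q[ok], PJ[ok], -cpj[ok]); add(Q[ok], MJ[ok], cmj[ok])
      }
    }
    ## ---- v-faces ----
    P <- idx(FV$i, FV$j); Q <- idx(FV$i, jp(FV$j))
    duP <- dupar[P]
    Vn <- 0.5 * (Av[P] + Av[Q]) * duP
    ap <- pmax(Vn, 0); aq <- pmin(Vn, 0)
    add(P, P, -ap); add(P, Q, -aq); add(Q, P, ap); add(Q, Q, aq)
    cP <- duP * Bvv[P] / (2 * dv); cQ <- duP * Bvv[Q] / (2 * dv)
    add(P, P, -cP); add(P, Q, cQ); add(Q, P, cP); add(Q, Q, -cQ)
    ip_ok <- per_u | (FV$i < nu); im_ok2 <- per_u | (FV$i > 1L)
    ok <- which(ip_ok & im_ok2)
    if (length(ok)) {
      imv <- ifelse(FV$i == 1L, nu, FV$i - 1L)
      du2 <- g$u[ip(FV$i)] - g$u[imv]
      if (per_u) {
        span_lo <- g$u[1L] - g$u_edges[1L]
        span_hi <- g$u_edges[nu + 1L] - g$u[nu]
        du2[FV$i == 1L] <- g$u[2L] - g$u[1L] + span_lo + span_hi
        du2[FV$i == nu] <- g$u[nu] - g$u[nu - 1L] + span_lo + span_hi
      }
      for (s2 in list(FV$j, jp(FV$j))) {
        PI <- idx(ip(FV$i), s2); MI <- idx(imv, s2)
        cpi <- duP * Buv[PI] / (4 * du2); cmi <- duP * Buv[MI] / (4 * du2)
        add(P[ok], PI[ok], cpi[ok]); add(P[ok], MI[ok], -cmi[ok])
        add(Q[ok], PI[ok], -cpi[ok]); add(Q[ok], MI[ok], cmi[ok])
      }
    }
    tr <- do.call(rbind, trips[seq_len(nt)])
    Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                         dims = c(N, N))
  }

  solve_one <- function(sgn) {
    mom <- jump_moments(surface, params, g$U, g$V, sgn = sgn)
    M <- assemble(mom)
    ## lambda = 0: vanishing-turnover limit (uniform birth, mean lifetime
    ## 1/eps far above the mixing time), one direct solve, positive.
    lam <- if (params$lambda > 0) params$lambda else 1e-4
    A <- M - Matrix::Diagonal(N, lam * cellpar)
    as.numeric(Matrix::solve(A, -(params$k / 2) * dAvec))
  }
  n_dens <- solve_one(+1) + solve_one(-1)      # per parameter area
  resid <- if (params$lambda > 0)
    abs(params$k * sum(dAvec) - params$lambda * sum(n_dens * cellpar)) /
      (params$k * sum(dAvec)) else NA_real_
  rho <- n_dens * cellpar / dAvec              # C_F = n / sqrt(g)
  out <- concentration_field(surface, g, matrix(rho, nu, nv), params,
                             source = "fokker_planck",
                             values_are_density = TRUE)
  attr(out, "residual") <- resid
  out
}
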