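## Stochastic translocation of membrane-bound filaments along directions of
## largest principal curvature: the discrete-time flow
##   X_{n+1} = X_n + chi_n l_n (cos theta_n, sin theta_n)
## in surface coordinates, with the heading obtained by rotating the largest
## principal direction by a Gaussian angular deviation eta, and the
## parameter-space step size l_n solving the arclength equation that fixes a
## constant step size L on the surface.

#' Translocation parameters
#'
#' @param L step size on the surface (um). Default 0.2 um (200 nm).
#' @param noise_model `"curvature_dependent"`: sigma = alpha / dc where dc is
#'   the local principal-curvature difference (the empirically supported
#'   dependence); or `"constant"`: sigma = sigma0.
#' @param sigma0 constant translocation noise (rad).
#' @param alpha noise-curvature coupling (rad um^-1).
#' @param sigma_max cap on sigma near umbilics (rad); at this value the
#'   angular distribution is effectively isotropic. Exactly umbilic points use
#'   uniformly random step angles.
#' @param k activation rate (filaments per timestep per um^2 of membrane).
#' @param lambda deactivation probability per step; mean processivity is
#'   1/lambda steps. `0` means infinite processivity.
#' @param chirality `"fixed_sign"`: each filament keeps its randomly drawn
#'   handedness for its whole lifetime (no backtracking); `"random_per_step"`:
#'   the sign is redrawn every step.
#' @param activation_model `"uniform_area"` activates with probability
#'   proportional to the area element; `"gaussian_curvature_weighted"`
#'   multiplies that density by `activation_weight(K)`.
#' @param activation_weight non-negative weight function of the Gaussian
#'   curvature (um^-2), used by the curvature-weighted activation model.
#' @param pole_zone radius of the pole safeguard zone, in units of the step
#'   size: oblique steps launched where the angular-coordinate circle is
#'   shorter than `pole_zone * L` (i.e. within about a step of a coordinate
#'   pole, where a straight parameter ray wraps around the pole) are taken
#'   instead as great-circle arcs on the nearest pole's (osculating) sphere.
#' @param seed default random seed for simulations using these parameters.
#' @return A `translocation_params` object.
#' @details The MreB-like defaults are L = 200 nm, alpha = 0.6 rad um^-1 (so
#'   sigma = 0.3 rad on a 0.5 um radius cylinder, where dc = 2 um^-1), and
#'   lambda = 1/30 per step, mapping the ~5 min persistence time at a 20 nm/s
#'   translocation speed (the E. coli MreB value) onto a mean lifetime of 30 steps.
#' @export
translocation_params <- function(L = 0.2,
                                 noise_model = c("curvature_dependent",
                                                 "constant"),
                                 sigma0 = 0.3, alpha = 0.6, sigma_max = pi,
                                 k = 1, lambda = 1 / 30,
                                 chirality = c("fixed_sign",
                                               "random_per_step"),
                                 activation_model = c("uniform_area",
                                     "gaussian_curvature_weighted"),
                                 activation_weight = NULL, pole_zone = 0.75,
                                 seed = 1L) {
  stopifnot(L > 0, sigma0 >= 0, alpha >= 0, sigma_max > 0, k >= 0,
            lambda >= 0, lambda <= 1, pole_zone >= 0)
  structure(list(L = L, noise_model = match.arg(noise_model),
                 sigma0 = sigma0, alpha = alpha, sigma_max = sigma_max,
                 k = k, lambda = lambda, chirality = match.arg(chirality),
                 pole_zone = pole_zone,
                 activation_model = match.arg(activation_model),
                 activation_weight = activation_weight,
                 seed = as.integer(seed)),
            class = "translocation_params")
}

#' @export
print.translocation_params <- function(x, ...) {
  cat("Translocation parameters:\n")
  cat(sprintf("  step size L = %g um; noise: %s (%s)\n", x$L, x$noise_model,
              if (x$noise_model == "constant") paste0("sigma0 = ", x$sigma0)
              else paste0("alpha = ", x$alpha, " rad/um")))
  cat(sprintf("  activation k = %g /um^2/step; deactivation lambda = %g /step",
              x$k, x$lambda))
  if (x$lambda > 0) cat(sprintf(" (processivity %.4g steps)", 1 / x$lambda))
  cat("\n  chirality:", x$chirality, "; activation:", x$activation_model,
      "\n")
  invisible(x)
}

#' Translocation noise at given curvature
#'
#' Constant model: sigma0. Curvature-dependent model: alpha / dc, capped at
#' `sigma_max` (the angular distribution becomes effectively isotropic near
#' umbilics, where the uniform-angle rule takes over at exact umbilics).
#'
#' @param params a [translocation_params()].
#' @param curv a [curvature_at()] result, or a numeric vector of
#'   principal-curvature differences dc (um^-1).
#' @return sigma in rad (vectorized).
#' @export
noise_sigma <- function(params, curv) {
  dc <- if (is.list(curv)) curv$dc else curv
  if (params$noise_model == "constant") rep(params$sigma0, length(dc))
  else pmin(params$alpha / pmax(dc, 1e-300), params$sigma_max)
}

#' Parameter-space step length for a fixed on-surface step size
#'
#' Solves the arclength equation: find l such that the curve
#' t -> r(u + t cos(theta), v + t sin(theta)), t in [0, l], has length L on
#' the surface. Solved by fixed-point iteration on l with Gauss-Legendre
#' quadrature of the speed along the parameter ray.
#'
#' @param surface a parametric surface.
#' @param u,v starting point.
#' @param theta heading angle from the u-axis (rad).
#' @param L step size on the surface (um).
#' @param iters fixed-point iterations.
#' @return l (parameter units), vectorized over inputs.
#' @export
step_length_in_parameters <- function(surface, u, v, theta, L, iters = 3L) {
  n <- max(length(u), length(v), length(theta))
  u <- rep_len(u, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
  ct <- cos(theta); st <- sin(theta)
  speed <- function(t) {            # |r_theta| at points u + t ct, v + t st
    e <- sg_eval(surface, u + t * ct, v + t * st, wrap = FALSE)
    d <- ct * e$ru + st * e$rv
    vnorm(d)
  }
  ## 2-point Gauss-Legendre nodes on [0, 1]
  g1 <- 0.5 - 0.5 / sqrt(3); g2 <- 0.5 + 0.5 / sqrt(3)
  ell <- L / speed(rep(0, n))
  for (i in seq_len(iters)) {
    s <- ell * (speed(ell * g1) + speed(ell * g2)) / 2
    ell <- ell * L / s
  }
  ell
}

## Draw activation locations with density proportional to the area element
## (optionally weighted by a Gaussian-curvature function). Rejection sampling
## against a uniform envelope in the parameter rectangle.
sample_activation <- function(surface, params, n) {
  d <- surface$domain
  wfun <- function(U, V) {
    w <- area_element(surface, U, V)
    if (params$activation_model == "gaussian_curvature_weighted") {
      stopifnot(is.function(params$activation_weight))
      cb <- curvature_batch(surface, U, V)
      w <- w * params$activation_weight(cb$K)
    }
    w
  }
  gs <- surface_grid(surface, 160, 80)
  wmax <- max(wfun(gs$U, gs$V)) * 1.05
  U <- V <- numeric(0)
  while (length(U) < n) {
    m <- max(2L * (n - length(U)), 64L)
    uu <- stats::runif(m, d[1], d[2]); vv <- stats::runif(m, d[3], d[4])
    keep <- stats::runif(m) * wmax < wfun(uu, vv)
    U <- c(U, uu[keep]); V <- c(V, vv[keep])
  }
  list(u = U[seq_len(n)], v = V[seq_len(n)])
}

## One synchronous step for a batch of active filaments.
## st: list(u, v, head (n x 3 unit 3D), chi (+-1 per filament)).
## Returns updated state plus per-step diagnostics (theta, eta, ell).
step_batch <- function(surface, params, st) {
  n <- length(st$u)
  cb <- curvature_batch(surface, st$u, st$v)
  sig <- noise_sigma(params, cb$dc)
  umb <- cb$umbilic
  w <- matrix(0, n, 3)
  eta <- numeric(n)
  if (any(!umb)) {
    i <- which(!umb)
    d <- cb$d1[i, , drop = FALSE]
    ## orient the (sign-ambiguous) principal direction continuously with the
    ## previous heading; chirality is carried by the heading itself
    dp <- rowSums(d * st$head[i, , drop = FALSE])
    flip <- dp < 0
    d[flip, ] <- -d[flip, ]
    if (params$chirality == "random_per_step") {
      bk <- stats::runif(length(i)) < 0.5
      d[bk, ] <- -d[bk, ]
    }
    eta_i <- stats::rnorm(length(i), 0, pmin(sig[i], params$sigma_max))
    tperp <- vcross(cb$n_in[i, , drop = FALSE], d)
    w[i, ] <- cos(eta_i) * d + sin(eta_i) * tperp
    eta[i] <- eta_i
  }
  if (any(umb)) {
    i <- which(umb)
    phi <- stats::runif(length(i), 0, 2 * pi)
    e1 <- cb$ru[i, , drop = FALSE] / sqrt(cb$E[i])
    e2raw <- cb$rv[i, , drop = FALSE] - (cb$F[i] / cb$E[i]) *
      cb$ru[i, , drop = FALSE]
    e2 <- e2raw / vnorm(e2raw)
    w[i, ] <- cos(phi) * e1 + sin(phi) * e2
    eta[i] <- NA_real_
  }
  adv <- advance_points(surface, st$u, st$v, w, params$L, curv = cb,
                        pole_zone = params$pole_zone)
  p <- surface$wrap(adv$u, adv$v)
  list(u = p$u, v = p$v, head = adv$head, chi = st$chi,
       theta = adv$theta, eta = eta, ell = adv$ell)
}

#' Advance one filament by one translocation step
#'
#' Single-filament form of the discrete-time flow; see
#' [translocation_params()]. The filament heading is the largest principal
#' direction (sign-matched to the previous heading) rotated in the tangent
#' plane by a Gaussian angular deviation; at umbilic points the step angle is
#' uniformly random. The parameter-space displacement has on-surface length L.
#'
#' @param state list with `u`, `v`, `heading` (unit 3D vector; used for
#'   direction continuity), `active`, `n` (step counter).
#' @param surface a parametric surface.
#' @param params a [translocation_params()].
#' @return The updated state (with fields `theta`, `eta`, `ell` of the step
#'   taken).
#' @export
translocation_step <- function(state, surface, params) {
  stopifnot(isTRUE(state$active))
  st <- list(u = state$u, v = state$v,
             head = matrix(state$heading, 1, 3), chi = 1)
  out <- step_batch(surface, params, st)
  list(u = out$u, v = out$v, heading = drop(out$head), active = TRUE,
       n = (state$n %||% 0L) + 1L, theta = out$theta, eta = out$eta,
       ell = out$ell)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Draw lifetimes in steps (geometric, mean 1/lambda) honouring a cap.
draw_lifetimes <- function(n, lambda, max_steps) {
  if (lambda <= 0) return(rep(as.integer(max_steps), n))
  pmin(stats::rgeom(n, lambda) + 1L, as.integer(max_steps))
}
## max_steps = 0 is allowed and means zero processivity in the strict sense:
## filaments are activated and immediately deactivated without stepping.

#' Simulate a single filament trajectory
#'
#' Activates a filament (at `start`, or at a random location with probability
#' proportional to membrane area), translocates it until deactivation
#' (geometric lifetime, mean 1/lambda steps) or `max_steps`, and records the
#' trajectory.
#'
#' @param surface a parametric surface.
#' @param params a [translocation_params()].
#' @param start optional c(u, v) start point.
#' @param max_steps hard cap on steps (also the lifetime when lambda = 0).
#' @param seed random seed (defaults to `params$seed`).
#' @return A `trajectory`: data.frame with columns step, u, v, x, y, z,
#'   theta, eta, ell.
#' @export
simulate_filament <- function(surface, params, start = NULL,
                              max_steps = 10000L, seed = NULL) {
  set.seed(seed %||% params$seed)
  en <- simulate_ensemble(surface, params, n_filaments = 1L,
                          max_steps = max_steps, record_trajectories = TRUE,
                          seed = NULL, .no_seed = TRUE, start = start)
  en$trajectories[[1L]]
}

#' Simulate an ensemble of translocating filaments
#'
#' Runs the activation / translocation / deactivation dynamics for
#' `n_filaments` independent filament lifetimes (renewal sampling: with
#' activation uniform per unit area at rate k and deactivation rate lambda,
#' the accumulated occupancy of independent lifetimes is the steady state of
#' the birth-death process, with mean total filament number k A / lambda).
#' Occupancies are binned on a structured surface grid to give the filament
#' number N_F per cell and concentration C_F = N_F / dA.
#'
#' @param surface a parametric surface.
#' @param params a [translocation_params()].
#' @param n_filaments number of filament lifetimes.
#' @param n_u,n_v occupancy grid resolution (defaults from the surface).
#' @param max_steps cap on any single lifetime (the lifetime itself when
#'   lambda = 0, i.e. infinite processivity).
#' @param record_trajectories keep full per-filament trajectories (memory!).
#' @param chunk number of filaments advanced synchronously.
#' @param start optional fixed c(u, v) start for every filament.
#' @param seed random seed (defaults to `params$seed`).
#' @return An `ensemble_result` with the occupancy `field` (a
#'   `concentration_field`), `total_steps`, and optionally `trajectories`.
#' @export
simulate_ensemble <- function(surface, params, n_filaments = 1000L,
                              n_u = NULL, n_v = NULL, max_steps = 10000L,
                              record_trajectories = FALSE, chunk = 4000L,
                              start = NULL, seed = NULL, .no_seed = FALSE) {
  if (!.no_seed) set.seed(seed %||% params$seed)
  g <- surface_grid(surface, n_u, n_v)
  counts <- matrix(0, g$n_u, g$n_v)
  trajs <- if (record_trajectories) vector("list", n_filaments) else NULL
  total_steps <- 0L
  bin_index <- function(u, v) {
    iu <- pmin(pmax(findInterval(u, g$u_edges, rightmost.closed = TRUE), 1L),
               g$n_u)
    iv <- pmin(pmax(findInterval(v, g$v_edges, rightmost.closed = TRUE), 1L),
               g$n_v)
    (iv - 1L) * g$n_u + iu
  }
  done <- 0L
  while (done < n_filaments) {
    m <- min(chunk, n_filaments - done)
    ids <- done + seq_len(m)
    life <- draw_lifetimes(m, params$lambda, max_steps)
    if (is.null(start)) {
      s0 <- sample_activation(surface, params, m)
    } else {
      s0 <- list(u = rep(start[1], m), v = rep(start[2], m))
    }
    ## initial heading: random tangent direction; its sign is the filament's
    ## chirality draw (kept by direction continuity under fixed_sign)
    e <- sg_eval(surface, s0$u, s0$v)
    phi <- stats::runif(m, 0, 2 * pi)
    E <- rowSums(e$ru^2); FF <- rowSums(e$ru * e$rv); G <- rowSums(e$rv^2)
    e1 <- e$ru / sqrt(E)
    e2r <- e$rv - (FF / E) * e$ru
    head0 <- cos(phi) * e1 + sin(phi) * (e2r / vnorm(e2r))
    st <- list(u = s0$u, v = s0$v, head = head0, chi = rep(1L, m))
    alive <- which(life > 0L)   # zero-step lifetimes record only the birth
    counts_idx <- bin_index(st$u, st$v)
    counts_tab <- tabulate(counts_idx, nbins = g$n_u * g$n_v)
    counts <- counts + counts_tab
    if (record_trajectories) {
      rec <- lapply(seq_len(m), function(i) {
        nn <- life[i] + 1L
        r <- list(u = numeric(nn), v = numeric(nn), theta = rep(NA_real_, nn),
                  eta = rep(NA_real_, nn), ell = rep(NA_real_, nn))
        r$u[1L] <- st$u[i]; r$v[1L] <- st$v[i]
        r
      })
    }
    nstep <- 0L
    while (length(alive)) {
      nstep <- nstep + 1L
      sub <- list(u = st$u[alive], v = st$v[alive],
                  head = st$head[alive, , drop = FALSE],
                  chi = st$chi[alive])
      out <- step_batch(surface, params, sub)
      st$u[alive] <- out$u; st$v[alive] <- out$v
      st$head[alive, ] <- out$head
      total_steps <- total_steps + length(alive)
      counts <- counts + tabulate(bin_index(out$u, out$v),
                                  nbins = g$n_u * g$n_v)
      if (record_trajectories) {
        for (j in seq_along(alive)) {
          i <- alive[j]
          rec[[i]]$u[nstep + 1L] <- out$u[j]
          rec[[i]]$v[nstep + 1L] <- out$v[j]
          rec[[i]]$theta[nstep + 1L] <- out$theta[j]
          rec[[i]]$eta[nstep + 1L] <- out$eta[j]
          rec[[i]]$ell[nstep + 1L] <- out$ell[j]
        }
      }
      alive <- alive[life[alive] > nstep]
    }
    if (record_trajectories) {
      for (i in seq_len(m)) {
        tr <- rec[[i]]
        xyz <- sg_eval(surface, tr$u, tr$v)$r
        df <- data.frame(step = seq_along(tr$u) - 1L, u = tr$u, v = tr$v,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         theta = tr$theta, eta = tr$eta, ell = tr$ell)
        attr(df, "surface_kind") <- surface$kind
        class(df) <- c("trajectory", "data.frame")
        trajs[[ids[i]]] <- df
      }
    }
    done <- done + m
  }
  field <- concentration_field(surface, g, counts, params,
                               source = "langevin")
  structure(list(field = field, total_steps = total_steps,
                 n_filaments = n_filaments, params = params,
                 trajectories = trajs, seed = seed %||% params$seed),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("Langevin filament ensemble:", x$n_filaments, "lifetimes,",
      x$total_steps, "steps\n")
  print(x$field)
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Filament trajectory:", nrow(x) - 1L, "steps on",
      attr(x, "surface_kind") %||% "a surface", "\n")
  NextMethod()
}

#' @export
plot.trajectory <- function(x, ...) {
  graphics::plot(x$u, x$v, type = "l", xlab = "u", ylab = "v",
                 main = "Filament trajectory (parameter space)", ...)
  graphics::points(x$u[1], x$v[1], col = "blue", pch = 16)
  graphics::points(x$u[nrow(x)], x$v[nrow(x)], col = "red", pch = 16)
  invisible(x)
}
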