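## Summary statistics of filament localization: region enrichment ratios,
## bulge occupancy, curvature-enrichment curves and per-hoop axial
## displacement statistics.

#' Partition a surface grid into named regions
#'
#' Region schemes by geometry: spherocylinders are split into hemispherical
#' `pole` caps and the cylindrical `bulk` at the cap-cylinder seam (an
#' optional exclusion half-width drops cells near the seam); tori (and bent
#' rods) get tube-angle bands `inner` (around the inner equator, tube angle
#' pi), `midline` (around +-pi/2) and `outer` (around 0); bulged cylinders are
#' split into `bulge` (the support of the bump) and `cylinder`.
#'
#' @param surface a parametric surface.
#' @param grid a [surface_grid()] (must match the field the partition is used
#'   with).
#' @param band_halfwidth half-width of the torus tube-angle bands (rad).
#' @param seam_exclusion half-width (um, along u) excluded around the
#'   spherocylinder seam.
#' @return A `region_partition`: character matrix of labels (NA = unlabeled)
#'   plus the grid.
#' @export
region_partition <- function(surface, grid, band_halfwidth = 15 * pi / 180,
                             seam_exclusion = 0) {
  U <- matrix(grid$U, grid$n_u, grid$n_v)
  V <- matrix(grid$V, grid$n_u, grid$n_v)
  lab <- matrix(NA_character_, grid$n_u, grid$n_v)
  d <- surface$dims
  if (surface$kind == "spherocylinder") {
    lab[] <- "pole"
    lab[U >= 0 & U <= d$length] <- "bulk"
    if (seam_exclusion > 0)
      lab[abs(U) < seam_exclusion |
          abs(U - d$length) < seam_exclusion] <- NA_character_
  } else if (surface$kind %in% c("torus", "bent_rod")) {
    ang <- function(x, c0) {
      dd <- abs(wrap_mod(x - c0, -pi, pi))
      dd <= band_halfwidth
    }
    lab[ang(V, pi)] <- "inner"
    lab[ang(V, pi / 2) | ang(V, -pi / 2)] <- "midline"
    lab[ang(V, 0)] <- "outer"
  } else if (surface$kind == "bulged_cylinder") {
    lab[] <- "cylinder"
    lab[abs(U - d$length / 2) <= d$bulge_width] <- "bulge"
  } else {
    stop("no default region scheme for kind '", surface$kind,
         "'; supply labels manually")
  }
  structure(list(labels = lab, grid = grid, kind = surface$kind),
            class = "region_partition")
}

#' Area-weighted enrichment ratio between two regions
#'
#' Ratio of area-weighted mean concentration C_F between two named regions of
#' a partition. Invariant to uniform rescaling of C_F.
#'
#' @param field a `concentration_field`.
#' @param partition a [region_partition()] on the same grid.
#' @param a,b region names (numerator, denominator).
#' @return The ratio (scalar).
#' @export
region_enrichment <- function(field, partition, a, b) {
  stopifnot(identical(dim(field$CF), dim(partition$labels)))
  mean_region <- function(r) {
    i <- which(partition$labels == r)
    if (!length(i)) stop("empty region '", r, "'")
    sum(field$CF[i] * field$dA[i]) / sum(field$dA[i])
  }
  mean_region(a) / mean_region(b)
}

#' Percentage of filaments contained in the bulge
#'
#' 100 * (filament number in the bulge region) / (total filament number).
#' Under zero processivity (uniform C_F) this equals the bulge area fraction.
#'
#' @param field a `concentration_field`.
#' @param partition a [region_partition()] with a `bulge` region.
#' @param region region name (default "bulge").
#' @return List with `percent`, `area_percent` (the area fraction, for
#'   reference) and `excess` (their difference).
#' @export
bulge_occupancy <- function(field, partition, region = "bulge") {
  i <- which(partition$labels == region)
  if (!length(i)) stop("empty region '", region, "'")
  pct <- 100 * sum(field$NF[i]) / sum(field$NF)
  apct <- 100 * sum(field$dA[i]) / sum(field$dA)
  list(percent = pct, area_percent = apct, excess = pct - apct)
}

#' Curvature-enrichment curve
#'
#' Bins the surface cells by mean (H) or Gaussian (K) curvature and reports
#' the area-weighted mean C_F per bin, normalized so the anchor bin (H = 1
#' um^-1 or K = 0 um^-2 by default) equals 1 a.u.
#'
#' @param field a `concentration_field`.
#' @param surface the surface the field lives on.
#' @param which `"H"` or `"K"`.
#' @param bins number of equal-width bins over the observed curvature range.
#' @param anchor curvature value whose bin is normalized to 1 a.u.
#' @return An `enrichment_curve` data.frame: `bin_center`, `mean_CF_au`,
#'   `sd_au`, `n_cells`, `area`.
#' @export
curvature_enrichment_curve <- function(field, surface, which = c("H", "K"),
                                       bins = 25, anchor = NULL) {
  which <- match.arg(which)
  g <- field$grid
  cb <- curvature_batch(surface, g$U, g$V)
  x <- if (which == "H") cb$H else cb$K
  if (is.null(anchor)) anchor <- if (which == "H") 1 else 0
  rng <- range(x)
  if (anchor < rng[1] || anchor > rng[2])
    stop("anchor curvature ", anchor, " outside the observed range")
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  bi <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), bins)
  cf <- as.vector(field$CF); dA <- as.vector(field$dA)
  wmean <- function(i) sum(cf[i] * dA[i]) / sum(dA[i])
  centers <- (edges[-1] + edges[-(bins + 1)]) / 2
  mu <- sdv <- area <- rep(NA_real_, bins)
  ncl <- integer(bins)
  for (b in seq_len(bins)) {
    i <- which(bi == b)
    ncl[b] <- length(i)
    if (length(i)) {
      mu[b] <- wmean(i)
      m <- mu[b]
      sdv[b] <- sqrt(sum(dA[i] * (cf[i] - m)^2) / sum(dA[i]))
      area[b] <- sum(dA[i])
    }
  }
  ab <- pmin(pmax(findInterval(anchor, edges, rightmost.closed = TRUE), 1L),
             bins)
  if (is.na(mu[ab]) || mu[ab] <= 0) stop("empty anchor bin")
  out <- data.frame(bin_center = centers, mean_CF_au = mu / mu[ab],
                    sd_au = sdv / mu[ab], n_cells = ncl, area = area)
  attr(out, "which") <- which
  attr(out, "anchor") <- anchor
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

#' @export
plot.enrichment_curve <- function(x, ...) {
  w <- attr(x, "which")
  graphics::plot(x$bin_center, x$mean_CF_au, type = "b", pch = 16,
                 xlab = if (w == "H") expression(H ~ (mu * m^-1))
                        else expression(K ~ (mu * m^-2)),
                 ylab = expression(C[F] ~ "(a.u.)"),
                 main = "Curvature-enrichment curve", ...)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

## Unwrap a periodic coordinate sequence by minimal-image increments.
unwrap_periodic <- function(x, span) {
  dx <- diff(x)
  dx <- dx - span * round(dx / span)
  c(x[1], x[1] + cumsum(dx))
}

#' Axial displacement per circumferential hoop
#'
#' Splits each trajectory on a cylinder of radius R at every completed 2 pi R
#' of cumulative unsigned circumferential arclength and records the net
#' (signed) axial displacement over each hoop; partial final hoops are
#' discarded. For sigma = 0 every displacement is exactly zero; in the
#' small-angle regime the standard deviation approaches sqrt(2 pi R L
#' sigma^2).
#'
#' @param trajectories a `trajectory` or list of them (on a cylinder).
#' @param surface the cylinder the trajectories were simulated on.
#' @return List with `displacements` (signed, um), `abs_displacements`,
#'   `n_hoops`, `mean`, `sd`, and a `histogram` (graphics::hist object,
#'   not plotted).
#' @export
axial_displacement_per_hoop <- function(trajectories, surface) {
  stopifnot(surface$kind == "cylinder")
  R <- surface$dims$radius
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  span_u <- surface$domain[2] - surface$domain[1]
  disp <- numeric(0)
  for (tr in trajectories) {
    if (nrow(tr) < 2) next
    u <- unwrap_periodic(tr$u, span_u)
    v <- unwrap_periodic(tr$v, 2 * pi)
    arc <- c(0, cumsum(abs(diff(v)) * R))
    n_complete <- floor(arc[length(arc)] / (2 * pi * R))
    if (n_complete < 1) next
    marks <- (seq_len(n_complete)) * 2 * pi * R
    ucross <- stats::approx(arc, u, xout = marks, ties = "ordered")$y
    disp <- c(disp, diff(c(stats::approx(arc, u, xout = 0)$y, ucross)))
  }
  if (!length(disp))
    stop("no completed hoops in the supplied trajectories")
  list(displacements = disp, abs_displacements = abs(disp),
       n_hoops = length(disp), mean = mean(disp), sd = stats::sd(disp),
       histogram = graphics::hist(disp, breaks = "FD", plot = FALSE))
}
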