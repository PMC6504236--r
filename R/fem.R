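## Linear (P1) finite elements on triangle meshes, used to solve the membrane
## shape equation Delta^2 h = q via its split into two Poisson problems with
## Dirichlet data (m = Delta h first, then h).

#' Structured triangle mesh on a rectangle
#'
#' @param xlim,ylim extents.
#' @param nx,ny node counts per side.
#' @return A `fem_mesh`: nodes (n x 2), triangles (m x 3, 1-based),
#'   `boundary` (indices of boundary nodes).
#' @export
fem_rect_mesh <- function(xlim, ylim, nx = 41, ny = 41) {
  xs <- seq(xlim[1], xlim[2], length.out = nx)
  ys <- seq(ylim[1], ylim[2], length.out = ny)
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  ## split each cell along its diagonal
  t1 <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
  t2 <- cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  bnd <- which(nodes[, 1] %in% xs[c(1, nx)] | nodes[, 2] %in% ys[c(1, ny)])
  structure(list(nodes = nodes, tri = rbind(t1, t2), boundary = bnd),
            class = "fem_mesh")
}

#' Polar (fan) triangle mesh on a disk
#'
#' @param a disk radius.
#' @param n_r radial rings; `n_t` angular divisions.
#' @return A `fem_mesh` (boundary = outer ring).
#' @export
fem_disk_mesh <- function(a, n_r = 24, n_t = 48) {
  nodes <- matrix(0, nrow = 1 + n_r * n_t, ncol = 2)
  for (i in seq_len(n_r)) {
    r <- a * i / n_r
    th <- 2 * pi * (seq_len(n_t) - 1) / n_t
    nodes[1 + (i - 1) * n_t + seq_len(n_t), ] <- cbind(r * cos(th),
                                                       r * sin(th))
  }
  ring <- function(i, k) 1 + (i - 1) * n_t + ((k - 1) %% n_t) + 1
  tris <- list()
  k <- seq_len(n_t)
  tris[[1]] <- cbind(1, ring(1, k), ring(1, k + 1))
  for (i in seq_len(n_r - 1)) {
    tris[[length(tris) + 1]] <- cbind(ring(i, k), ring(i + 1, k),
                                      ring(i + 1, k + 1))
    tris[[length(tris) + 1]] <- cbind(ring(i, k), ring(i + 1, k + 1),
                                      ring(i, k + 1))
  }
  structure(list(nodes = nodes, tri = do.call(rbind, tris),
                 boundary = 1 + (n_r - 1) * n_t + seq_len(n_t)),
            class = "fem_mesh")
}

## Assemble P1 stiffness (K) and mass (M) matrices (sparse, symmetric).
fem_assemble <- function(mesh) {
  tri <- mesh$tri
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  d23 <- p2 - p3; d31 <- p3 - p1; d12 <- p1 - p2
  area2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  A <- abs(area2) / 2
  b <- cbind(d23[, 2], d31[, 2], d12[, 2]) / area2   # dphi_i/dx
  c_ <- cbind(-d23[, 1], -d31[, 1], -d12[, 1]) / area2
  ii <- jj <- kk <- mm <- NULL
  for (i in 1:3) for (j in 1:3) {
    ii <- c(ii, tri[, i]); jj <- c(jj, tri[, j])
    kk <- c(kk, A * (b[, i] * b[, j] + c_[, i] * c_[, j]))
    mm <- c(mm, A / 12 * (1 + (i == j)))
  }
  n <- nrow(mesh$nodes)
  list(K = Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(n, n)),
       M = Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(n, n)),
       area = A)
}

## Solve -?: weak Poisson problem  Delta u = f  with Dirichlet data:
## find u with u = val on `dir_nodes` and  integral grad u . grad phi = - integral f phi
## for all free test functions. `f` is a nodal vector (may be zero).
fem_poisson <- function(asm, f_nodal, dir_nodes, dir_values) {
  n <- nrow(asm$K)
  u <- numeric(n)
  u[dir_nodes] <- dir_values
  free <- setdiff(seq_len(n), dir_nodes)
  rhs <- -(asm$M %*% f_nodal)[free] - (asm$K[free, dir_nodes, drop = FALSE]
                                       %*% u[dir_nodes])
  u[free] <- as.numeric(Matrix::solve(asm$K[free, free], rhs))
  u
}

#' Solve the membrane shape equation on a Monge patch
#'
#' Solves the biharmonic problem Delta^2 h = load by the split m = Delta h:
#' first the Poisson problem Delta m = load with Dirichlet data for m
#' (continuity of mean curvature, since 2H = Delta h in the small-gradient
#' Monge gauge), then Delta h = m with Dirichlet data for h (continuity of
#' height). Both solves use P1 finite elements.
#'
#' @param mesh a `fem_mesh` ([fem_rect_mesh()], [fem_disk_mesh()]).
#' @param load right-hand side of the biharmonic equation (scalar or nodal
#'   vector); for a pressure-loaded membrane this is p/kb.
#' @param h_bc,m_bc Dirichlet data: lists with `nodes` and `values`
#'   (defaults: zero on the mesh boundary).
#' @return A `deformation_field`: nodal `h`, `m` (= Delta h), the mesh, and
#'   the assembled matrices for energy evaluation.
#' @examples
#' mesh <- fem_disk_mesh(1, 24, 48)
#' fld <- solve_shape_equation(mesh, load = 1)
#' max(fld$h)   # ~ 3/64 at the center
#' @export
solve_shape_equation <- function(mesh, load = 0, h_bc = NULL, m_bc = NULL) {
  asm <- fem_assemble(mesh)
  n <- nrow(mesh$nodes)
  if (is.null(m_bc)) m_bc <- list(nodes = mesh$boundary, values = 0)
  if (is.null(h_bc)) h_bc <- list(nodes = mesh$boundary, values = 0)
  loadv <- rep_len(load, n)
  m <- fem_poisson(asm, loadv, m_bc$nodes, rep_len(m_bc$values,
                                                   length(m_bc$nodes)))
  h <- fem_poisson(asm, m, h_bc$nodes, rep_len(h_bc$values,
                                               length(h_bc$nodes)))
  structure(list(h = h, m = m, mesh = mesh, asm = asm, load = loadv),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat("Monge-gauge deformation field:", nrow(x$mesh$nodes), "nodes,",
      nrow(x$mesh$tri), "triangles\n")
  cat(sprintf("  h range: [%.4g, %.4g]; max |Delta h|: %.4g\n",
              min(x$h), max(x$h), max(abs(x$m))))
  invisible(x)
}

## Quadratic functionals of a deformation field.
fem_bending_integral <- function(field)       # integral (Delta h)^2 dA
  as.numeric(Matrix::crossprod(field$m, field$asm$M %*% field$m))
fem_volume_integral <- function(field)        # integral h dA
  sum(field$asm$M %*% field$h)
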