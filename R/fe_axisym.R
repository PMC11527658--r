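# Axisymmetric linear-elastic finite elements (constant-strain triangles).
#
# Strain vector convention: (eps_rr, eps_theta, eps_zz, gamma_rz) with
# engineering shear. One-point quadrature at the element centroid with the
# full-ring volume weight 2*pi*rbar*A; all applied forces and the fixator
# spring are total (full-ring) quantities.

# per-element shape-function gradients and geometric weights
.elem_geom <- function(mesh) {
  tr <- mesh$triangles
  r <- mesh$nodes[, 1]; z <- mesh$nodes[, 2]
  r1 <- r[tr[, 1]]; r2 <- r[tr[, 2]]; r3 <- r[tr[, 3]]
  z1 <- z[tr[, 1]]; z2 <- z[tr[, 2]]; z3 <- z[tr[, 3]]
  A2 <- (r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1) # = 2*A > 0
  list(
    b1 = (z2 - z3) / A2, b2 = (z3 - z1) / A2, b3 = (z1 - z2) / A2,
    c1 = (r3 - r2) / A2, c2 = (r1 - r3) / A2, c3 = (r2 - r1) / A2,
    area = A2 / 2, rbar = (r1 + r2 + r3) / 3
  )
}

# 4x6 strain-displacement matrix entries as vectors over elements;
# columns ordered (u_r1, u_z1, u_r2, u_z2, u_r3, u_z3)
.elem_B <- function(g) {
  m <- length(g$area)
  t3 <- 1 / (3 * g$rbar) # hoop row N_i / r at the centroid
  B <- vector("list", 4)
  zero <- numeric(m)
  B[[1]] <- list(g$b1, zero, g$b2, zero, g$b3, zero)
  B[[2]] <- list(t3, zero, t3, zero, t3, zero)
  B[[3]] <- list(zero, g$c1, zero, g$c2, zero, g$c3)
  B[[4]] <- list(g$c1, g$b1, g$c2, g$b2, g$c3, g$b3)
  B
}

# sparse-triplet element stiffness assembly over the full dof set
# (dofs: node n -> u_r at 2n-1, u_z at 2n)
.assemble_axisym <- function(mesh, E, nu) {
  g <- .elem_geom(mesh)
  B <- .elem_B(g)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  w <- 2 * pi * g$rbar * g$area
  # D = lam * m m^T + mu * diag(2,2,2,1), m = (1,1,1,0)
  v <- lapply(1:6, function(a) B[[1]][[a]] + B[[2]][[a]] + B[[3]][[a]])
  tr <- mesh$triangles
  eldof <- cbind(2L * tr[, 1] - 1L, 2L * tr[, 1],
                 2L * tr[, 2] - 1L, 2L * tr[, 2],
                 2L * tr[, 3] - 1L, 2L * tr[, 3])
  m <- nrow(tr)
  ii <- vector("list", 36); jj <- vector("list", 36); xx <- vector("list", 36)
  k <- 0L
  for (a in 1:6) {
    for (b in 1:6) {
      k <- k + 1L
      kab <- w * (lam * v[[a]] * v[[b]] +
                  mu * (2 * (B[[1]][[a]] * B[[1]][[b]] +
                             B[[2]][[a]] * B[[2]][[b]] +
                             B[[3]][[a]] * B[[3]][[b]]) +
                        B[[4]][[a]] * B[[4]][[b]]))
      ii[[k]] <- eldof[, a]; jj[[k]] <- eldof[, b]; xx[[k]] <- kab
    }
  }
  list(i = unlist(ii), j = unlist(jj), x = unlist(xx),
       ndof = 2L * nrow(mesh$nodes))
}

#' General axisymmetric linear-elastic solve
#'
#' Solves the constrained linear system for arbitrary Dirichlet data, rigid
#' ties (groups of dofs sharing one unknown) and total (full-ring) point
#' loads. This is the workhorse behind [solve_axial()] and the patch tests.
#'
#' @param mesh An `axisym_mesh`.
#' @param E,nu Per-element Young's modulus (MPa) and Poisson's ratio.
#' @param fixed_dofs Integer vector of constrained dof ids (node `n` has
#'   radial dof `2n-1`, axial dof `2n`).
#' @param fixed_values Prescribed values for `fixed_dofs` (recycled; mm).
#' @param ties List of integer dof-id vectors; each group shares one unknown.
#' @param load_dofs,load_values Total applied forces, N (a load on any member
#'   of a tie group acts on the group unknown).
#' @return List with `u` (full dof vector, mm), `factor` (Cholesky of the
#'   reduced operator), `map` (full dof -> reduced index, 0 if fixed),
#'   `triplets` (assembly triplets, for reaction recovery) and `ndof`.
#' @export
fe_solve_axisym <- function(mesh, E, nu,
                            fixed_dofs = integer(), fixed_values = 0,
                            ties = list(),
                            load_dofs = integer(), load_values = numeric()) {
  stopifnot(length(E) == nrow(mesh$triangles),
            length(nu) == nrow(mesh$triangles),
            all(E > 0), all(nu > 0), all(nu < 0.5))
  asm <- .assemble_axisym(mesh, E, nu)
  red <- .reduce_system(asm, fixed_dofs, fixed_values, ties,
                        load_dofs, load_values)
  fac <- Matrix::Cholesky(red$K, LDL = FALSE)
  ur <- as.numeric(Matrix::solve(fac, red$f))
  u <- .expand_solution(ur, red)
  list(u = u, factor = fac, map = red$map, u0 = red$u0,
       triplets = asm, ndof = asm$ndof, reduced = red)
}

# build reduced symmetric system from triplets + constraints
.reduce_system <- function(asm, fixed_dofs, fixed_values, ties,
                           load_dofs, load_values) {
  ndof <- asm$ndof
  fixed_values <- rep_len(fixed_values, length(fixed_dofs))
  map <- integer(ndof)
  free <- setdiff(seq_len(ndof), c(fixed_dofs, unlist(ties)))
  map[free] <- seq_along(free)
  nred <- length(free)
  for (grp in ties) {
    if (any(grp %in% fixed_dofs)) stop("tied dof is also fixed")
    nred <- nred + 1L
    map[grp] <- nred
  }
  u0 <- numeric(ndof)
  u0[fixed_dofs] <- fixed_values
  ir <- map[asm$i]; jr <- map[asm$j]
  keep <- ir > 0L & jr > 0L
  K <- Matrix::sparseMatrix(i = ir[keep], j = jr[keep], x = asm$x[keep],
                            dims = c(nred, nred))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  f <- numeric(nred)
  if (length(load_dofs)) {
    lr <- map[load_dofs]
    if (any(lr == 0L)) stop("load applied to a fixed dof")
    f[unique(lr)] <- vapply(unique(lr),
                            function(d) sum(load_values[lr == d]), 0)
  }
  # prescribed-displacement contribution to the rhs
  pres <- ir > 0L & jr == 0L & u0[asm$j] != 0
  if (any(pres)) {
    contrib <- asm$x[pres] * u0[asm$j[pres]]
    agg <- rowsum(contrib, ir[pres])
    f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] - agg[, 1]
  }
  list(K = K, f = f, map = map, u0 = u0, nred = nred)
}

.expand_solution <- function(ur, red) {
  u <- red$u0
  sel <- red$map > 0L
  u[sel] <- ur[red$map[sel]]
  u
}

#' Nonlinear fixator spring
#'
#' The external fixator is an axial spring that is stiff
#' (`k_stiff` = 4600 N/mm) up to a transition force of 100 N, compliant
#' (`k_free` = 10 N/mm) over the group-dependent free travel, then stiff
#' again. The force-displacement curve is continuous and non-decreasing.
#'
#' @param free_travel Free axial travel, mm (>= 0); group dependent, see
#'   [group_config()].
#' @param k_stiff,k_free Spring stiffnesses, N/mm.
#' @param transition_force Force at which free travel begins, N.
#' @return Object of class `fixator_spring`.
#' @export
fixator_spring <- function(free_travel, k_stiff = 4600, k_free = 10,
                           transition_force = 100) {
  if (free_travel < 0) stop("free_travel must be non-negative")
  if (!(k_stiff > k_free && k_free > 0)) stop("need k_stiff > k_free > 0")
  if (transition_force <= 0) stop("transition_force must be positive")
  structure(list(free_travel = free_travel, k_stiff = k_stiff,
                 k_free = k_free, transition_force = transition_force),
            class = "fixator_spring")
}

#' @export
print.fixator_spring <- function(x, ...) {
  cat(sprintf("<fixator_spring> %g N/mm to %g N, then %g N/mm over %.3f mm free travel\n",
              x$k_stiff, x$transition_force, x$k_free, x$free_travel))
  invisible(x)
}

#' Spring force at a given gap closure
#'
#' @param d Relative axial displacement (gap closure), mm, >= 0; vectorised.
#' @param spring A [fixator_spring()].
#' @return Force, N (total, full ring).
#' @export
spring_force <- function(d, spring) {
  stopifnot(inherits(spring, "fixator_spring"), all(d >= 0))
  d1 <- spring$transition_force / spring$k_stiff
  d2 <- d1 + spring$free_travel
  ifelse(d <= d1, spring$k_stiff * d,
         ifelse(d <= d2,
                spring$transition_force + spring$k_free * (d - d1),
                spring$transition_force + spring$k_free * spring$free_travel +
                  spring$k_stiff * (d - d2)))
}

#' Spring displacement at a given force (inverse of [spring_force()])
#'
#' @param force Applied force, N, >= 0; vectorised.
#' @param spring A [fixator_spring()].
#' @return Gap closure, mm.
#' @export
spring_displacement <- function(force, spring) {
  stopifnot(inherits(spring, "fixator_spring"), all(force >= 0))
  F1 <- spring$transition_force
  F2 <- F1 + spring$k_free * spring$free_travel
  d1 <- F1 / spring$k_stiff
  ifelse(force <= F1, force / spring$k_stiff,
         ifelse(force <= F2, d1 + (force - F1) / spring$k_free,
                d1 + spring$free_travel + (force - F2) / spring$k_stiff))
}

#' Solve the axially loaded fixated construct
#'
#' Boundary conditions follow the fixator rig: the distal end-face nodes are
#' rigidly tied to a fully fixed control node (u_r = 0, u_z = 0); the
#' proximal end-face nodes are rigidly tied to a control node that is free
#' axially only (u_r = 0, shared u_z). The nonlinear spring connects the two
#' control nodes and the total axial load is applied to the proximal control
#' node in compression. The piecewise-linear spring balance is solved
#' exactly: with the spring removed the reduced operator is factorised once,
#' the load and a unit control force are solved, and the scalar equilibrium
#' is resolved analytically segment by segment.
#'
#' @param mesh An `axisym_mesh` spanning z in `[-L/2, L/2]`.
#' @param E,nu Per-element material properties (MPa, -).
#' @param spring A [fixator_spring()], or `NULL` for no fixator.
#' @param load Total axial compressive load, N (>= 0).
#' @param diagnostics If `TRUE`, compute reaction-balance diagnostics
#'   (costs one extra sparse product).
#' @return List of class `axial_solution`: `u` (full dof vector), `ifm`
#'   (gap closure between control nodes, mm), `spring_force` (N),
#'   `load` (N), and optionally `residual` (relative axial force imbalance).
#' @export
solve_axial <- function(mesh, E, nu, spring = NULL, load = 500,
                        diagnostics = FALSE) {
  stopifnot(load >= 0)
  zl <- range(mesh$nodes[, 2])
  tol <- 1e-8
  distal <- which(abs(mesh$nodes[, 2] - zl[1]) < tol)
  proximal <- which(abs(mesh$nodes[, 2] - zl[2]) < tol)
  fixed <- c(2L * distal - 1L, 2L * distal, 2L * proximal - 1L)
  tie <- list(2L * proximal) # shared axial dof = proximal control node
  asm <- .assemble_axisym(mesh, E, nu)
  red <- .reduce_system(asm, fixed, 0, tie,
                        load_dofs = 2L * proximal[1], load_values = -load)
  fac <- Matrix::Cholesky(red$K, LDL = FALSE)
  x <- as.numeric(Matrix::solve(fac, red$f))
  pd <- red$map[2L * proximal[1]]
  if (is.null(spring)) {
    ur <- x
    d <- -x[pd]
    Fs <- 0
  } else {
    ep <- numeric(red$nred); ep[pd] <- 1
    y <- as.numeric(Matrix::solve(fac, ep))
    xp <- x[pd]; yp <- y[pd]
    d <- .spring_balance(xp, yp, spring)
    Fs <- spring_force(d, spring)
    ur <- x + Fs * y
  }
  u <- .expand_solution(ur, red)
  out <- list(u = u, ifm = d, spring_force = Fs, load = load,
              proximal_nodes = proximal, distal_nodes = distal)
  if (diagnostics) {
    K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                              dims = c(asm$ndof, asm$ndof))
    fint <- as.numeric(K %*% u)
    # axial ground reaction: distal-face mesh forces plus the spring's
    # ground leg must together carry the applied load
    Rz <- sum(fint[2L * distal]) + Fs
    out$residual <- abs(Rz - load) / max(load, 1)
    out$reactions <- fint
  }
  class(out) <- "axial_solution"
  out
}

# exact piecewise-linear solve of d = -xp - F_s(d) * yp
.spring_balance <- function(xp, yp, spring) {
  if (-xp <= 0) return(0)
  d1 <- spring$transition_force / spring$k_stiff
  d2 <- d1 + spring$free_travel
  segs <- list(
    c(lo = 0, hi = d1, F0 = 0, k = spring$k_stiff, d0 = 0),
    c(lo = d1, hi = d2, F0 = spring$transition_force, k = spring$k_free, d0 = d1),
    c(lo = d2, hi = Inf,
      F0 = spring$transition_force + spring$k_free * spring$free_travel,
      k = spring$k_stiff, d0 = d2)
  )
  for (s in segs) {
    d <- (-xp - (s["F0"] - s["k"] * s["d0"]) * yp) / (1 + s["k"] * yp)
    if (d >= s["lo"] - 1e-12 && d <= s["hi"] + 1e-12) {
      return(unname(max(d, 0)))
    }
  }
  stop("spring balance failed (no segment admits a solution)")
}

#' @export
print.axial_solution <- function(x, ...) {
  cat(sprintf("<axial_solution> load %.0f N, IFM %.4f mm, spring force %.1f N\n",
              x$load, x$ifm, x$spring_force))
  if (!is.null(x$residual)) {
    cat(sprintf("  axial equilibrium residual: %.2e\n", x$residual))
  }
  invisible(x)
}

#' Recover element strains from a displacement field
#'
#' Constant-strain triangles evaluated at element centroids. The full 3D
#' strain tensor is assembled (radial, hoop `u_r/r`, axial, and the r-z
#' shear); its three principal values are the two in-plane eigenvalues and
#' the hoop strain. The distortional strain is the octahedral shear strain
#' \deqn{\gamma_{oct} = \tfrac{2}{3}\sqrt{(\varepsilon_1-\varepsilon_2)^2 +
#'   (\varepsilon_2-\varepsilon_3)^2 + (\varepsilon_3-\varepsilon_1)^2}.}
#'
#' @param mesh An `axisym_mesh`.
#' @param u Full dof displacement vector (from [solve_axial()] etc.), mm.
#' @return Data frame per element: strain components `eps_rr`, `eps_tt`,
#'   `eps_zz`, `gam_rz`, and `eps_min`, `eps_max`, `eps_dist`.
#' @export
recover_strains <- function(mesh, u) {
  g <- .elem_geom(mesh)
  tr <- mesh$triangles
  ur1 <- u[2 * tr[, 1] - 1]; uz1 <- u[2 * tr[, 1]]
  ur2 <- u[2 * tr[, 2] - 1]; uz2 <- u[2 * tr[, 2]]
  ur3 <- u[2 * tr[, 3] - 1]; uz3 <- u[2 * tr[, 3]]
  eps_rr <- g$b1 * ur1 + g$b2 * ur2 + g$b3 * ur3
  eps_zz <- g$c1 * uz1 + g$c2 * uz2 + g$c3 * uz3
  gam <- g$c1 * ur1 + g$b1 * uz1 + g$c2 * ur2 + g$b2 * uz2 +
    g$c3 * ur3 + g$b3 * uz3
  # hoop strain u_r / r at the centroid; on-axis limit du_r/dr
  on_axis <- g$rbar < 1e-9
  eps_tt <- ifelse(on_axis, eps_rr, (ur1 + ur2 + ur3) / (3 * g$rbar))
  # principal strains: in-plane eigenvalues + hoop
  cm <- (eps_rr + eps_zz) / 2
  rad <- sqrt(((eps_rr - eps_zz) / 2)^2 + (gam / 2)^2)
  e1 <- cm + rad; e2 <- cm - rad; e3 <- eps_tt
  eps_max <- pmax(e1, e2, e3)
  eps_min <- pmin(e1, e2, e3)
  eps_dist <- (2 / 3) * sqrt((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2)
  data.frame(eps_rr = eps_rr, eps_tt = eps_tt, eps_zz = eps_zz, gam_rz = gam,
             eps_min = eps_min, eps_max = eps_max, eps_dist = eps_dist)
}
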