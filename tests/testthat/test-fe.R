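test_that("spring force-displacement law matches its piecewise definition", {
  sp <- fixator_spring(free_travel = 0.31)
  d1 <- 100 / 4600
  expect_equal(spring_force(0, sp), 0)
  expect_equal(spring_force(d1, sp), 100)
  # middle of the free-travel segment
  expect_equal(spring_force(d1 + 0.155, sp), 100 + 10 * 0.155)
  # stiff again beyond the free travel
  expect_equal(spring_force(d1 + 0.31 + 0.01, sp), 103.1 + 46)
  # continuity at both break points
  eps <- 1e-10
  for (d0 in c(d1, d1 + 0.31)) {
    expect_equal(spring_force(d0 - eps, sp), spring_force(d0 + eps, sp),
                 tolerance = 1e-6)
  }
  # monotone non-decreasing on a fine grid
  d <- seq(0, 1, by = 1e-3)
  expect_true(all(diff(spring_force(d, sp)) >= 0))
  # inverse round-trips
  f <- c(0, 50, 100, 101, 103, 200, 500)
  expect_equal(spring_force(spring_displacement(f, sp), sp), f)
  # spring alone carrying 500 N
  expect_equal(spring_displacement(500, sp),
               100 / 4600 + 0.31 + (500 - 103.1) / 4600, tolerance = 1e-12)
  expect_error(fixator_spring(-0.1), "non-negative")
})

test_that("axial tube stiffness matches the closed-form bar solution", {
  mesh <- tube_mesh(80, 6, 8, target_edge = 0.8)
  np <- nrow(mesh$triangles)
  zl <- range(mesh$nodes[, 2])
  bot <- which(abs(mesh$nodes[, 2] - zl[1]) < 1e-8)
  top <- which(abs(mesh$nodes[, 2] - zl[2]) < 1e-8)
  sol <- fe_solve_axisym(mesh, rep(10000, np), rep(0.36, np),
                         fixed_dofs = 2L * bot, fixed_values = 0,
                         ties = list(2L * top),
                         load_dofs = 2L * top[1], load_values = -500)
  shortening <- -sol$u[2L * top[1]]
  A <- pi * (8^2 - 6^2)
  expect_equal(shortening, 500 * 80 / (10000 * A), tolerance = 0.01)
  # frictionless uniform compression is exactly representable: much tighter
  expect_equal(shortening, 500 * 80 / (10000 * A), tolerance = 1e-9)
})

test_that("patch test: admissible linear fields are reproduced to round-off", {
  # in axisymmetry constant-strain linear fields require u_r = b*r (so that
  # the hoop strain equals the radial strain) and zero r-z shear
  mesh <- coarse_mesh("B", edge = 2.5)
  n <- nrow(mesh$nodes)
  b <- 2e-3; a <- 1e-3; cc <- -3e-3
  uex <- numeric(2 * n)
  uex[seq(1, 2 * n, 2)] <- b * mesh$nodes[, 1]
  uex[seq(2, 2 * n, 2)] <- a + cc * mesh$nodes[, 2]
  bn <- boundary_nodes(mesh)
  fx <- c(2L * bn - 1L, 2L * bn)
  m <- nrow(mesh$triangles)
  sol <- fe_solve_axisym(mesh, rep(1000, m), rep(0.3, m),
                         fixed_dofs = fx, fixed_values = uex[fx])
  expect_lt(max(abs(sol$u - uex)), 1e-12)
  st <- recover_strains(mesh, sol$u)
  expect_lt(max(abs(st$eps_rr - b)), 1e-12)
  expect_lt(max(abs(st$eps_tt - b)), 1e-12)
  expect_lt(max(abs(st$eps_zz - cc)), 1e-12)
  expect_lt(max(abs(st$gam_rz)), 1e-12)
})

test_that("reduced stiffness operator is symmetric positive definite", {
  mesh <- coarse_mesh("A", edge = 3)
  m <- nrow(mesh$triangles)
  zl <- range(mesh$nodes[, 2])
  bot <- which(abs(mesh$nodes[, 2] - zl[1]) < 1e-8)
  sol <- fe_solve_axisym(mesh, rep(100, m), rep(0.3, m),
                         fixed_dofs = c(2L * bot - 1L, 2L * bot))
  K <- sol$reduced$K
  expect_lt(max(abs(K - Matrix::t(K))), 1e-9 * max(abs(K)))
  ev <- min(eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(ev, 0)
})

test_that("fixated construct balances the applied load to 1e-8", {
  mesh <- coarse_mesh("A", edge = 1.2)
  E <- ifelse(mesh$region == "callus", 3, 10000)
  nu <- ifelse(mesh$region == "callus", 0.30, 0.36)
  sol <- solve_axial(mesh, E, nu, spring = fixator_spring(0.07),
                     load = 500, diagnostics = TRUE)
  expect_lt(sol$residual, 1e-8)
  expect_gt(sol$ifm, 0)
  expect_gt(sol$spring_force, 0)
  # spring and callus path share the load
  expect_lt(sol$spring_force, 500)
})

test_that("solution is invariant to how the spring balance is segmented", {
  # the same state solved with springs whose free travel brackets the
  # operating point on different segments must agree with the piecewise law
  mesh <- coarse_mesh("A", edge = 1.5)
  E <- ifelse(mesh$region == "callus", 3, 10000)
  nu <- ifelse(mesh$region == "callus", 0.30, 0.36)
  for (ft in c(0.02, 0.07, 0.5)) {
    sol <- solve_axial(mesh, E, nu, spring = fixator_spring(ft), load = 500)
    expect_equal(sol$spring_force, spring_force(sol$ifm, fixator_spring(ft)),
                 tolerance = 1e-9)
  }
})

test_that("zero load gives the zero solution", {
  mesh <- coarse_mesh("A", edge = 1.5)
  E <- ifelse(mesh$region == "callus", 3, 10000)
  nu <- ifelse(mesh$region == "callus", 0.30, 0.36)
  sol <- solve_axial(mesh, E, nu, spring = fixator_spring(0.07), load = 0)
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(sol$ifm, 0)
})

test_that("strain recovery reproduces canonical states", {
  # uniaxial compression: eps_zz = -0.01 on a single element
  mesh <- tube_mesh(2, 6, 8, target_edge = 1)
  n <- nrow(mesh$nodes)
  u <- numeric(2 * n)
  u[seq(2, 2 * n, 2)] <- -0.01 * mesh$nodes[, 2]
  st <- recover_strains(mesh, u)
  expect_equal(st$eps_min, rep(-0.01, nrow(st)), tolerance = 1e-12)
  expect_equal(st$eps_max, rep(0, nrow(st)), tolerance = 1e-12)
  # octahedral shear of the uniaxial state: (2/3)*sqrt(2)*0.01
  expect_equal(st$eps_dist, rep((2 / 3) * sqrt(2) * 0.01, nrow(st)),
               tolerance = 1e-12)
  # pure r-z shear, engineering gamma = 0.02 -> principals +-0.01
  u <- numeric(2 * n)
  u[seq(1, 2 * n, 2)] <- 0.02 * mesh$nodes[, 2] # du_r/dz = 0.02
  st <- recover_strains(mesh, u)
  expect_equal(st$eps_max, rep(0.01, nrow(st)), tolerance = 1e-12)
  expect_equal(st$eps_min, rep(-0.01, nrow(st)), tolerance = 1e-12)
  # ordering invariant
  expect_true(all(st$eps_min <= st$eps_max))
  expect_true(all(st$eps_dist >= 0))
})
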