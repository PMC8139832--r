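test_that("spatial grid spans [0, L] with the requested step", {
  g <- spatial_grid(1000, 0.1)
  expect_equal(g$n_points, 10001L)
  expect_equal(g$x[1], 0)
  expect_equal(g$x[g$n_points], 1000)
  expect_error(spatial_grid(-1, 0.1))
})

test_that("periodic binding profile places sites at p1*n with width p2", {
  g <- spatial_grid(1000, 0.1)
  bp <- binding_profile(g, "periodic", a_max = 10, p1 = 2, p2 = 0.2)
  # site 1 occupies [2, 2.2): nodes at x = 2.0 and 2.1
  expect_equal(bp$a[g$x >= 2 - 1e-9 & g$x < 2.2 - 1e-9], c(10, 10))
  expect_equal(bp$a[abs(g$x - 2.2) < 1e-9], 0)
  expect_equal(bp$a[abs(g$x - 3.0) < 1e-9], 0)
  expect_equal(bp$a[abs(g$x - 4.0) < 1e-9], 10)
  # discretized mean binding equals the continuum a_max*p2/p1
  expect_equal(mean(bp$a[-length(bp$a)]), 10 * 0.2 / 2, tolerance = 1e-2)
  expect_equal(bp$site_intervals$x_start[1:3], c(2, 4, 6))
})

test_that("band scenario confines sites to the window", {
  g <- spatial_grid(1000, 0.1)
  bp <- binding_profile(g, "band", a_max = 10, band = c(50, 60))
  on <- bp$a > 0
  expect_true(all(g$x[on] >= 50 & g$x[on] <= 60))
  expect_gt(sum(on), 0)
  # absent_beyond: sites only up to the cut-off
  bp2 <- binding_profile(g, "absent_beyond", a_max = 10, band = 10)
  expect_true(all(g$x[bp2$a > 0] <= 10))
  expect_gt(sum(bp2$a > 0), 0)
})

test_that("degenerate and invalid binding profiles are handled", {
  g <- spatial_grid(100, 0.1)
  expect_true(all(binding_profile(g, "zero")$a == 0))
  expect_true(all(binding_profile(g, "periodic", a_max = 0)$a == 0))
  expect_error(binding_profile(g, "periodic", p1 = 0.2, p2 = 0.3),
               "overlapping")
  expect_error(binding_profile(g, "band", band = c(50, 200)), "outside")
  expect_error(binding_profile(g, "random_halfnormal"), "seed")
})

test_that("random half-normal amplitudes are reproducible with the configured mean", {
  g <- spatial_grid(1000, 0.1)
  b1 <- binding_profile(g, "random_halfnormal", a_max = 10, seed = 42)
  b2 <- binding_profile(g, "random_halfnormal", a_max = 10, seed = 42)
  b3 <- binding_profile(g, "random_halfnormal", a_max = 10, seed = 43)
  expect_identical(b1$a, b2$a)
  expect_false(identical(b1$a, b3$a))
  expect_true(all(b1$a_site >= 0))
  # |N(0, A*sqrt(pi/2))| has mean A; 499 sites give ~5% standard error
  expect_equal(mean(b1$a_site), 10, tolerance = 0.15)
})

test_that("one Euler step matches the hand-coded stencil oracle node by node", {
  set.seed(7)
  grid <- spatial_grid(1, 0.1)  # 11 nodes
  kin <- kinetic_params(D = 20, b = 0.1, c = 0.1, dt = 1e-4)
  a <- runif(11, 0, 5); g <- runif(11, 0, 0.3)
  binding <- list(a = a); source <- list(g = g)
  st <- ligand_state(grid, runif(11), runif(11))
  stepped <- step_forward(st, grid, kin, binding, source)
  oracle <- stencil_step_oracle(st$u, st$v, a, g,
                                kin$D, kin$b, kin$c, grid$dx, kin$dt)
  expect_equal(stepped$u, oracle$u, tolerance = 1e-14)
  expect_equal(stepped$v, oracle$v, tolerance = 1e-14)
})

test_that("compiled integrator reproduces repeated R reference steps", {
  set.seed(11)
  m <- small_model(L = 5, dx = 0.1, dt = 1e-4)
  st <- ligand_state(m$grid, runif(m$grid$n_points), runif(m$grid$n_points))
  r_state <- st
  for (i in 1:50)
    r_state <- step_forward(r_state, m$grid, m$kin, m$binding, m$source)
  sim <- simulate_ligand(m$grid, m$kin, m$binding, m$source,
                         t_end = 50 * m$kin$dt, record_every = 50 * m$kin$dt,
                         init = st)
  f <- final_state(sim)
  expect_equal(f$u, r_state$u, tolerance = 1e-12)
  expect_equal(f$v, r_state$v, tolerance = 1e-12)
})

test_that("trivial fixed points are preserved", {
  m <- small_model()
  zero_src <- list(g = numeric(m$grid$n_points))
  st <- ligand_state(m$grid)
  s1 <- step_forward(st, m$grid, m$kin, m$binding, zero_src)
  expect_true(all(s1$u == 0) && all(s1$v == 0))
  # constant u with no binding/exchange: Laplacian of a constant is 0
  kin0 <- kinetic_params(D = 20, b = 0, c = 0, g_max = 0, R = 1, dt = 1e-4)
  bp0 <- binding_profile(m$grid, "zero")
  stc <- ligand_state(m$grid, u = rep(3, m$grid$n_points))
  s2 <- step_forward(stc, m$grid, kin0, bp0, zero_src)
  expect_equal(s2$u, rep(3, m$grid$n_points))
})

test_that("stability violations are refused with the stability number named", {
  grid <- spatial_grid(10, 0.1)
  kin <- kinetic_params(D = 20, dt = 1e-3)  # D*dt/dx^2 = 2
  expect_error(simulate_ligand(grid, kin, binding_profile(grid, "zero"),
                               t_end = 1), "D\\*dt/dx\\^2 = 2")
})

test_that("mass is conserved without production and internalization", {
  grid <- spatial_grid(50, 0.1)
  kin <- kinetic_params(D = 20, b = 0.1, c = 0, g_max = 0, R = 1, dt = 1e-4)
  binding <- binding_profile(grid, "periodic", a_max = 10)
  init <- ligand_state(grid, u = exp(-(grid$x - 25)^2 / 5))
  sim <- simulate_ligand(grid, kin, binding, source = NULL,
                         t_end = 10, record_every = 1, init = init)
  m0 <- sum(total_mass(final_state(sim, 1), grid))
  masses <- vapply(seq_along(sim$times),
                   function(i) sum(total_mass(final_state(sim, i), grid)),
                   numeric(1))
  expect_lt(max(abs(masses - m0)) / m0, 1e-6)
})

test_that("fields stay non-negative under the stability condition", {
  run <- scenario_run("baseline")
  expect_true(all(run$sim$U >= 0))
  expect_true(all(run$sim$V >= 0))
})

test_that("step-halving leaves the final fields essentially unchanged", {
  m <- small_model(L = 30, dt = 2e-4)
  sim1 <- simulate_ligand(m$grid, m$kin, m$binding, m$source,
                          t_end = 2, record_every = 2)
  kin2 <- kinetic_params(D = 20, b = 0.1, c = 0.1, g_max = 0.2, R = 1,
                         dt = 1e-4)
  sim2 <- simulate_ligand(m$grid, kin2, m$binding, m$source,
                          t_end = 2, record_every = 2)
  f1 <- final_state(sim1); f2 <- final_state(sim2)
  expect_equal(f1$v, f2$v, tolerance = 1e-3)
  expect_lt(max(abs(f1$u - f2$u)) / max(f2$u), 1e-3)
})

test_that("integrator agrees with an independent stiff ODE solver on a small grid", {
  skip_if_not_installed("deSolve")
  m <- small_model(L = 10, dx = 0.2, dt = 1e-4)
  n <- m$grid$n_points
  rhs <- function(t, y, parms) {
    u <- y[1:n]; v <- y[(n + 1):(2 * n)]
    lap <- c(2 * (u[2] - u[1]),
             u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n],
             2 * (u[n - 1] - u[n])) / m$grid$dx^2
    du <- m$kin$D * lap - m$binding$a * u + m$kin$b * v + m$source$g
    dv <- m$binding$a * u - (m$kin$b + m$kin$c) * v
    list(c(du, dv))
  }
  ode_out <- deSolve::lsoda(y = numeric(2 * n), times = c(0, 1), func = rhs,
                            parms = NULL, rtol = 1e-9, atol = 1e-12)
  sim <- simulate_ligand(m$grid, m$kin, m$binding, m$source,
                         t_end = 1, record_every = 1)
  f <- final_state(sim)
  expect_equal(f$u, unname(ode_out[2, 2:(n + 1)]), tolerance = 1e-4)
  expect_equal(f$v, unname(ode_out[2, (n + 2):(2 * n + 1)]), tolerance = 1e-4)
})

test_that("steady-state detection distinguishes transient from equilibrated runs", {
  run <- scenario_run("baseline")
  expect_true(check_steady_state(run$sim, c(90, 100), tol = 1e-2)$steady)
  expect_false(check_steady_state(run$sim, c(0, 10), tol = 1e-2)$steady)
  # identical snapshots: exactly steady
  sim2 <- run$sim
  sim2$U[1, ] <- sim2$U[2, ]; sim2$V[1, ] <- sim2$V[2, ]
  chk <- check_steady_state(sim2, c(sim2$times[1], sim2$times[2]))
  expect_true(chk$steady)
  expect_equal(chk$max_rel_change, 0)
  expect_error(check_steady_state(run$sim, c(1, 2)), "two recorded snapshots")
})

test_that("production balances internalization at steady state", {
  run <- scenario_run("baseline")
  f <- final_state(run$sim)
  kin <- run$sim$kin; grid <- run$sim$grid
  influx <- kin$g_max * kin$R
  outflux <- kin$c * trapz_oracle(f$v, grid$dx)
  expect_equal(outflux / influx, 1, tolerance = 0.02)
})

test_that("total_mass computes trapezoidal integrals", {
  grid <- spatial_grid(1000, 0.1)
  st <- ligand_state(grid, u = rep(1, grid$n_points))
  m <- total_mass(st, grid)
  expect_equal(unname(m["mass_u"]), 1000)
  expect_equal(unname(m["mass_v"]), 0)
  expect_equal(unname(total_mass(ligand_state(grid), grid)), c(0, 0))
})

test_that("photoconversion labels evolve correctly", {
  m <- small_model(L = 30, dx = 0.1, dt = 1e-4)
  base <- simulate_ligand(m$grid, m$kin, m$binding, m$source,
                          t_end = 20, record_every = 20)
  steady <- final_state(base)

  # labelled mass strictly decreases under internalization
  pc <- simulate_photoconversion(steady, c(2, 6), m$grid, m$kin, m$binding,
                                 m$source, t_end = 5, record_every = 1)
  lab_mass <- vapply(seq_along(pc$times), function(i) {
    st <- ligand_state(m$grid, pc$U_lab[i, ], pc$V_lab[i, ])
    sum(total_mass(st, m$grid))
  }, numeric(1))
  expect_true(all(diff(lab_mass) < 0))
  # labelled never exceeds total
  expect_true(all(pc$U_lab <= pc$U_tot + 1e-12))
  expect_true(all(pc$V_lab <= pc$V_tot + 1e-12))

  # labelling a region where u = v = 0 keeps the labels at zero for all time
  st_compact <- ligand_state(m$grid, u = ifelse(m$grid$x < 5, 1, 0))
  pc0 <- simulate_photoconversion(st_compact, c(25, 29), m$grid, m$kin,
                                  m$binding, m$source,
                                  t_end = 0.5, record_every = 0.5)
  expect_true(all(pc0$U_lab == 0) && all(pc0$V_lab == 0))

  # no exchange, no internalization: bound label is frozen
  kin_frozen <- kinetic_params(D = 20, b = 0, c = 0, g_max = 0.2, R = 1,
                               dt = 1e-4)
  st0 <- ligand_state(m$grid, u = numeric(m$grid$n_points),
                      v = exp(-m$grid$x / 5))
  pcf <- simulate_photoconversion(st0, c(0, 30), m$grid, kin_frozen,
                                  binding_profile(m$grid, "zero"),
                                  m$source, t_end = 1, record_every = 1)
  expect_equal(pcf$V_lab[2, ], pcf$V_lab[1, ], tolerance = 1e-12)

  expect_error(simulate_photoconversion(steady, c(-5, 2), m$grid, m$kin,
                                        m$binding, m$source, t_end = 1),
               "outside")
})
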