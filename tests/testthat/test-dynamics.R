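mkstate <- function(u) structure(list(u = u, time = 0), class = "pcp_state")

test_that("unbound pools implement perimeter-averaged depletion", {
  t <- hex44
  p <- model_params()
  # empty membrane: full pools
  pl <- unbound_pools(mkstate(rep(0, t$n_he)), t, p)
  expect_equal(pl$f_ubd, rep(1, t$n_cells))
  expect_equal(pl$g_ubd, rep(1, t$n_cells))
  # uniform loading u = 0.05 on unit junctions: mean bound = 0.05
  pl <- unbound_pools(mkstate(rep(0.05, t$n_he)), t, p)
  expect_equal(pl$f_ubd, rep(0.95, t$n_cells), tolerance = 1e-12)
  # conservation identity at an arbitrary state
  set.seed(2)
  u <- runif(t$n_he, 0, 0.4)
  pl <- unbound_pools(mkstate(u), t, p)
  len <- t$he_length
  for (ci in c(1, 9)) {
    he <- t$cell_he[[ci]]
    expect_equal(pl$f_ubd[ci] + sum(u[he] * len[he]) / sum(len[he]), 1,
                 tolerance = 1e-12)
  }
})

test_that("drift has the empty-membrane rate and F-G swap symmetry", {
  t <- hex66
  p <- model_params(f0 = 0.8, g0 = 0.6, alpha = 4, beta = 7, eta0 = 0)
  op <- assemble_operator(t, p$lambda_u, p$lambda_d)
  d0 <- drift(mkstate(rep(0, t$n_he)), t, op, p)
  expect_equal(d0, rep(p$kappa * p$f0 * p$g0, t$n_he), tolerance = 1e-12)

  # swapping the two protein species maps the drift onto itself:
  # (f0, g0) -> (g0, f0) together with u -> v (= u on opposite half-edges)
  set.seed(4)
  u <- runif(t$n_he, 0, 0.25)
  ps <- p; ps$f0 <- p$g0; ps$g0 <- p$f0
  d1 <- drift(mkstate(u), t, op, p)
  d2 <- drift(mkstate(u[t$he_opp]), t, op, ps)
  expect_equal(d2, d1[t$he_opp], tolerance = 1e-12)
})

test_that("the uniform symmetric state is a fixed point of the drift", {
  t <- hex44
  p <- model_params(eta0 = 0)
  op <- assemble_operator(t, 0.5)
  # independent scalar root of the uniform balance
  us <- uniroot(function(u) {
    up <- 1 + p$alpha * u
    p$kappa * (p$f0 - u) * (p$g0 - u) * up - p$gamma * u * (1 + p$beta * u) / up
  }, c(0, min(p$f0, p$g0) - 1e-9), tol = 1e-14)$root
  d <- drift(mkstate(rep(us, t$n_he)), t, op, p)
  expect_lt(max(abs(d)), 1e-10)
})

test_that("noise-free integration matches an adaptive ODE solver", {
  t <- build_hexagonal(2, 2)
  p <- model_params(eta0 = 0)
  op <- assemble_operator(t, 0.5)
  ic <- init_state(t, "random", 0.4, seed = 6)
  tr <- simulate(t, p, ic, Tend = 10, seed = 1, record_every = 10,
                 check_steady = FALSE)
  ref <- deSolve::ode(
    y = ic$u, times = c(0, 10),
    func = function(tm, y, parms)
      list(drift(mkstate(y), t, op, p)),
    method = "lsoda", rtol = 1e-10, atol = 1e-12)
  uref <- as.numeric(ref[2, -1])
  uend <- tr$U[nrow(tr$U), ]
  expect_lt(max(abs(uend - uref)) / max(abs(uref)), 1e-6)
})

test_that("the integrator converges at fourth order", {
  t <- build_hexagonal(2, 2)
  op <- assemble_operator(t, 0.5)
  ic <- init_state(t, "random", 0.4, seed = 8)
  endstate <- function(dt) {
    p <- model_params(eta0 = 0, dt = dt)
    tr <- simulate(t, p, ic, Tend = 2, seed = 1, record_every = 2,
                   check_steady = FALSE)
    tr$U[nrow(tr$U), ]
  }
  uref <- endstate(2e-4)
  e1 <- max(abs(endstate(4e-3) - uref))
  e2 <- max(abs(endstate(2e-3) - uref))
  expect_gt(e1 / e2, 10)   # ~16 for a 4th-order scheme
  expect_lt(e1 / e2, 25)
})

test_that("additive noise has the Euler-Maruyama variance scaling", {
  t <- hex66
  # negligible drift: variance of u grows as eta0^2 * n * dt
  p <- model_params(kappa = 1e-9, gamma = 1e-9, eta0 = 0.1, alpha = 0, beta = 0)
  ic <- mkstate(rep(5, t$n_he))
  nst <- 200
  tr <- simulate(t, p, ic, Tend = nst * p$dt, seed = 33,
                 record_every = nst * p$dt, check_steady = FALSE)
  dev <- tr$U[nrow(tr$U), ] - 5
  expect_equal(mean(dev^2), p$eta0^2 * nst * p$dt, tolerance = 0.25)
})

test_that("simulations are reproducible and seeds matter", {
  t <- hex44
  p <- model_params()
  ic <- init_state(t, "random", 0.5, seed = 2)
  t1 <- simulate(t, p, ic, Tend = 1, seed = 7, check_steady = FALSE)
  t2 <- simulate(t, p, ic, Tend = 1, seed = 7, check_steady = FALSE)
  t3 <- simulate(t, p, ic, Tend = 1, seed = 8, check_steady = FALSE)
  expect_identical(t1$U, t2$U)
  expect_gt(max(abs(t1$U - t3$U)), 0)
  # init_state reproducibility
  expect_identical(init_state(t, "random", 0.5, seed = 2)$u, ic$u)
  expect_gt(max(abs(init_state(t, "random", 0.5, seed = 3)$u - ic$u)), 0)
})

test_that("initial-condition modes have the advertised structure", {
  t <- hex66
  pol <- init_state(t, "polarized", 0.4, direction = c(1, 0))
  d <- cell_dipoles(pol, t)
  expect_true(all(abs(((d$phi_ip + 180) %% 360) - 180) < 15))

  alt <- init_state(t, "alternating", 0.3)
  da <- cell_dipoles(alt, t)
  expect_lt(max(da$mag), 1e-6)
  jp <- abs(alt$u - alt$u[t$he_opp])
  expect_gt(min(jp), 0.1)   # junctions polarized although cells are not

  expect_error(suppressWarnings(init_state(t, "random", amplitude = 5)),
               "overdraw")
})

test_that("the alternating zero-net-polarity pattern is unstable", {
  t <- hex44
  p <- model_params(eta0 = 1e-3)
  ic <- init_state(t, "alternating", 0.3)
  q0 <- order_parameters(cell_dipoles(ic, t))$Qbar
  tr <- simulate(t, p, ic, Tend = 60, seed = 5, check_steady = FALSE)
  qT <- tr$Qbar[length(tr$Qbar)]
  expect_lt(q0, 1e-6)
  expect_gt(qT, 0.5)   # infinitesimal noise destroys the intermixed state
})

test_that("noise-free dynamics are equivariant under a quarter turn", {
  d <- disordered(6, 6, 0.3, 12)
  r <- rotate_tissue_90(d)
  p <- model_params(eta0 = 0)
  ic <- init_state(d, "polarized", 0.4, direction = c(1, 1))
  icr <- init_state(r, "polarized", 0.4, direction = c(-1, 1))
  trd <- simulate(d, p, ic, Tend = 15, seed = 1, check_steady = FALSE)
  trr <- simulate(r, p, icr, Tend = 15, seed = 1, check_steady = FALSE)
  od <- order_parameters(cell_dipoles(state_at(trd), d))
  orr <- order_parameters(cell_dipoles(state_at(trr), r))
  expect_equal(orr$Qbar, od$Qbar, tolerance = 1e-6)
  expect_equal((orr$phi_mean - od$phi_mean) %% 360, 90, tolerance = 0.5)
})

test_that("pools stay solvent along noise-free trajectories", {
  t <- hex44
  p <- model_params(eta0 = 0)
  ic <- init_state(t, "random", 0.5, seed = 9)
  tr <- simulate(t, p, ic, Tend = 30, seed = 1, record_every = 1,
                 check_steady = FALSE)
  for (i in seq_along(tr$times)) {
    pl <- unbound_pools(state_at(tr, i), t, p)
    expect_true(all(pl$f_ubd >= 0) && all(pl$g_ubd >= 0))
    expect_true(all(pl$f_ubd <= p$f0 + 1e-12))
  }
})

test_that("boundary cues clamp a strip and bulk cues orient the tissue", {
  t <- hex66
  p <- model_params(eta0 = 0)
  cue <- cue_schedule("boundary", direction = c(1, 0), depth = 2)
  tr <- simulate(t, p, init_state(t, "random", 0.3, seed = 3), cue = cue,
                 Tend = 5, seed = 1, record_every = 1, check_steady = FALSE)
  bc <- pcpsim:::boundary_clamp(t, cue, amplitude = 0.5)
  expect_equal(tr$U[3, bc$he], bc$value, tolerance = 1e-12)
  expect_equal(tr$U[6, bc$he], bc$value, tolerance = 1e-12)

  cueb <- cue_schedule("bulk", direction = c(0, 1), M = 3, tau_m = Inf)
  trb <- simulate(t, p, init_state(t, "random", 0.3, seed = 3), cue = cueb,
                  Tend = 40, seed = 1, check_steady = FALSE)
  o <- order_parameters(cell_dipoles(state_at(trb), t))
  expect_lt(pcpsim:::fold_axial(o$phi_mean - 90), 15)
  expect_equal((o$phi_mean) %% 360, 90, tolerance = 15)
})
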