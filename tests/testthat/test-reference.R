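test_that("reference solver reproduces the closed-form annulus solution", {
  p <- ox_params()
  s <- ox_sources(120, 120, r = 4.8, cv = 137, keff = 2000)
  Rout <- 100
  ref <- solve_reference(240, s, p,
                         outer_circle = list(x = 120, y = 120, radius = Rout,
                                             value = 0))
  q_exact <- 2000 * 137 / (1 + 2000 * log(Rout / 4.8) / (2 * pi * 2000))
  expect_equal(ref$q, q_exact, tolerance = 1e-10)
  ## field matches the log profile at interior radii
  r <- c(10, 30, 70)
  phi_exact <- q_exact / (2 * pi * p$D) * log(Rout / r)
  expect_equal(ref$phi(120 + r, rep(120, 3)), phi_exact, tolerance = 1e-10)
})

test_that("reference without sources returns the uniform Dirichlet field", {
  ref <- solve_reference(240, ox_sources(numeric(0), numeric(0)), ox_params(),
                         bc = ox_bc(values = list(3)))
  expect_equal(ref$q, numeric(0))
  expect_equal(ref$phi(c(10, 200), c(5, 100)), c(3, 3))
})

test_that("reference fluxes are stable under basis refinement", {
  p <- ox_params()
  s <- ox_sources(120, 120, r = 4.8, cv = 137, keff = 2000)
  for (bc in list(ox_bc(values = list(0)), bench_bc())) {
    ref <- solve_reference(240, s, p, bc = bc)
    expect_lt(ref$refine, 1e-3)
    expect_lt(ref$bc_residual, 1e-8)
  }
})

test_that("periodic reference basis is harmonic, periodic and conservative", {
  p <- ox_params(); L <- 240
  s <- ox_sources(c(80, 160), c(100, 140), r = 4.8, cv = c(137, 0),
                  keff = 2000)
  bas <- oxsplit2d:::periodic_basis(s, L, K = 4)
  dl <- 0.01
  for (cidx in c(2L, 3L, 6L)) {
    vv <- function(x, y) bas$val(x, y)[, cidx]
    lap <- (vv(30 + dl, 55) + vv(30 - dl, 55) + vv(30, 55 + dl) +
            vv(30, 55 - dl) - 4 * vv(30, 55)) / dl^2
    expect_lt(abs(lap), 1e-6)
    expect_equal(vv(30 + L, 55), vv(30, 55), tolerance = 1e-12)
    expect_equal(vv(30, 55 - L), vv(30, 55), tolerance = 1e-12)
    ## analytic gradient against finite differences
    gx <- (vv(30 + dl, 55) - vv(30 - dl, 55)) / (2 * dl)
    expect_equal(bas$dx(30, 55)[, cidx], gx, tolerance = 1e-6)
  }
  ref <- solve_reference(L, s, p, bc = periodic_bc(), K = 10)
  expect_lt(abs(sum(ref$q)) / sum(abs(ref$q)), 1e-12)
  expect_lt(ref$bc_residual, 1e-8)
})

test_that("slab (periodic-x) reference basis gradients are consistent", {
  s <- ox_sources(120, 120, r = 4.8, cv = 137, keff = 2000)
  bas <- oxsplit2d:::slab_basis(s, 240, K = 4, Mf = 3)
  dl <- 0.01
  for (cidx in c(2L, 5L, 15L, 17L)) {
    vv <- function(x, y) bas$val(x, y)[, cidx]
    gx <- (vv(70 + dl, 95) - vv(70 - dl, 95)) / (2 * dl)
    gy <- (vv(70, 95 + dl) - vv(70, 95 - dl)) / (2 * dl)
    expect_equal(bas$dx(70, 95)[, cidx], gx, tolerance = 1e-6)
    expect_equal(bas$dy(70, 95)[, cidx], gy, tolerance = 1e-6)
    expect_equal(vv(70 + 240, 95), vv(70, 95), tolerance = 1e-12)
  }
})

test_that("fast Poisson solver components are correct", {
  ## DST-I via FFT against the direct O(n^2) transform
  v <- sin(1:7) + 0.3 * cos((1:7)^2)
  direct <- vapply(1:7, function(k) sum(v * sin(pi * (1:7) * k / 8)),
                   numeric(1))
  expect_equal(as.vector(oxsplit2d:::dst1_mat(matrix(v, ncol = 1))), direct,
               tolerance = 1e-12)
  ## manufactured Poisson problem: phi = sin(pi x/L) sin(2 pi y/L)
  L <- 2; N <- 64L; hf <- L / N
  xg <- seq(hf, L - hf, by = hf)
  u_exact <- outer(xg, xg, function(x, y) sin(pi * x / L) * sin(2 * pi * y / L))
  lam <- -(pi / L)^2 - (2 * pi / L)^2
  ## discrete RHS uses the 5-point Laplacian eigenvalue for an exact match
  lam_h <- -(2 - 2 * cos(pi / N)) / hf^2 - (2 - 2 * cos(2 * pi / N)) / hf^2
  f <- lam_h * u_exact
  u <- oxsplit2d:::poisson_dirichlet_fft(f, hf)
  expect_equal(u, u_exact, tolerance = 1e-10)
})

test_that("Peaceman flux reduces to the bare coupling at R = 0.2 h", {
  q <- peaceman_flux(cv = 137, phi_k = 60, keff = 2000, D = 2000,
                     R = 0.2 * 48, h = 48)
  expect_equal(q, 2000 * (137 - 60))
  expect_equal(peaceman_flux(137, 60, 1e-12, 2000, 4.8, 48), 0,
               tolerance = 1e-6)
  expect_equal(peaceman_flux(100, 20, 1500, 1800, 4, 50),
               1500 * 80 / (1 + 1500 / (2 * pi * 1800) * log(4 / 10)))
})

test_that("error metrics are zero at equality and scale as expected", {
  cfg <- single_source_config()
  fit <- ox_solve(cfg$grid, cfg$sources, cfg$params, n = 3)
  fake <- list(q = fit$q, wall = wall_average(fit),
               phi = function(x, y) interpolate_concentration(fit, x, y))
  em <- error_metrics(fit, fake)
  expect_equal(em$eps_q_g, 0, tolerance = 1e-12)
  expect_equal(em$eps_phi_g, 0, tolerance = 1e-9)
  fake2 <- fake; fake2$q <- fit$q / 2
  expect_equal(error_metrics(fit, fake2)$eps_q, 1)
  expect_error(error_metrics(ox_solve(cfg$grid,
                                      ox_sources(numeric(0), numeric(0)),
                                      cfg$params), fake), "do not match")
})

test_that("reactive reference agrees with the linear one as M -> 0", {
  p0 <- ox_params(); s <- ox_sources(120, 120, r = 4.8, cv = 137, keff = 2000)
  bc <- ox_bc(values = list(68.5))
  lin <- solve_reference(240, s, p0, bc = bc)
  rea <- solve_reference(240, s, ox_params(M = 1e-6), bc = bc, fine_n = 128L)
  expect_equal(rea$q, lin$q, tolerance = 1e-5)
})
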