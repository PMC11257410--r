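test_that("single-source potential matches its closed form", {
  D <- 2000
  s <- ox_sources(0, 0, r = 1, cv = 137, keff = 2000)
  ## q = 2 pi D at distance e R gives exactly -1
  expect_equal(source_potential(s, 2 * pi * D, exp(1), 0, D), -1)
  ## zero on the wall and inside the disk
  expect_equal(source_potential(s, 5e4, 1, 0, D), 0)
  expect_equal(source_potential(s, 5e4, 0.3, 0.2, D), 0)
  expect_equal(source_potential(s, 0, 3, 4, D), 0)
})

test_that("rapid-field gradient matches central finite differences", {
  cfg <- single_source_config()
  fit <- ox_solve(cfg$grid, cfg$sources, cfg$params, n = 3)
  k <- locate_cell(cfg$grid, 120, 120)
  del <- 1e-4
  for (pt in list(c(135, 128), c(100, 95))) {
    rf <- rapid_field(fit, k, pt[1], pt[2])
    fx <- (rapid_field(fit, k, pt[1] + del, pt[2])$val -
           rapid_field(fit, k, pt[1] - del, pt[2])$val) / (2 * del)
    fy <- (rapid_field(fit, k, pt[1], pt[2] + del)$val -
           rapid_field(fit, k, pt[1], pt[2] - del)$val) / (2 * del)
    expect_equal(rf$gx, fx, tolerance = 1e-6)
    expect_equal(rf$gy, fy, tolerance = 1e-6)
  }
  ## empty neighborhood: zero field and gradient
  rf0 <- rapid_field(fit, 1L, 30, 30)
  expect_identical(c(rf0$val, rf0$gx, rf0$gy), c(0, 0, 0))
})

test_that("potentials are harmonic away from their disk", {
  D <- 2000
  del <- 0.05
  for (pt in list(c(10, 3), c(-6, 8), c(2, -15))) {
    lap <- (oxsplit2d:::pot_val(pt[1] + del, pt[2], 0, 0, 4.8, D) +
            oxsplit2d:::pot_val(pt[1] - del, pt[2], 0, 0, 4.8, D) +
            oxsplit2d:::pot_val(pt[1], pt[2] + del, 0, 0, 4.8, D) +
            oxsplit2d:::pot_val(pt[1], pt[2] - del, 0, 0, 4.8, D) -
            4 * oxsplit2d:::pot_val(pt[1], pt[2], 0, 0, 4.8, D)) / del^2
    expect_lt(abs(lap), 1e-8)
  }
})

test_that("an external potential carries zero net flux through a closed wall", {
  ## conservativeness of the localization perturbation: for source i and a
  ## potential centered at another source j, the wall integral of the normal
  ## gradient vanishes (harmonic, singularity outside the disk)
  D <- 2000
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  R <- 4.8
  xi <- 100; yi <- 80        # wall of source i
  xj <- 131; yj <- 97        # external singularity
  gr <- oxsplit2d:::pot_grad(xi + R * cos(th), yi + R * sin(th), xj, yj,
                             4.8, D)
  flux <- mean(gr$gx * cos(th) + gr$gy * sin(th)) * 2 * pi * R
  expect_lt(abs(flux) / (1 / (2 * pi * D)), 1e-10)
})

test_that("face jumps vanish for identical rapid fields and flip sign correctly", {
  cfg <- single_source_config()
  g <- cfg$grid
  nb <- build_neighborhoods(g, cfg$sources, 3)
  D <- cfg$params$D
  ## face between two block cells (identical source sets): zero jump
  expect_equal(face_jump(g, cfg$sources, nb, 12, 13,
                         c(96, 96), c(96, 144), c(1, 0), D = D),
               0)
  ## face between block cell 9 (ix=4,iy=2) and outside cell 10: nonzero.
  ## Exchanging the cells keeps the flux half (two sign flips) and negates
  ## the value half: J_km + J_mk = int n.(grad r_m - grad r_k) dl and
  ## J_km - J_mk = (2/h) int (r_m - r_k) dl
  jkm <- face_jump(g, cfg$sources, nb, 9, 10,
                   c(192, 48), c(192, 96), c(1, 0), D = D)
  jmk <- face_jump(g, cfg$sources, nb, 10, 9,
                   c(192, 48), c(192, 96), c(-1, 0), D = D)
  expect_gt(abs(jkm), 0)
  fk <- oxsplit2d:::face_integrals(cfg$sources, nb$cell_sources[[9]],
                                   c(192, 48), c(192, 96), c(1, 0), D)
  expect_equal(jkm + jmk, -fk$flx, tolerance = 1e-10)
  expect_equal(jkm - jmk, -2 * fk$avg, tolerance = 1e-10)
  ## no sources anywhere: zero
  s0 <- ox_sources(numeric(0), numeric(0))
  nb0 <- build_neighborhoods(g, s0, 3)
  expect_length(face_jump(g, s0, nb0, 12, 13,
                          c(96, 96), c(96, 144), c(1, 0), D = D), 0)
})

test_that("face integrals agree with adaptive quadrature", {
  D <- 2000
  s <- ox_sources(120, 120, r = 4.8, cv = 137, keff = 2000)
  cs <- data.frame(j = 1L, ox = 0, oy = 0)
  p0 <- c(144, 96); p1 <- c(144, 144)   # face near the source
  fi <- oxsplit2d:::face_integrals(s, cs, p0, p1, c(1, 0), D)
  g_int <- stats::integrate(function(t)
    oxsplit2d:::pot_val(rep(144, length(t)), t, 120, 120, 4.8, D), 96, 144,
    rel.tol = 1e-12)$value
  f_int <- stats::integrate(function(t)
    oxsplit2d:::pot_grad(rep(144, length(t)), t, 120, 120, 4.8, D)$gx,
    96, 144, rel.tol = 1e-12)$value
  expect_equal(fi$avg, g_int / 48, tolerance = 1e-8)
  expect_equal(fi$flx, f_int, tolerance = 1e-8)
})

test_that("localization bound scales as 1/(n-1)^2 and vanishes inside", {
  expect_equal(localization_error_bound(numeric(0), 2000, 5), 0)
  b3 <- localization_error_bound(c(1e5, -5e4), 2000, 3)
  b5 <- localization_error_bound(c(1e5, -5e4), 2000, 5)
  expect_gt(b3, 0)
  expect_equal(b3 / b5, ((5 - 1) / (3 - 1))^2)
})
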