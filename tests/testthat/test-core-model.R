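test_that("grid construction gives square cells and rejects degenerate grids", {
  g <- ox_grid(240, 5)
  expect_equal(g$h, 48)
  expect_equal(g$F, 25L)
  expect_equal(g$cx[13], 120)  # central cell center
  expect_error(ox_grid(240, 1), "at least 3")
  expect_error(ox_bc(left = "periodic"), "opposite pairs")
  expect_error(ox_bc(left = "robin"), "must be one of")
})

test_that("cell ownership is half-open and partitions the domain", {
  g <- ox_grid(240, 5)
  ## cell centers map to their own cell
  expect_equal(locate_cell(g, g$cx, g$cy), seq_len(g$F))
  ## a point exactly on an interior face belongs to the +x / +y cell
  expect_equal(locate_cell(g, 48, 10), 2L)
  expect_equal(locate_cell(g, 10, 48), 6L)
  expect_error(locate_cell(g, -5, 10), "outside")
  ## periodic wrap: shifting by one period gives the same cell
  gp <- ox_grid(240, 8, periodic_bc())
  pts <- cbind(runif(20, 0, 240), runif(20, 0, 240))
  expect_equal(locate_cell(gp, pts[, 1] + 240, pts[, 2] - 240),
               locate_cell(gp, pts[, 1], pts[, 2]))
})

test_that("neighborhood blocks cover n x n cells, clip and wrap correctly", {
  cfg <- single_source_config()
  nb <- build_neighborhoods(cfg$grid, cfg$sources, n = 3)
  members <- which(vapply(nb$cell_sources, nrow, integer(1)) > 0)
  ## 9 central cells carry the source, none else
  expect_length(members, 9L)
  expect_setequal(members, as.vector(outer(7:9, c(0, 5, 10), "+")))
  expect_error(build_neighborhoods(cfg$grid, cfg$sources, n = 2), ">= 3")
  expect_error(build_neighborhoods(cfg$grid, cfg$sources, n = 7),
               "cannot exceed")
  ## two sources: overlap cells carry both potentials
  s2 <- ox_sources(c(96, 144), c(120, 120), r = 4.8, cv = c(0, 137),
                   keff = 2000)
  nb2 <- build_neighborhoods(cfg$grid, s2, n = 3)
  both <- which(vapply(nb2$cell_sources, nrow, integer(1)) == 2L)
  expect_true(length(both) > 0)
  expect_equal(nb2$cell_sources[[both[1]]]$j, c(1L, 2L))
  ## periodic corner block wraps across all four corners
  gp <- ox_grid(240, 8, periodic_bc())
  sc <- ox_sources(15, 15, r = 4.8, cv = 137, keff = 2000)
  nbp <- build_neighborhoods(gp, sc, n = 3)
  corners <- c(cell_id(gp, 1L, 1L), cell_id(gp, 8L, 1L),
               cell_id(gp, 1L, 8L), cell_id(gp, 8L, 8L))
  expect_true(all(vapply(nbp$cell_sources[corners], nrow, integer(1)) == 1L))
  ## the wrapped members see the source through a shifted periodic image
  far <- nbp$cell_sources[[cell_id(gp, 8L, 8L)]]
  expect_equal(c(far$ox, far$oy), c(240, 240))
})

test_that("neighborhood membership is symmetric with block membership", {
  gp <- ox_grid(240, 8, periodic_bc())
  set.seed(3)
  xy <- sample_hardcore_sources(240, 6, min_sep = 30, periodic = TRUE,
                                seed = 3)
  s <- ox_sources(xy[, 1], xy[, 2], r = 4.8, cv = 137, keff = 2000)
  nb <- build_neighborhoods(gp, s, n = 5)
  for (j in seq_len(6)) {
    for (k in seq_len(gp$F)) {
      in_E <- j %in% nb$cell_sources[[k]]$j
      in_block <- k %in% nb$blocks[[j]]
      expect_identical(in_E, in_block)
    }
  }
})

test_that("effective exchange coefficient follows the wall/lumen composition", {
  Db <- 1400
  ## infinitely permeable wall: the intravascular limit 8 pi D_beta
  expect_equal(effective_permeability(Db, 1e12, 4.8), 8 * pi * Db,
               tolerance = 1e-8)
  ## 4 D_beta / (K_m R) = 1 halves the limit
  R <- 4.8; Km <- 4 * Db / R
  expect_equal(effective_permeability(Db, Km, R), 4 * pi * Db)
  ## generic case against direct evaluation of the formula
  expect_equal(effective_permeability(1000, 25, 3),
               8 * pi * 1000 / (1 + 4 * 1000 / (25 * 3)))
  expect_error(effective_permeability(-1, 1, 1), "positive")
})

test_that("layer table carries the laminar study constants", {
  lt <- layer_table()
  expect_equal(lt$e2dsd, c(250, 325, 400, 475))
  expect_equal(lt$cld, c(0.8, 0.94, 1.08, 1.2))
  expect_equal(lt$phi_cap_ratio, c(0.4, 0.45, 0.5, 0.55))
  ## PA concentration of layer I is the reference arteriolar inlet value
  expect_equal(lt$po2_pa[1] * ox_params()$alpha, 137.61, tolerance = 1e-6)
})

test_that("hard-core sampling honors separation, exclusion and the seed", {
  expect_equal(nrow(sample_hardcore_sources(240, 0)), 0L)
  xy <- sample_hardcore_sources(240, 17, min_sep = 25, periodic = TRUE,
                                seed = 5)
  expect_equal(nrow(xy), 17L)
  dx <- abs(outer(xy[, 1], xy[, 1], "-")); dx <- pmin(dx, 240 - dx)
  dy <- abs(outer(xy[, 2], xy[, 2], "-")); dy <- pmin(dy, 240 - dy)
  dd <- sqrt(dx^2 + dy^2); diag(dd) <- Inf
  expect_gte(min(dd), 25)
  ## exclusion region stays empty
  xye <- sample_hardcore_sources(400, 30, min_sep = 25,
                                 exclusion = list(x = 200, y = 200, r = 100),
                                 periodic = TRUE, seed = 6)
  expect_gte(min(sqrt((xye[, 1] - 200)^2 + (xye[, 2] - 200)^2)), 100)
  ## reproducible
  expect_identical(xy, sample_hardcore_sources(240, 17, min_sep = 25,
                                               periodic = TRUE, seed = 5))
  ## infeasible packing errors out
  expect_error(sample_hardcore_sources(50, 100, min_sep = 25, seed = 1,
                                       max_tries = 2000), "infeasible")
})

test_that("sources are validated against the domain", {
  g <- ox_grid(240, 5)
  expect_error(validate_ok <- oxsplit2d:::validate_sources(
    g, ox_sources(2, 120, r = 4.8, cv = 137, keff = 2000)), "crosses")
  expect_error(oxsplit2d:::validate_sources(
    g, ox_sources(c(120, 125), c(120, 120), r = 4.8, cv = 137, keff = 2000)),
    "overlap")
  expect_error(ox_sources(1, 1, r = -1), "positive")
})
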