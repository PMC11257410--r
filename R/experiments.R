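## ---- benchmark drivers --------------------------------------------------------
##
## Every driver is reproducible from (configuration, seed) and returns plain
## data.frames carrying the seeds and parameter values it used.

## the single-source benchmark boundary conditions: a genuine combination of
## the three kinds (periodic left/right, Dirichlet bottom at phi_max/2,
## zero-flux top). Relative flux errors are invariant to the Dirichlet level
## for the linear problem; the mid-range level keeps reference concentrations
## O(phi_max) so relative concentration errors are meaningful.
benchmark_bc <- function(phi_d = 68.5) {
  ox_bc(left = "periodic", right = "periodic", bottom = "dirichlet",
        top = "neumann", values = list(bottom = phi_d))
}

## neighborhood size giving an analytic region of extent ~ `extent` um
n_for_extent <- function(h, cells, extent = 144) {
  max(3L, min(as.integer(cells), as.integer(round(extent / h))))
}

#' Single-source grid-size sweep
#'
#' Sweeps the coarse-grid resolution for a single vessel whose center is
#' snapped to the center of the cell containing the domain center, and
#' compares the multiscale model and the coarse-grid FV baseline against the
#' resolved reference. The neighborhood extent is held at ~30 R.
#'
#' @param cells_list cells per side for each grid (h/L = 1/cells).
#' @param L domain side (um).
#' @param R,cv,keff source radius, concentration, exchange coefficient.
#' @param params an [ox_params()]; set `M > 0` for the reactive variant
#'   (solved on an all-Dirichlet box so the nonlinear reference is available).
#' @param bc boundary conditions (default: the periodic/Dirichlet/Neumann
#'   combination of the single-source benchmark).
#' @param extent neighborhood extent (um), default 144 = 30 R.
#' @return data.frame with per-grid global errors of both models.
#' @export
sweep_grid_size <- function(cells_list = c(3L, 4L, 5L, 6L, 8L, 10L, 12L),
                            L = 240, R = 4.8, cv = 137, keff = 2000,
                            params = ox_params(), bc = NULL, extent = 30 * R) {
  reactive <- params$M > 0
  if (is.null(bc))
    bc <- if (reactive) ox_bc(values = list(params$phi_max / 2))
          else benchmark_bc(params$phi_max / 2)
  out <- NULL
  for (cells in cells_list) {
    g <- ox_grid(L, cells, bc)
    k <- locate_cell(g, L / 2, L / 2)
    s <- ox_sources(g$cx[k], g$cy[k], r = R, cv = cv, keff = keff)
    nn <- n_for_extent(g$h, cells, extent)
    ref <- solve_reference(L, s, params, bc = bc)
    em <- error_metrics(ox_solve(g, s, params, n = nn), ref)
    ef <- error_metrics(solve_coarse_fv(g, s, params), ref)
    out <- rbind(out, data.frame(
      cells = cells, h = g$h, h_over_L = g$h / L, n = nn,
      q_ref = ref$q,
      eps_q_ms = em$eps_q_g, eps_phi_ms = em$eps_phi_g,
      eps_q_fv = ef$eps_q_g, eps_phi_fv = ef$eps_phi_g))
  }
  out
}

#' Boundary-proximity sweep
#'
#' Moves a single source towards a zero-flux (Neumann) side of a 5x5 grid,
#' with Dirichlet 0 on the other sides, from wall contact (`d = 0`, realized
#' with a small inward offset of 1e-2 R) to beyond one grid cell.
#'
#' @param d_over_h wall-boundary distances in units of the cell size.
#' @param cells grid cells per side (5 for the reference benchmark).
#' @inheritParams sweep_grid_size
#' @param n neighborhood size.
#' @return data.frame of global flux errors vs `d/h` for both models.
#' @export
sweep_boundary_distance <- function(d_over_h = c(0, 0.1, 0.2, 0.35, 0.5,
                                                 0.7, 0.9, 1, 1.2),
                                    cells = 5L, L = 240, R = 4.8, cv = 137,
                                    keff = 2000, params = ox_params(),
                                    n = 3L) {
  bc <- ox_bc(bottom = "neumann", values = list(0))
  g <- ox_grid(L, cells, bc)
  out <- NULL
  for (doh in d_over_h) {
    d <- doh * g$h
    yc <- R + d + if (doh == 0) 1e-2 * R else 0
    s <- ox_sources(L / 2, yc, r = R, cv = cv, keff = keff)
    ref <- solve_reference(L, s, params, bc = bc)
    em <- error_metrics(ox_solve(g, s, params, n = n), ref)
    ef <- error_metrics(solve_coarse_fv(g, s, params), ref)
    out <- rbind(out, data.frame(
      d_over_h = doh, d = d, q_ref = ref$q,
      eps_q_ms = em$eps_q_g, eps_q_fv = ef$eps_q_g,
      refine = ref$refine))
  }
  out
}

#' Source-position sweep (cell center to cell corner)
#'
#' Moves the source from the center of the central cell to its corner on a
#' 5x5 all-Dirichlet grid and evaluates the flux error with and without the
#' sub-grid interpolation of the wall average.
#'
#' @param frac positions along the center-to-corner diagonal (0 = center,
#'   1 = corner).
#' @inheritParams sweep_boundary_distance
#' @return data.frame of global flux errors per position and wall mode.
#' @export
sweep_source_position <- function(frac = c(0, 0.25, 0.5, 0.75, 1),
                                  cells = 5L, L = 240, R = 4.8, cv = 137,
                                  keff = 2000, params = ox_params(),
                                  n = 3L) {
  bc <- ox_bc(values = list(0))
  g <- ox_grid(L, cells, bc)
  out <- NULL
  for (t in frac) {
    pos <- L / 2 + t * g$h / 2
    s <- ox_sources(pos, pos, r = R, cv = cv, keff = keff)
    ref <- solve_reference(L, s, params, bc = bc)
    ei <- error_metrics(ox_solve(g, s, params, n = n,
                                 wall_mode = "interpolated"), ref)
    en <- error_metrics(ox_solve(g, s, params, n = n,
                                 wall_mode = "nearest_cell"), ref)
    out <- rbind(out, data.frame(
      frac = t, x = pos, q_ref = ref$q,
      eps_q_interpolated = ei$eps_q_g, eps_q_nearest = en$eps_q_g))
  }
  out
}

#' Source/sink dipole sweep
#'
#' A source (`Cv = phi_max`) and a sink (`Cv = 0`) placed symmetrically about
#' the domain center, with increasing separation, solved for two neighborhood
#' sizes. Probes the interplay between source separation and the localization
#' of the rapid term.
#'
#' @param d_over_R center-to-center separations in source radii.
#' @param n_list neighborhood sizes.
#' @inheritParams sweep_boundary_distance
#' @return data.frame with per-vessel flux errors for each (d, n).
#' @export
sweep_dipole <- function(d_over_R = c(10, 15, 20, 25, 30, 35, 40),
                         n_list = c(3L, 5L), cells = 5L, L = 240, R = 4.8,
                         keff = 2000, params = ox_params()) {
  bc <- ox_bc(values = list(params$phi_max / 2))
  g <- ox_grid(L, cells, bc)
  out <- NULL
  for (dR in d_over_R) {
    d <- dR * R
    s <- ox_sources(c(L / 2 - d / 2, L / 2 + d / 2), c(L / 2, L / 2),
                    r = R, cv = c(0, params$phi_max), keff = keff)
    ref <- solve_reference(L, s, params, bc = bc)
    for (nn in n_list) {
      fit <- ox_solve(g, s, params, n = nn)
      em <- error_metrics(fit, ref)
      out <- rbind(out, data.frame(
        d_over_R = dR, d = d, n = nn,
        eps_q_sink = em$eps_q[1L], eps_q_source = em$eps_q[2L],
        eps_q_g = em$eps_q_g,
        bound = localization_error_bound(ref$q[1L], params$D, nn) /
          abs(ref$q[2L] / keff)))
    }
  }
  out
}

#' Realistic multi-source benchmark (periodic capillary cross-section)
#'
#' Places `S` vessels by seeded hard-core sampling in a periodic box,
#' randomly assigns one third of them as sources (`Cv = phi_max`) and two
#' thirds as sinks (`Cv = 0`), and measures the global flux/concentration
#' errors against the periodic resolved reference, either as a function of
#' the neighborhood size `n` (fixed grid) or of the grid size (fixed
#' neighborhood extent ~30 R).
#'
#' @param seeds integer vector of placement seeds (one realization each).
#' @param n_list neighborhood sizes (mode `"neighborhood"`).
#' @param cells_list grid sizes (mode `"grid"`).
#' @param S number of vessels.
#' @param mode sweep type.
#' @param min_sep hard-core minimum separation (um).
#' @inheritParams sweep_boundary_distance
#' @param ref_K multipole order of the periodic reference.
#' @return data.frame of global errors per (seed, n or cells).
#' @export
run_multi_source <- function(seeds = 1:10, n_list = c(3L, 5L, 7L, 9L),
                             cells_list = c(8L, 12L, 16L), S = 17L,
                             mode = c("neighborhood", "grid"),
                             min_sep = 25, L = 240, R = 4.8, keff = 2000,
                             params = ox_params(), ref_K = 12L) {
  mode <- match.arg(mode)
  bc <- ox_bc("periodic", "periodic", "periodic", "periodic")
  out <- NULL
  for (seed in seeds) {
    set.seed(seed)
    xy <- sample_hardcore_sources(L, S, min_sep = min_sep, periodic = TRUE,
                                  seed = seed)
    cv <- rep(0, S)
    cv[sample.int(S, round(S / 3))] <- params$phi_max
    s <- ox_sources(xy[, 1L], xy[, 2L], r = R, cv = cv, keff = keff)
    ref <- solve_reference(L, s, params, bc = bc, K = ref_K)
    if (mode == "neighborhood") {
      g <- ox_grid(L, 16L, bc)
      for (nn in n_list) {
        em <- error_metrics(ox_solve(g, s, params, n = nn), ref)
        ef <- error_metrics(solve_coarse_fv(g, s, params), ref)
        out <- rbind(out, data.frame(seed = seed, n = nn, cells = 16L,
                                     eps_q_ms = em$eps_q_g,
                                     eps_phi_ms = em$eps_phi_g,
                                     eps_q_fv = ef$eps_q_g))
      }
    } else {
      for (cells in cells_list) {
        g <- ox_grid(L, cells, bc)
        nn <- n_for_extent(g$h, cells, 30 * R)
        em <- error_metrics(ox_solve(g, s, params, n = nn), ref)
        ef <- error_metrics(solve_coarse_fv(g, s, params), ref)
        out <- rbind(out, data.frame(seed = seed, n = nn, cells = cells,
                                     eps_q_ms = em$eps_q_g,
                                     eps_phi_ms = em$eps_phi_g,
                                     eps_q_fv = ef$eps_q_g))
      }
    }
  }
  out
}

## ---- periarteriolar oxygen gradient study -------------------------------------

#' Build one periarteriolar configuration
#'
#' A penetrating arteriole (PA) of radius 20 um at the center of a periodic
#' 400 um box, surrounded by a capillary-free cylinder of radius `R_cyl` =
#' 100 um; capillaries of radius 4.8 um are placed beyond `R_cyl` by seeded
#' hard-core sampling at the layer's equivalent 2D source density, with wall
#' concentrations drawn from a Gaussian around the layer's
#' capillary-to-arteriole ratio (sd 0.1 phi_PA, truncated at 0.05 phi_PA).
#' Wall concentrations are imposed through an asymptotically large exchange
#' coefficient (1000 x the capillary K_eff).
#'
#' @param layer layer label ("I".."IV") or a row of [layer_table()].
#' @param seed placement/concentration seed.
#' @param L domain side (um); 400 um gives the 20 um sampling grid.
#' @param R_pa,R_cyl,R_cap PA, capillary-free and capillary radii (um).
#' @param min_sep hard-core separation (um).
#' @param keff_large asymptotic exchange coefficient (um^2/s).
#' @return list with `sources` (PA first), `phi_pa`, `layer`, `seed`, `L`.
#' @export
periarteriolar_config <- function(layer = "II", seed = 1L, L = 400,
                                  R_pa = 20, R_cyl = 100, R_cap = 4.8,
                                  min_sep = 25, keff_large = 2e6) {
  lay <- if (is.character(layer)) {
    lt <- layer_table()
    lt[match(layer, lt$layer), ]
  } else layer
  if (is.na(lay$layer[1L])) stop("unknown layer: ", layer)
  phi_pa <- lay$po2_pa * 1.39
  set.seed(seed)
  ncap <- round(lay$e2dsd * (L^2 - pi * R_cyl^2) / 1e6)
  xy <- sample_hardcore_sources(L, ncap, min_sep = min_sep,
                                exclusion = list(x = L / 2, y = L / 2,
                                                 r = R_cyl),
                                periodic = TRUE, seed = seed)
  cv_cap <- pmax(rnorm(ncap, lay$phi_cap_ratio * phi_pa, 0.1 * phi_pa),
                 0.05 * phi_pa)
  sources <- ox_sources(c(L / 2, xy[, 1L]), c(L / 2, xy[, 2L]),
                        r = c(R_pa, rep(R_cap, ncap)),
                        cv = c(phi_pa, cv_cap), keff = keff_large)
  list(sources = sources, phi_pa = phi_pa, layer = lay$layer[1L],
       seed = seed, L = L, R_pa = R_pa, R_cyl = R_cyl)
}

#' Periarteriolar oxygen gradient study for one layer
#'
#' Solves the reactive problem for seeded realizations of the layer's
#' capillary bed and aggregates: the azimuthally averaged radial profile of
#' the normalized concentration around the PA (mean and sd over
#' realizations), the relative deviation of the local CMRO2 from its spatial
#' mean inside the capillary-free region, and the mean normalized tissue
#' concentration beyond `R_cyl`.
#'
#' @param layer layer label ("I".."IV").
#' @param M maximal metabolic rate (nmol cm^-3 s^-1); 40 = 2.4 umol/cm^3/min.
#' @param realizations number of seeded realizations.
#' @param seed base seed (realization i uses `seed + i`).
#' @param cells coarse grid cells per side (20 = experimental sampling).
#' @param n neighborhood size.
#' @param resolution raster points per side for spatial averages.
#' @param dr,n_theta radial profile controls.
#' @param params_base an [ox_params()] supplying D, K, alpha, phi_max.
#' @return list with `profile` (r, mean, sd over realizations of the
#'   normalized azimuthal mean), `mean_outside` (per realization),
#'   `cmro2_max_dev` (per realization), `config` echo.
#' @export
run_periarteriolar <- function(layer = "II", M = 40, realizations = 30L,
                               seed = 7L, cells = 20L, n = 10L,
                               resolution = 160L, dr = 2, n_theta = 180L,
                               params_base = ox_params()) {
  bc <- ox_bc("periodic", "periodic", "periodic", "periodic")
  pars <- ox_params(D = params_base$D, M = M, K = params_base$K,
                    alpha = params_base$alpha, phi_max = params_base$phi_max)
  profs <- list(); mos <- numeric(0); devs <- numeric(0)
  cfg0 <- NULL
  for (i in seq_len(realizations)) {
    cfg <- periarteriolar_config(layer, seed = seed + i)
    if (is.null(cfg0)) cfg0 <- cfg
    g <- ox_grid(cfg$L, cells, bc)
    fit <- ox_solve(g, cfg$sources, pars, n = n)
    pr <- radial_profile(fit, dr = dr, n_theta = n_theta)
    profs[[i]] <- pr$mean / cfg$phi_pa
    mos <- c(mos, mean_outside_radius(fit, R_cut = cfg$R_cyl,
                                      resolution = resolution) / cfg$phi_pa)
    ## CMRO2 deviation inside the capillary-free annulus
    xr <- (seq_len(resolution) - 0.5) * cfg$L / resolution
    pts <- expand.grid(x = xr, y = xr)
    dd <- sqrt((pts$x - cfg$L / 2)^2 + (pts$y - cfg$L / 2)^2)
    sel <- dd < cfg$R_cyl & dd > cfg$R_pa
    cm <- cmro2_field(fit, pts$x[sel], pts$y[sel])
    devs <- c(devs, max(abs(cm - mean(cm)) / mean(cm)))
  }
  pm <- do.call(cbind, profs)
  prof <- data.frame(r = seq(dr / 2, cfg0$L / 2, by = dr),
                     mean = rowMeans(pm), sd = apply(pm, 1L, sd))
  list(profile = prof, mean_outside = mos, cmro2_max_dev = devs,
       layer = layer, M = M, seed = seed, realizations = realizations)
}

#' Laminar sweep across cortical layers I-IV
#'
#' Runs the periarteriolar study for each layer and fits the least-squares
#' line of the mean normalized tissue concentration beyond the capillary-free
#' radius against the layer's equivalent 2D source density (mm^-2).
#'
#' @inheritParams run_periarteriolar
#' @param layers layer labels.
#' @param density_only if `TRUE`, hold the capillary concentration ratio at
#'   the layer-II value while sweeping only the density.
#' @return list with `per_layer` (data.frame of per-realization means),
#'   `fit` (lm), `slope`, `intercept`, and their 95% confidence intervals.
#' @export
run_layer_sweep <- function(layers = c("I", "II", "III", "IV"), M = 40,
                            realizations = 30L, seed = 7L, cells = 20L,
                            n = 10L, resolution = 160L,
                            density_only = FALSE,
                            params_base = ox_params()) {
  bc <- ox_bc("periodic", "periodic", "periodic", "periodic")
  pars <- ox_params(D = params_base$D, M = M, K = params_base$K,
                    alpha = params_base$alpha, phi_max = params_base$phi_max)
  lt <- layer_table()
  per <- NULL
  for (li in seq_along(layers)) {
    lay <- lt[match(layers[li], lt$layer), ]
    if (density_only) {
      layII <- lt[lt$layer == "II", ]
      lay$phi_cap_ratio <- layII$phi_cap_ratio
      lay$po2_pa <- layII$po2_pa
    }
    for (i in seq_len(realizations)) {
      cfg <- periarteriolar_config(lay, seed = seed + 1000L * li + i)
      g <- ox_grid(cfg$L, cells, bc)
      fit <- ox_solve(g, cfg$sources, pars, n = n)
      mo <- mean_outside_radius(fit, R_cut = cfg$R_cyl,
                                resolution = resolution) / cfg$phi_pa
      per <- rbind(per, data.frame(layer = layers[li], e2dsd = lay$e2dsd,
                                   realization = i, mean_outside = mo))
    }
  }
  fit <- stats::lm(mean_outside ~ e2dsd, data = per)
  ci <- stats::confint(fit)
  list(per_layer = per, fit = fit,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       slope_ci = ci[2L, ], intercept_ci = ci[1L, ],
       M = M, realizations = realizations, seed = seed,
       density_only = density_only)
}
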