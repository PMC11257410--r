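## ---- dual mesh -------------------------------------------------------------
##
## Sub-grid reconstruction interpolates the slow field bilinearly on the dual
## mesh obtained by joining FV cell centers; along non-periodic sides the dual
## mesh is completed by boundary nodes (face midpoints and domain corners)
## carrying the discrete boundary values, so the reconstruction meets the
## boundary conditions at the nodes. Each interpolation node i contributes
## gamma_i(x) * (v_i + r_i(x)), where v_i is the node's slow value and r_i the
## rapid field of the node's cell continued analytically to x; this bridges
## the rapid-term discontinuities, making the reconstruction continuous.

## per-axis dual node layout
dual_axis <- function(grid, axis = c("x", "y")) {
  axis <- match.arg(axis)
  per <- if (axis == "x") grid$bc$periodic_x else grid$bc$periodic_y
  n <- if (axis == "x") grid$nx else grid$ny
  cc <- if (axis == "x") grid$xc else grid$yc
  if (per) {
    list(coord = cc, type = rep("c", n), cell = seq_len(n),
         side = rep("", n), periodic = TRUE)
  } else {
    sides <- if (axis == "x") c("left", "right") else c("bottom", "top")
    list(coord = c(0, cc, grid$L),
         type = c("b", rep("c", n), "b"),
         cell = c(1L, seq_len(n), n),
         side = c(sides[1L], rep("", n), sides[2L]),
         periodic = FALSE)
  }
}

## outward normal component for a boundary side
side_normal <- function(side) {
  switch(side,
         left = c(-1, 0), right = c(1, 0),
         bottom = c(0, -1), top = c(0, 1))
}

## Linear functional describing the slow value v_i carried by dual node
## (i, j):  v_i = sum(ws * s) + sum(wq * q) + const.
## Boundary nodes carry the same face-averaged dummy values as the FV
## balance: Dirichlet nodes phi_D(node) minus the Simpson face-average of the
## rapid term; Neumann nodes the cell value minus half the face-averaged
## rapid flux (so the total flux through the face vanishes). This keeps the
## reconstruction consistent with the discrete boundary treatment and avoids
## extrapolating near-singular pointwise gradients.
## Returns list(cell, ws_idx, ws_val, wq (dense length S), const).
node_functional <- function(grid, sources, nbr, ax, ay, i, j) {
  S <- nrow(sources)
  tx <- ax$type[i]; ty <- ay$type[j]
  xn <- ax$coord[i]; yn <- ay$coord[j]
  cell <- cell_id(grid, ax$cell[i], ay$cell[j])
  wq <- numeric(S); const <- 0
  ws_idx <- integer(0); ws_val <- numeric(0)
  cs <- nbr$cell_sources[[cell]]
  h <- grid$h; L <- grid$L
  face_span <- function(side) {
    x0 <- (ax$cell[i] - 1L) * h; y0 <- (ay$cell[j] - 1L) * h
    switch(side,
           bottom = list(p0 = c(x0, 0), p1 = c(x0 + h, 0)),
           top = list(p0 = c(x0, L), p1 = c(x0 + h, L)),
           left = list(p0 = c(0, y0), p1 = c(0, y0 + h)),
           right = list(p0 = c(L, y0), p1 = c(L, y0 + h)))
  }
  face_ints <- function(side) {
    fs <- face_span(side)
    face_integrals(sources, cs, fs$p0, fs$p1, side_normal(side),
                   grid$D_cache)
  }
  if (tx == "c" && ty == "c") {
    ws_idx <- cell; ws_val <- 1
  } else {
    sides <- character(0)
    if (tx == "b") sides <- c(sides, ax$side[i])
    if (ty == "b") sides <- c(sides, ay$side[j])
    kinds <- vapply(sides, function(s) unname(grid$bc$sides[s]), character(1))
    if (any(kinds == "dirichlet")) {
      s <- sides[which(kinds == "dirichlet")[1L]]
      const <- bc_value(grid$bc, s, xn, yn)
      fi <- face_ints(s)
      if (length(fi$j)) for (t in seq_along(fi$j))
        wq[fi$j[t]] <- wq[fi$j[t]] - fi$avg[t]
    } else {
      ws_idx <- cell; ws_val <- 1
      for (s in sides) {
        fi <- face_ints(s)
        if (length(fi$j)) for (t in seq_along(fi$j))
          wq[fi$j[t]] <- wq[fi$j[t]] - 0.5 * fi$flx[t]
      }
    }
  }
  list(cell = cell, ws_idx = ws_idx, ws_val = ws_val, wq = wq, const = const)
}

## Build the full dual mesh with all node functionals. D is needed for the
## potentials; it is stashed on the grid (grid$D_cache) to keep signatures
## short.
build_dualmesh <- function(grid, sources, nbr, D) {
  grid$D_cache <- D
  ax <- dual_axis(grid, "x"); ay <- dual_axis(grid, "y")
  px <- length(ax$coord); py <- length(ay$coord)
  nodes <- vector("list", px * py)
  for (j in seq_len(py))
    for (i in seq_len(px))
      nodes[[(j - 1L) * px + i]] <-
        node_functional(grid, sources, nbr, ax, ay, i, j)
  list(ax = ax, ay = ay, px = px, py = py, nodes = nodes, D = D)
}

## locate the dual interval along one axis; returns (i_left, shift_left,
## i_right, shift_right, t) where shifts unwrap periodic nodes
dual_interval <- function(axl, v, L) {
  co <- axl$coord
  p <- length(co)
  if (axl$periodic) {
    v <- wrap_coord(v, L)
    i <- findInterval(v, co)
    il <- ifelse(i == 0L | i == p, p, i)
    ir <- ifelse(i == 0L | i == p, 1L, i + 1L)
    sl <- ifelse(i == 0L, -L, 0)
    sr <- ifelse(i == p, L, 0)
    xl <- co[il] + sl; xr <- co[ir] + sr
    t <- (v - xl) / (xr - xl)
  } else {
    i <- pmin(pmax(findInterval(v, co), 1L), p - 1L)
    il <- i; ir <- i + 1L
    sl <- numeric(length(v)); sr <- sl
    t <- (v - co[il]) / (co[ir] - co[il])
  }
  list(il = as.integer(il), ir = as.integer(ir), sl = sl, sr = sr, t = t)
}

## Full linear functional of the reconstruction at a single point:
## I_phi(x) = sum(ws * s) + sum(wq * q) + const
iphi_functional <- function(dm, grid, sources, nbr, x, y) {
  S <- nrow(sources)
  if (grid$bc$periodic_x) x <- wrap_coord(x, grid$L)
  if (grid$bc$periodic_y) y <- wrap_coord(y, grid$L)
  ivx <- dual_interval(dm$ax, x, grid$L)
  ivy <- dual_interval(dm$ay, y, grid$L)
  gam <- c((1 - ivx$t) * (1 - ivy$t), ivx$t * (1 - ivy$t),
           (1 - ivx$t) * ivy$t, ivx$t * ivy$t)
  ii <- c(ivx$il, ivx$ir, ivx$il, ivx$ir)
  jj <- c(ivy$il, ivy$il, ivy$ir, ivy$ir)
  sx <- c(ivx$sl, ivx$sr, ivx$sl, ivx$sr)
  sy <- c(ivy$sl, ivy$sl, ivy$sr, ivy$sr)
  ws <- numeric(grid$F); wq <- numeric(S); const <- 0
  for (t in 1:4) {
    nf <- dm$nodes[[(jj[t] - 1L) * dm$px + ii[t]]]
    g <- gam[t]
    if (g == 0) next
    if (length(nf$ws_idx)) ws[nf$ws_idx] <- ws[nf$ws_idx] + g * nf$ws_val
    wq <- wq + g * nf$wq
    const <- const + g * nf$const
    ## analytic continuation of the node cell's rapid field to x
    cs <- nbr$cell_sources[[nf$cell]]
    if (nrow(cs)) {
      for (u in seq_len(nrow(cs))) {
        jjj <- cs$j[u]
        wq[jjj] <- wq[jjj] +
          g * pot_val(x - sx[t], y - sy[t],
                      sources$x[jjj] + cs$ox[u], sources$y[jjj] + cs$oy[u],
                      sources$r[jjj], dm$D)
      }
    }
  }
  list(ws = ws, wq = wq, const = const)
}

## Fast batched evaluation of I_phi at many points given solved (s, q).
## Shares the node functionals with iphi_functional().
eval_iphi_points <- function(dm, grid, sources, nbr, s, q, x, y) {
  S <- nrow(sources)
  if (grid$bc$periodic_x) x <- wrap_coord(x, grid$L)
  if (grid$bc$periodic_y) y <- wrap_coord(y, grid$L)
  ## scalar slow value of every node
  nv <- vapply(dm$nodes, function(nf) {
    v <- nf$const
    if (length(nf$ws_idx)) v <- v + sum(nf$ws_val * s[nf$ws_idx])
    if (S) v <- v + sum(nf$wq * q)
    v
  }, numeric(1))
  ivx <- dual_interval(dm$ax, x, grid$L)
  ivy <- dual_interval(dm$ay, y, grid$L)
  out <- numeric(length(x))
  corner <- function(ii, jjv, sxv, syv, gam) {
    key <- paste(ii, jjv, sxv, syv, sep = "_")
    for (k in split(seq_along(x), key)) {
      idn <- (jjv[k[1L]] - 1L) * dm$px + ii[k[1L]]
      nf <- dm$nodes[[idn]]
      cs <- nbr$cell_sources[[nf$cell]]
      rv <- rapid_eval(sources, cs, q, x[k], y[k], dm$D,
                       shift = c(sxv[k[1L]], syv[k[1L]]))
      out[k] <<- out[k] + gam[k] * (nv[idn] + rv)
    }
  }
  g00 <- (1 - ivx$t) * (1 - ivy$t); g10 <- ivx$t * (1 - ivy$t)
  g01 <- (1 - ivx$t) * ivy$t;       g11 <- ivx$t * ivy$t
  corner(ivx$il, ivy$il, ivx$sl, ivy$sl, g00)
  corner(ivx$ir, ivy$il, ivx$sr, ivy$sl, g10)
  corner(ivx$il, ivy$ir, ivx$sl, ivy$sr, g01)
  corner(ivx$ir, ivy$ir, ivx$sr, ivy$sr, g11)
  out
}

## ---- user-facing reconstruction -------------------------------------------

#' Cell-center concentration
#'
#' The discrete concentration at the FV cell centers,
#' `phi_k = s_k + r_k(q; x_k)` (slow value plus the cell's rapid field).
#'
#' @param fit an [ox_solve()] result.
#' @param k optional subset of cell indices.
#' @return Numeric vector of concentrations.
#' @export
cell_center_concentration <- function(fit, k = seq_len(fit$grid$F)) {
  vapply(k, function(kk) {
    fit$s[kk] + rapid_eval(fit$sources, fit$nbr$cell_sources[[kk]], fit$q,
                           fit$grid$cx[kk], fit$grid$cy[kk], fit$params$D)
  }, numeric(1))
}

#' Sub-grid reconstructed concentration
#'
#' Evaluates the reconstruction `I_phi` (bilinear slow field on the dual mesh
#' plus analytically continued rapid terms) at arbitrary points. The result
#' is continuous across grid faces, interpolates the cell-center values
#' exactly, and meets Dirichlet boundary values at the boundary nodes.
#'
#' @param fit an [ox_solve()] result.
#' @param x,y evaluation points (um), vectorised.
#' @return Concentrations at the points.
#' @export
interpolate_concentration <- function(fit, x, y) {
  L <- fit$grid$L
  if (!fit$grid$bc$periodic_x && any(x < -1e-9 | x > L + 1e-9))
    stop("x outside the non-periodic domain")
  if (!fit$grid$bc$periodic_y && any(y < -1e-9 | y > L + 1e-9))
    stop("y outside the non-periodic domain")
  eval_iphi_points(fit$dualmesh, fit$grid, fit$sources, fit$nbr,
                   fit$s, fit$q, x, y)
}

#' Vessel-wall average concentration
#'
#' Average concentration on the wall of source `j`. By Gauss's mean-value
#' theorem for harmonic fields this equals the reconstructed concentration at
#' the source center (`mode = "interpolated"`); `mode = "nearest_cell"` is the
#' non-interpolated variant that uses the host cell's discrete slow value
#' plus the potentials of the other neighborhood sources at the center.
#'
#' @param fit an [ox_solve()] result.
#' @param j source index (vectorised).
#' @param mode `"interpolated"` (default) or `"nearest_cell"`.
#' @return Wall-average concentrations.
#' @export
wall_average <- function(fit, j = seq_len(nrow(fit$sources)),
                         mode = c("interpolated", "nearest_cell")) {
  mode <- match.arg(mode)
  if (mode == "interpolated")
    return(interpolate_concentration(fit, fit$sources$x[j], fit$sources$y[j]))
  vapply(j, function(jj) {
    k <- locate_cell(fit$grid, fit$sources$x[jj], fit$sources$y[jj])
    cs <- fit$nbr$cell_sources[[k]]
    cs <- cs[cs$j != jj, , drop = FALSE]
    fit$s[k] + rapid_eval(fit$sources, cs, fit$q,
                          fit$sources$x[jj], fit$sources$y[jj], fit$params$D)
  }, numeric(1))
}

#' Rasterized reconstruction of the concentration field
#'
#' Samples `I_phi` on a uniform raster. Points falling inside a source disk
#' are flagged and set to that source's wall-average concentration.
#'
#' @param fit an [ox_solve()] result.
#' @param resolution number of raster points per side (>= grid cells).
#' @return List with `x`, `y` (pixel-center coordinates), `phi` (matrix,
#'   `x` by `y`), and `inside` (logical matrix flagging in-vessel pixels).
#' @export
raster_field <- function(fit, resolution = 8L * fit$grid$nx) {
  resolution <- as.integer(resolution)
  if (resolution < fit$grid$nx)
    stop("raster resolution must be at least the grid resolution")
  L <- fit$grid$L
  xr <- (seq_len(resolution) - 0.5) * L / resolution
  pts <- expand.grid(x = xr, y = xr)
  phi <- interpolate_concentration(fit, pts$x, pts$y)
  msk <- mask_wall_values(fit, pts$x, pts$y, phi)
  list(x = xr, y = xr,
       phi = matrix(msk$phi, resolution, resolution),
       inside = matrix(msk$inside, resolution, resolution))
}

## replace values at points lying inside a source disk by that source's wall
## average; returns list(phi, inside)
mask_wall_values <- function(fit, x, y, phi) {
  inside <- rep(FALSE, length(x))
  src <- fit$sources
  if (nrow(src)) {
    wall <- wall_average(fit)
    L <- fit$grid$L
    for (j in seq_len(nrow(src))) {
      dx <- x - src$x[j]; dy <- y - src$y[j]
      if (fit$grid$bc$periodic_x) dx <- dx - L * round(dx / L)
      if (fit$grid$bc$periodic_y) dy <- dy - L * round(dy / L)
      inj <- dx^2 + dy^2 <= src$r[j]^2
      phi[inj] <- wall[j]
      inside <- inside | inj
    }
  }
  list(phi = phi, inside = inside)
}

#' Local metabolic consumption (CMRO2) field
#'
#' Pointwise Michaelis-Menten consumption rate `M * phi / (phi + K)` from the
#' reconstructed concentration; values lie in `[0, M)`.
#'
#' @param fit an [ox_solve()] result (typically a reactive solution).
#' @param x,y evaluation points; alternatively pass a raster via `raster`.
#' @param raster optional result of [raster_field()].
#' @return Consumption rates at the points (same shape as the input).
#' @export
cmro2_field <- function(fit, x = NULL, y = NULL, raster = NULL) {
  M <- fit$params$M; K <- fit$params$K
  if (!is.null(raster)) {
    phi <- raster$phi
  } else {
    phi <- interpolate_concentration(fit, x, y)
    phi <- mask_wall_values(fit, x, y, phi)$phi
  }
  M * phi / (phi + K)
}

#' Azimuthally averaged radial concentration profile
#'
#' Averages the reconstructed concentration over rays around a center point,
#' as used for periarteriolar oxygen gradient profiles. Sample points inside
#' a vessel are replaced by the vessel's wall-average concentration, so the
#' profile is constant (the wall value) inside the central vessel.
#'
#' @param fit an [ox_solve()] result.
#' @param center length-2 center (um); defaults to the domain center.
#' @param r_max largest radius (um), default half the domain side.
#' @param dr radial bin width (um), default 2 um.
#' @param n_theta number of rays, default 360.
#' @return data.frame with `r` (bin center radii), `mean` and `sd` of the
#'   concentration over the rays.
#' @export
radial_profile <- function(fit, center = c(fit$grid$L / 2, fit$grid$L / 2),
                           r_max = fit$grid$L / 2, dr = 2, n_theta = 360L) {
  rs <- seq(dr / 2, r_max, by = dr)
  th <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  pts_x <- as.vector(outer(rs, th, function(r, a) center[1L] + r * cos(a)))
  pts_y <- as.vector(outer(rs, th, function(r, a) center[2L] + r * sin(a)))
  L <- fit$grid$L
  if (fit$grid$bc$periodic_x) pts_x <- wrap_coord(pts_x, L)
  if (fit$grid$bc$periodic_y) pts_y <- wrap_coord(pts_y, L)
  phi <- interpolate_concentration(fit, pts_x, pts_y)
  phi <- mask_wall_values(fit, pts_x, pts_y, phi)$phi
  m <- matrix(phi, nrow = length(rs))
  data.frame(r = rs,
             mean = rowMeans(m),
             sd = apply(m, 1L, sd))
}

#' Mean concentration outside a radius
#'
#' Area-weighted raster mean of the reconstructed concentration over the
#' region farther than `R_cut` from `center` (periodic minimum-image
#' distance on periodic domains). In-vessel pixels carry wall values.
#'
#' @param fit an [ox_solve()] result.
#' @param center length-2 center (um).
#' @param R_cut cutoff radius (um), must be below half the domain side.
#' @param resolution raster points per side.
#' @return Scalar mean concentration.
#' @export
mean_outside_radius <- function(fit, center = c(fit$grid$L / 2, fit$grid$L / 2),
                                R_cut, resolution = 8L * fit$grid$nx) {
  if (R_cut >= fit$grid$L / 2)
    stop("R_cut must be smaller than half the domain side")
  ras <- raster_field(fit, resolution)
  pts <- expand.grid(x = ras$x, y = ras$y)
  dx <- pts$x - center[1L]; dy <- pts$y - center[2L]
  L <- fit$grid$L
  if (fit$grid$bc$periodic_x) dx <- dx - L * round(dx / L)
  if (fit$grid$bc$periodic_y) dy <- dy - L * round(dy / L)
  sel <- dx^2 + dy^2 > R_cut^2
  mean(as.vector(ras$phi)[sel])
}
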