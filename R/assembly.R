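## ---- discrete system assembly ----------------------------------------------
##
## Unknowns: s (one slow value per cell, length F) and q (one wall flux per
## source, length S). The slow-field rows are the TPFA balance
##   -4 s_k + sum_m f_{k,m} = (M / 2D) * integral of the saturation term,
## with face values
##   interior/periodic: f = (s_k + s_m)/2 + J_{k,m}/2
##   Dirichlet:         f = Simpson face-average of (phi_D - r_k)
##   Neumann:           f = s_k - 1/2 int n.grad r_k dl   (zero total flux)
## The S coupling rows impose q_j = K_eff (Cv_j - wall average), the wall
## average being either the sub-grid interpolation at the source center or
## the host cell's discrete value (nearest-cell variant).

## internal: both halves of the face-jump coefficients.
## J_{k,m} = flux + val,  J_{m,k} = flux - val  (normal/operand conventions)
face_jump_parts <- function(sources, nbr, k, m, p0, p1, nrm, D, nn0, wrap) {
  ## sources seen identically from both cells (same periodic image) cancel
  ## exactly in both halves of the jump; integrate only the difference
  csk <- nbr$cell_sources[[k]]
  csm <- nbr$cell_sources[[m]]
  keyk <- sprintf("%d@%g@%g", csk$j, csk$ox, csk$oy)
  keym <- sprintf("%d@%g@%g", csm$j, csm$ox + wrap[1L], csm$oy + wrap[2L])
  fk <- face_integrals(sources, csk[!(keyk %in% keym), , drop = FALSE],
                       p0, p1, nrm, D, nn0 = nn0)
  fm <- face_integrals(sources, csm[!(keym %in% keyk), , drop = FALSE],
                       p0, p1, nrm, D, nn0 = nn0, shift = wrap)
  S <- nrow(sources)
  flux <- numeric(S); val <- numeric(S)
  if (length(fm$j)) for (i in seq_along(fm$j)) {
    flux[fm$j[i]] <- flux[fm$j[i]] + 0.5 * fm$flx[i]
    val[fm$j[i]] <- val[fm$j[i]] + fm$avg[i]
  }
  if (length(fk$j)) for (i in seq_along(fk$j)) {
    flux[fk$j[i]] <- flux[fk$j[i]] - 0.5 * fk$flx[i]
    val[fk$j[i]] <- val[fk$j[i]] - fk$avg[i]
  }
  list(flux = flux, val = val)
}

#' Assemble the discrete block system
#'
#' Builds the sparse blocks of the coupled system
#' `A s + B q = b` (slow-field balance) and `C s + D q = b_beta`
#' (vessel-wall exchange), for the multiscale model or for the well-mixed
#' coarse-grid baseline (`rapid = FALSE`, in which case no jump or
#' boundary-subtraction terms appear and the exchange uses the host cell's
#' discrete value directly).
#'
#' @param grid an [ox_grid()].
#' @param sources an [ox_sources()] table.
#' @param params an [ox_params()].
#' @param n neighborhood size (cells per side) for the rapid-term
#'   localization.
#' @param wall_mode `"interpolated"` (sub-grid interpolation of the wall
#'   average, the default) or `"nearest_cell"`.
#' @param rapid logical; `FALSE` assembles the coarse-grid FV baseline.
#' @param face_nodes number of Simpson nodes per face (odd); default scales
#'   with `h / min(r)`.
#' @return An object of class `ox_system` with the sparse blocks, right-hand
#'   sides and all geometric bookkeeping.
#' @export
assemble_system <- function(grid, sources, params, n = 3L,
                            wall_mode = c("interpolated", "nearest_cell"),
                            rapid = TRUE, face_nodes = NULL) {
  wall_mode <- match.arg(wall_mode)
  validate_sources(grid, sources)
  S <- nrow(sources); Fn <- grid$F
  bcs <- grid$bc$sides
  if (S == 0L && !any(bcs == "dirichlet"))
    stop("ill-posed problem: no Dirichlet side and no sources")
  nbr <- build_neighborhoods(grid, sources, max(n, 3L))
  if (!rapid) {
    ## baseline carries no rapid term anywhere
    nbr$cell_sources <- lapply(nbr$cell_sources,
                               function(d) d[0L, , drop = FALSE])
    nbr$key <- rep("", Fn)
  }
  dm <- build_dualmesh(grid, sources, nbr, params$D)
  h <- grid$h; L <- grid$L
  if (is.null(face_nodes))
    face_nodes <- face_nn(h, if (S) min(sources$r) else h)
  w <- simpson_weights(face_nodes)

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)   # A triplets
  bi <- integer(0); bj <- integer(0); bx <- numeric(0)   # B triplets
  cc <- numeric(Fn)                                      # constants (LHS)
  addA <- function(i, j, v) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, v)
  }
  addB <- function(i, coefs) {
    nz <- which(coefs != 0)
    if (length(nz)) {
      bi <<- c(bi, rep(i, length(nz))); bj <<- c(bj, nz)
      bx <<- c(bx, coefs[nz])
    }
  }

  for (k in seq_len(Fn)) addA(k, k, -4)

  dir_face <- function(k, p0, p1, side) {
    pts <- face_nodes(p0, p1, face_nodes)
    phid <- bc_value(grid$bc, side, pts[, 1L], pts[, 2L])
    dl <- h / (face_nodes - 1L)
    cc[k] <<- cc[k] + sum(w * phid) * dl / h
    fi <- face_integrals(sources, nbr$cell_sources[[k]], p0, p1,
                         side_normal(side), params$D, nn0 = face_nodes)
    if (length(fi$j)) {
      coefs <- numeric(S); coefs[fi$j] <- coefs[fi$j] - fi$avg
      addB(k, coefs)
    }
  }
  neu_face <- function(k, p0, p1, side) {
    addA(k, k, 1)
    fi <- face_integrals(sources, nbr$cell_sources[[k]], p0, p1,
                         side_normal(side), params$D, nn0 = face_nodes)
    if (length(fi$j)) {
      coefs <- numeric(S); coefs[fi$j] <- coefs[fi$j] - 0.5 * fi$flx
      addB(k, coefs)
    }
  }
  int_face <- function(k, m, p0, p1, nrm, wrap) {
    addA(k, k, 0.5); addA(k, m, 0.5)
    addA(m, m, 0.5); addA(m, k, 0.5)
    if (S > 0L &&
        !(identical(nbr$key[k], nbr$key[m]) && all(wrap == 0))) {
      jp <- face_jump_parts(sources, nbr, k, m, p0, p1, nrm, params$D,
                            face_nodes, wrap)
      addB(k, 0.5 * (jp$flux + jp$val))
      addB(m, 0.5 * (jp$flux - jp$val))
    }
  }

  for (iy in seq_len(grid$ny)) {
    for (ix in seq_len(grid$nx)) {
      k <- cell_id(grid, ix, iy)
      x0 <- (ix - 1L) * h; y0 <- (iy - 1L) * h
      ## +x face
      if (ix < grid$nx) {
        int_face(k, cell_id(grid, ix + 1L, iy),
                 c(x0 + h, y0), c(x0 + h, y0 + h), c(1, 0), c(0, 0))
      } else if (grid$bc$periodic_x) {
        int_face(k, cell_id(grid, 1L, iy),
                 c(x0 + h, y0), c(x0 + h, y0 + h), c(1, 0), c(L, 0))
      } else if (bcs["right"] == "dirichlet") {
        dir_face(k, c(L, y0), c(L, y0 + h), "right")
      } else neu_face(k, c(L, y0), c(L, y0 + h), "right")
      ## +y face
      if (iy < grid$ny) {
        int_face(k, cell_id(grid, ix, iy + 1L),
                 c(x0, y0 + h), c(x0 + h, y0 + h), c(0, 1), c(0, 0))
      } else if (grid$bc$periodic_y) {
        int_face(k, cell_id(grid, ix, 1L),
                 c(x0, y0 + h), c(x0 + h, y0 + h), c(0, 1), c(0, L))
      } else if (bcs["top"] == "dirichlet") {
        dir_face(k, c(x0, L), c(x0 + h, L), "top")
      } else neu_face(k, c(x0, L), c(x0 + h, L), "top")
      ## -x face (only domain boundary; interior handled from the left cell)
      if (ix == 1L && !grid$bc$periodic_x) {
        if (bcs["left"] == "dirichlet")
          dir_face(k, c(0, y0), c(0, y0 + h), "left")
        else neu_face(k, c(0, y0), c(0, y0 + h), "left")
      }
      ## -y face
      if (iy == 1L && !grid$bc$periodic_y) {
        if (bcs["bottom"] == "dirichlet")
          dir_face(k, c(x0, 0), c(x0 + h, 0), "bottom")
        else neu_face(k, c(x0, 0), c(x0 + h, 0), "bottom")
      }
    }
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(Fn, Fn))
  B <- if (S) Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(Fn, S))
       else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(Fn, 0L))
  b <- -cc

  ## coupling rows
  ci <- integer(0); cj <- integer(0); cx <- numeric(0)
  di <- integer(0); dj <- integer(0); dx <- numeric(0)
  bb <- numeric(S)
  if (S > 0L) {
    if (!rapid) {
      host <- locate_cell(grid, sources$x, sources$y)
      for (j in seq_len(S)) {
        keff <- sources$keff[j]
        ci <- c(ci, j); cj <- c(cj, host[j]); cx <- c(cx, keff)
        di <- c(di, j); dj <- c(dj, j); dx <- c(dx, 1)
        bb[j] <- keff * sources$cv[j]
      }
      ## baseline: flux q_j feeds the FV balance of its host cell
      B <- B + Matrix::sparseMatrix(i = host, j = seq_len(S),
                                    x = rep(1 / (2 * params$D), S),
                                    dims = c(Fn, S))
    } else if (wall_mode == "interpolated") {
      for (j in seq_len(S)) {
        keff <- sources$keff[j]
        fn <- iphi_functional(dm, grid, sources, nbr,
                              sources$x[j], sources$y[j])
        nzs <- which(fn$ws != 0)
        ci <- c(ci, rep(j, length(nzs))); cj <- c(cj, nzs)
        cx <- c(cx, keff * fn$ws[nzs])
        wq <- keff * fn$wq; wq[j] <- wq[j] + 1
        nzq <- which(wq != 0)
        di <- c(di, rep(j, length(nzq))); dj <- c(dj, nzq); dx <- c(dx, wq[nzq])
        bb[j] <- keff * (sources$cv[j] - fn$const)
      }
    } else {
      host <- locate_cell(grid, sources$x, sources$y)
      for (j in seq_len(S)) {
        keff <- sources$keff[j]
        k <- host[j]
        ci <- c(ci, j); cj <- c(cj, k); cx <- c(cx, keff)
        cs <- nbr$cell_sources[[k]]
        wq <- numeric(S); wq[j] <- 1
        if (nrow(cs)) for (t in seq_len(nrow(cs))) {
          jj <- cs$j[t]
          if (jj == j) next
          wq[jj] <- wq[jj] + keff *
            pot_val(sources$x[j], sources$y[j],
                    sources$x[jj] + cs$ox[t], sources$y[jj] + cs$oy[t],
                    sources$r[jj], params$D)
        }
        nzq <- which(wq != 0)
        di <- c(di, rep(j, length(nzq))); dj <- c(dj, nzq); dx <- c(dx, wq[nzq])
        bb[j] <- keff * sources$cv[j]
      }
    }
  }
  C <- Matrix::sparseMatrix(i = ci, j = cj, x = cx, dims = c(S, Fn))
  D <- Matrix::sparseMatrix(i = di, j = dj, x = dx, dims = c(S, S))

  structure(list(A = A, B = B, C = C, D = D, b = b, bb = bb,
                 grid = grid, sources = sources, nbr = nbr, params = params,
                 dualmesh = dm, wall_mode = wall_mode, rapid = rapid,
                 n = n, face_nodes = face_nodes),
            class = "ox_system")
}

## ---- metabolic volume terms -------------------------------------------------

## Precompute per-cell quadrature data for the Michaelis-Menten integrals:
## tensor-product Simpson nodes, weights, the member potentials at the nodes,
## and analytic in-disk corrections (tissue does not occupy the vessel lumen,
## so each disk's share of the cell integral is subtracted, evaluated at the
## disk center).
metab_precomp <- function(sys, nq = 11L) {
  grid <- sys$grid; sources <- sys$sources; nbr <- sys$nbr
  D <- sys$params$D; h <- grid$h
  w1 <- simpson_weights(nq) * (h / (nq - 1L))
  w2 <- as.vector(outer(w1, w1))
  t1 <- seq(0, h, length.out = nq)
  offx <- as.vector(outer(t1, rep(1, nq)))
  offy <- as.vector(outer(rep(1, nq), t1))
  out <- vector("list", grid$F)
  for (k in seq_len(grid$F)) {
    x0 <- (grid$ix[k] - 1L) * h; y0 <- (grid$iy[k] - 1L) * h
    xs <- x0 + offx; ys <- y0 + offy
    cs <- nbr$cell_sources[[k]]
    m <- nrow(cs)
    G <- matrix(0, nq * nq, m)
    disks <- list()
    if (m) {
      for (t in seq_len(m)) {
        jj <- cs$j[t]
        sx <- sources$x[jj] + cs$ox[t]; sy <- sources$y[jj] + cs$oy[t]
        G[, t] <- pot_val(xs, ys, sx, sy, sources$r[jj], D)
        ar <- circle_rect_overlap(sx, sy, sources$r[jj], x0, x0 + h, y0, y0 + h)
        if (ar > 0) {
          gcen <- vapply(seq_len(m), function(u) {
            jju <- cs$j[u]
            pot_val(sx, sy, sources$x[jju] + cs$ox[u],
                    sources$y[jju] + cs$oy[u], sources$r[jju], D)
          }, numeric(1))
          disks[[length(disks) + 1L]] <- list(area = ar, gcen = gcen)
        }
      }
    }
    out[[k]] <- list(js = cs$j, G = G, w2 = w2, disks = disks)
  }
  out
}

#' Metabolic volume vector and its Jacobian blocks
#'
#' Integral contribution of the Michaelis-Menten consumption to each cell's
#' balance: `-(M / 2D) * int_{V_k} (1 - K / (K + s_k + r_k(x))) dV`, with
#' tensor-product Simpson quadrature, analytic subtraction of the vessel-lumen
#' share (no tissue there), and analytic differentiation for the Newton
#' Jacobian.
#'
#' @param sys an [assemble_system()] result.
#' @param s,q current slow values and fluxes.
#' @param pre precomputed quadrature data (internal; built on first use).
#' @return list with `val` (length F), `ds` (diagonal of the Jacobian w.r.t.
#'   s) and `dq` (F x S sparse Jacobian w.r.t. q).
#' @export
metabolic_vector <- function(sys, s, q, pre = NULL) {
  params <- sys$params
  M <- params$M; K <- params$K
  Fn <- sys$grid$F; S <- nrow(sys$sources)
  if (M == 0)
    return(list(val = numeric(Fn), ds = numeric(Fn),
                dq = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                          x = numeric(0), dims = c(Fn, S))))
  if (K <= 0) stop("metabolic_vector needs K > 0 when M > 0")
  if (is.null(pre)) pre <- metab_precomp(sys)
  scl <- -M / (2 * params$D)
  val <- numeric(Fn); ds <- numeric(Fn)
  di <- integer(0); dj <- integer(0); dxv <- numeric(0)
  for (k in seq_len(Fn)) {
    pk <- pre[[k]]
    m <- length(pk$js)
    phi <- s[k] + if (m) as.vector(pk$G %*% q[pk$js]) else 0
    if (any(phi <= -K))
      stop("concentration reached the Michaelis-Menten pole (phi <= -K) in cell ", k)
    sat <- 1 - K / (K + phi)
    dsat <- K / (K + phi)^2
    I0 <- sum(pk$w2 * sat)
    Id <- sum(pk$w2 * dsat)
    Iq <- if (m) as.vector(crossprod(pk$G, pk$w2 * dsat)) else numeric(0)
    for (dk in pk$disks) {
      phic <- s[k] + if (m) sum(dk$gcen * q[pk$js]) else 0
      I0 <- I0 - dk$area * (1 - K / (K + phic))
      dd <- K / (K + phic)^2
      Id <- Id - dk$area * dd
      if (m) Iq <- Iq - dk$area * dd * dk$gcen
    }
    val[k] <- scl * I0
    ds[k] <- scl * Id
    if (m) {
      di <- c(di, rep(k, m)); dj <- c(dj, pk$js); dxv <- c(dxv, scl * Iq)
    }
  }
  dq <- Matrix::sparseMatrix(i = di, j = dj, x = dxv, dims = c(Fn, S))
  list(val = val, ds = ds, dq = dq)
}

#' Total discrete flux of the reconstructed field through the outer boundary
#'
#' Sums, over all non-periodic boundary faces, the TPFA flux of the slow
#' field plus the quadrature flux of the rapid term — the discrete outflow of
#' `phi = s + r`. For nonreactive all-Dirichlet problems this balances the
#' total vessel-tissue exchange `sum(q)` (up to quadrature tolerance);
#' Neumann faces contribute zero by construction.
#'
#' @param fit an [ox_solve()] result.
#' @return Scalar outflow (same units as `q`).
#' @export
boundary_flux <- function(fit) {
  grid <- fit$grid; sys <- fit$system
  h <- grid$h; L <- grid$L; D <- fit$params$D
  bcs <- grid$bc$sides
  total <- 0
  face_out <- function(k, p0, p1, side) {
    kind <- bcs[side]
    if (kind == "periodic") return(0)
    cs <- sys$nbr$cell_sources[[k]]
    fi <- face_integrals(fit$sources, cs, p0, p1, side_normal(side),
                         D, nn0 = sys$face_nodes)
    rflux <- if (length(fi$j)) sum(D * fi$flx * fit$q[fi$j]) else 0
    if (kind == "dirichlet") {
      pts <- face_nodes(p0, p1, sys$face_nodes)
      w <- simpson_weights(sys$face_nodes)
      phid <- bc_value(grid$bc, side, pts[, 1L], pts[, 2L])
      dl <- h / (sys$face_nodes - 1L)
      f <- sum(w * phid) * dl / h
      if (length(fi$j)) f <- f - sum(fi$avg * fit$q[fi$j])
      sflux <- 2 * D * (fit$s[k] - f)
      sflux + rflux
    } else {
      0  # zero total flux imposed on Neumann faces
    }
  }
  for (iy in seq_len(grid$ny)) {
    for (ix in seq_len(grid$nx)) {
      k <- cell_id(grid, ix, iy)
      x0 <- (ix - 1L) * h; y0 <- (iy - 1L) * h
      if (ix == 1L && !grid$bc$periodic_x)
        total <- total + face_out(k, c(0, y0), c(0, y0 + h), "left")
      if (ix == grid$nx && !grid$bc$periodic_x)
        total <- total + face_out(k, c(L, y0), c(L, y0 + h), "right")
      if (iy == 1L && !grid$bc$periodic_y)
        total <- total + face_out(k, c(x0, 0), c(x0 + h, 0), "bottom")
      if (iy == grid$ny && !grid$bc$periodic_y)
        total <- total + face_out(k, c(x0, L), c(x0 + h, L), "top")
    }
  }
  total
}
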