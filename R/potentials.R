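## ---- single-layer (logarithmic) potentials -------------------------------
##
## The rapid part of the concentration field is a sum of single-source
## potentials. Only the flux-proportional part is kept:
##   g_j(x) = (1 / 2 pi D) ln(R_j / ||x - x_j||)   outside the disk,
##   g_j(x) = 0                                    inside (and on) the disk,
## so that q_j * g_j is the contribution of source j. The additive constant
## (the wall average) is absorbed into the slow field; g is continuous across
## the wall since ln(1) = 0.

## value of g for one source at (sx, sy), vectorised over evaluation points
pot_val <- function(x, y, sx, sy, R, D) {
  rho2 <- (x - sx)^2 + (y - sy)^2
  out <- numeric(length(rho2))
  ok <- rho2 > R^2
  out[ok] <- log(R^2 / rho2[ok]) / (4 * pi * D)
  out
}

## gradient of g (zero inside the disk)
pot_grad <- function(x, y, sx, sy, R, D) {
  dx <- x - sx; dy <- y - sy
  rho2 <- dx^2 + dy^2
  gx <- numeric(length(rho2)); gy <- gx
  ok <- rho2 > R^2
  c1 <- -1 / (2 * pi * D)
  gx[ok] <- c1 * dx[ok] / rho2[ok]
  gy[ok] <- c1 * dy[ok] / rho2[ok]
  list(gx = gx, gy = gy)
}

#' Single-source logarithmic potential
#'
#' Flux-proportional part of the single-layer potential of a circular source:
#' `q / (2 pi D) * ln(R / ||x - x_j||)` outside the disk and 0 inside. The
#' wall average (the additive constant of the full potential) is carried by
#' the slow field, so the retained part vanishes on the vessel wall.
#'
#' @param source one-row [ox_sources()] table (or list with `x`, `y`, `r`).
#' @param q flux per unit length carried by the source.
#' @param x,y evaluation points (vectorised).
#' @param D tissue diffusion coefficient.
#' @return Concentration contribution at the points.
#' @export
#' @examples
#' s <- ox_sources(0, 0, r = 1)
#' source_potential(s, q = 2 * pi * 2000, x = exp(1), y = 0, D = 2000)  # -1
source_potential <- function(source, q, x, y, D) {
  q * pot_val(x, y, source$x[1L], source$y[1L], source$r[1L], D)
}

## rapid field of one cell: value (and optionally gradient) at points.
## `cellsrc` is one entry of nbr$cell_sources; `shift` translates the
## evaluation points into the cell's frame (used across periodic wraps).
rapid_eval <- function(sources, cellsrc, q, x, y, D, grad = FALSE,
                       shift = c(0, 0)) {
  x <- x - shift[1L]; y <- y - shift[2L]
  val <- numeric(length(x))
  gx <- numeric(length(x)); gy <- numeric(length(x))
  if (nrow(cellsrc) > 0L) {
    for (i in seq_len(nrow(cellsrc))) {
      j <- cellsrc$j[i]
      sx <- sources$x[j] + cellsrc$ox[i]
      sy <- sources$y[j] + cellsrc$oy[i]
      val <- val + q[j] * pot_val(x, y, sx, sy, sources$r[j], D)
      if (grad) {
        gr <- pot_grad(x, y, sx, sy, sources$r[j], D)
        gx <- gx + q[j] * gr$gx
        gy <- gy + q[j] * gr$gy
      }
    }
  }
  if (grad) list(val = val, gx = gx, gy = gy) else val
}

#' Rapid (analytic) field of a grid cell
#'
#' Sum of the localized single-source potentials attached to cell `k`
#' (the sources in its neighborhood set), evaluated by analytic continuation
#' at arbitrary points, together with its gradient.
#'
#' @param fit an [ox_solve()] result, or a list with fields `grid`, `sources`,
#'   `nbr`, `params` and flux vector `q`.
#' @param k cell index.
#' @param x,y evaluation points.
#' @param q optional flux vector overriding `fit$q`.
#' @return `list(val, gx, gy)`.
#' @export
rapid_field <- function(fit, k, x, y, q = fit$q) {
  rapid_eval(fit$sources, fit$nbr$cell_sources[[k]], q, x, y,
             fit$params$D, grad = TRUE)
}

#' Localization error bound
#'
#' Upper bound of the relative perturbation induced by truncating the rapid
#' field to an `n x n` neighborhood: sources outside the block contribute
#' `4 |q_j| / (2 pi D (n - 1)^2)` each, so the bound decays like
#' `1 / (n - 1)^2`.
#'
#' @param q fluxes of the sources *outside* the neighborhood (those inside
#'   contribute nothing).
#' @param D tissue diffusion coefficient.
#' @param n neighborhood size (>= 3).
#' @return Nonnegative scalar bound (concentration units).
#' @export
localization_error_bound <- function(q, D, n) {
  stopifnot(n >= 3)
  sum(4 * abs(q)) / (2 * pi * D * (n - 1)^2)
}

## ---- face-jump machinery --------------------------------------------------

## Simpson nodes along a face from p0 to p1 (columns x, y)
face_nodes <- function(p0, p1, nn) {
  t <- seq(0, 1, length.out = nn)
  cbind(x = p0[1L] + t * (p1[1L] - p0[1L]),
        y = p0[2L] + t * (p1[2L] - p0[2L]))
}

## default node count for face quadrature: resolves the smallest source
## radius, minimum 11, odd
face_nn <- function(h, rmin) {
  nn <- max(11L, 2L * as.integer(ceiling(h / rmin)) + 1L)
  if (nn %% 2L == 0L) nn + 1L else nn
}

## Per-source face integrals of the rapid term of ONE cell on a straight
## face: for each member (j, ox, oy) of `cellsrc`, returns
##   avg_g  = (1/len) int g_j dl        and
##   flx_g  = int n . grad g_j dl
## along the segment p0 -> p1 with unit normal `nrm`. Composite Simpson,
## with the node count doubled until two successive levels agree to
## `tol` (relative to the largest integral), so near-tangent sources are
## integrated accurately. `shift` translates points into the cell frame.
face_integrals <- function(sources, cellsrc, p0, p1, nrm, D,
                           nn0 = 11L, tol = 1e-10, shift = c(0, 0)) {
  m <- nrow(cellsrc)
  if (m == 0L) return(list(j = integer(0), avg = numeric(0), flx = numeric(0)))
  len <- sqrt(sum((p1 - p0)^2))
  ## evaluating at pts - shift with the member offsets is the same as
  ## shifting the effective source positions by + shift
  sx <- sources$x[cellsrc$j] + cellsrc$ox + shift[1L]
  sy <- sources$y[cellsrc$j] + cellsrc$oy + shift[2L]
  Rj <- sources$r[cellsrc$j]
  c1 <- -1 / (2 * pi * D)
  level <- function(nn) {
    pts <- face_nodes(p0, p1, nn)
    w <- simpson_weights(nn)
    dl <- len / (nn - 1L)
    ## vectorized over (node, member)
    dx <- rep(pts[, 1L], m) - rep(sx, each = nn)
    dy <- rep(pts[, 2L], m) - rep(sy, each = nn)
    rho2 <- dx^2 + dy^2
    R2 <- rep(Rj^2, each = nn)
    ok <- rho2 > R2
    g <- numeric(nn * m)
    g[ok] <- log(R2[ok] / rho2[ok]) / (4 * pi * D)
    gn <- numeric(nn * m)
    gn[ok] <- c1 * (dx[ok] * nrm[1L] + dy[ok] * nrm[2L]) / rho2[ok]
    dim(g) <- c(nn, m); dim(gn) <- c(nn, m)
    list(avg = as.vector(crossprod(w, g)) * dl / len,
         flx = as.vector(crossprod(w, gn)) * dl)
  }
  nn <- nn0
  cur <- level(nn)
  repeat {
    nn2 <- 2L * nn - 1L
    if (nn2 > 4097L) break
    nxt <- level(nn2)
    scale <- max(abs(c(cur$avg, cur$flx, nxt$avg, nxt$flx)), 1e-300)
    if (max(abs(c(nxt$avg - cur$avg, nxt$flx - cur$flx))) < tol * scale) {
      cur <- nxt
      break
    }
    nn <- nn2; cur <- nxt
  }
  list(j = cellsrc$j, avg = cur$avg, flx = cur$flx)
}

#' Face-jump coefficients of the rapid term
#'
#' Linear coefficients (in the flux vector `q`) of the jump term
#' \deqn{J_{k,m} = \tfrac12 \int_{\partial V_{k,m}} n \cdot (\nabla r_m -
#' \nabla r_k)\, dl + \tfrac1h \int_{\partial V_{k,m}} (r_m - r_k)\, dl,}
#' which transfers the localization-induced discontinuities of the rapid term
#' across a finite-volume face into the slow-field balance. Both line
#' integrals use adaptive composite Simpson quadrature. Exchanging the two
#' cells flips both the normal and the operand order: the flux half is then
#' unchanged while the value half changes sign (their sum over the two
#' adjacent rows is what deposits each source's flux into the slow field);
#' the jump is identically zero when the two cells carry the same
#' (source, image) sets.
#'
#' @param grid,sources,nbr grid, source table and [build_neighborhoods()] map.
#' @param k,m cell indices of the two sides; `m` is reached from `k` along
#'   `normal`.
#' @param p0,p1 face endpoints in `k`'s frame.
#' @param normal unit normal pointing from `k` into `m`.
#' @param wrap translation such that `pts - wrap` lies in `m`'s frame
#'   (nonzero only across a periodic wrap).
#' @param D tissue diffusion coefficient.
#' @param nn number of Simpson nodes (odd).
#' @return Numeric vector of length `nrow(sources)`: coefficients such that
#'   `J_{k,m} = sum(coef * q)`.
#' @export
face_jump <- function(grid, sources, nbr, k, m, p0, p1, normal,
                      wrap = c(0, 0), D, nn = NULL) {
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop("degenerate (zero-length) face")
  if (is.null(nn))
    nn <- face_nn(grid$h, if (nrow(sources)) min(sources$r) else grid$h)
  coef <- numeric(nrow(sources))
  ## skip entirely when the two rapid fields are identical
  same <- identical(nbr$key[k], nbr$key[m]) && all(wrap == 0)
  if (same) return(coef)
  fk <- face_integrals(sources, nbr$cell_sources[[k]], p0, p1, normal, D,
                       nn0 = nn)
  fm <- face_integrals(sources, nbr$cell_sources[[m]], p0, p1, normal, D,
                       nn0 = nn, shift = wrap)
  if (length(fm$j))
    for (i in seq_along(fm$j))
      coef[fm$j[i]] <- coef[fm$j[i]] + 0.5 * fm$flx[i] + fm$avg[i]
  if (length(fk$j))
    for (i in seq_along(fk$j))
      coef[fk$j[i]] <- coef[fk$j[i]] - 0.5 * fk$flx[i] - fk$avg[i]
  coef
}
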