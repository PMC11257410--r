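#' Boundary condition specification for a rectangular domain
#'
#' Each of the four sides carries one of three conditions: `"dirichlet"`
#' (fixed concentration), `"neumann"` (zero total flux) or `"periodic"`.
#' Periodic sides must come in opposite pairs (left/right, bottom/top).
#' Dirichlet values may be constants or functions of the along-side
#' coordinate (a function of `(x, y)` returning concentrations).
#'
#' @param left,right,bottom,top side conditions, each one of
#'   `"dirichlet"`, `"neumann"`, `"periodic"`.
#' @param values named list of Dirichlet values (constant or `function(x, y)`)
#'   for the sides that are Dirichlet; a single unnamed constant is recycled
#'   to every Dirichlet side. Defaults to 0.
#' @return An object of class `ox_bc`.
#' @export
#' @examples
#' ox_bc()                                  # all Dirichlet, value 0
#' ox_bc("periodic", "periodic", "periodic", "periodic")
#' ox_bc(bottom = "neumann", values = list(0))
ox_bc <- function(left = "dirichlet", right = "dirichlet",
                  bottom = "dirichlet", top = "dirichlet",
                  values = list(0)) {
  sides <- c(left = left, right = right, bottom = bottom, top = top)
  ok <- c("dirichlet", "neumann", "periodic")
  if (!all(sides %in% ok))
    stop("boundary conditions must be one of: ", paste(ok, collapse = ", "))
  if (xor(sides["left"] == "periodic", sides["right"] == "periodic") ||
      xor(sides["bottom"] == "periodic", sides["top"] == "periodic"))
    stop("periodic sides must come in opposite pairs")
  vals <- list(left = 0, right = 0, bottom = 0, top = 0)
  if (!is.null(values)) {
    if (is.null(names(values)) || identical(names(values), rep("", length(values)))) {
      if (length(values) != 1L)
        stop("unnamed `values` must be a single constant")
      for (s in names(vals)) vals[[s]] <- values[[1L]]
    } else {
      for (s in names(values)) {
        if (!s %in% names(vals)) stop("unknown side in `values`: ", s)
        vals[[s]] <- values[[s]]
      }
    }
  }
  structure(list(sides = sides, values = vals,
                 periodic_x = unname(sides["left"] == "periodic"),
                 periodic_y = unname(sides["bottom"] == "periodic")),
            class = "ox_bc")
}

## evaluate the Dirichlet value of a side at points (x, y)
bc_value <- function(bc, side, x, y) {
  v <- bc$values[[side]]
  if (is.function(v)) v(x, y) else rep(v, length.out = length(x))
}

#' Coarse cartesian finite-volume grid
#'
#' Builds the square-cell tessellation used by the coarse finite-volume
#' discretization: cell centers, neighbour topology (with periodic wrapping
#' where requested) and the boundary-condition bookkeeping. Cells own the
#' half-open square `[x, x + h) x [y, y + h)`.
#'
#' @param L domain side length (um); the domain is the square `[0, L]^2`.
#' @param cells number of cells per side (`>= 3`).
#' @param bc an [ox_bc()] boundary specification.
#' @return An object of class `ox_grid` with fields `L`, `nx`, `ny`, `h`,
#'   `xc`, `yc` (cell-center coordinate vectors), `cx`, `cy` (per-cell center
#'   coordinates, column-major over `ix` then `iy`), and `bc`.
#' @export
#' @examples
#' g <- ox_grid(240, 5)          # h = 48 um, 25 cells
#' g$h
ox_grid <- function(L, cells, bc = ox_bc()) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0,
            is.numeric(cells), length(cells) == 1L)
  cells <- as.integer(cells)
  if (cells < 3L)
    stop("the coarse grid needs at least 3 cells per side")
  if (!inherits(bc, "ox_bc")) stop("`bc` must be an ox_bc() object")
  h <- L / cells
  xc <- (seq_len(cells) - 0.5) * h
  idx <- expand.grid(ix = seq_len(cells), iy = seq_len(cells))
  structure(list(L = L, nx = cells, ny = cells, h = h,
                 xc = xc, yc = xc,
                 cx = xc[idx$ix], cy = xc[idx$iy],
                 ix = idx$ix, iy = idx$iy,
                 F = cells * cells, bc = bc),
            class = "ox_grid")
}

#' @export
print.ox_grid <- function(x, ...) {
  cat(sprintf("Cartesian FV grid: %d x %d cells, h = %g um on [0, %g]^2 um\n",
              x$nx, x$ny, x$h, x$L))
  cat("  sides:", paste(sprintf("%s=%s", names(x$bc$sides), x$bc$sides),
                        collapse = ", "), "\n")
  invisible(x)
}

## linear cell index from 1-based (ix, iy)
cell_id <- function(grid, ix, iy) (iy - 1L) * grid$nx + ix

## wrap a coordinate into [0, L) for a periodic axis
wrap_coord <- function(v, L) v - L * floor(v / L)

#' Locate the grid cell containing a point
#'
#' Cells own the half-open square `[x, x+h) x [y, y+h)`, so a point lying
#' exactly on an interior face belongs to the cell on its +x / +y side.
#' On periodic axes the point is wrapped into the domain first.
#'
#' @param grid an [ox_grid()].
#' @param x,y point coordinates (um), vectorised.
#' @return Integer vector of linear cell indices (column-major, x fastest).
#' @export
#' @examples
#' g <- ox_grid(240, 5)
#' locate_cell(g, 120, 120)   # central cell
locate_cell <- function(grid, x, y) {
  L <- grid$L; h <- grid$h
  if (grid$bc$periodic_x) x <- wrap_coord(x, L)
  if (grid$bc$periodic_y) y <- wrap_coord(y, L)
  eps <- 1e-9 * L
  if (any(x < -eps | x > L + eps | y < -eps | y > L + eps))
    stop("point outside the (non-periodic) domain")
  ix <- pmin(pmax(floor(x / h), 0), grid$nx - 1L) + 1L
  iy <- pmin(pmax(floor(y / h), 0), grid$ny - 1L) + 1L
  ## half-open rule: x exactly on a face belongs to the +x cell; floor()
  ## already does that, but clamp points sitting exactly on the far domain
  ## edge into the last cell
  cell_id(grid, as.integer(ix), as.integer(iy))
}

## Area of the intersection between the disk (cx, cy, r) and the axis-aligned
## rectangle [x0, x1] x [y0, y1]. Chord integration with composite Simpson on
## a fine subdivision; exact enough (rel. error < 1e-8) for the small vessel
## disks used here.
circle_rect_overlap <- function(cx, cy, r, x0, x1, y0, y1) {
  a <- max(x0, cx - r); b <- min(x1, cx + r)
  if (a >= b) return(0)
  nn <- 201L
  xs <- seq(a, b, length.out = nn)
  half <- sqrt(pmax(r^2 - (xs - cx)^2, 0))
  lo <- pmax(cy - half, y0); hi <- pmin(cy + half, y1)
  chord <- pmax(hi - lo, 0)
  w <- simpson_weights(nn) * (b - a) / (nn - 1L)
  sum(w * chord)
}

## composite Simpson weights for an odd number of equally spaced nodes,
## normalised so that sum(w * f) * dx integrates f (weights exclude dx)
simpson_weights <- function(n) {
  stopifnot(n >= 3L, n %% 2L == 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1; w[n] <- 1
  w / 3
}
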