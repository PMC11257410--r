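#' Localization neighborhoods for the rapid term
#'
#' For every source `j`, the analytic (rapid) part of the concentration field
#' is only carried by an `n x n` block of grid cells centered on the cell
#' containing the source. Conversely, every cell `k` keeps the set
#' `E(Vhat_k)` of sources whose block contains it; only those potentials are
#' summed in the cell's rapid field. Blocks are clipped at non-periodic
#' boundaries and wrapped (with the matching periodic image of the source) at
#' periodic ones.
#'
#' `n` controls the localization error, which decays like `1/(n-1)^2`; odd
#' `n >= 3` gives a block centered on the host cell. Even `n` is accepted
#' (the block extends one extra cell towards +x/+y, consistent with the
#' half-open cell convention) so that study configurations with even
#' neighborhood sizes can be reproduced.
#'
#' @param grid an [ox_grid()].
#' @param sources an [ox_sources()] table.
#' @param n neighborhood size in cells per side (`>= 3`, at most the number
#'   of cells per side).
#' @return An object of class `ox_neighborhoods` with fields:
#'   `n`; `blocks` (per source, integer vector of member cell ids);
#'   `cell_sources` (per cell, data.frame with columns `j`, `ox`, `oy` giving
#'   the member sources and the periodic image offsets under which they are
#'   seen from that cell); and `key` (per cell, character key identifying the
#'   (source, image) set, used to detect faces with identical rapid fields).
#' @export
#' @examples
#' g <- ox_grid(240, 5)
#' s <- ox_sources(120, 120)
#' nb <- build_neighborhoods(g, s, n = 3)
#' sum(lengths(lapply(nb$cell_sources, function(d) d$j)) > 0)  # 9 cells
build_neighborhoods <- function(grid, sources, n) {
  n <- as.integer(n)
  if (n < 3L) stop("neighborhood size n must be >= 3")
  if (n > grid$nx || n > grid$ny)
    stop("neighborhood size n cannot exceed the number of cells per side")
  validate_sources(grid, sources)
  S <- nrow(sources)
  Fn <- grid$F
  cs <- vector("list", Fn)
  for (k in seq_len(Fn)) cs[[k]] <- list(j = integer(0), ox = numeric(0), oy = numeric(0))
  blocks <- vector("list", max(S, 0L))
  lo <- (n - 1L) %/% 2L
  hi <- n %/% 2L
  if (S > 0L) {
    host <- locate_cell(grid, sources$x, sources$y)
    for (j in seq_len(S)) {
      hix <- grid$ix[host[j]]; hiy <- grid$iy[host[j]]
      members <- integer(0)
      for (dy in (-lo):hi) {
        for (dx in (-lo):hi) {
          ux <- hix + dx; uy <- hiy + dy   # unwrapped 1-based indices
          if (grid$bc$periodic_x) {
            wx <- ((ux - 1L) %% grid$nx) + 1L
            offx <- -grid$L * ((ux - wx) %/% grid$nx)
          } else {
            if (ux < 1L || ux > grid$nx) next
            wx <- ux; offx <- 0
          }
          if (grid$bc$periodic_y) {
            wy <- ((uy - 1L) %% grid$ny) + 1L
            offy <- -grid$L * ((uy - wy) %/% grid$ny)
          } else {
            if (uy < 1L || uy > grid$ny) next
            wy <- uy; offy <- 0
          }
          k <- cell_id(grid, wx, wy)
          members <- c(members, k)
          cs[[k]]$j <- c(cs[[k]]$j, j)
          cs[[k]]$ox <- c(cs[[k]]$ox, offx)
          cs[[k]]$oy <- c(cs[[k]]$oy, offy)
        }
      }
      blocks[[j]] <- members
    }
  }
  cell_sources <- lapply(cs, function(d) {
    df <- data.frame(j = d$j, ox = d$ox, oy = d$oy)
    df[order(df$j, df$ox, df$oy), , drop = FALSE]
  })
  key <- vapply(cell_sources, function(d) {
    if (nrow(d) == 0L) "" else paste(sprintf("%d@%g@%g", d$j, d$ox, d$oy),
                                     collapse = ";")
  }, character(1))
  structure(list(n = n, blocks = blocks, cell_sources = cell_sources,
                 key = key, S = S),
            class = "ox_neighborhoods")
}
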