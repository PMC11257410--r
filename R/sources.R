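#' Circular vascular sources
#'
#' A set of circular vessel cross-sections embedded in the tissue domain.
#' Each source has a center, a radius, a cross-section averaged intravascular
#' concentration `cv` and an effective exchange coefficient `keff` (see
#' [effective_permeability()]). The source disks must lie inside the domain
#' and be pairwise disjoint.
#'
#' @param x,y center coordinates (um).
#' @param r radii (um), recycled.
#' @param cv intravascular concentrations (nmol cm^-3), recycled.
#' @param keff effective exchange coefficients (um^2/s), recycled.
#' @return A data.frame of class `ox_sources` with columns `x`, `y`, `r`,
#'   `cv`, `keff`.
#' @export
#' @examples
#' ox_sources(120, 120, r = 4.8, cv = 137, keff = 2000)
ox_sources <- function(x, y, r = 4.8, cv = 137, keff = 2000) {
  n <- length(x)
  stopifnot(length(y) == n)
  s <- data.frame(x = as.numeric(x), y = as.numeric(y),
                  r = rep_len(as.numeric(r), n),
                  cv = rep_len(as.numeric(cv), n),
                  keff = rep_len(as.numeric(keff), n))
  if (n > 0 && (any(s$r <= 0) || any(s$keff <= 0)))
    stop("source radii and exchange coefficients must be strictly positive")
  class(s) <- c("ox_sources", "data.frame")
  s
}

## validate sources against a grid: inside the domain, pairwise disjoint.
## Distances use the periodic metric on periodic axes.
validate_sources <- function(grid, sources) {
  if (nrow(sources) == 0L) return(invisible(TRUE))
  L <- grid$L
  if (!grid$bc$periodic_x &&
      any(sources$x - sources$r < 0 | sources$x + sources$r > L))
    stop("a source disk crosses a non-periodic x boundary of the domain")
  if (!grid$bc$periodic_y &&
      any(sources$y - sources$r < 0 | sources$y + sources$r > L))
    stop("a source disk crosses a non-periodic y boundary of the domain")
  n <- nrow(sources)
  if (n > 1L) {
    dx <- abs(outer(sources$x, sources$x, "-"))
    dy <- abs(outer(sources$y, sources$y, "-"))
    if (grid$bc$periodic_x) dx <- pmin(dx, L - dx)
    if (grid$bc$periodic_y) dy <- pmin(dy, L - dy)
    dist <- sqrt(dx^2 + dy^2)
    rsum <- outer(sources$r, sources$r, "+")
    diag(dist) <- Inf
    if (any(dist <= rsum))
      stop("source disks overlap")
  }
  invisible(TRUE)
}

#' Hard-core random placement of capillary sources
#'
#' Draws source centers uniformly in the domain under a minimum-separation
#' (hard-core) constraint, optionally excluding a central disk (the
#' capillary-free periarteriolar region). Placement is by dart throwing with
#' bounded retries and is reproducible for a given seed. On periodic domains
#' distances are measured with the periodic metric.
#'
#' @param L domain side (um).
#' @param count number of sources to place.
#' @param min_sep minimum center-to-center separation (um); default 25 um,
#'   the order of typical capillary spacing at cortical densities.
#' @param exclusion optional `list(x=, y=, r=)` disk from which centers are
#'   excluded.
#' @param periodic logical; use the periodic distance metric.
#' @param margin keep centers at least this far from non-periodic boundaries.
#' @param seed integer seed (applied with [set.seed()]); `NULL` leaves the
#'   random-number state untouched.
#' @param max_tries maximum dart throws before giving up.
#' @return A two-column matrix of centers (`x`, `y`).
#' @export
#' @examples
#' xy <- sample_hardcore_sources(240, 17, seed = 1, periodic = TRUE)
#' nrow(xy)
sample_hardcore_sources <- function(L, count, min_sep = 25,
                                    exclusion = NULL, periodic = TRUE,
                                    margin = 0, seed = NULL,
                                    max_tries = 20000L * max(count, 1L)) {
  if (!is.null(seed)) set.seed(seed)
  if (count == 0L) return(matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))))
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  lo <- margin; hi <- L - margin
  while (length(xs) < count) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("hard-core packing infeasible after ", max_tries, " tries")
    px <- runif(1, lo, hi); py <- runif(1, lo, hi)
    if (!is.null(exclusion)) {
      dx <- px - exclusion$x; dy <- py - exclusion$y
      if (periodic) {
        dx <- dx - L * round(dx / L); dy <- dy - L * round(dy / L)
      }
      if (dx^2 + dy^2 < exclusion$r^2) next
    }
    if (length(xs)) {
      dx <- abs(xs - px); dy <- abs(ys - py)
      if (periodic) { dx <- pmin(dx, L - dx); dy <- pmin(dy, L - dy) }
      if (any(dx^2 + dy^2 < min_sep^2)) next
    }
    xs <- c(xs, px); ys <- c(ys, py)
  }
  cbind(x = xs, y = ys)
}
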