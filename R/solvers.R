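## ---- linear and nonlinear solvers -------------------------------------------

## stack the blocks into one sparse (F+S) x (F+S) matrix
full_matrix <- function(sys, dAs = NULL, dBq = NULL) {
  A <- sys$A; B <- sys$B
  if (!is.null(dAs)) A <- A + Matrix::Diagonal(x = dAs)
  if (!is.null(dBq)) B <- B + dBq
  rbind(cbind(A, B), cbind(sys$C, sys$D))
}

#' Solve the nonreactive (linear) discrete system
#'
#' Direct sparse solve of the coupled slow-field/exchange system. Fails with
#' diagnostics if the system is singular (for example a pure-Neumann problem
#' without sources).
#'
#' @param sys an [assemble_system()] result.
#' @return list with `s` (length F), `q` (length S), `residual` (relative
#'   residual of the full system) and `iterations` (0 for the direct solve).
#' @export
solve_nonreactive <- function(sys) {
  Fn <- sys$grid$F; S <- nrow(sys$sources)
  M <- full_matrix(sys)
  rhs <- c(sys$b, sys$bb)
  sol <- tryCatch(as.vector(Matrix::solve(M, rhs)),
                  error = function(e)
                    stop("linear system is singular or ill-conditioned ",
                         "(pure-Neumann nonreactive problems without sources ",
                         "are ill-posed): ", conditionMessage(e)))
  res <- as.vector(M %*% sol) - rhs
  nb <- sqrt(sum(rhs^2))
  list(s = sol[seq_len(Fn)],
       q = if (S) sol[Fn + seq_len(S)] else numeric(0),
       residual = sqrt(sum(res^2)) / max(nb, .Machine$double.eps),
       iterations = 0L, residual_history = numeric(0))
}

#' Solve the reactive (Michaelis-Menten) discrete system
#'
#' Newton-Raphson iteration on the coupled residual, with the exact Jacobian
#' of the metabolic volume terms and step halving when a step fails to reduce
#' the residual. The nonreactive solution is the initial guess.
#'
#' @param sys an [assemble_system()] result.
#' @param tol relative residual tolerance (default 1e-10).
#' @param max_iter maximum Newton iterations.
#' @param metab_nodes Simpson nodes per cell side for the metabolic integrals.
#' @return list with `s`, `q`, `residual`, `iterations`,
#'   `residual_history`.
#' @export
solve_reactive <- function(sys, tol = 1e-10, max_iter = 50L,
                           metab_nodes = 11L) {
  lin <- solve_nonreactive(sys)
  if (sys$params$M == 0) return(lin)
  Fn <- sys$grid$F; S <- nrow(sys$sources)
  pre <- metab_precomp(sys, nq = metab_nodes)
  rhs <- c(sys$b, sys$bb)
  nb <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
  xx <- c(lin$s, lin$q)
  resid <- function(xx) {
    s <- xx[seq_len(Fn)]; q <- if (S) xx[Fn + seq_len(S)] else numeric(0)
    mv <- metabolic_vector(sys, s, q, pre)
    r <- c(as.vector(sys$A %*% s) + as.vector(sys$B %*% q) + mv$val - sys$b,
           as.vector(sys$C %*% s) + as.vector(sys$D %*% q) - sys$bb)
    list(r = r, mv = mv)
  }
  rr <- resid(xx)
  rn <- sqrt(sum(rr$r^2)) / nb
  hist <- rn
  it <- 0L
  while (rn > tol && it < max_iter) {
    it <- it + 1L
    J <- rbind(cbind(sys$A + Matrix::Diagonal(x = rr$mv$ds),
                     sys$B + rr$mv$dq),
               cbind(sys$C, sys$D))
    dx <- as.vector(Matrix::solve(J, -rr$r))
    step <- 1
    for (tr in 0:8) {
      xn <- xx + step * dx
      rrn <- tryCatch(resid(xn), error = function(e) NULL)
      if (!is.null(rrn)) {
        rnn <- sqrt(sum(rrn$r^2)) / nb
        if (rnn < rn || rnn < tol) break
      }
      step <- step / 2
    }
    if (is.null(rrn) || (rnn >= rn && rnn > tol))
      stop("Newton iteration stalled; residual history: ",
           paste(signif(c(hist, if (!is.null(rrn)) rnn), 4), collapse = ", "))
    xx <- xn; rr <- rrn; rn <- rnn
    hist <- c(hist, rn)
  }
  if (rn > tol)
    stop("Newton did not converge in ", max_iter, " iterations; residuals: ",
         paste(signif(hist, 4), collapse = ", "))
  list(s = xx[seq_len(Fn)],
       q = if (S) xx[Fn + seq_len(S)] else numeric(0),
       residual = rn, iterations = it, residual_history = hist)
}

#' Fit the multiscale oxygen-transport model
#'
#' The main entry point: assembles and solves the steady diffusion
#' (--consumption) problem for a set of circular vascular sources on a coarse
#' cartesian grid, using the slow/rapid operator splitting (or the well-mixed
#' coarse-grid baseline). Returns a fitted-model object with the usual
#' accessor methods ([predict.ox_fit()] evaluates the sub-grid
#' reconstruction).
#'
#' @param grid an [ox_grid()].
#' @param sources an [ox_sources()] table (possibly empty).
#' @param params an [ox_params()]; metabolism is on whenever `params$M > 0`.
#' @param n neighborhood size (cells per side) for the rapid-term
#'   localization; >= 3.
#' @param method `"multiscale"` (default) or `"coarse_fv"` (the well-mixed
#'   baseline without any rapid term).
#' @param wall_mode wall-average closure for the exchange rows; see
#'   [wall_average()].
#' @param tol,max_iter Newton controls for the reactive problem.
#' @param metab_nodes Simpson nodes per cell side for metabolic integrals.
#' @param face_nodes Simpson nodes per face for the jump integrals.
#' @return An object of class `ox_fit` with components `s` (slow field),
#'   `q` (wall fluxes), `grid`, `sources`, `params`, `nbr`, `dualmesh`,
#'   `system`, and `convergence`.
#' @export
#' @examples
#' g <- ox_grid(240, 5)
#' s <- ox_sources(120, 120, r = 4.8, cv = 137, keff = 2000)
#' fit <- ox_solve(g, s, ox_params(), n = 3)
#' coef(fit)          # wall flux q
ox_solve <- function(grid, sources = ox_sources(numeric(0), numeric(0)),
                     params = ox_params(), n = 3L,
                     method = c("multiscale", "coarse_fv"),
                     wall_mode = c("interpolated", "nearest_cell"),
                     tol = 1e-10, max_iter = 50L, metab_nodes = 11L,
                     face_nodes = NULL) {
  method <- match.arg(method)
  wall_mode <- match.arg(wall_mode)
  sys <- assemble_system(grid, sources, params, n = n, wall_mode = wall_mode,
                         rapid = (method == "multiscale"),
                         face_nodes = face_nodes)
  sol <- if (params$M > 0)
    solve_reactive(sys, tol = tol, max_iter = max_iter,
                   metab_nodes = metab_nodes)
  else solve_nonreactive(sys)
  structure(list(s = sol$s, q = sol$q, grid = grid, sources = sources,
                 params = params, nbr = sys$nbr, dualmesh = sys$dualmesh,
                 system = sys, method = method, wall_mode = wall_mode,
                 n = n,
                 convergence = list(iterations = sol$iterations,
                                    residual = sol$residual,
                                    residual_history = sol$residual_history)),
            class = "ox_fit")
}

## ---- S3 methods -------------------------------------------------------------

#' @export
print.ox_fit <- function(x, ...) {
  cat(sprintf("Multiscale oxygen transport fit (%s, wall mode: %s)\n",
              x$method, x$wall_mode))
  print(x$grid)
  cat(sprintf("  sources: %d; neighborhood n = %d\n", nrow(x$sources), x$n))
  cat(sprintf("  %s problem, residual %.2e (%d Newton iterations)\n",
              if (x$params$M > 0) "reactive" else "nonreactive",
              x$convergence$residual, x$convergence$iterations))
  if (length(x$q))
    cat("  wall fluxes q:", paste(signif(x$q, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ox_fit <- function(object, ...) {
  phi <- cell_center_concentration(object)
  out <- list(fit = object, phi_range = range(phi), phi_mean = mean(phi),
              q = object$q,
              total_exchange = sum(object$q),
              wall = if (nrow(object$sources)) wall_average(object) else numeric(0))
  class(out) <- "summary.ox_fit"
  out
}

#' @export
print.summary.ox_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  cell-center concentration: mean %.3g, range [%.3g, %.3g]\n",
              x$phi_mean, x$phi_range[1L], x$phi_range[2L]))
  cat(sprintf("  total vessel-tissue exchange sum(q) = %.6g\n",
              x$total_exchange))
  if (length(x$wall))
    cat("  wall averages:", paste(signif(x$wall, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ox_fit <- function(object, ...) {
  setNames(object$q,
           if (length(object$q)) paste0("q", seq_along(object$q)) else NULL)
}

#' Reconstructed concentration at new points
#'
#' @param object an [ox_solve()] fit.
#' @param newdata data.frame with columns `x` and `y` (um). Defaults to the
#'   FV cell centers.
#' @param mask_vessels replace in-vessel points by wall averages.
#' @param ... unused.
#' @return Numeric vector of concentrations.
#' @export
predict.ox_fit <- function(object, newdata = NULL, mask_vessels = TRUE, ...) {
  if (is.null(newdata))
    return(cell_center_concentration(object))
  phi <- interpolate_concentration(object, newdata$x, newdata$y)
  if (mask_vessels)
    phi <- mask_wall_values(object, newdata$x, newdata$y, phi)$phi
  phi
}

#' @export
residuals.ox_fit <- function(object, ...) {
  sys <- object$system
  s <- object$s; q <- object$q
  mv <- metabolic_vector(sys, s, q)
  c(as.vector(sys$A %*% s) + as.vector(sys$B %*% q) + mv$val - sys$b,
    as.vector(sys$C %*% s) + as.vector(sys$D %*% q) - sys$bb)
}

#' Plot the reconstructed concentration field
#'
#' @param x an [ox_solve()] fit.
#' @param resolution raster points per side.
#' @param ... passed to [graphics::image()].
#' @export
plot.ox_fit <- function(x, resolution = 8L * x$grid$nx, ...) {
  ras <- raster_field(x, resolution)
  image(ras$x, ras$y, ras$phi, asp = 1, col = hcl.colors(64, "viridis"),
        xlab = "x (um)", ylab = "y (um)",
        main = "reconstructed oxygen concentration", ...)
  if (nrow(x$sources))
    symbols(x$sources$x, x$sources$y, circles = x$sources$r, inches = FALSE,
            add = TRUE, fg = "white")
  invisible(ras)
}
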