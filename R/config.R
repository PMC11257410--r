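#' Read a solver configuration from a YAML file
#'
#' Configuration layout (units: um, s, nmol cm^-3):
#' ```yaml
#' domain: {side_um: 240, cells: 5,
#'          bc: {left: dirichlet, right: dirichlet,
#'               top: dirichlet, bottom: dirichlet, value: 0}}
#' sources:
#'   - {x_um: 120, y_um: 120, r_um: 4.8, cv: 137, keff: 2000}
#' params: {D: 2000, M: 0, K: 13.7, alpha: 1.39, phi_max: 137}
#' solver: {n: 3, tol: 1e-10, max_iter: 50, wall_mode: interpolated,
#'          method: multiscale, seed: 1}
#' ```
#'
#' @param path path to the YAML file.
#' @return list with `grid`, `sources`, `params`, `solver`.
#' @export
read_ox_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$domain)) stop("config is missing the `domain` section")
  dom <- cfg$domain
  bcspec <- dom$bc
  if (is.null(bcspec)) bcspec <- list()
  val <- if (!is.null(bcspec$value)) list(bcspec$value) else list(0)
  bc <- ox_bc(left = bcspec$left %||% "dirichlet",
              right = bcspec$right %||% "dirichlet",
              bottom = bcspec$bottom %||% "dirichlet",
              top = bcspec$top %||% "dirichlet",
              values = val)
  grid <- ox_grid(dom$side_um, dom$cells, bc)
  src <- cfg$sources
  sources <- if (is.null(src) || length(src) == 0L)
    ox_sources(numeric(0), numeric(0))
  else ox_sources(vapply(src, `[[`, numeric(1), "x_um"),
                  vapply(src, `[[`, numeric(1), "y_um"),
                  vapply(src, function(s) s$r_um %||% 4.8, numeric(1)),
                  vapply(src, function(s) s$cv %||% 137, numeric(1)),
                  vapply(src, function(s) s$keff %||% 2000, numeric(1)))
  pp <- cfg$params %||% list()
  params <- ox_params(D = pp$D %||% 2000, M = pp$M %||% 0,
                      K = pp$K %||% 13.7, alpha = pp$alpha %||% 1.39,
                      phi_max = pp$phi_max %||% 137)
  sol <- cfg$solver %||% list()
  solver <- list(n = sol$n %||% 3L, tol = sol$tol %||% 1e-10,
                 max_iter = sol$max_iter %||% 50L,
                 wall_mode = sol$wall_mode %||% "interpolated",
                 method = sol$method %||% "multiscale",
                 seed = sol$seed %||% NULL)
  list(grid = grid, sources = sources, params = params, solver = solver)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve a problem described by a configuration file
#'
#' @param config path to a YAML configuration, or the result of
#'   [read_ox_config()].
#' @return An [ox_solve()] fit.
#' @export
ox_solve_config <- function(config) {
  cfg <- if (is.character(config)) read_ox_config(config) else config
  if (!is.null(cfg$solver$seed)) set.seed(cfg$solver$seed)
  ox_solve(cfg$grid, cfg$sources, cfg$params, n = cfg$solver$n,
           method = cfg$solver$method, wall_mode = cfg$solver$wall_mode,
           tol = cfg$solver$tol, max_iter = cfg$solver$max_iter)
}
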