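## shared fixtures: small configurations used across the unit tests

single_source_config <- function(cells = 5L, bc = ox_bc(values = list(0)),
                                 x = 120, y = 120, cv = 137, keff = 2000) {
  list(grid = ox_grid(240, cells, bc),
       sources = ox_sources(x, y, r = 4.8, cv = cv, keff = keff),
       params = ox_params())
}

periodic_bc <- function() ox_bc("periodic", "periodic", "periodic", "periodic")

## the single-source benchmark boundary combination used by the error study
bench_bc <- function() oxsplit2d:::benchmark_bc(68.5)
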