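# Shared reduced-resolution scenario runs (dx = 0.2, dt = 4e-4), memoized so
# several test files can reuse the same integration.
.scenario_cache <- new.env(parent = emptyenv())

scenario_run <- function(name) {
  if (is.null(.scenario_cache[[name]]))
    .scenario_cache[[name]] <- run_scenario(gradient_scenario(name, "reduced"))
  .scenario_cache[[name]]
}

# small model setup used by unit tests: short domain, a few docking sites
small_model <- function(L = 50, dx = 0.1, dt = 1e-4, D = 20, b = 0.1,
                        c = 0.1, g_max = 0.2, R = 1, a_max = 10) {
  grid <- spatial_grid(L, dx)
  kin <- kinetic_params(D = D, b = b, c = c, g_max = g_max, R = R, dt = dt)
  list(grid = grid, kin = kin,
       binding = binding_profile(grid, "periodic", a_max = a_max),
       source = source_profile(grid, kin))
}
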