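# Shared fixtures: coarse, fast solver settings and memoised canonical
# solutions so several test files can reuse one solve.

quick_settings <- function(...) {
  args <- utils::modifyList(list(max_outer = 3000L), list(...))
  do.call(solver_settings, args)
}

straight_case <- function(resolution = c(16, 48), U = 0.02, mu = 0.0035,
                          ...) {
  make_case("healthy", props = newtonian_properties(mu = mu), U = U,
            geometry = lumen_geometry(0.002, 0.02),
            resolution = resolution, settings = quick_settings(),
            thermal = list(enabled = FALSE), ...)
}

.solution_cache <- new.env(parent = emptyenv())

cached_solution <- function(key, fun) {
  if (is.null(.solution_cache[[key]])) .solution_cache[[key]] <- fun()
  .solution_cache[[key]]
}

canonical_conservation <- function(name, resolution = c(32, 96)) {
  cached_solution(paste0("cons_", name, paste(resolution, collapse = "x")),
                  function() verify_conservation(name,
                                                 resolution = resolution))
}
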