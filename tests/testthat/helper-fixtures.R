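# Shared fixtures: small deterministic runs reused across test files.
# Everything is generated in code; nothing is read from disk.

smoke_mpk_traj <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- quickrun_config("E0_L0.0001_MPK", "smoke")
      cache <<- run_cord_simulation(p)
    }
    cache
  }
})

# a tiny parameter set for fast solver tests
tiny_params <- function(...) {
  cord_params(
    numerics = list(n_r = 9, n_z = 3, dt = 5,
                    report_times = c(0, 600, 1800)),
    protocol = list(T_chemo = 1800),
    ...
  )
}
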