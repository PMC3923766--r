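# Shared fixtures: small parameter objects used across test files.

default_model <- function(...) {
  args <- utils::modifyList(
    list(N = 100L, epsilon = 0.1, p = 0.1, delta = 0.2,
         mode = "symmetric", topology = "well_mixed", seed = 1L),
    list(...))
  do.call(damage_model, args)
}

# tiny instance with a two-level damage lattice {0.5, 1}; exactly solvable
tiny_model <- function(...) {
  default_model(N = 3L, epsilon = 0.5, p = 0.3, delta = 1.0, ...)
}

plateau_stats <- function(trajectory, window = c(100, 400)) {
  s <- trajectory$summary
  w <- s$t >= window[1] & s$t <= window[2]
  list(mean_damage = mean(s$mean_damage[w]), f0 = mean(s$f0[w]))
}
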