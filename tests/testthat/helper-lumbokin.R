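# Shared fixtures: geometries and cards are cheap to build and deterministic;
# the expensive full-chain computations used by the acceptance suite are
# memoised in a session-level environment so several test blocks can share
# one run.

geom_full <- build_default_spine()
geom_toy <- build_default_spine(n_levels = 1)   # L5-S1 functional unit
card_h <- material_card("healthy")
card_d <- material_card("degenerated")

.accept_cache <- new.env(parent = emptyenv())

acceptance_calibrations <- function() {
  if (is.null(.accept_cache$cals)) {
    .accept_cache$cals <- lapply(
      setNames(nm = c("FLX", "EXT", "LB", "AR")),
      function(mv) calibrate(mv, geometry = geom_full, cards = card_h)
    )
  }
  .accept_cache$cals
}

acceptance_degeneration <- function() {
  if (is.null(.accept_cache$study)) {
    .accept_cache$study <- degeneration_study(geom_full, card_h)
  }
  .accept_cache$study
}

# small helper: segment state constructor
seg_state <- function(level = "L3-L4", t = c(0, 0, 0), r = c(0, 0, 0)) {
  list(level = level, translation = t, rotation = r)
}
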