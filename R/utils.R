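# Shared helpers: error classes and seeded RNG scoping.

# Parse/format errors (CLI exit code 2)
stop_parse <- function(...) {
  stop(structure(class = c("lipidrules_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Routing/scoring errors (CLI exit code 3)
stop_routing <- function(...) {
  stop(structure(class = c("lipidrules_routing_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic package internals go through this so that a run is fully
# reproducible from its root seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-item child seed derived from a root seed. Arithmetic (not
# RNG-based) so that item i's draws are unchanged when more items are added.
child_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) * 48271 + as.double(index) * 9973 +
          as.double(salt) * 7919) %% 2147483629
  as.integer(s) + 1L
}
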