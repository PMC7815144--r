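# Named RNG streams derived from one root seed. Each stream owns a saved
# .Random.seed state; evaluating under a stream swaps the global state in,
# runs the expression, and captures the advanced state back. Keeping the
# demographic, schedule, mutation and initialization draws on separate
# streams means that e.g. adding cells never perturbs the supply schedule.

makeStreams <- function(seed, names = c("init", "schedule", "demography",
                                        "mutation")) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  subSeeds <- sample.int(.Machine$integer.max - 1L, length(names))
  streams <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(subSeeds[i])
    assign(names[i], get(".Random.seed", envir = globalenv()),
           envir = streams)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  streams
}

withStream <- function(streams, name, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
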