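# internal helpers

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards,
# so generation is a pure function of its seed arguments.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

clip01 <- function(x) pmin(pmax(x, 0), 1)
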