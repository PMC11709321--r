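## Seed substreams: all randomness flows from one master seed through
## named substreams, so that e.g. the landscape draw is unchanged when
## only the polymorphism stream is re-used.

.substream_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * (31L^(seq_len(nchar(name)) %% 7L)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

## Evaluate `expr` under the substream's RNG state, leaving the caller's
## global RNG untouched.
.with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(.substream_seed(master, name))
  expr
}

## A stateful normal-deviate generator on its own substream (used for
## multi-start optimization); state persists across calls.
.substream_rng <- function(master, name) {
  env <- new.env()
  .with_substream(master, name, env$state <- get(".Random.seed", globalenv()))
  function(n, sd = 1) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    x <- stats::rnorm(n, 0, sd)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  }
}
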