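# layout conversion between the user-facing (B, C, H, W) tensor convention
# and the internal (H, W, C, B) storage
as_internal <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  aperm(x, c(3L, 4L, 2L, 1L))
}

as_external <- function(x) {
  aperm(x, c(4L, 3L, 1L, 2L))
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
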