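# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order map rows canonically: numeric chromosomes first, then position
map_order <- function(map) {
  order(suppressWarnings(as.numeric(map$chrom)), map$chrom, map$pos_bp)
}
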