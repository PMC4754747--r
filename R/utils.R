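# evaluate expr under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# Pearson correlation that tolerates zero variance by returning NA
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("cannot normalize a near-zero vector")
  v / n
}
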