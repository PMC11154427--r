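## Numerically stable softplus and friends; positivity of variances and
## lengthscales is enforced by optimizing on the softplus-inverse scale.
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Run code with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## Deterministic per-unit substream seed from (seed, unit index).
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483647)
}

## B[idx1, idx2] lookup matrix for the stacked multi-output representation.
blook <- function(Bm, idx1, idx2) {
  matrix(Bm[cbind(rep(idx1 + 1L, times = length(idx2)),
                  rep(idx2 + 1L, each = length(idx1)))],
         nrow = length(idx1), ncol = length(idx2))
}
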