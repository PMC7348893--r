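#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation calls do not perturb
# user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-gene seed derived from the dataset seed. The stride is a
# prime much larger than any realistic replicate count, so seeds from
# different (dataset seed, gene index) pairs do not collide; kept below
# .Machine$integer.max because R seeds are 32-bit.
gene_seed <- function(seed, gene_index) {
  as.integer((as.double(seed) + as.double(gene_index) * 1000003) %% 2147483647)
}
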