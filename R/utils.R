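# Internal helpers shared across modules.

# round() in R rounds half to even; cohort percentages are reported rounded
# half-up, so provide it explicitly.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL leaves the current stream in place.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Largest-remainder apportionment of `n` items to fractions `p` (sums to 1).
# Guarantees the counts sum to n exactly, so small families are exactly
# representable. Ties in remainder go to the earlier category.
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0))
  raw <- n * p / sum(p)
  k <- floor(raw)
  rem <- raw - k
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(-rem, seq_along(p))
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

MARKER_FAMILIES <- c("NarG", "NarH", "NirK", "NirS", "Nor", "NosZ")

# enzymes counted in profiles / phenotype calls, pathway order
PATHWAY_ENZYMES <- c("nar", "nir", "nor", "nos")
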