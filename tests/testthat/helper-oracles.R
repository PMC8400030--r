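# Independent oracles, written separately from the package implementation.

# Plain-R affine-gap global alignment DP (Gotoh) with the documented
# deterministic tie-break: final/diagonal choices prefer M > X > Y, gap
# states prefer extending over opening. Returns score, aligned strings and
# the identity statistic computed by brute-force character comparison.
oracle_align <- function(a, b, match = 1, mismatch = 0,
                         gap_open = -10, gap_extend = -1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  m <- length(x); n <- length(y)
  M <- X <- Y <- matrix(-Inf, m + 1, n + 1)
  pM <- pX <- pY <- matrix("", m + 1, n + 1)
  M[1, 1] <- 0
  for (i in seq_len(m)) {
    X[i + 1, 1] <- gap_open + i * gap_extend
    pX[i + 1, 1] <- if (i == 1) "M" else "X"
  }
  for (j in seq_len(n)) {
    Y[1, j + 1] <- gap_open + j * gap_extend
    pY[1, j + 1] <- if (j == 1) "M" else "Y"
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (x[i] == y[j]) match else mismatch
      cand <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
      k <- which.max(cand)             # first max: priority M > X > Y
      M[i + 1, j + 1] <- cand[k] + s
      pM[i + 1, j + 1] <- names(cand)[k]
      cand <- c(X = X[i, j + 1] + gap_extend,
                M = M[i, j + 1] + gap_open + gap_extend,
                Y = Y[i, j + 1] + gap_open + gap_extend)
      k <- which.max(cand)             # priority: extend, then M, then Y
      X[i + 1, j + 1] <- cand[k]
      pX[i + 1, j + 1] <- names(cand)[k]
      cand <- c(Y = Y[i + 1, j] + gap_extend,
                M = M[i + 1, j] + gap_open + gap_extend,
                X = X[i + 1, j] + gap_open + gap_extend)
      k <- which.max(cand)
      Y[i + 1, j + 1] <- cand[k]
      pY[i + 1, j + 1] <- names(cand)[k]
    }
  }
  fin <- c(M = M[m + 1, n + 1], X = X[m + 1, n + 1], Y = Y[m + 1, n + 1])
  state <- names(fin)[which.max(fin)]
  score <- max(fin)
  ga <- gb <- character(0)
  i <- m; j <- n
  while (i > 0 || j > 0) {
    if (state == "M") {
      prev <- pM[i + 1, j + 1]
      ga <- c(x[i], ga); gb <- c(y[j], gb); i <- i - 1; j <- j - 1
    } else if (state == "X") {
      prev <- pX[i + 1, j + 1]
      ga <- c(x[i], ga); gb <- c("-", gb); i <- i - 1
    } else {
      prev <- pY[i + 1, j + 1]
      ga <- c("-", ga); gb <- c(y[j], gb); j <- j - 1
    }
    state <- prev
  }
  gap <- ga == "-" | gb == "-"
  inner <- which(!gap)
  keep <- if (length(inner)) seq(min(inner), max(inner)) else integer(0)
  matches <- sum(ga[keep] == gb[keep] & !gap[keep])
  list(score = score,
       aligned_a = paste(ga, collapse = ""),
       aligned_b = paste(gb, collapse = ""),
       matches = matches,
       alignment_length = length(keep),
       percent_identity = if (length(keep)) matches / length(keep) else 0)
}

# end product by walking the reduction chain and reporting the product of
# the last enzyme present
oracle_end_product <- function(nar, nir, nor, nos) {
  chain <- c(nitrite = nar, NO = nir, N2O = nor, N2 = nos)
  present <- names(chain)[chain]
  if (length(present) == 0) "none" else present[length(present)]
}

# contiguous-interval check on the positions of present enzymes
oracle_consecutive <- function(nar, nir, nor, nos) {
  pos <- which(c(nar, nir, nor, nos))
  if (length(pos) <= 1) return(TRUE)
  all(diff(pos) == 1)
}

# random sequence over an alphabet
rand_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# 8-taxon, 4-clade alignment with saturating diagnostic signal:
# `block` columns support each clade cherry, one block supports the central
# AB|CD split, and each taxon gets a private block so all distances are
# positive. Expected unrooted topology: cherries (A1,A2) (B1,B2) (C1,C2)
# (D1,D2) with an AB|CD central edge.
saturating_alignment <- function(block = 500) {
  taxa <- c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2")
  clade <- substr(taxa, 1, 1)
  cols <- list()
  for (cl in c("A", "B", "C", "D"))
    cols[[length(cols) + 1]] <- rep(ifelse(clade == cl, "A", "C"), block)
  cols[[length(cols) + 1]] <- rep(ifelse(clade %in% c("A", "B"), "G", "T"),
                                  block)
  for (k in seq_along(taxa)) {
    v <- rep("A", length(taxa)); v[k] <- "T"
    cols[[length(cols) + 1]] <- rep(v, block %/% 5)
  }
  mat <- do.call(cbind, lapply(cols, function(v)
    matrix(v, nrow = length(taxa))))
  data.frame(id = taxa, description = "",
             residues = apply(mat, 1, paste, collapse = ""),
             stringsAsFactors = FALSE)
}

# small two-family community config used across tests
small_config <- function(seed = 1, n1 = 4L, n2 = 4L, ...) {
  fs <- data.frame(family = c("FamA", "FamB"), n_species = c(n1, n2),
                   non = c(0.25, 0.25), partial = c(0.5, 0.5),
                   complete = c(0.25, 0.25))
  simulation_config(fs, seed = seed, p_no_genome = 0, ...)
}
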