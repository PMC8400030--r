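#' Pairwise p-distance matrix from an aligned nucleotide FASTA
#'
#' For each pair of sequences, distance = mismatches / comparable columns,
#' where a column is comparable when both sequences carry a plain base
#' (`A`, `C`, `G`, `T`); columns with a gap or `N` in either sequence are
#' excluded for that pair (pairwise deletion). A pair with zero comparable
#' columns is an error naming the pair.
#'
#' @param aligned data frame of aligned nucleotide records
#'   ([read_fasta()] with `alphabet = "dna_aligned"`), all the same length.
#' @return symmetric numeric matrix with zero diagonal, dimnames = record
#'   ids.
#' @export
p_distance_matrix <- function(aligned) {
  n <- nrow(aligned)
  if (n < 2) stop("need at least two sequences")
  len <- nchar(aligned$residues)
  if (length(unique(len)) != 1)
    stop("aligned records must all have the same length")
  if (len[1] < 1) stop("alignment has zero columns")
  chars <- do.call(rbind, strsplit(aligned$residues, "", fixed = TRUE))
  plain <- chars %in% c("A", "C", "G", "T")
  dim(plain) <- dim(chars)
  d <- matrix(0, n, n, dimnames = list(aligned$id, aligned$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- plain[i, ] & plain[j, ]
      nc <- sum(comp)
      if (nc == 0)
        stop("no comparable columns between '", aligned$id[i], "' and '",
             aligned$id[j], "'")
      d[i, j] <- d[j, i] <- sum(chars[i, comp] != chars[j, comp]) / nc
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou–Nei neighbour joining: repeatedly join the pair (i, j) minimising
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`, with branch
#' lengths from the standard two-point formulas. Ties in Q are broken
#' deterministically by the lexicographically smallest label pair, where a
#' cluster is labelled by the smallest leaf label it contains; the result is
#' therefore invariant to the input ordering of the matrix. Negative branch
#' lengths are clamped to zero without redistributing the deficit.
#'
#' @param d symmetric distance matrix with unique dimnames, `n >= 3`.
#' @return an unrooted `"phylo"` object (basal trifurcation).
#' @export
nj_tree <- function(d) {
  n <- nrow(d)
  if (n < 3) stop("neighbour joining needs at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs))
    stop("distance matrix needs unique row/column names")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")

  ids <- seq_len(n)              # active node ids (leaves 1..n)
  minlab <- labs                 # tie-break label per active node
  D <- d
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  created <- 0L

  pick_pair <- function(Q, minlab) {
    m <- min(Q)
    hits <- which(Q == m, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    key <- apply(hits, 1, function(ij) {
      p <- sort(c(minlab[ij[1]], minlab[ij[2]]))
      paste(p, collapse = "\r")
    })
    hits[order(key)[1], ]
  }

  while (length(ids) > 3) {
    m <- length(ids)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- pick_pair(Q, minlab)
    i <- ij[1]; j <- ij[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    created <- created + 1L
    new_id <- n + created
    edges <- rbind(edges, c(new_id, ids[i]), c(new_id, ids[j]))
    lens <- c(lens, max(0, bi), max(0, bj))
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    ids <- c(ids[keep], new_id)
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
    rownames(D) <- colnames(D) <- NULL
  }

  # final three nodes join at the basal trifurcation
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  created <- created + 1L
  root_prov <- n + created
  edges <- rbind(edges, c(root_prov, ids[1]), c(root_prov, ids[2]),
                 c(root_prov, ids[3]))
  lens <- c(lens, max(0, x1), max(0, x2), max(0, x3))

  # renumber internal nodes so the basal node is n + 1 (ape convention)
  n_int <- created
  remap <- function(v) ifelse(v <= n, v, n + 1L + (n + n_int - v))
  edge <- cbind(remap(edges[, 1]), remap(edges[, 2]))
  storage.mode(edge) <- "integer"
  phy <- structure(list(edge = edge, edge.length = lens,
                        tip.label = labs, Nnode = n_int),
                   class = "phylo")
  stats::reorder(phy, "cladewise")
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Builds the NJ tree of the full alignment, then `n_reps` column resamples
#' with replacement (alignment length preserved), NJ on each, and attaches to
#' every internal node of the original tree the percentage of replicates
#' whose tree contains the same leaf bipartition (rounded half-up to an
#' integer, stored in `node.label`). Replicate r draws its columns under the
#' deterministic substream seed `(seed + r) mod (2^31 - 1)`, so partial
#' reruns are stable and results do not depend on the caller's RNG state.
#'
#' @param aligned aligned nucleotide records as for [p_distance_matrix()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed master seed for the replicate substreams.
#' @return the original NJ `"phylo"` tree with integer supports in
#'   `node.label`.
#' @export
bootstrap_support <- function(aligned, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  orig <- nj_tree(p_distance_matrix(aligned))
  len <- nchar(aligned$residues[1])
  chars <- do.call(rbind, strsplit(aligned$residues, "", fixed = TRUE))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- with_seed((seed + r) %% (2^31 - 1),
                     sample.int(len, len, replace = TRUE))
    resampled <- data.frame(
      id = aligned$id,
      residues = apply(chars[, idx, drop = FALSE], 1, paste, collapse = ""),
      stringsAsFactors = FALSE)
    reps[[r]] <- nj_tree(p_distance_matrix(resampled))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(orig, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  orig$node.label <- as.character(as.integer(
    round_half_up(100 * counts / n_reps, 0)))
  orig
}

#' Root a tree on an outgroup leaf
#'
#' Roots the tree on the outgroup's pendant edge, splitting that edge in
#' half. Leaf bipartitions are unchanged; re-rooting on the same leaf is
#' idempotent on topology.
#'
#' @param tree a `"phylo"` object.
#' @param outgroup_label a leaf label present in the tree.
#' @return rooted `"phylo"` object.
#' @export
root_on_outgroup <- function(tree, outgroup_label) {
  if (!(outgroup_label %in% tree$tip.label))
    stop("outgroup '", outgroup_label, "' is not a leaf of the tree")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  rooted <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  root <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1] == root)
  if (length(kids) == 2 && !is.null(rooted$edge.length)) {
    total <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- total / 2
  }
  rooted
}
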