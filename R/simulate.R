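#' Configuration for a synthetic community
#'
#' Describes a community with known ground truth: how many species per
#' family, the mix of non/partial/complete denitrifiers among them, the
#' percent identity at which true marker homologs and decoy proteins sit
#' relative to the reference panel, the fraction of species without an
#' available genome, and the expected 16S divergence.
#'
#' @param family_spec data frame with columns `family`, `n_species` and the
#'   class-mix fractions `non`, `partial`, `complete` (each row sums to 1).
#'   Defaults to [default_family_spec()].
#' @param identity_true target identity of true homologs to the panel,
#'   in (0, 1]. Default 0.85, comfortably above the 0.65 acceptance
#'   threshold.
#' @param identity_decoy identity of decoy proteins (mutated panel copies),
#'   in (0, 1), strictly below `identity_true`. Default 0.30.
#' @param p_no_genome fraction of species flagged "no genome available".
#'   Default 25/147, the NGA rate of the reference cohort.
#' @param seed integer master seed; identical configs give byte-identical
#'   communities.
#' @param tree_depth expected root-to-tip divergence of the simulated 16S
#'   tree, in substitutions/site. Default 0.10.
#' @param n_decoys decoy proteins per genome-available species (>= 5).
#' @param s16_length simulated 16S alignment length (default 1500 nt).
#' @return validated config (class `"halonitro_simconfig"`).
#' @export
simulation_config <- function(family_spec = default_family_spec(),
                              identity_true = 0.85, identity_decoy = 0.30,
                              p_no_genome = 25 / 147, seed = 1,
                              tree_depth = 0.10, n_decoys = 5,
                              s16_length = 1500) {
  need <- c("family", "n_species", "non", "partial", "complete")
  if (!all(need %in% names(family_spec)))
    stop("family_spec needs columns: ", paste(need, collapse = ", "))
  if (any(family_spec$n_species < 1))
    stop("each family needs at least one species")
  mix <- as.matrix(family_spec[, c("non", "partial", "complete")])
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-9))
    stop("class-mix fractions must be non-negative and sum to 1")
  if (identity_true <= 0 || identity_true > 1)
    stop("identity_true must be in (0, 1]")
  if (identity_decoy <= 0 || identity_decoy >= 1)
    stop("identity_decoy must be in (0, 1)")
  if (identity_true < identity_decoy)
    stop("identity_true must be >= identity_decoy, otherwise no detection ",
         "threshold can separate homologs from decoys")
  if (p_no_genome < 0 || p_no_genome >= 1)
    stop("p_no_genome must be in [0, 1)")
  stopifnot(tree_depth > 0, n_decoys >= 5, s16_length >= 100)
  structure(list(family_spec = family_spec, identity_true = identity_true,
                 identity_decoy = identity_decoy,
                 p_no_genome = p_no_genome, seed = as.integer(seed),
                 tree_depth = tree_depth, n_decoys = as.integer(n_decoys),
                 s16_length = as.integer(s16_length)),
            class = "halonitro_simconfig")
}

#' @rdname simulation_config
#' @details `default_family_spec()` emulates the four well-represented
#'   haloarchaeal families of the reference cohort with their observed
#'   class mixes (fractions of genome-available species that are
#'   non/partial/complete denitrifiers).
#' @export
default_family_spec <- function() {
  data.frame(
    family = c("Natrialbaceae", "Haloarculaceae", "Halorubraceae",
               "Haloferacaceae"),
    n_species = c(44L, 21L, 29L, 27L),
    non = c(15 / 40, 3 / 19, 8 / 22, 3 / 27),
    partial = c(23 / 40, 7 / 19, 14 / 22, 20 / 27),
    complete = c(2 / 40, 9 / 19, 0, 4 / 27),
    stringsAsFactors = FALSE)
}

#' Generate a reference marker panel of synthetic protein sequences
#'
#' One random sequence per enzyme family over the 20-letter amino-acid
#' alphabet. The NirK and NirS members are constrained to share < 40%
#' identity (checked with [global_align()]) so nitrite-reductase typing is
#' unambiguous; random sequences of these lengths essentially always satisfy
#' this, but the constraint is enforced by regeneration.
#'
#' @param seed integer seed; generation is byte-reproducible.
#' @param family_lengths named residue counts for the six families
#'   (`NarG`, `NarH`, `NirK`, `NirS`, `Nor`, `NosZ`), each >= 50.
#' @return panel data frame with columns `id`, `family`, `residues`,
#'   `description` (carrying the `family=` tag used in panel FASTA files).
#' @export
generate_reference_panel <- function(seed,
    family_lengths = c(NarG = 400, NarH = 250, NirK = 320, NirS = 320,
                       Nor = 350, NosZ = 300)) {
  if (!setequal(names(family_lengths), MARKER_FAMILIES))
    stop("family_lengths must name exactly the six enzyme families")
  if (any(family_lengths < 50))
    stop("panel sequences must be at least 50 residues")
  with_seed(seed, {
    seqs <- vapply(MARKER_FAMILIES, function(fam)
      paste(sample(AA_ALPHABET, family_lengths[[fam]], replace = TRUE),
            collapse = ""), "")
    repeat {
      pid <- global_align(seqs[["NirK"]], seqs[["NirS"]])$percent_identity
      if (pid < 0.40) break
      seqs[["NirS"]] <- paste(
        sample(AA_ALPHABET, family_lengths[["NirS"]], replace = TRUE),
        collapse = "")
    }
    data.frame(id = paste0("REF_", MARKER_FAMILIES),
               family = MARKER_FAMILIES, residues = unname(seqs),
               description = paste0("family=", MARKER_FAMILIES),
               stringsAsFactors = FALSE)
  })
}

#' Mutate a protein to a target percent identity
#'
#' Substitutes exactly `round(L * (1 - target_identity))` positions, chosen
#' uniformly without replacement, each replaced by a residue drawn uniformly
#' from the 19 alternatives (no indels). The realised identity to the input
#' is therefore within 0.5/L of the target.
#'
#' @param seq protein sequence (plain string over the 20-letter alphabet).
#' @param target_identity fraction in (0, 1].
#' @param seed optional seed; `NULL` uses (and advances) the caller's RNG
#'   stream.
#' @return mutated sequence.
#' @export
mutate_to_identity <- function(seq, target_identity, seed = NULL) {
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]")
  L <- nchar(seq)
  k <- round(L * (1 - target_identity))
  if (k == 0) return(seq)
  with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(L, k)
    for (p in pos)
      ch[p] <- sample(setdiff(AA_ALPHABET, ch[p]), 1)
    paste(ch, collapse = "")
  })
}

# subsets of the four enzymes with 1-3 members (the 14 "partial" profiles)
partial_subsets <- function() {
  out <- list()
  for (m in 1:14) {
    flags <- as.logical(bitwAnd(m, c(1L, 2L, 4L, 8L)))
    if (sum(flags) %in% 1:3) out[[length(out) + 1L]] <- flags
  }
  out
}

#' Generate a synthetic community with known ground truth
#'
#' Produces, for a cohort laid out by `config`:
#'
#' * a taxonomy (species, family, genome availability),
#' * a ground-truth marker profile per genome-available species (classes
#'   allocated within each family by largest-remainder rounding of the mix
#'   fractions; "partial" species draw a uniformly random non-empty,
#'   non-full subset of the four enzymes),
#' * one proteome per genome-available species containing homologs of its
#'   true markers mutated to `identity_true` against the panel, a NarH
#'   homolog whenever NarG is present, and `n_decoys` decoy proteins
#'   (mutated panel copies at `identity_decoy`, so the detection threshold
#'   is genuinely exercised),
#' * a gene order with the *narH* gene placed immediately after *narG*,
#' * 16S-like sequences evolved along a random bifurcating tree by a uniform
#'   (Jukes–Cantor) substitution process with expected root-to-tip
#'   divergence `tree_depth` (no indels, so the sequences are aligned by
#'   construction).
#'
#' Identical configs (including the seed) give byte-identical communities.
#' Nitrite-reductase homologs are always seeded from the NirK panel member,
#' mirroring the NirK-only observation in haloarchaea.
#'
#' @param config a [simulation_config()].
#' @return list with elements `config`, `taxonomy`, `truth` (profiles +
#'   class per species, `NA` flags for species without genomes), `panel`,
#'   `proteomes` (named list of record data frames), `gene_order`, `s16`
#'   (aligned records), `tree` (the true `"phylo"` tree).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "halonitro_simconfig"))
  fs <- config$family_spec
  panel <- generate_reference_panel(config$seed + 1L)
  with_seed(config$seed, {
    species <- unlist(lapply(seq_len(nrow(fs)), function(k)
      sprintf("%s_sp%03d", fs$family[k], seq_len(fs$n_species[k]))))
    family <- rep(fs$family, fs$n_species)
    n_total <- length(species)
    n_nga <- as.integer(round_half_up(n_total * config$p_no_genome, 0))
    nga <- rep(FALSE, n_total)
    if (n_nga > 0) nga[sample.int(n_total, n_nga)] <- TRUE
    taxonomy <- data.frame(species = species, family = family,
                           genome_available = !nga,
                           stringsAsFactors = FALSE)

    # class allocation per family over genome-available species
    cls <- rep(NA_character_, n_total)
    for (k in seq_len(nrow(fs))) {
      idx <- which(family == fs$family[k] & !nga)
      if (length(idx) == 0) next
      counts <- largest_remainder(length(idx),
                                  c(fs$non[k], fs$partial[k], fs$complete[k]))
      cls[sample(idx)] <- rep(c("non", "partial", "complete"), counts)
    }

    subsets <- partial_subsets()
    prof <- matrix(FALSE, n_total, 4,
                   dimnames = list(species, PATHWAY_ENZYMES))
    for (i in which(!nga)) {
      prof[i, ] <- switch(cls[i],
        non = rep(FALSE, 4),
        complete = rep(TRUE, 4),
        partial = subsets[[sample.int(length(subsets), 1)]])
    }

    proteomes <- list()
    gene_rows <- list()
    panel_seq <- function(fam) panel$residues[panel$family == fam]
    for (i in which(!nga)) {
      sp <- species[i]
      fams <- character(0)
      if (prof[i, "nar"]) fams <- c(fams, "NarG", "NarH")
      if (prof[i, "nir"]) fams <- c(fams, "NirK")
      if (prof[i, "nor"]) fams <- c(fams, "Nor")
      if (prof[i, "nos"]) fams <- c(fams, "NosZ")
      ids <- character(0); seqs <- character(0); roles <- character(0)
      for (fam in fams) {
        ids <- c(ids, sprintf("%s_P%02d", sp, length(ids) + 1L))
        seqs <- c(seqs, mutate_to_identity(panel_seq(fam),
                                           config$identity_true))
        roles <- c(roles, fam)
      }
      for (d in seq_len(config$n_decoys)) {
        src <- sample(MARKER_FAMILIES, 1)
        ids <- c(ids, sprintf("%s_P%02d", sp, length(ids) + 1L))
        seqs <- c(seqs, mutate_to_identity(panel_seq(src),
                                           config$identity_decoy))
        roles <- c(roles, paste0("decoy:", src))
      }
      proteomes[[sp]] <- data.frame(id = ids, description = roles,
                                    residues = seqs,
                                    stringsAsFactors = FALSE)
      # gene order: shuffle, then force narH right after narG
      ord <- sample(ids)
      if (prof[i, "nar"]) {
        g <- ids[roles == "NarG"][1]
        h <- ids[roles == "NarH"][1]
        ord <- setdiff(ord, h)
        at <- match(g, ord)
        ord <- append(ord, h, after = at)
      }
      gene_rows[[sp]] <- data.frame(
        species = sp, replicon = "chr",
        position = seq_along(ord) - 1L, gene_id = ord,
        marker_truth = proteomes[[sp]]$description[match(ord, ids)],
        stringsAsFactors = FALSE)
    }
    gene_order <- do.call(rbind, c(gene_rows, list(make.row.names = FALSE)))

    # 16S along a random bifurcating tree, JC-style uniform substitutions
    tree <- ape::rtree(n_total, tip.label = sample(species))
    depths <- ape::node.depth.edgelength(tree)[seq_len(n_total)]
    tree$edge.length <- tree$edge.length * config$tree_depth / mean(depths)
    sim <- phangorn::simSeq(tree, l = config$s16_length, type = "DNA")
    mat <- toupper(as.character(sim))
    s16 <- data.frame(
      id = rownames(mat),
      description = "",
      residues = apply(mat, 1, paste, collapse = ""),
      stringsAsFactors = FALSE)
    s16 <- s16[match(species, s16$id), , drop = FALSE]
    rownames(s16) <- NULL

    truth <- data.frame(species = species, family = family,
                        genome_available = !nga,
                        nar = ifelse(nga, NA, prof[, "nar"]),
                        nir = ifelse(nga, NA, prof[, "nir"]),
                        nir_type = ifelse(nga, NA_character_,
                                          ifelse(prof[, "nir"], "NirK",
                                                 "absent")),
                        nor = ifelse(nga, NA, prof[, "nor"]),
                        nos = ifelse(nga, NA, prof[, "nos"]),
                        class = ifelse(nga, NA_character_, cls),
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL

    list(config = config, taxonomy = taxonomy, truth = truth, panel = panel,
         proteomes = proteomes, gene_order = gene_order, s16 = s16,
         tree = tree)
  })
}

#' Write a synthetic community to disk
#'
#' Writes one protein FASTA per species under `proteomes/`, the panel FASTA,
#' the combined aligned 16S FASTA, the gene-order and taxonomy TSVs, the
#' ground truth as JSON and the true tree as Newick.
#'
#' @param community result of [generate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (sp in names(community$proteomes))
    write_fasta(community$proteomes[[sp]],
                file.path(dir, "proteomes", paste0(sp, ".fasta")))
  write_fasta(community$panel, file.path(dir, "panel.fasta"))
  write_fasta(community$s16, file.path(dir, "s16_aligned.fasta"))
  write_gene_order(community$gene_order, file.path(dir, "gene_order.tsv"))
  write_taxonomy(community$taxonomy, file.path(dir, "taxonomy.tsv"))
  jsonlite::write_json(community$truth,
                       file.path(dir, "ground_truth.json"), digits = NA)
  write_newick(community$tree, file.path(dir, "true_tree.nwk"))
  invisible(dir)
}
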