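#' Detect marker enzymes across a set of proteomes
#'
#' Runs [scan_proteome()] on every genome-available species, fills the NarG
#' `context_verified` flag from the gene order, and assembles the presence
#' profiles with [build_profiles()].
#'
#' @param proteomes named list of proteome record data frames (names =
#'   species).
#' @param panel panel data frame from [read_panel()].
#' @param gene_orders combined gene-order data frame.
#' @param taxonomy taxonomy data frame.
#' @param threshold identity acceptance threshold (default 0.65).
#' @param window NarH adjacency window (default 2).
#' @return list with `hits` (all species) and `profiles`.
#' @export
detect_markers <- function(proteomes, panel, gene_orders, taxonomy,
                           threshold = 0.65, window = 2) {
  hit_list <- lapply(names(proteomes), function(sp)
    scan_proteome(proteomes[[sp]], panel, threshold = threshold,
                  species = sp))
  hits <- do.call(rbind, c(hit_list, list(make.row.names = FALSE)))
  for (sp in unique(hits$species)) {
    sel <- hits$species == sp & hits$enzyme == "NarG" & hits$accepted
    if (any(sel))
      hits$context_verified[sel] <-
        verify_nar_context(sp, hits, gene_orders, window = window)
  }
  profiles <- build_profiles(hits, gene_orders, taxonomy,
                             scanned_species = names(proteomes),
                             window = window)
  list(hits = hits, profiles = profiles)
}

#' Pipeline configuration
#'
#' @param proteome_dir directory of per-species protein FASTAs
#'   (`<species>.fasta`).
#' @param panel path to the marker panel FASTA.
#' @param taxonomy path to the taxonomy TSV.
#' @param gene_orders path to the gene-order TSV.
#' @param alignment optional path to an aligned 16S FASTA; when given, the
#'   NJ + bootstrap tree is built.
#' @param outgroup optional leaf label to root the tree on.
#' @param threshold identity acceptance threshold in (0, 1], default 0.65.
#' @param window NarH adjacency window (>= 1), default 2.
#' @param bootstrap bootstrap replicates (>= 1), default 1000.
#' @param seed seed for the bootstrap substreams.
#' @param out_dir output directory.
#' @return validated config list (class `"halonitro_config"`).
#' @export
pipeline_config <- function(proteome_dir, panel, taxonomy, gene_orders,
                            alignment = NULL, outgroup = NULL,
                            threshold = 0.65, window = 2, bootstrap = 1000,
                            seed = 1, out_dir = "halonitro_out") {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (window < 1) stop("window must be >= 1")
  if (bootstrap < 1) stop("bootstrap must be >= 1")
  for (p in c(proteome_dir, panel, taxonomy, gene_orders, alignment))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  structure(list(proteome_dir = proteome_dir, panel = panel,
                 taxonomy = taxonomy, gene_orders = gene_orders,
                 alignment = alignment, outgroup = outgroup,
                 threshold = threshold, window = window,
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "halonitro_config")
}

#' Run the whole pipeline: detect, classify, summarise (and tree)
#'
#' Orchestrates marker detection, phenotype classification and cohort
#' summaries (plus the bootstrapped NJ tree when an alignment is supplied),
#' writing all artifacts and a manifest JSON recording the configuration,
#' package version and seed. Reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return list with `hits`, `profiles`, `calls`, `summary`, `tree`
#'   (or `NULL`), invisibly; artifacts written under `config$out_dir`:
#'   `hits.tsv`, `profiles.tsv`, `phenotypes.tsv`, `family_summary.tsv`,
#'   `combinations.tsv`, `cohort.json`, `tree.nwk`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "halonitro_config"))
  taxonomy <- read_taxonomy(config$taxonomy)
  panel <- read_panel(config$panel)
  gene_orders <- read_gene_order(config$gene_orders)
  files <- list.files(config$proteome_dir, pattern = "\\.fasta$",
                      full.names = TRUE)
  proteomes <- lapply(files, read_fasta, alphabet = "protein")
  names(proteomes) <- sub("\\.fasta$", "", basename(files))

  det <- detect_markers(proteomes, panel, gene_orders, taxonomy,
                        threshold = config$threshold,
                        window = config$window)
  calls <- classify_profiles(det$profiles)
  summ <- cohort_summary(calls, det$profiles, taxonomy)

  tree <- NULL
  if (!is.null(config$alignment)) {
    aligned <- read_fasta(config$alignment, alphabet = "dna_aligned")
    tree <- bootstrap_support(aligned, n_reps = config$bootstrap,
                              seed = config$seed)
    if (!is.null(config$outgroup))
      tree <- root_on_outgroup(tree, config$outgroup)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write.table(det$hits, out("hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_profiles(det$profiles, out("profiles.tsv"))
  write.table(calls, out("phenotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(summ$families, out("family_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summ$combinations, out("combinations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    summ[c("n_species_total", "n_genomes", "n_denitrifiers",
           "pct_denitrifiers", "pct_non", "pct_partial", "pct_complete")],
    out("cohort.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(tree)) write_newick(tree, out("tree.nwk"))
  jsonlite::write_json(
    list(package = "halonitro",
         version = as.character(utils::packageVersion("halonitro")),
         config = unclass(config)),
    out("manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(list(hits = det$hits, profiles = det$profiles, calls = calls,
                 summary = summ, tree = tree))
}
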