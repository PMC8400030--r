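#' Packaged synthetic cohort of 147 haloarchaeal species
#'
#' A per-species marker-profile table for a synthetic cohort of 147 species
#' in 10 families, 25 of them without an available genome, constructed so
#' that its family-level classification counts match a published genome
#' survey of the class *Halobacteria* (36 non-, 71 partial and 15 complete
#' denitrifiers over 122 genomes). The family-level counts are the
#' constrained quantity; the assignment of particular enzyme subsets to
#' particular species within a family is synthetic (the published counts are
#' family-marginal), as are the species names. All nitrite reductases are
#' NirK, mirroring the cohort's NirK-only observation.
#'
#' @return list with `taxonomy` (147 rows: `species`, `family`,
#'   `genome_available`) and `profiles` (122 rows, genome-available species
#'   only: `species`, `nar`, `nir`, `nir_type`, `nor`, `nos`).
#' @export
load_cohort_fixture <- function() {
  path <- system.file("extdata", "synthetic_cohort_profiles.tsv",
                      package = "halonitro", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$genome_available <- as.logical(tab$genome_available)
  taxonomy <- tab[, c("species", "family", "genome_available")]
  profiles <- tab[tab$genome_available,
                  c("species", "nar", "nir", "nir_type", "nor", "nos")]
  for (col in PATHWAY_ENZYMES) profiles[[col]] <- as.logical(profiles[[col]])
  rownames(profiles) <- NULL
  list(taxonomy = taxonomy, profiles = validate_profiles(profiles))
}
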