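#' Family-level completeness table
#'
#' One row per family plus a TOTAL row, with counts of species, species
#' without an available genome, and non/partial/complete denitrifiers, and
#' percentages computed exclusively over genome-available species
#' (denominator `n_species - n_no_genome`), rounded half-up to one decimal.
#' Species without genomes contribute only to `n_species` and `n_no_genome`.
#'
#' @param calls phenotype calls from [classify_profiles()] (genome-available
#'   species only).
#' @param taxonomy taxonomy data frame (all species, including those without
#'   genomes).
#' @return data frame with columns `family`, `n_species`, `n_no_genome`,
#'   `n_non`, `n_partial`, `n_complete`, `pct_non`, `pct_partial`,
#'   `pct_complete`.
#' @export
family_table <- function(calls, taxonomy) {
  if (nrow(calls) > 0 && !all(calls$species %in% taxonomy$species))
    stop("species missing from taxonomy: ",
         paste(setdiff(calls$species, taxonomy$species), collapse = ", "))
  fams <- unique(taxonomy$family)
  if (nrow(taxonomy) == 0)
    return(data.frame(family = character(), n_species = integer(),
                      n_no_genome = integer(), n_non = integer(),
                      n_partial = integer(), n_complete = integer(),
                      pct_non = numeric(), pct_partial = numeric(),
                      pct_complete = numeric(), stringsAsFactors = FALSE))
  cls <- calls$completeness[match(taxonomy$species, calls$species)]
  row_for <- function(fam, sub, subcls) {
    n <- nrow(sub)
    nga <- sum(!sub$genome_available)
    avail <- n - nga
    counts <- c(non = sum(subcls == "non", na.rm = TRUE),
                partial = sum(subcls == "partial", na.rm = TRUE),
                complete = sum(subcls == "complete", na.rm = TRUE))
    pct <- if (avail > 0) round_half_up(100 * counts / avail, 1)
           else rep(NA_real_, 3)
    data.frame(family = fam, n_species = n, n_no_genome = nga,
               n_non = counts[["non"]], n_partial = counts[["partial"]],
               n_complete = counts[["complete"]],
               pct_non = pct[[1]], pct_partial = pct[[2]],
               pct_complete = pct[[3]], stringsAsFactors = FALSE)
  }
  rows <- lapply(fams, function(fam) {
    sel <- taxonomy$family == fam
    row_for(fam, taxonomy[sel, , drop = FALSE], cls[sel])
  })
  rows <- c(rows, list(row_for("TOTAL", taxonomy, cls)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-enzyme presence counts
#'
#' Number of genome-available species carrying each marker enzyme, with the
#' nitrite reductase count broken down by type (NirK vs NirS).
#'
#' @param profiles profile data frame.
#' @return data frame with columns `enzyme` (`nar`, `nir`, `nirK`, `nirS`,
#'   `nor`, `nos`, `none`) and `n_species`; `none` counts species with no
#'   marker at all.
#' @export
enzyme_distribution <- function(profiles) {
  profiles <- validate_profiles(profiles)
  data.frame(
    enzyme = c("nar", "nir", "nirK", "nirS", "nor", "nos", "none"),
    n_species = c(sum(profiles$nar), sum(profiles$nir),
                  sum(profiles$nir_type == "NirK"),
                  sum(profiles$nir_type == "NirS"),
                  sum(profiles$nor), sum(profiles$nos),
                  sum(!profiles$nar & !profiles$nir & !profiles$nor &
                        !profiles$nos)),
    stringsAsFactors = FALSE)
}

#' Counts of the sixteen marker combinations
#'
#' @param profiles profile data frame.
#' @param taxonomy optional taxonomy; when given, counts are additionally
#'   split by family.
#' @return data frame with columns `combination` (e.g. `"nar+nir"`, `"none"`),
#'   optionally `family`, and `n_species`; every one of the 16 subsets is
#'   reported, zeros included.
#' @export
combination_counts <- function(profiles, taxonomy = NULL) {
  profiles <- validate_profiles(profiles)
  combo_of <- function(k) {
    present <- PATHWAY_ENZYMES[c(profiles$nar[k], profiles$nir[k],
                                 profiles$nor[k], profiles$nos[k])]
    if (length(present) == 0) "none" else paste(present, collapse = "+")
  }
  all16 <- vapply(0:15, function(m) {
    present <- PATHWAY_ENZYMES[as.logical(bitwAnd(m, c(1L, 2L, 4L, 8L)))]
    if (length(present) == 0) "none" else paste(present, collapse = "+")
  }, "")
  combos <- vapply(seq_len(nrow(profiles)), combo_of, "")
  if (is.null(taxonomy)) {
    data.frame(combination = all16,
               n_species = as.integer(table(factor(combos, levels = all16))),
               stringsAsFactors = FALSE)
  } else {
    fam <- taxonomy$family[match(profiles$species, taxonomy$species)]
    tab <- table(factor(combos, levels = all16), fam)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("combination", "family", "n_species")
    out$n_species <- as.integer(out$n_species)
    out
  }
}

#' Potential gas-emitter fractions of a cohort
#'
#' Fractions of species whose theoretical pathway end product is NO, is N2O,
#' is either gas, and of species carrying Nos (able to reduce N2O to N2) —
#' each reported over two denominators: potential denitrifiers, and all
#' genome-available species. Percentages are rounded half-up to one decimal.
#' With zero denitrifiers the denitrifier-denominator percentages are
#' undefined (`NA`), not 0.
#'
#' @param calls phenotype calls from [classify_profiles()], one row per
#'   genome-available species.
#' @return data frame with columns `quantity` (`NO_enders`, `N2O_enders`,
#'   `gas_emitters`, `nos_bearers`), `n`, `pct_of_denitrifiers`,
#'   `pct_of_genomes`, plus attributes `n_genomes` and `n_denitrifiers`.
#' @export
emitter_fractions <- function(calls) {
  if (nrow(calls) == 0) stop("at least one genome-available species required")
  n_gen <- nrow(calls)
  n_den <- sum(calls$status == "denitrifier")
  n <- c(NO_enders = sum(calls$end_product == "NO"),
         N2O_enders = sum(calls$end_product == "N2O"),
         gas_emitters = sum(calls$end_product %in% c("NO", "N2O")),
         nos_bearers = sum(calls$emitter == "N2_reducer"))
  out <- data.frame(
    quantity = names(n), n = as.integer(n),
    pct_of_denitrifiers = if (n_den > 0) round_half_up(100 * n / n_den, 1)
                          else rep(NA_real_, 4),
    pct_of_genomes = round_half_up(100 * n / n_gen, 1),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_genomes") <- n_gen
  attr(out, "n_denitrifiers") <- n_den
  out
}

#' Headline cohort summary
#'
#' Totals and percentages over genome-available species: denitrifier share
#' and partial/complete shares, per-enzyme totals, combination counts and
#' emitter fractions, in one list.
#'
#' @param calls phenotype calls.
#' @param profiles matching profile table.
#' @param taxonomy taxonomy table.
#' @return list with elements `n_species_total`, `n_genomes`,
#'   `n_denitrifiers`, `pct_denitrifiers`, `pct_non`, `pct_partial`,
#'   `pct_complete`, `enzymes`, `combinations`, `emitters`, `families`.
#' @export
cohort_summary <- function(calls, profiles, taxonomy) {
  n_gen <- nrow(calls)
  n_den <- sum(calls$status == "denitrifier")
  pct <- function(k) round_half_up(100 * k / n_gen, 1)
  list(n_species_total = nrow(taxonomy),
       n_genomes = n_gen,
       n_denitrifiers = n_den,
       pct_denitrifiers = pct(n_den),
       pct_non = pct(sum(calls$completeness == "non")),
       pct_partial = pct(sum(calls$completeness == "partial")),
       pct_complete = pct(sum(calls$completeness == "complete")),
       enzymes = enzyme_distribution(profiles),
       combinations = combination_counts(profiles),
       emitters = emitter_fractions(calls),
       families = family_table(calls, taxonomy))
}
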