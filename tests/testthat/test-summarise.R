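# random cohort used for the brute-force recount checks
make_cohort <- function(seed, n = 40) {
  set.seed(seed)
  prof <- data.frame(
    species = sprintf("sp%03d", 1:n),
    nar = runif(n) < 0.3, nir = runif(n) < 0.6,
    nor = runif(n) < 0.6, nos = runif(n) < 0.3,
    stringsAsFactors = FALSE)
  prof$nir_type <- ifelse(prof$nir, "NirK", "absent")
  prof <- prof[, c("species", "nar", "nir", "nir_type", "nor", "nos")]
  tax <- data.frame(species = prof$species,
                    family = sample(c("FamA", "FamB", "FamC"), n,
                                    replace = TRUE),
                    genome_available = TRUE, stringsAsFactors = FALSE)
  list(profiles = prof, taxonomy = tax,
       calls = classify_profiles(prof))
}

test_that("family table counts equal the generator's class allocation", {
  comm <- generate_community(small_config(seed = 61, n1 = 8L, n2 = 8L))
  det <- detect_markers(comm$proteomes, comm$panel, comm$gene_order,
                        comm$taxonomy)
  ft <- family_table(classify_profiles(det$profiles), comm$taxonomy)
  truth <- comm$truth
  for (fam in c("FamA", "FamB")) {
    row <- ft[ft$family == fam, ]
    expect_equal(row$n_non,
                 sum(truth$family == fam & truth$class == "non",
                     na.rm = TRUE))
    expect_equal(row$n_partial,
                 sum(truth$family == fam & truth$class == "partial",
                     na.rm = TRUE))
    expect_equal(row$n_complete,
                 sum(truth$family == fam & truth$class == "complete",
                     na.rm = TRUE))
  }
})

test_that("family table: TOTAL row equals column sums, percentages recompute", {
  co <- make_cohort(71)
  ft <- family_table(co$calls, co$taxonomy)
  tot <- ft[ft$family == "TOTAL", ]
  fam <- ft[ft$family != "TOTAL", ]
  for (col in c("n_species", "n_no_genome", "n_non", "n_partial",
                "n_complete"))
    expect_equal(tot[[col]], sum(fam[[col]]))
  for (k in seq_len(nrow(ft))) {
    denom <- ft$n_species[k] - ft$n_no_genome[k]
    expect_equal(ft$n_non[k] + ft$n_partial[k] + ft$n_complete[k], denom)
    for (cls in c("non", "partial", "complete"))
      expect_equal(ft[[paste0("pct_", cls)]][k],
                   halonitro:::round_half_up(
                     100 * ft[[paste0("n_", cls)]][k] / denom, 1))
    expect_lt(abs(ft$pct_non[k] + ft$pct_partial[k] + ft$pct_complete[k]
                  - 100), 0.15)
  }
})

test_that("family table is invariant to row order and catches unknown species", {
  co <- make_cohort(72)
  shuffled <- co$calls[sample(nrow(co$calls)), ]
  expect_equal(family_table(shuffled, co$taxonomy),
               family_table(co$calls, co$taxonomy))
  rogue <- co$calls
  rogue$species[1] <- "not_in_taxonomy"
  expect_error(family_table(rogue, co$taxonomy), "missing from taxonomy")
  expect_equal(nrow(family_table(co$calls[0, ], co$taxonomy[0, ])), 0)
})

test_that("species without genomes only count in n_species and n_no_genome", {
  tax <- data.frame(species = c("s1", "s2", "s3"), family = "FamA",
                    genome_available = c(TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  prof <- data.frame(species = "s1", nar = FALSE, nir = TRUE,
                     nir_type = "NirK", nor = FALSE, nos = FALSE,
                     stringsAsFactors = FALSE)
  ft <- family_table(classify_profiles(prof), tax)
  row <- ft[ft$family == "FamA", ]
  expect_equal(row$n_species, 3)
  expect_equal(row$n_no_genome, 2)
  expect_equal(row$n_partial, 1)
  expect_equal(row$pct_partial, 100)  # denominator is genomes only
})

test_that("enzyme distribution equals an independent tally", {
  co <- make_cohort(73)
  ed <- enzyme_distribution(co$profiles)
  get <- function(e) ed$n_species[ed$enzyme == e]
  expect_equal(get("nar"), sum(co$profiles$nar))
  expect_equal(get("nir"), sum(co$profiles$nir))
  expect_equal(get("nirK"), sum(co$profiles$nir_type == "NirK"))
  expect_equal(get("nirS"), 0)
  expect_equal(get("nor"), sum(co$profiles$nor))
  expect_equal(get("nos"), sum(co$profiles$nos))
  expect_equal(get("none"), sum(rowSums(
    co$profiles[, c("nar", "nir", "nor", "nos")]) == 0))

  one <- data.frame(species = "s", nar = TRUE, nir = TRUE,
                    nir_type = "NirK", nor = TRUE, nos = TRUE,
                    stringsAsFactors = FALSE)
  expect_equal(enzyme_distribution(one)$n_species,
               c(1L, 1L, 1L, 0L, 1L, 1L, 0L))
})

test_that("combination counts cover all 16 subsets and sum to the cohort", {
  co <- make_cohort(74)
  cc <- combination_counts(co$profiles)
  expect_equal(nrow(cc), 16)
  expect_equal(sum(cc$n_species), nrow(co$profiles))
  # independent recount of one combination
  expect_equal(cc$n_species[cc$combination == "nir+nor"],
               sum(co$profiles$nir & co$profiles$nor & !co$profiles$nar &
                     !co$profiles$nos))
  byfam <- combination_counts(co$profiles, co$taxonomy)
  expect_equal(sum(byfam$n_species), nrow(co$profiles))
})

test_that("emitter fractions equal a brute-force recount over both denominators", {
  co <- make_cohort(75)
  ef <- emitter_fractions(co$calls)
  n_den <- sum(rowSums(co$profiles[, c("nar", "nir", "nor", "nos")]) > 0)
  n_gen <- nrow(co$profiles)
  expect_equal(attr(ef, "n_denitrifiers"), n_den)
  recount <- vapply(seq_len(nrow(co$profiles)), function(k)
    oracle_end_product(co$profiles$nar[k], co$profiles$nir[k],
                       co$profiles$nor[k], co$profiles$nos[k]), "")
  n_no <- sum(recount == "NO"); n_n2o <- sum(recount == "N2O")
  g <- function(q, col) ef[[col]][ef$quantity == q]
  expect_equal(g("NO_enders", "n"), n_no)
  expect_equal(g("N2O_enders", "n"), n_n2o)
  expect_equal(g("gas_emitters", "n"), n_no + n_n2o)
  expect_equal(g("nos_bearers", "n"), sum(co$profiles$nos))
  expect_equal(g("NO_enders", "pct_of_denitrifiers"),
               halonitro:::round_half_up(100 * n_no / n_den, 1))
  expect_equal(g("N2O_enders", "pct_of_genomes"),
               halonitro:::round_half_up(100 * n_n2o / n_gen, 1))
})

test_that("degenerate emitter inputs: no Nos, no denitrifiers, empty cohort", {
  prof <- data.frame(species = c("s1", "s2"), nar = c(TRUE, FALSE),
                     nir = c(TRUE, FALSE), nir_type = c("NirK", "absent"),
                     nor = FALSE, nos = FALSE, stringsAsFactors = FALSE)
  ef <- emitter_fractions(classify_profiles(prof))
  expect_equal(ef$n[ef$quantity == "nos_bearers"], 0)

  none <- prof; none$nar <- none$nir <- FALSE; none$nir_type <- "absent"
  ef <- emitter_fractions(classify_profiles(none))
  expect_true(all(is.na(ef$pct_of_denitrifiers)))  # undefined, not 0
  expect_true(all(ef$pct_of_genomes == 0))

  expect_error(emitter_fractions(classify_profiles(prof[0, ])),
               "at least one")
})
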