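test_that("config validation rejects impossible settings", {
  fs <- data.frame(family = "F", n_species = 4L,
                   non = 0.25, partial = 0.5, complete = 0.25)
  expect_s3_class(simulation_config(fs), "halonitro_simconfig")
  bad <- fs; bad$non <- 0.3
  expect_error(simulation_config(bad), "sum to 1")
  expect_error(simulation_config(fs, identity_true = 0.3,
                                 identity_decoy = 0.5), "identity_true")
  expect_error(simulation_config(fs, identity_decoy = 0), "identity_decoy")
  expect_error(simulation_config(fs, p_no_genome = 1), "p_no_genome")
  zero <- fs; zero$n_species <- 0L
  expect_error(simulation_config(zero), "at least one species")
})

test_that("panel generation is reproducible and NirK/NirS are well separated", {
  p1 <- generate_reference_panel(seed = 1)
  p2 <- generate_reference_panel(seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1$residues,
                         generate_reference_panel(seed = 2)$residues))
  expect_equal(nchar(p1$residues[p1$family == "NarG"]), 400)
  expect_true(all(strsplit(paste(p1$residues, collapse = ""), "")[[1]]
                  %in% halonitro:::AA_ALPHABET))
  pid <- global_align(p1$residues[p1$family == "NirK"],
                      p1$residues[p1$family == "NirS"])$percent_identity
  expect_lt(pid, 0.40)
  expect_error(generate_reference_panel(1, c(NarG = 40)), "six enzyme")
  expect_error(generate_reference_panel(
    1, c(NarG = 40, NarH = 250, NirK = 320, NirS = 320, Nor = 350,
         NosZ = 300)), "at least 50")
})

test_that("mutate_to_identity hits the target exactly by brute-force count", {
  base <- generate_reference_panel(seed = 2)
  s <- base$residues[base$family == "NarG"]  # 400 residues
  expect_identical(mutate_to_identity(s, 1.0, seed = 1), s)
  mut <- mutate_to_identity(s, 0.70, seed = 1)
  diffs <- sum(strsplit(s, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(diffs, 120)
  expect_equal(nchar(mut), nchar(s))
  expect_equal(global_align(s, mut)$percent_identity, 0.70)
  expect_error(mutate_to_identity(s, 0), "target_identity")
  expect_error(mutate_to_identity(s, 1.2), "target_identity")
  # below-threshold product is not detected
  panel <- generate_reference_panel(seed = 3)
  half <- mutate_to_identity(panel$residues[panel$family == "NirK"], 0.50,
                             seed = 4)
  hits <- scan_proteome(
    data.frame(id = "P1", description = "", residues = half),
    panel, threshold = 0.65, species = "sp")
  expect_false(any(hits$accepted))
})

test_that("class allocation is exact for small families (largest remainder)", {
  fs <- data.frame(family = "F", n_species = 4L,
                   non = 0.25, partial = 0.5, complete = 0.25)
  comm <- generate_community(simulation_config(fs, seed = 11,
                                               p_no_genome = 0))
  tab <- table(comm$truth$class)
  expect_equal(tab[["non"]], 1)
  expect_equal(tab[["partial"]], 2)
  expect_equal(tab[["complete"]], 1)
  n_enz <- rowSums(comm$truth[, c("nar", "nir", "nor", "nos")])
  expect_equal(sum(n_enz == 0), 1)
  expect_equal(sum(n_enz == 4), 1)
  expect_true(all(n_enz[comm$truth$class == "partial"] %in% 1:3))
})

test_that("no-genome species are flagged at the configured rate and carry no proteome", {
  fs <- data.frame(family = "F", n_species = 10L,
                   non = 0.5, partial = 0.5, complete = 0)
  comm <- generate_community(simulation_config(fs, seed = 12,
                                               p_no_genome = 0.5))
  expect_equal(sum(!comm$taxonomy$genome_available), 5)
  nga <- comm$taxonomy$species[!comm$taxonomy$genome_available]
  expect_true(all(!nga %in% names(comm$proteomes)))
  expect_true(all(is.na(comm$truth$class[!comm$taxonomy$genome_available])))
})

test_that("identical configs give byte-identical communities", {
  cfg <- small_config(seed = 21)
  expect_identical(generate_community(cfg), generate_community(cfg))
  other <- generate_community(small_config(seed = 22))
  expect_false(identical(generate_community(cfg)$s16, other$s16))
})

test_that("community structure: markers, narH adjacency, decoys, 16S", {
  cfg <- small_config(seed = 31, n1 = 5L, n2 = 5L)
  comm <- generate_community(cfg)
  truth <- comm$truth
  for (k in seq_len(nrow(truth))) {
    sp <- truth$species[k]
    prot <- comm$proteomes[[sp]]
    expect_gte(sum(startsWith(prot$description, "decoy:")), 5)
    if (truth$nar[k]) {
      go <- comm$gene_order[comm$gene_order$species == sp, ]
      pg <- go$position[go$marker_truth == "NarG"]
      ph <- go$position[go$marker_truth == "NarH"]
      expect_equal(abs(pg - ph), 1)
    }
  }
  # 16S: one aligned sequence per species, distances well-formed
  expect_equal(comm$s16$id, comm$taxonomy$species)
  expect_equal(length(unique(nchar(comm$s16$residues))), 1)
  d <- p_distance_matrix(comm$s16)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
})

test_that("pipeline recovery: detection reproduces the ground truth", {
  cfg <- small_config(seed = 41, n1 = 6L, n2 = 6L)  # 0.85 vs 0.30 identity
  comm <- generate_community(cfg)
  det <- detect_markers(comm$proteomes, comm$panel, comm$gene_order,
                        comm$taxonomy)
  truth <- comm$truth[comm$truth$genome_available,
                      c("species", "nar", "nir", "nir_type", "nor", "nos")]
  truth <- truth[order(truth$species), ]
  prof <- det$profiles[order(det$profiles$species), ]
  rownames(truth) <- rownames(prof) <- NULL
  expect_equal(prof, truth)
  # classification downstream is coherent with the generator's classes
  calls <- classify_profiles(det$profiles)
  cls <- comm$truth$class[match(calls$species, comm$truth$species)]
  expect_equal(calls$completeness, cls)
})

test_that("write_community round-trips through the readers", {
  dir <- withr::local_tempdir()
  comm <- generate_community(small_config(seed = 51))
  write_community(comm, dir)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax, comm$taxonomy)
  go <- read_gene_order(file.path(dir, "gene_order.tsv"))
  expect_equal(go, comm$gene_order[names(go)])
  panel <- read_panel(file.path(dir, "panel.fasta"))
  expect_equal(panel$residues, comm$panel$residues)
  s16 <- read_fasta(file.path(dir, "s16_aligned.fasta"), "dna_aligned")
  expect_equal(s16$residues, comm$s16$residues)
  sp <- comm$taxonomy$species[comm$taxonomy$genome_available][1]
  prot <- read_fasta(file.path(dir, "proteomes", paste0(sp, ".fasta")),
                     "protein")
  expect_equal(prot$residues, comm$proteomes[[sp]]$residues)
})
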