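#' Read a marker reference panel
#'
#' A panel is a protein FASTA whose record descriptions carry the enzyme
#' family as `family=NarG` (families: NarG, NarH, NirK, NirS, Nor, NosZ).
#'
#' @param path path to the panel FASTA.
#' @return data frame with columns `id`, `family`, `residues`.
#' @export
read_panel <- function(path) {
  rec <- read_fasta(path, alphabet = "protein")
  fam <- regmatches(rec$description,
                    regexpr("family=[A-Za-z]+", rec$description))
  if (length(fam) != nrow(rec))
    stop("every panel record needs a 'family=<enzyme>' tag in its description")
  fam <- sub("^family=", "", fam)
  bad <- setdiff(fam, MARKER_FAMILIES)
  if (length(bad) > 0)
    stop("unknown enzyme family in panel: ", paste(bad, collapse = ", "))
  data.frame(id = rec$id, family = fam, residues = rec$residues,
             stringsAsFactors = FALSE)
}

#' Scan a proteome for denitrification marker enzymes
#'
#' Aligns every proteome sequence to every panel member with
#' [global_align()] and keeps, per enzyme family, the single best hit
#' (highest percent identity; ties broken by the lexicographically smaller
#' protein id, then subject id). A hit is accepted when its identity is at
#' least `threshold` (the comparison is inclusive and made on the exact
#' ratio matches/alignment_length, with no pre-rounding). Best hits below the
#' threshold are retained with `accepted = FALSE` for reporting.
#'
#' @param proteome data frame of protein records (`id`, `residues`) for one
#'   species, as from [read_fasta()].
#' @param panel panel data frame from [read_panel()].
#' @param threshold identity acceptance threshold, default 0.65.
#' @param species species name attached to the hits.
#' @param match,mismatch,gap_open,gap_extend scoring passed to
#'   [global_align()]; the acceptance rule itself uses only identity.
#' @return data frame of marker hits: `species`, `enzyme`, `protein_id`,
#'   `subject_id`, `percent_identity`, `accepted`, `context_verified`
#'   (`NA` until [verify_nar_context()] fills it for NarG).
#' @export
scan_proteome <- function(proteome, panel, threshold = 0.65,
                          species = NA_character_,
                          match = 1, mismatch = 0,
                          gap_open = -10, gap_extend = -1) {
  if (!all(MARKER_FAMILIES %in% panel$family))
    stop("panel must contain at least one reference per enzyme family")
  stopifnot(threshold > 0, threshold <= 1)
  empty <- data.frame(species = character(), enzyme = character(),
                      protein_id = character(), subject_id = character(),
                      percent_identity = numeric(), accepted = logical(),
                      context_verified = logical(), stringsAsFactors = FALSE)
  if (is.null(proteome) || nrow(proteome) == 0) {
    warning("empty proteome for species ", species)
    return(empty)
  }
  # stable scan order regardless of input row order
  prot <- proteome[order(proteome$id), , drop = FALSE]
  out <- empty
  for (fam in MARKER_FAMILIES) {
    refs <- panel[panel$family == fam, , drop = FALSE]
    refs <- refs[order(refs$id), , drop = FALSE]
    best <- NULL
    for (p in seq_len(nrow(prot))) {
      for (r in seq_len(nrow(refs))) {
        aln <- global_align(prot$residues[p], refs$residues[r],
                            match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend)
        cand <- list(protein_id = prot$id[p], subject_id = refs$id[r],
                     identity = aln$percent_identity)
        if (is.null(best) || cand$identity > best$identity)
          best <- cand
        # rows are visited in sorted id order, so the first of a tie wins
      }
    }
    out <- rbind(out, data.frame(
      species = species, enzyme = fam,
      protein_id = best$protein_id, subject_id = best$subject_id,
      percent_identity = best$identity,
      accepted = best$identity >= threshold,
      context_verified = NA, stringsAsFactors = FALSE))
  }
  out
}

#' Verify the genetic context of an accepted NarG hit
#'
#' Respiratory nitrate reductase is reported only when the gene coding for
#' its electron-transfer subunit NarH lies nearby: this returns `TRUE` iff an
#' accepted NarH hit is on the same replicon within `window` ordinal gene
#' positions of the NarG gene. Absence of an accepted NarH hit yields
#' `FALSE`; a NarG gene id missing from the gene order is an error (it cannot
#' be distinguished from a mis-keyed annotation table).
#'
#' @param species species name.
#' @param hits marker hits for that species from [scan_proteome()].
#' @param gene_order gene-order data frame from [read_gene_order()].
#' @param window maximum ordinal distance counted as adjacent (default 2,
#'   either side, same replicon).
#' @return logical flag.
#' @export
verify_nar_context <- function(species, hits, gene_order, window = 2) {
  stopifnot(window >= 1)
  h <- hits[hits$species == species, , drop = FALSE]
  narg <- h[h$enzyme == "NarG" & h$accepted, , drop = FALSE]
  if (nrow(narg) == 0) stop("species has no accepted NarG hit")
  go <- gene_order[gene_order$species == species, , drop = FALSE]
  gpos <- go[go$gene_id == narg$protein_id[1], , drop = FALSE]
  if (nrow(gpos) == 0)
    stop("NarG gene '", narg$protein_id[1],
         "' absent from gene order of ", species)
  narh <- h[h$enzyme == "NarH" & h$accepted, , drop = FALSE]
  if (nrow(narh) == 0) return(FALSE)
  hpos <- go[go$gene_id == narh$protein_id[1], , drop = FALSE]
  if (nrow(hpos) == 0) return(FALSE)
  hpos$replicon[1] == gpos$replicon[1] &&
    abs(hpos$position[1] - gpos$position[1]) <= window
}

#' Type the nitrite reductase of a species
#'
#' Returns the panel family of the accepted Nir hit (`"NirK"` or `"NirS"`),
#' or `"absent"` when neither is accepted. Accepted hits of the same protein
#' to both panels are an ambiguity error; when different proteins hit the two
#' panels, the higher-identity one wins (an exact tie is also ambiguous).
#'
#' @param hits marker hits for one species.
#' @return `"NirK"`, `"NirS"` or `"absent"`.
#' @export
type_nir <- function(hits) {
  nir <- hits[hits$enzyme %in% c("NirK", "NirS") & hits$accepted, ,
              drop = FALSE]
  if (nrow(nir) == 0) return("absent")
  if (nrow(nir) == 1) return(nir$enzyme[1])
  if (nir$protein_id[1] == nir$protein_id[2] ||
      nir$percent_identity[1] == nir$percent_identity[2])
    stop("ambiguous nitrite reductase type: accepted hits to both ",
         "NirK and NirS panels")
  nir$enzyme[which.max(nir$percent_identity)]
}

#' Build marker presence profiles from hits
#'
#' One profile per genome-available species. `nar` is set only when the NarG
#' hit is accepted *and* its genetic context is verified
#' ([verify_nar_context()]); an accepted NarG without an adjacent NarH gene
#' does not count (some species grow anaerobically on nitrate without a
#' canonical Nar, and other molybdopterin oxidoreductases can masquerade as
#' NarG). Species without genomes are excluded.
#'
#' @param hits combined marker-hit data frame over all scanned species.
#' @param gene_orders combined gene-order data frame.
#' @param taxonomy taxonomy data frame from [read_taxonomy()].
#' @param scanned_species species for which a proteome was scanned; a
#'   genome-available species outside this set is a consistency error.
#' @param window NarH adjacency window, passed to [verify_nar_context()].
#' @return data frame of profiles: `species`, `nar`, `nir`, `nir_type`,
#'   `nor`, `nos`.
#' @export
build_profiles <- function(hits, gene_orders, taxonomy,
                           scanned_species = unique(hits$species),
                           window = 2) {
  avail <- taxonomy$species[taxonomy$genome_available]
  missing <- setdiff(avail, scanned_species)
  if (length(missing) > 0)
    stop("genome-available species without a scanned proteome: ",
         paste(missing, collapse = ", "))
  if (length(avail) == 0)
    return(data.frame(species = character(), nar = logical(),
                      nir = logical(), nir_type = character(),
                      nor = logical(), nos = logical(),
                      stringsAsFactors = FALSE))
  rows <- lapply(sort(avail), function(sp) {
    h <- hits[hits$species == sp, , drop = FALSE]
    acc <- function(fam) any(h$enzyme == fam & h$accepted)
    nar <- FALSE
    if (acc("NarG"))
      nar <- verify_nar_context(sp, h, gene_orders, window = window)
    nt <- type_nir(h)
    data.frame(species = sp, nar = nar, nir = nt != "absent",
               nir_type = nt, nor = acc("Nor"), nos = acc("NosZ"),
               stringsAsFactors = FALSE)
  })
  validate_profiles(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
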