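#' Read a FASTA file into a record table
#'
#' Records are returned as a data frame with columns `id`, `description` and
#' `residues`, in file order. Wrapped sequence lines are concatenated and the
#' leading `>` is stripped from ids. Malformed input is rejected, never
#' silently repaired.
#'
#' @param path path to a FASTA file.
#' @param alphabet one of `"protein"` (20 amino-acid letters plus `X`),
#'   `"dna"` (`ACGT` plus `N`) or `"dna_aligned"` (`dna` plus the gap
#'   character `-`).
#' @return a data frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna", "dna_aligned")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), description = character(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("not a FASTA file (first line is not a header): ", path)
  grp <- cumsum(hdr)
  ids <- character(max(grp)); desc <- character(max(grp))
  res <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  seqs <- character(max(grp))
  seqs[as.integer(names(res))] <- res
  for (k in which(hdr)) {
    h <- sub("^>", "", lines[k])
    sp <- regmatches(h, regexpr("\\s", h))
    if (length(sp) == 0) { ids[grp[k]] <- h; desc[grp[k]] <- "" }
    else {
      ids[grp[k]] <- sub("\\s.*$", "", h)
      desc[grp[k]] <- sub("^\\S+\\s+", "", h)
    }
  }
  if (any(!nzchar(ids))) stop("empty record id in ", path)
  if (anyDuplicated(ids))
    stop("duplicated record id in ", path, ": ",
         ids[duplicated(ids)][1])
  if (any(!nzchar(seqs)))
    stop("record with no residues in ", path, ": ", ids[!nzchar(seqs)][1])
  allowed <- switch(alphabet,
    protein     = c(AA_ALPHABET, "X"),
    dna         = c("A", "C", "G", "T", "N"),
    dna_aligned = c("A", "C", "G", "T", "N", "-"))
  for (k in seq_along(seqs)) {
    ch <- strsplit(seqs[k], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% allowed))
    if (length(bad) > 0)
      stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
           " of record '", ids[k], "' for alphabet ", alphabet)
  }
  data.frame(id = ids, description = desc, residues = seqs,
             stringsAsFactors = FALSE)
}

#' Write a record table to FASTA
#'
#' @param records data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    d <- if ("description" %in% names(records)) records$description[k] else ""
    hdr <- if (nzchar(d)) paste0(">", records$id[k], " ", d)
           else paste0(">", records$id[k])
    writeLines(hdr, con)
    s <- records$residues[k]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a species taxonomy table
#'
#' Tab-separated with header columns `species`, `family` and
#' `genome_available` (logical). Species must be unique.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `species`, `family`, `genome_available`.
#' @export
read_taxonomy <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "family", "genome_available")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("taxonomy table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$species))
    stop("duplicated species in taxonomy: ",
         tab$species[duplicated(tab$species)][1])
  tab$genome_available <- as.logical(tab$genome_available)
  if (anyNA(tab$genome_available))
    stop("genome_available must be TRUE/FALSE")
  tab[need]
}

#' @rdname read_taxonomy
#' @param taxonomy data frame as returned by `read_taxonomy()`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a gene-order table
#'
#' Gene positions are 0-based ordinal indices along a replicon (not genomic
#' coordinates): the adjacency check for *narH* only needs the ordering.
#' Within each (species, replicon) the positions must be the consecutive
#' integers 0, 1, 2, ...
#'
#' @param path path to a TSV with header columns `species`, `replicon`,
#'   `position`, `gene_id`.
#' @return data frame with those columns.
#' @export
read_gene_order <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "replicon", "position", "gene_id")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("gene-order table lacks column(s): ", paste(miss, collapse = ", "))
  tab$position <- as.integer(tab$position)
  validate_gene_order(tab[need])
}

validate_gene_order <- function(tab) {
  key <- paste(tab$species, tab$replicon, sep = "\r")
  for (g in split(tab$position, key)) {
    if (!identical(sort(g), seq(0L, length(g) - 1L)))
      stop("gene positions on a replicon must be consecutive from 0")
  }
  tab
}

#' @rdname read_gene_order
#' @param gene_order data frame as returned by `read_gene_order()`.
#' @export
write_gene_order <- function(gene_order, path) {
  write.table(gene_order, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Newick serialisation
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()]. Bootstrap
#' supports are carried as internal node labels (the MEGA convention), branch
#' lengths after colons. Round-tripping preserves topology, leaf labels,
#' branch lengths and supports.
#'
#' @param text a Newick string (or a path when `file` is used).
#' @return `read_newick()`: an [ape::read.tree()] `"phylo"` object;
#'   `write_newick()`: a Newick string (also written to `file` if given).
#' @export
read_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick string")
  tr
}

#' @rdname read_newick
#' @param tree a `"phylo"` object.
#' @param file optional output path.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 10)
  if (!is.null(file)) writeLines(s, file)
  invisible(s)
}

#' Read/write a marker presence matrix
#'
#' One row per genome-available species with logical columns `nar`, `nir`,
#' `nor`, `nos` and the character column `nir_type`
#' (`"NirK"`, `"NirS"` or `"absent"`).
#'
#' @param path path to the TSV file.
#' @return data frame of profiles.
#' @export
read_profiles <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "nar", "nir", "nir_type", "nor", "nos")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("profile table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in PATHWAY_ENZYMES) tab[[col]] <- as.logical(tab[[col]])
  validate_profiles(tab[need])
}

validate_profiles <- function(profiles) {
  if (anyDuplicated(profiles$species))
    stop("duplicated species in profile table")
  bad <- !profiles$nir & profiles$nir_type != "absent"
  if (any(bad)) stop("nir = FALSE requires nir_type = 'absent'")
  if (!all(profiles$nir_type %in% c("NirK", "NirS", "absent")))
    stop("nir_type must be NirK, NirS or absent")
  profiles
}

#' @rdname read_profiles
#' @param profiles data frame of profiles.
#' @export
write_profiles <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
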