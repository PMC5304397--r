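# Readers and writers for the external formats the pipeline touches.
# All coordinates are 1-based inclusive (GFF/BLAST convention).
# Readers validate strictly and reject malformed records rather than coerce.

.AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX"

#' Read a protein FASTA file
#'
#' @param path FASTA file (optionally gzipped).
#' @param species_map optional named character vector gene id -> species;
#'   by default species are parsed from a \code{"SPECIES|gene"} id prefix.
#' @param sep species prefix separator.
#' @return data.frame with columns \code{gene_id}, \code{species},
#'   \code{sequence}.  Errors on duplicate ids, empty sequences or letters
#'   outside the 20 amino acids plus X.
#' @export
read_proteins <- function(path, species_map = NULL, sep = "|") {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  if (any(nchar(sq) == 0L)) {
    stop("empty sequence for ", paste(ids[nchar(sq) == 0L], collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", .AA_ALPHABET), sq)
  if (any(bad)) {
    stop("non amino-acid letters in sequence(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  data.frame(gene_id = ids,
             species = species_of(ids, species_map, sep),
             sequence = unname(sq),
             stringsAsFactors = FALSE)
}

#' Read a CDS FASTA file
#'
#' Coding sequences must have length divisible by 3 and contain no internal
#' stop codon; a terminal stop codon is allowed and trimmed.  Ambiguous
#' bases (N) are allowed and handled downstream (codon columns containing N
#' are excluded from substitution counting).
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{gene_id}, \code{cds}.
#' @export
read_cds <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sq <- toupper(gsub("U", "T", as.character(seqs), fixed = TRUE))
  if (any(nchar(sq) == 0L)) stop("empty CDS for ", paste(ids[nchar(sq) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", sq)
  if (any(bad)) {
    stop("non-nucleotide letters in CDS: ", paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  if (any(nchar(sq) %% 3L != 0L)) {
    stop("CDS length not divisible by 3: ",
         paste(ids[nchar(sq) %% 3L != 0L], collapse = ", "))
  }
  sq <- vapply(seq_along(sq), function(i) .trim_terminal_stop(sq[i], ids[i]), character(1L))
  data.frame(gene_id = ids, cds = unname(sq), stringsAsFactors = FALSE)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.trim_terminal_stop <- function(cds, id) {
  cods <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  n <- length(cods)
  if (cods[n] %in% .STOP_CODONS) cods <- cods[-n]
  if (length(cods) == 0L) stop("CDS of ", id, " is a bare stop codon")
  if (any(cods %in% .STOP_CODONS)) stop("internal stop codon in CDS of ", id)
  paste(cods, collapse = "")
}

#' Check that a CDS translates to its paired protein
#'
#' @param cds coding sequence (terminal stop already trimmed).
#' @param protein amino-acid sequence.
#' @return invisibly TRUE; errors naming the first mismatching codon
#'   position otherwise.  Codons containing N translate to X and match
#'   any amino acid.
#' @export
check_cds_matches_protein <- function(cds, protein) {
  aa <- translate_cds(cds)
  pr <- strsplit(toupper(protein), "")[[1]]
  if (length(aa) != length(pr)) {
    stop(sprintf("CDS translates to %d residues but protein has %d",
                 length(aa), length(pr)))
  }
  mismatch <- which(aa != pr & aa != "X" & pr != "X")
  if (length(mismatch) > 0L) {
    stop(sprintf("translation mismatch at protein position %d (%s vs %s)",
                 mismatch[1L], aa[mismatch[1L]], pr[mismatch[1L]]))
  }
  invisible(TRUE)
}

#' Translate a CDS under the standard genetic code
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return character vector of amino acids (one per codon); codons with N
#'   give X, stop codons give \code{"*"}.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  cods <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  unname(.codon_tables()$aa_of[cods])
}

#' Read a 12-column tabular similarity-hit file
#'
#' Expects the classic 12-column tab-separated layout: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore.
#' Self-hits are retained; they are filtered downstream.
#'
#' @param path hits file.
#' @return data.frame with typed columns named as above.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(.empty_hits())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L)) {
    .fail_line(path, which(nc != 12L)[1L],
               sprintf("expected 12 tab-separated columns, found %d", nc[nc != 12L][1L]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) .fail_line(path, which(is.na(v))[1L], paste("malformed", name))
    v
  }
  int <- function(col, name) {
    v <- suppressWarnings(as.integer(m[, col]))
    if (anyNA(v)) .fail_line(path, which(is.na(v))[1L], paste("malformed", name))
    v
  }
  hits <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = num(3L, "pident"), length = int(4L, "length"),
    mismatch = int(5L, "mismatch"), gapopen = int(6L, "gapopen"),
    qstart = int(7L, "qstart"), qend = int(8L, "qend"),
    sstart = int(9L, "sstart"), send = int(10L, "send"),
    evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore"),
    stringsAsFactors = FALSE)
  bad <- which(hits$qstart > hits$qend | hits$sstart > hits$send)
  if (length(bad) > 0L) .fail_line(path, bad[1L], "start coordinate exceeds end")
  bad <- which(hits$pident < 0 | hits$pident > 100)
  if (length(bad) > 0L) .fail_line(path, bad[1L], "pident outside [0, 100]")
  bad <- which(hits$evalue < 0)
  if (length(bad) > 0L) .fail_line(path, bad[1L], "negative E-value")
  hits
}

.empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Write similarity hits in the 12-column tabular layout
#' @param hits data.frame as returned by \code{\link{read_hits}}.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rooted species timetree in Newick format
#'
#' Branch lengths are relative divergence times; they must be present and
#' non-negative, leaf labels must be unique and the tree rooted.
#'
#' @param path Newick file, or a Newick string ending in ";".
#' @return an \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  tree <- if (grepl(";\\s*$", path)) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input")
  if (ape::Ntip(tree) < 2L) stop("species tree must have at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in species tree")
  if (is.null(tree$edge.length)) stop("species tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in species tree")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  tree
}

#' Read / write a gene-family dump
#'
#' One family per line, members tab-separated (the MCL dump convention).
#' Family ids are assigned by line order as \code{fam<line number>}.
#'
#' @param path dump file.
#' @return named list of character vectors (one per family).
#' @export
read_family_dump <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fams <- strsplit(lines, "\t", fixed = TRUE)
  all_genes <- unlist(fams)
  if (anyDuplicated(all_genes)) {
    stop("gene appears in more than one family: ",
         paste(utils::head(unique(all_genes[duplicated(all_genes)]), 5L), collapse = ", "))
  }
  names(fams) <- sprintf("fam%05d", seq_along(fams))
  fams
}

#' @rdname read_family_dump
#' @param families named list of character vectors.
#' @export
write_family_dump <- function(families, path) {
  writeLines(vapply(families, paste, character(1L), collapse = "\t"), path)
  invisible(path)
}

#' Read a gene-position table
#'
#' Tab-separated with header \code{gene_id, scaffold, start, end, strand};
#' coordinates 1-based inclusive, strand \code{+} or \code{-}.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_positions <- function(path) {
  pos <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "integer", "character"))
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  if (!identical(names(pos), need)) {
    stop("position table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(pos$gene_id)) stop("duplicate gene_id in position table")
  if (any(pos$start > pos$end)) {
    stop("start > end for ", paste(pos$gene_id[pos$start > pos$end], collapse = ", "))
  }
  if (!all(pos$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  pos
}

#' Collapse isoforms to one record per gene by longest CDS
#'
#' When a proteome contains several transcripts per gene, the transcript
#' with the longest CDS is selected.  Ties break on isoform id
#' (lexicographically first) for determinism.
#'
#' @param cds data.frame from \code{\link{read_cds}} (isoform-level ids).
#' @param isoform_to_gene named character vector isoform id -> gene id.
#' @return subset of \code{cds}, one row per gene, with a
#'   \code{gene} column added.
#' @export
collapse_isoforms <- function(cds, isoform_to_gene) {
  miss <- setdiff(cds$gene_id, names(isoform_to_gene))
  if (length(miss) > 0L) {
    stop("no gene mapping for isoform(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  cds$gene <- unname(isoform_to_gene[cds$gene_id])
  ord <- order(cds$gene, -nchar(cds$cds), cds$gene_id)
  cds <- cds[ord, , drop = FALSE]
  cds <- cds[!duplicated(cds$gene), , drop = FALSE]
  rownames(cds) <- NULL
  cds
}

#' Read / write a pairwise dN/dS table
#'
#' Adapter for externally computed dN/dS estimates (e.g. from a
#' maximum-likelihood codon tool) so that every downstream analysis can be
#' run on external tables for parity.
#'
#' @param path TSV with header \code{gene_a, gene_b, dN, dS, omega,
#'   S_sites, N_sites, n_codons, saturated}.
#' @return data.frame of paralog-pair estimates.
#' @export
read_dnds_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "dN", "dS", "omega", "S_sites", "N_sites",
            "n_codons", "saturated")
  if (!all(need %in% names(d))) {
    stop("dN/dS table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(d$dN < 0, na.rm = TRUE) || any(d$dS < 0, na.rm = TRUE)) {
    stop("negative dN or dS in table")
  }
  d[need]
}

#' @rdname read_dnds_table
#' @param estimates data.frame of pair estimates.
#' @export
write_dnds_table <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
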