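# Pairwise protein alignment, codon threading and NG86 dN/dS estimation.
#
# The estimator is Nei-Gojobori (1986) codon counting: per-codon
# synonymous/nonsynonymous site fractions averaged over the two sequences
# (mutations to stop codons count as nonsynonymous so that
# S_sites + N_sites = 3 * compared codons exactly), per-codon-pair
# substitution counts averaged over all shortest mutational pathways with
# pathways through stop codons excluded, and a Jukes-Cantor multiple-hit
# correction d = -(3/4) ln(1 - (4/3) p) applied to the proportions.

.dupdyn_cache <- new.env(parent = emptyenv())

.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# Lazily built lookup tables: amino acid per codon (N-containing codons
# map to X), per-codon synonymous site fractions, and per-codon-pair
# averaged synonymous/nonsynonymous difference counts for all 61 x 61
# sense-codon pairs (pathway enumeration done once, then cached).
.codon_tables <- function() {
  if (!is.null(.dupdyn_cache$tables)) return(.dupdyn_cache$tables)
  nts <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))  # all 64
  aa <- .GENETIC_CODE[codons]
  sense <- codons[aa != "*"]
  # translation including ambiguous codons
  amb <- expand.grid(a = c(nts, "N"), b = c(nts, "N"), c = c(nts, "N"),
                     stringsAsFactors = FALSE)
  amb_cod <- paste0(amb$a, amb$b, amb$c)
  aa_of <- ifelse(amb_cod %in% codons, unname(.GENETIC_CODE[amb_cod]), "X")
  names(aa_of) <- amb_cod

  # synonymous site fraction per sense codon: at each position, the
  # fraction of the 3 possible changes that are synonymous (changes to
  # stops count as nonsynonymous)
  syn_sites <- vapply(sense, function(cod) {
    s <- 0
    for (pos in 1:3) {
      orig <- substr(cod, pos, pos)
      for (nt in setdiff(nts, orig)) {
        mut <- cod
        substr(mut, pos, pos) <- nt
        if (.GENETIC_CODE[mut] == .GENETIC_CODE[cod]) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1L))

  ns <- length(sense)
  Sd <- matrix(0, ns, ns, dimnames = list(sense, sense))
  Nd <- Sd
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i < j) next
      cnt <- .pathway_counts(sense[i], sense[j])
      Sd[i, j] <- Sd[j, i] <- cnt[1L]
      Nd[i, j] <- Nd[j, i] <- cnt[2L]
    }
  }
  .dupdyn_cache$tables <- list(codons = codons, sense = sense, aa_of = aa_of,
                               syn_sites = syn_sites, Sd = Sd, Nd = Nd)
  .dupdyn_cache$tables
}

# Average synonymous/nonsynonymous substitution counts between two sense
# codons over all orderings of the single-nucleotide steps, excluding
# pathways that pass through a stop codon.  If every pathway is blocked,
# the raw differences are split evenly between the two classes.
.pathway_counts <- function(ca, cb) {
  diffpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(diffpos)
  if (k == 0L) return(c(0, 0))
  perms <- .permutations(diffpos)
  syn <- 0; nonsyn <- 0; nvalid <- 0L
  for (p in seq_len(nrow(perms))) {
    cur <- ca
    s <- 0; n <- 0; ok <- TRUE
    for (pos in perms[p, ]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      if (.GENETIC_CODE[nxt] == "*") { ok <- FALSE; break }
      if (.GENETIC_CODE[nxt] == .GENETIC_CODE[cur]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { syn <- syn + s; nonsyn <- nonsyn + n; nvalid <- nvalid + 1L }
  }
  if (nvalid == 0L) return(c(k / 2, k / 2))
  c(syn / nvalid, nonsyn / nvalid)
}

.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Global pairwise protein alignment
#'
#' Optimal global alignment (Needleman-Wunsch with affine gaps) under
#' BLOSUM62 with the standard protein-search gap costs: a gap of length L
#' costs \code{gap_open + L * gap_extend}.  Deterministic for fixed inputs.
#'
#' @param a,b amino-acid sequences (character strings).
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @param matrix substitution matrix name, default \code{"BLOSUM62"}.
#' @return object of class \code{pairwise_alignment}: list with
#'   \code{aligned_a}, \code{aligned_b} (gapped strings), \code{score},
#'   \code{identity} (percent over aligned columns) and
#'   \code{aligned_columns} (count of gapless columns).
#' @export
align_protein_pair <- function(a, b, gap_open = 11, gap_extend = 1,
                               matrix = "BLOSUM62") {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  submat <- .get_submat(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  both <- ca != "-" & cb != "-"
  structure(list(
    aligned_a = pa, aligned_b = pb,
    score = Biostrings::score(aln),
    identity = 100 * sum(ca == cb & both) / max(1L, sum(both)),
    aligned_columns = sum(both)),
    class = "pairwise_alignment")
}

.get_submat <- function(name) {
  key <- paste0("submat_", name)
  if (is.null(.dupdyn_cache[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .dupdyn_cache[[key]] <- e[[name]]
  }
  .dupdyn_cache[[key]]
}

#' Thread CDS onto a protein alignment
#'
#' Converts an amino-acid alignment into a codon alignment by substituting
#' each residue with its source codon and each gap with a codon gap
#' (\code{"---"}).  The translation of each CDS must match its ungapped
#' protein row; a mismatch is an error naming the offending position.
#'
#' @param aln a \code{pairwise_alignment}.
#' @param cds_a,cds_b coding sequences for the two rows (terminal stop
#'   already trimmed).
#' @return object of class \code{codon_alignment}: list with character
#'   vectors \code{codons_a}, \code{codons_b} and \code{n_codons} (number
#'   of alignment columns).
#' @export
thread_codons <- function(aln, cds_a, cds_b) {
  row_a <- strsplit(aln$aligned_a, "")[[1]]
  row_b <- strsplit(aln$aligned_b, "")[[1]]
  codons_a <- .thread_one(row_a, cds_a, "a")
  codons_b <- .thread_one(row_b, cds_b, "b")
  structure(list(codons_a = codons_a, codons_b = codons_b,
                 n_codons = length(codons_a)),
            class = "codon_alignment")
}

.thread_one <- function(row, cds, label) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS ", label, " length not divisible by 3")
  cods <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- .codon_tables()$aa_of[cods]
  ungapped <- row[row != "-"]
  if (length(aa) != length(ungapped)) {
    stop(sprintf("CDS %s has %d codons but aligned protein row has %d residues",
                 label, length(aa), length(ungapped)))
  }
  mism <- which(aa != ungapped & aa != "X" & ungapped != "X")
  if (length(mism) > 0L) {
    stop(sprintf("translation of CDS %s does not match protein at residue %d (%s vs %s)",
                 label, mism[1L], aa[mism[1L]], ungapped[mism[1L]]))
  }
  out <- rep("---", length(row))
  out[row != "-"] <- cods
  out
}

#' NG86 pairwise dN/dS
#'
#' Nei-Gojobori codon-counting estimate of synonymous and nonsynonymous
#' divergence between two aligned coding sequences, with Jukes-Cantor
#' correction.  Columns containing a gap, an ambiguous base or a stop
#' codon are excluded from counting.
#'
#' @param caln a \code{codon_alignment}.
#' @return object of class \code{dnds_estimate}: list with \code{dN},
#'   \code{dS} (substitutions per site; \code{Inf} when the corrected
#'   distance is undefined, see \code{saturated}), \code{omega}
#'   (\code{dN/dS}, \code{NA} when dS is 0 or saturated), \code{S_sites},
#'   \code{N_sites} (average site counts; their sum is 3 x the compared
#'   codons), \code{n_codons} (compared codon columns) and
#'   \code{saturated} (TRUE when (4/3) p >= 1 for either class).
#' @export
ng86_dnds <- function(caln) {
  tb <- .codon_tables()
  ia <- match(caln$codons_a, tb$sense)
  ib <- match(caln$codons_b, tb$sense)
  keep <- !is.na(ia) & !is.na(ib)   # drops gaps, N-containing and stop codons
  if (!any(keep)) stop("no comparable codon columns")
  ia <- ia[keep]; ib <- ib[keep]
  n_codons <- length(ia)
  S <- sum((tb$syn_sites[ia] + tb$syn_sites[ib]) / 2)
  N <- 3 * n_codons - S
  idx <- cbind(ia, ib)
  Sd <- sum(tb$Sd[idx])
  Nd <- sum(tb$Nd[idx])
  pS <- Sd / S
  pN <- Nd / N
  sat_s <- (4 / 3) * pS >= 1
  sat_n <- (4 / 3) * pN >= 1
  jc <- function(p, sat) if (sat) Inf else max(0, -0.75 * log(1 - (4 / 3) * p))
  dS <- jc(pS, sat_s)
  dN <- jc(pN, sat_n)
  omega <- if (sat_s || sat_n || dS == 0) NA_real_ else dN / dS
  structure(list(dN = dN, dS = dS, omega = omega,
                 S_sites = S, N_sites = N, n_codons = n_codons,
                 saturated = sat_s || sat_n),
            class = "dnds_estimate")
}

#' Full dN/dS estimate for one gene pair
#'
#' Convenience wrapper: align the proteins, thread the codon alignment and
#' run NG86.
#'
#' @param prot_a,prot_b protein sequences.
#' @param cds_a,cds_b matching coding sequences.
#' @param ... passed to \code{\link{align_protein_pair}}.
#' @return a \code{dnds_estimate}.
#' @export
pair_dnds <- function(prot_a, prot_b, cds_a, cds_b, ...) {
  aln <- align_protein_pair(prot_a, prot_b, ...)
  ng86_dnds(thread_codons(aln, cds_a, cds_b))
}

#' Classify a paralog pair as pre- or post-speciation
#'
#' A pair is "old" (duplicated before speciation) when its dS exceeds the
#' speciation threshold (the mean dS of 1:1 orthologs) and "young"
#' otherwise; a pair exactly at the threshold is called young.
#'
#' @param dS numeric vector of pairwise synonymous divergences.
#' @param speciation_threshold mean 1:1-ortholog dS.
#' @return character vector, \code{"old"} or \code{"young"}.
#' @export
classify_pair_age <- function(dS, speciation_threshold) {
  ifelse(dS > speciation_threshold, "old", "young")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("dN = %.4f, dS = %.4f, omega = %s (%d codons, S = %.1f, N = %.1f%s)\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega),
              x$n_codons, x$S_sites, x$N_sites,
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}
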