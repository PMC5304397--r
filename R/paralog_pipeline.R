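# The duplicate-gene inference chain: nearest-paralog selection, filter
# cascades, 1:1 ortholog extraction, the speciation threshold on the dS
# axis, age distributions and ancestral-duplicate loss rates.

#' Nearest-paralog pair set from within-species similarity hits
#'
#' Hits are filtered to alignments of at least \code{min_aln} residues
#' with at least \code{min_identity} percent identity; per gene the
#' highest-bitscore non-self hit is its nearest paralog, and the union of
#' these per-gene choices is deduplicated on unordered pairs (reciprocal
#' best hits yield one pair).  Ties on bitscore break to the
#' lexicographically smallest subject for determinism.
#'
#' @param hits data.frame of within-species similarity hits
#'   (\code{\link{read_hits}} layout).
#' @param min_aln minimum alignment length (residues), default 150.
#' @param min_identity minimum percent identity, default 30.
#' @param species_map optional named vector gene -> species; when supplied
#'   (or when ids carry a species prefix) cross-species hits raise an
#'   error, enforcing the within-species precondition.
#' @return data.frame with columns \code{gene_a}, \code{gene_b}
#'   (\code{gene_a < gene_b}), one row per unordered pair, sorted.
#' @export
nearest_paralogs <- function(hits, min_aln = 150, min_identity = 30,
                             species_map = NULL) {
  if (!is.null(species_map)) {
    sq <- species_of(hits$qseqid, species_map)
    ss <- species_of(hits$sseqid, species_map)
    if (any(sq != ss)) stop("cross-species hits passed to nearest_paralogs()")
  }
  keep <- hits$qseqid != hits$sseqid &
    hits$length >= min_aln & hits$pident >= min_identity
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  h <- h[order(h$qseqid, -h$bitscore, h$sseqid), , drop = FALSE]
  best <- h[!duplicated(h$qseqid), , drop = FALSE]
  op <- .order_pair(best$qseqid, best$sseqid)
  pairs <- unique(data.frame(gene_a = op$a, gene_b = op$b,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Attach dN/dS estimates to a pair table
#'
#' Runs \code{\link{pair_dnds}} (align, thread, NG86) for each pair.
#'
#' @param pairs data.frame with \code{gene_a}, \code{gene_b}.
#' @param proteins data.frame from \code{\link{read_proteins}}.
#' @param cds data.frame from \code{\link{read_cds}} (1:1 with proteins by
#'   \code{gene_id}).
#' @param ... passed to \code{\link{align_protein_pair}}.
#' @return \code{pairs} with columns \code{dN}, \code{dS}, \code{omega},
#'   \code{S_sites}, \code{N_sites}, \code{n_codons}, \code{saturated}
#'   appended.
#' @export
estimate_pairs <- function(pairs, proteins, cds, ...) {
  prot <- stats::setNames(proteins$sequence, proteins$gene_id)
  cd <- stats::setNames(cds$cds, cds$gene_id)
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  miss <- setdiff(genes, intersect(names(prot), names(cd)))
  if (length(miss) > 0L) {
    stop("missing protein or CDS for: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  est <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    e <- pair_dnds(prot[[a]], prot[[b]], cd[[a]], cd[[b]], ...)
    data.frame(dN = e$dN, dS = e$dS, omega = e$omega, S_sites = e$S_sites,
               N_sites = e$N_sites, n_codons = e$n_codons,
               saturated = e$saturated)
  })
  cbind(pairs, do.call(rbind, est))
}

#' Exclude saturated pairs
#'
#' Pairs with dS strictly greater than \code{max_ds} (default 2) likely
#' suffer from saturation and are dropped; a pair exactly at the bound is
#' kept.
#'
#' @param pairs data.frame with a \code{dS} column.
#' @param max_ds saturation bound, default 2.
#' @return filtered data.frame.
#' @export
filter_saturation <- function(pairs, max_ds = 2.0) {
  out <- pairs[!is.na(pairs$dS) & pairs$dS <= max_ds, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strict filtering for dN/dS comparisons
#'
#' Removes pairs whose estimates are unreliable because the sequences are
#' insufficiently diverged or short: by default a pair is dropped when
#' \code{dN < min_d} OR \code{dS < min_d} OR \code{S_sites < min_s_sites}.
#' The alternative reading of the rule, where the site condition must hold
#' jointly with the divergence condition
#' (\code{(dN < min_d | dS < min_d) & S_sites < min_s_sites}), is
#' available via \code{rule = "and_sites"}.
#'
#' @param pairs data.frame with \code{dN}, \code{dS}, \code{S_sites}.
#' @param min_d minimum dN and dS, default 0.01.
#' @param min_s_sites minimum synonymous sites, default 50.
#' @param rule \code{"or"} (default) or \code{"and_sites"}.
#' @return filtered data.frame.
#' @export
filter_for_omega <- function(pairs, min_d = 0.01, min_s_sites = 50,
                             rule = c("or", "and_sites")) {
  rule <- match.arg(rule)
  low_d <- pairs$dN < min_d | pairs$dS < min_d
  low_s <- pairs$S_sites < min_s_sites
  drop <- if (rule == "or") low_d | low_s else low_d & low_s
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract 1:1 orthologs between two species from gene families
#'
#' @param families named list of gene-id vectors.
#' @param species_a,species_b the two species labels.
#' @param species_map optional named vector gene -> species (default:
#'   \code{"SPECIES|gene"} prefix).
#' @return data.frame with \code{gene_a} (from \code{species_a}),
#'   \code{gene_b} (from \code{species_b}) and \code{family_id}, one row
#'   per family that has exactly one member in each species.
#' @export
extract_one_to_one <- function(families, species_a, species_b,
                               species_map = NULL) {
  rows <- lapply(names(families), function(fid) {
    genes <- families[[fid]]
    sp <- species_of(genes, species_map)
    ga <- genes[sp == species_a]
    gb <- genes[sp == species_b]
    if (length(ga) == 1L && length(gb) == 1L) {
      data.frame(gene_a = ga, gene_b = gb, family_id = fid,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      family_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Speciation threshold on the dS axis
#'
#' Arithmetic mean dS of 1:1 orthologs after excluding saturated pairs;
#' the peak of the ortholog dS distribution marks the speciation time.
#'
#' @param ortholog_ds numeric vector of 1:1-ortholog dS values.
#' @param max_ds saturation bound applied before averaging, default 2.
#' @return mean dS (the old/young classification threshold).
#' @export
speciation_threshold <- function(ortholog_ds, max_ds = 2.0) {
  ds <- ortholog_ds[!is.na(ortholog_ds) & ortholog_ds <= max_ds]
  if (length(ds) == 0L) stop("no ortholog dS values after saturation filtering")
  mean(ds)
}

#' Paralog age distribution on the dS axis
#'
#' Half-open bins \code{[lo, hi)} of width \code{bin_width} covering
#' \code{[0, max_ds]}; pairs with dS > \code{max_ds} are excluded first.
#'
#' @param ds numeric vector of paralog-pair dS values.
#' @param bin_width bin width, default 0.05.
#' @param max_ds saturation bound, default 2.
#' @return object of class \code{age_distribution}: data.frame with
#'   \code{lo}, \code{hi}, \code{count}; counts sum to the number of
#'   retained pairs.
#' @export
age_distribution <- function(ds, bin_width = 0.05, max_ds = 2.0) {
  ds <- ds[!is.na(ds) & ds <= max_ds]
  breaks <- seq(0, max_ds + bin_width, by = bin_width)
  idx <- findInterval(ds, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  out <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1L],
                    count = counts)
  class(out) <- c("age_distribution", "data.frame")
  out
}

#' Ancestral-duplicate loss rates between two genomes
#'
#' A family is counted as carrying an ancestral (pre-speciation) duplicate
#' in species X when it contains a within-X paralog pair with
#' \code{threshold < dS <= max_ds}.  That duplicate is scored as lost in
#' the other species Y when the family retains at most one member in Y
#' ("lost one or both paralogs").  The loss rate is lost / ancestral.
#'
#' @param pairs_a,pairs_b estimated within-species paralog pair tables
#'   (columns \code{gene_a}, \code{gene_b}, \code{dS}) for species A and B.
#' @param families named list of gene-id vectors (the shared clustering).
#' @param threshold speciation threshold from
#'   \code{\link{speciation_threshold}}.
#' @param species_a,species_b species labels.
#' @param species_map optional named vector gene -> species.
#' @param max_ds saturation bound, default 2.
#' @return list with \code{n_ancestral_a}, \code{n_lost_in_b},
#'   \code{loss_rate_ab} (fraction; NA with \code{undefined_ab = TRUE}
#'   when no ancestral duplicates), the symmetric \code{*_ba} fields, and
#'   \code{table}: the 2x2 lost/retained contingency table
#'   (rows: ancestral-in-A, ancestral-in-B).
#' @export
ancestral_loss_rates <- function(pairs_a, pairs_b, families, threshold,
                                 species_a, species_b, species_map = NULL,
                                 max_ds = 2.0) {
  fam_of <- stats::setNames(rep(names(families), lengths(families)),
                            unlist(families, use.names = FALSE))
  count_in <- function(sp) {
    genes <- unlist(families, use.names = FALSE)
    fams <- rep(names(families), lengths(families))
    keep <- species_of(genes, species_map) == sp
    tab <- table(factor(fams[keep], levels = names(families)))
    stats::setNames(as.integer(tab), names(families))
  }
  ancestral_families <- function(pairs) {
    old <- !is.na(pairs$dS) & pairs$dS > threshold & pairs$dS <= max_ds
    fa <- fam_of[pairs$gene_a[old]]
    fb <- fam_of[pairs$gene_b[old]]
    same <- !is.na(fa) & !is.na(fb) & fa == fb
    unique(fa[same])
  }
  anc_a <- ancestral_families(pairs_a)
  anc_b <- ancestral_families(pairs_b)
  copies_a <- count_in(species_a)
  copies_b <- count_in(species_b)
  lost_ab <- sum(copies_b[anc_a] <= 1L)
  lost_ba <- sum(copies_a[anc_b] <= 1L)
  rate <- function(lost, n) if (n == 0L) NA_real_ else lost / n
  tab <- matrix(c(lost_ab, length(anc_a) - lost_ab,
                  lost_ba, length(anc_b) - lost_ba),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("ancestral_in_a", "ancestral_in_b"),
                                c("lost", "retained")))
  list(n_ancestral_a = length(anc_a), n_lost_in_b = lost_ab,
       loss_rate_ab = rate(lost_ab, length(anc_a)),
       undefined_ab = length(anc_a) == 0L,
       n_ancestral_b = length(anc_b), n_lost_in_a = lost_ba,
       loss_rate_ba = rate(lost_ba, length(anc_b)),
       undefined_ba = length(anc_b) == 0L,
       table = tab)
}

#' Loss rate from counts
#'
#' @param n_lost families that lost one or both paralogs.
#' @param n_ancestral families with a pre-speciation duplicate.
#' @return fraction lost; errors when \code{n_ancestral} is 0.
#' @export
loss_rate <- function(n_lost, n_ancestral) {
  if (n_ancestral <= 0) stop("loss rate undefined: no ancestral duplicates")
  if (n_lost < 0 || n_lost > n_ancestral) stop("n_lost must be in [0, n_ancestral]")
  n_lost / n_ancestral
}

#' Percent increase between two means
#'
#' @param larger,smaller the two mean values.
#' @return percent increase of \code{larger} over \code{smaller}.
#' @export
percent_increase <- function(larger, smaller) {
  if (smaller <= 0) stop("baseline mean must be positive")
  100 * (larger - smaller) / smaller
}

#' End-to-end duplicate-gene loss analysis for a genome pair
#'
#' Runs the full chain on raw inputs: cluster gene families from filtered
#' similarity hits (MCL), select nearest paralogs within each species,
#' estimate dN/dS for paralog and 1:1-ortholog pairs, set the speciation
#' threshold from mean ortholog dS, and compute ancestral-duplicate loss
#' rates in both directions.
#'
#' @param proteins,cds data.frames as from \code{\link{read_proteins}} /
#'   \code{\link{read_cds}}.
#' @param hits all-against-all similarity hits
#'   (\code{\link{read_hits}} layout, both within- and cross-species).
#' @param species_a,species_b the two species labels.
#' @param min_aln,min_identity nearest-paralog alignment filters (see
#'   \code{\link{nearest_paralogs}}).
#' @param max_evalue,min_coverage clustering hit filters (see
#'   \code{\link{filter_hits}}).
#' @param inflation MCL inflation.
#' @param max_ds saturation bound on dS.
#' @param species_map optional gene -> species map.
#' @return list with \code{families}, \code{pairs_a}, \code{pairs_b}
#'   (estimated paralog pairs), \code{orthologs} (estimated 1:1 pairs),
#'   \code{threshold} (mean ortholog dS) and \code{loss} (the
#'   \code{\link{ancestral_loss_rates}} result).
#' @export
duplication_history_analysis <- function(proteins, cds, hits,
                                         species_a, species_b,
                                         min_aln = 150, min_identity = 30,
                                         max_evalue = 1e-5, min_coverage = 0.5,
                                         inflation = 2.1, max_ds = 2.0,
                                         species_map = NULL) {
  lens <- stats::setNames(nchar(proteins$sequence), proteins$gene_id)
  filt <- filter_hits(hits, lens, max_evalue, min_coverage)
  fams <- mcl_cluster(build_graph(filt, nodes = proteins$gene_id),
                      inflation = inflation)
  sp_q <- species_of(hits$qseqid, species_map)
  sp_s <- species_of(hits$sseqid, species_map)
  est <- function(sp) {
    pairs <- nearest_paralogs(hits[sp_q == sp & sp_s == sp, , drop = FALSE],
                              min_aln = min_aln, min_identity = min_identity)
    estimate_pairs(pairs, proteins, cds)
  }
  pairs_a <- est(species_a)
  pairs_b <- est(species_b)
  oo <- extract_one_to_one(fams, species_a, species_b, species_map)
  orthologs <- estimate_pairs(oo[, c("gene_a", "gene_b")], proteins, cds)
  threshold <- speciation_threshold(orthologs$dS, max_ds = max_ds)
  loss <- ancestral_loss_rates(pairs_a, pairs_b, fams, threshold,
                               species_a, species_b, species_map, max_ds)
  list(families = fams, pairs_a = pairs_a, pairs_b = pairs_b,
       orthologs = orthologs, threshold = threshold, loss = loss)
}
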