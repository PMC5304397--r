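# Simulators with known ground truth for every input the pipeline
# consumes: birth-death family-size histories on a timetree, two-species
# gene families with dated duplications and coding sequences diverging
# under a tunable-omega codon process, similarity hits derived from those
# sequences, and negative-binomial count matrices with a planted DE set
# enriched in chosen gene categories.

#' Simulate one linear birth-death branch
#'
#' Exact Gillespie simulation of a linear birth-death process with equal
#' per-gene gain and loss rate \code{lambda} (total event rate
#' \code{2 lambda n}); size 0 is absorbing.
#'
#' @param n0 starting copy number.
#' @param t branch length.
#' @param lambda per-gene rate.
#' @return copy number at the end of the branch.
#' @export
simulate_bd_branch <- function(n0, t, lambda) {
  n <- n0
  if (lambda == 0 || t == 0) return(n)
  tcur <- 0
  repeat {
    if (n == 0L) break
    tcur <- tcur + stats::rexp(1L, rate = 2 * lambda * n)
    if (tcur > t) break
    n <- n + sample(c(1L, -1L), 1L)
  }
  n
}

#' Simulate gene family sizes on a species tree
#'
#' Families start at the root with sizes from \code{root_size_dist}
#' (conditioned >= 1) and evolve down every branch by Gillespie
#' birth-death simulation, so that empirical transition frequencies can be
#' cross-checked against \code{\link{bd_transition_prob}} without
#' discretisation bias.
#'
#' @param tree rooted \code{phylo} timetree.
#' @param lambda per-gene gain/loss rate (scalar, applied to all
#'   branches) or a \code{\link{bd_model}}.
#' @param n_families number of families.
#' @param root_size_dist function(n) returning n root sizes (>= 1);
#'   default geometric with mean 2.
#' @param seed optional integer fixing all randomness.
#' @return list with \code{matrix} (family x species tip counts),
#'   \code{node_sizes} (family x node ground-truth sizes, columns indexed
#'   by node id) and \code{root_sizes}.
#' @export
simulate_family_sizes <- function(tree, lambda, n_families,
                                  root_size_dist = function(n) 1L + stats::rgeom(n, 0.5),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lam_edge <- if (inherits(lambda, "bd_model")) .lambda_by_edge(tree, lambda)
              else rep(lambda, nrow(tree$edge))
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  roots <- root_size_dist(n_families)
  while (any(roots < 1L)) roots[roots < 1L] <- root_size_dist(sum(roots < 1L))
  sizes <- base::matrix(0L, n_families, nnode)
  sizes[, ntip + 1L] <- as.integer(roots)
  # preorder: parents before children (reverse postorder edge sweep)
  tr <- stats::reorder(tree, "postorder")
  lam_post <- lam_edge[match(paste(tr$edge[, 1L], tr$edge[, 2L]),
                             paste(tree$edge[, 1L], tree$edge[, 2L]))]
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    sizes[, ch] <- vapply(sizes[, p], simulate_bd_branch,
                          integer(1L), t = tr$edge.length[e],
                          lambda = lam_post[e])
  }
  mat <- sizes[, seq_len(ntip), drop = FALSE]
  dimnames(mat) <- list(sprintf("fam%05d", seq_len(n_families)), tree$tip.label)
  list(matrix = mat, node_sizes = sizes, root_sizes = as.integer(roots))
}

#' Evolve a coding sequence for a span of time
#'
#' Mutation proposals arrive as a Poisson process with per-nucleotide
#' intensity \code{intensity}; synonymous proposals are always accepted,
#' nonsynonymous proposals with probability \code{omega}, and proposals
#' creating a stop codon are rejected.  Synonymous divergence therefore
#' accumulates at about \code{intensity} per synonymous site per unit
#' time, and the realised dN/dS reflects \code{omega}.
#'
#' @param cds nucleotide string (no stop codons, length divisible by 3).
#' @param t time span.
#' @param intensity per-nucleotide proposal rate per unit time.
#' @param omega acceptance probability of nonsynonymous proposals.
#' @return mutated coding sequence.
#' @export
evolve_cds <- function(cds, t, intensity = 1.0, omega = 0.2) {
  nts <- c("A", "C", "G", "T")
  x <- strsplit(toupper(cds), "")[[1]]
  L <- length(x)
  n_prop <- stats::rpois(1L, intensity * L * t)
  if (n_prop == 0L) return(cds)
  positions <- sample.int(L, n_prop, replace = TRUE)
  accept_draw <- stats::runif(n_prop)
  for (k in seq_len(n_prop)) {
    pos <- positions[k]
    new_nt <- sample(setdiff(nts, x[pos]), 1L)
    ci <- (pos - 1L) %/% 3L
    cod <- x[(ci * 3L + 1L):(ci * 3L + 3L)]
    newcod <- cod
    newcod[(pos - 1L) %% 3L + 1L] <- new_nt
    aa_old <- .GENETIC_CODE[[paste(cod, collapse = "")]]
    aa_new <- .GENETIC_CODE[[paste(newcod, collapse = "")]]
    if (aa_new == "*") next
    if (aa_new != aa_old && accept_draw[k] > omega) next
    x[pos] <- new_nt
  }
  paste(x, collapse = "")
}

#' Random coding sequence of sense codons
#'
#' @param n_codons number of codons.
#' @return nucleotide string with no stop codons.
#' @export
random_cds <- function(n_codons) {
  sense <- .codon_tables()$sense
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Configuration for a two-species duplicate-gene world
#'
#' The defaults describe a generalist/specialist aphid-like pair: total
#' ortholog synonymous divergence about 0.26 (speciation at age
#' \code{t_spec} on each side with unit substitution intensity), families
#' with pre-speciation duplications whose ages keep old-pair dS clearly
#' above the speciation threshold but below saturation, post-speciation
#' duplications younger than the split, purifying selection
#' (\code{omega = 0.2}) and an asymmetric ancestral-duplicate loss
#' probability (species A losing twice as often as species B).
#'
#' @param n_families number of gene families.
#' @param species two species labels (A = higher-loss lineage).
#' @param t_spec age of the speciation (relative time units).
#' @param t_root age at which family root sequences start evolving.
#' @param dup_age_margin minimum age gap between pre-speciation
#'   duplications and the speciation, keeping the planted old/young dS
#'   classes separated.
#' @param p_ancestral probability a family carries a pre-speciation
#'   duplication.
#' @param p_young probability each post-speciation lineage duplicates
#'   again.
#' @param loss_prob named per-species probability that one copy of an
#'   ancestral duplicate pair is lost in that species.
#' @param n_codons gene length in codons.
#' @param intensity per-nucleotide mutation-proposal rate per unit time.
#' @param omega nonsynonymous acceptance probability.
#' @return configuration list for
#'   \code{\link{simulate_two_species_world}}.
#' @export
two_species_config <- function(n_families = 40L,
                               species = c("Mper", "Apis"),
                               t_spec = 0.13, t_root = 0.65,
                               dup_age_margin = 0.075,
                               p_ancestral = 0.4, p_young = 0.25,
                               loss_prob = c(0.5, 0.25),
                               n_codons = 150L,
                               intensity = 1.0, omega = 0.2) {
  names(loss_prob) <- species
  list(n_families = n_families, species = species, t_spec = t_spec,
       t_root = t_root, dup_age_margin = dup_age_margin,
       p_ancestral = p_ancestral, p_young = p_young, loss_prob = loss_prob,
       n_codons = n_codons, intensity = intensity, omega = omega)
}

#' Simulate a two-species genome pair with dated duplications
#'
#' Generates gene families with explicit duplication times (so pre/post
#' speciation truth is exact), evolves coding sequences along the implied
#' gene trees under \code{\link{evolve_cds}}, and applies per-species loss
#' of ancestral duplicates.  Gene ids follow the \code{"SPECIES|gene"}
#' convention.
#'
#' @param config from \code{\link{two_species_config}}.
#' @param seed optional integer fixing all randomness.
#' @return list with \code{proteins} and \code{cds} (data.frames as from
#'   the readers), \code{genes} (per-gene truth: family, species, lineage
#'   of the ancestral copy, duplication age of its most recent
#'   duplication or NA), \code{families} (per-family truth:
#'   \code{ancestral_dup}, \code{dup_age}, per-species copy number and
#'   loss flags) and \code{true_families} (named list of gene ids, the
#'   planted clustering).
#' @export
simulate_two_species_world <- function(config = two_species_config(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  gene_rows <- list(); fam_rows <- list(); fam_members <- list()
  for (f in seq_len(cf$n_families)) {
    fid <- sprintf("fam%03d", f)
    root_seq <- random_cds(cf$n_codons)
    anc_dup <- stats::runif(1L) < cf$p_ancestral
    dup_age <- NA_real_
    # ancestral copies present at speciation, each with its sequence
    if (anc_dup) {
      dup_age <- stats::runif(1L, cf$t_spec + cf$dup_age_margin, cf$t_root)
      pre <- evolve_cds(root_seq, cf$t_root - dup_age, cf$intensity, cf$omega)
      anc <- list(evolve_cds(pre, dup_age - cf$t_spec, cf$intensity, cf$omega),
                  evolve_cds(pre, dup_age - cf$t_spec, cf$intensity, cf$omega))
    } else {
      anc <- list(evolve_cds(root_seq, cf$t_root - cf$t_spec,
                             cf$intensity, cf$omega))
    }
    copies <- list()   # per species list of list(seq, lineage, young_age)
    lost <- stats::setNames(c(FALSE, FALSE), cf$species)
    for (sp in cf$species) {
      keep <- seq_along(anc)
      if (anc_dup && stats::runif(1L) < cf$loss_prob[[sp]]) {
        keep <- sample(seq_along(anc), 1L)    # lose one of the two copies
        lost[[sp]] <- TRUE
      }
      sp_copies <- list()
      for (li in keep) {
        if (stats::runif(1L) < cf$p_young) {
          yage <- stats::runif(1L, 0, cf$t_spec)
          base <- evolve_cds(anc[[li]], cf$t_spec - yage, cf$intensity, cf$omega)
          sp_copies <- c(sp_copies, list(
            list(seq = evolve_cds(base, yage, cf$intensity, cf$omega),
                 lineage = li, young_age = yage),
            list(seq = evolve_cds(base, yage, cf$intensity, cf$omega),
                 lineage = li, young_age = yage)))
        } else {
          sp_copies <- c(sp_copies, list(
            list(seq = evolve_cds(anc[[li]], cf$t_spec, cf$intensity, cf$omega),
                 lineage = li, young_age = NA_real_)))
        }
      }
      copies[[sp]] <- sp_copies
    }
    members <- character()
    for (sp in cf$species) {
      for (i in seq_along(copies[[sp]])) {
        gid <- sprintf("%s|%sg%d", sp, fid, i)
        members <- c(members, gid)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gid, species = sp, family = fid,
          lineage = copies[[sp]][[i]]$lineage,
          young_age = copies[[sp]][[i]]$young_age,
          cds = copies[[sp]][[i]]$seq, stringsAsFactors = FALSE)
      }
    }
    fam_members[[fid]] <- members
    nc <- vapply(copies, length, integer(1L))
    fam_rows[[length(fam_rows) + 1L]] <- data.frame(
      family = fid, ancestral_dup = anc_dup, dup_age = dup_age,
      n_a = nc[[1L]], n_b = nc[[2L]],
      lost_a = lost[[1L]], lost_b = lost[[2L]], stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  fams <- do.call(rbind, fam_rows)
  prot <- vapply(genes$cds, function(s) paste(translate_cds(s), collapse = ""),
                 character(1L), USE.NAMES = FALSE)
  list(proteins = data.frame(gene_id = genes$gene_id, species = genes$species,
                             sequence = prot, stringsAsFactors = FALSE),
       cds = data.frame(gene_id = genes$gene_id, cds = genes$cds,
                        stringsAsFactors = FALSE),
       genes = genes[, c("gene_id", "species", "family", "lineage", "young_age")],
       families = fams,
       true_families = fam_members,
       config = cf)
}

#' Derive an all-against-all similarity-hit table from sequences
#'
#' Emulates a protein similarity search: candidate pairs are seeded by
#' shared amino-acid words (two distinct shared k-mers required, the
#' classic two-hit heuristic), seeded pairs are globally aligned with the
#' package aligner, and scores are converted into BLAST-like records:
#' bit score \code{(0.267 score + 3.19) / ln 2} (standard gapped BLOSUM62
#' Karlin-Altschul constants) and E-value surrogate
#' \code{len_q x total_db_length x 2^-bits}.  Records with E-value above
#' \code{max_evalue_emit} are not emitted.  No randomness is involved, so
#' the table is a deterministic function of the sequences.
#'
#' @param proteins data.frame with \code{gene_id}, \code{sequence}.
#' @param max_evalue_emit emission cutoff, default 1e-3 (comfortably
#'   looser than the downstream clustering filter).
#' @param self_hits include self-alignments, default TRUE.
#' @param word_size seed k-mer length, default 4.
#' @param min_words distinct shared words required to trigger an
#'   alignment, default 2.
#' @return hit data.frame in the \code{\link{read_hits}} layout.
#' @export
simulate_hits <- function(proteins, max_evalue_emit = 1e-3, self_hits = TRUE,
                          word_size = 4L, min_words = 2L) {
  ids <- proteins$gene_id
  seqs <- proteins$sequence
  n <- length(ids)
  db_len <- sum(nchar(seqs))
  submat <- .get_submat("BLOSUM62")
  # inverted word index -> candidate ordered pairs sharing >= min_words
  words <- lapply(seqs, function(s) {
    unique(substring(s, seq_len(max(0L, nchar(s) - word_size + 1L)),
                     word_size:nchar(s)))
  })
  idx <- split(rep(seq_len(n), lengths(words)), unlist(words))
  pa <- list(); pb <- list()
  for (members in idx) {
    if (length(members) < 2L || length(members) > 50L) next  # mask ubiquitous words
    pa[[length(pa) + 1L]] <- rep(members, each = length(members))
    pb[[length(pb) + 1L]] <- rep(members, times = length(members))
  }
  qi <- unlist(pa); si <- unlist(pb)
  off <- which(qi != si)
  keys <- (qi[off] - 1) * n + si[off]
  shared <- table(keys)
  cand_keys <- as.numeric(names(shared)[shared >= min_words])
  qi <- as.integer((cand_keys - 1) %/% n + 1)
  si <- as.integer((cand_keys - 1) %% n + 1)
  if (self_hits) { qi <- c(seq_len(n), qi); si <- c(seq_len(n), si) }
  if (length(qi) == 0L) return(.empty_hits())
  aas <- Biostrings::AAStringSet(seqs)
  aln <- Biostrings::pairwiseAlignment(
    aas[qi], aas[si], type = "global", substitutionMatrix = submat,
    gapOpening = 11, gapExtension = 1)
  score <- Biostrings::score(aln)
  bits <- (0.267 * score + 3.19) / log(2)
  evalue <- nchar(seqs[qi]) * db_len * 2^(-bits)
  keep <- which(evalue <= max_evalue_emit)
  if (length(keep) == 0L) return(.empty_hits())
  aln <- aln[keep]
  nmat <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  gapo <- Biostrings::insertion(ind)[, "Length"] +
    Biostrings::deletion(ind)[, "Length"]
  alen <- nmat + nmis + Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  out <- data.frame(
    qseqid = ids[qi[keep]], sseqid = ids[si[keep]],
    pident = round(100 * nmat / pmax(1L, nmat + nmis), 2L),
    length = as.integer(alen),
    mismatch = as.integer(nmis),
    gapopen = as.integer(gapo),
    qstart = 1L, qend = nchar(seqs[qi[keep]]),
    sstart = 1L, send = nchar(seqs[si[keep]]),
    evalue = evalue[keep], bitscore = round(bits[keep], 1L),
    stringsAsFactors = FALSE)
  ord <- order(out$qseqid, out$sseqid)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a count matrix with a planted DE set
#'
#' Negative-binomial counts for two conditions with per-sample size
#' factors; a planted fraction of genes is differentially expressed with
#' log2 fold change \code{log2fc} (random sign), and membership in the DE
#' set has elevated odds for genes in the designated categories,
#' emulating enrichment of duplicated/expanded/tandem gene classes among
#' host-responsive genes.
#'
#' @param n_genes number of genes (ids \code{g0001...} unless
#'   \code{gene_ids} given).
#' @param gene_ids optional explicit gene ids.
#' @param categories named list of gene-id vectors.
#' @param de_fraction baseline probability of DE membership, default
#'   0.05.
#' @param enrich_odds named odds multiplier per category (default 4 for
#'   every category).
#' @param log2fc planted absolute log2 fold change, default 2.
#' @param dispersion NB dispersion (1/size), default 0.05.
#' @param meanlog,sdlog log-normal parameters of baseline expression.
#' @param n_rep replicates per condition, default 3.
#' @param seed optional integer.
#' @return list with \code{matrix} (genes x samples), \code{condition},
#'   \code{size_factors}, \code{de_truth} (gene ids) and \code{log2fc}
#'   (signed planted effect per gene, 0 for non-DE).
#' @export
simulate_counts <- function(n_genes = 2000L, gene_ids = NULL,
                            categories = list(), de_fraction = 0.05,
                            enrich_odds = NULL, log2fc = 2,
                            dispersion = 0.05, meanlog = log(200),
                            sdlog = 1, n_rep = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n_genes))
  n_genes <- length(gene_ids)
  if (is.null(enrich_odds)) {
    enrich_odds <- stats::setNames(rep(4, length(categories)), names(categories))
  }
  logit <- function(p) log(p / (1 - p))
  eta <- rep(logit(de_fraction), n_genes)
  for (nm in names(categories)) {
    eta[gene_ids %in% categories[[nm]]] <-
      eta[gene_ids %in% categories[[nm]]] + log(enrich_odds[[nm]])
  }
  is_de <- stats::runif(n_genes) < 1 / (1 + exp(-eta))
  sign_fc <- sample(c(-1, 1), n_genes, replace = TRUE)
  fc <- ifelse(is_de, sign_fc * log2fc, 0)
  base_mean <- stats::rlnorm(n_genes, meanlog, sdlog)
  sf <- stats::runif(2L * n_rep, 0.7, 1.3)
  condition <- rep(c("A", "B"), each = n_rep)
  mu <- outer(base_mean, rep(1, 2L * n_rep))
  mu[, condition == "A"] <- mu[, condition == "A"] * 2^(-fc / 2)
  mu[, condition == "B"] <- mu[, condition == "B"] * 2^(fc / 2)
  mu <- sweep(mu, 2L, sf, "*")
  counts <- base::matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
    nrow = n_genes, dimnames = list(gene_ids, sprintf("s%d", seq_len(2L * n_rep))))
  list(matrix = counts, condition = condition, size_factors = sf,
       de_truth = gene_ids[is_de], log2fc = fc)
}

#' Simulate gene positions with planted tandem arrays
#'
#' Lays genes out on scaffolds in random order, then inserts the planted
#' arrays as runs of adjacent same-family genes.
#'
#' @param families named list of gene-id vectors.
#' @param tandem_families family ids to plant as tandem arrays (all their
#'   genes adjacent on one scaffold); all other genes are scattered.
#' @param n_scaffolds number of scaffolds.
#' @param gene_span bp per gene slot, default 2000.
#' @param seed optional integer.
#' @return list with \code{positions} (data.frame as from
#'   \code{\link{read_positions}}) and \code{true_arrays} (family ids
#'   planted tandem).
#' @export
simulate_positions <- function(families, tandem_families = character(),
                               n_scaffolds = 5L, gene_span = 2000L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_genes <- unlist(families, use.names = FALSE)
  tandem_genes <- unlist(families[tandem_families], use.names = FALSE)
  loose <- sample(setdiff(all_genes, tandem_genes))
  blocks <- c(lapply(families[tandem_families], identity),
              as.list(loose))
  blocks <- sample(blocks)   # shuffle block order, arrays stay contiguous
  scaffold_of <- sort(sample.int(n_scaffolds, length(blocks), replace = TRUE))
  rows <- list()
  slot <- stats::setNames(rep(0L, n_scaffolds), seq_len(n_scaffolds))
  for (b in seq_along(blocks)) {
    scf <- scaffold_of[b]
    for (g in blocks[[b]]) {
      start <- slot[[scf]] * gene_span + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, scaffold = sprintf("scaf%02d", scf),
        start = start, end = start + gene_span - 500L,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      slot[[scf]] <- slot[[scf]] + 1L
    }
  }
  pos <- do.call(rbind, rows)
  rownames(pos) <- NULL
  list(positions = pos, true_arrays = tandem_families)
}
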