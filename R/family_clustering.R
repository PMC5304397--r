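# Similarity-hit filtering, protein similarity graph and Markov clustering.
#
# MCL here is the classic flow simulation: add self-loops, column-normalise
# the weighted adjacency matrix, then iterate expansion (matrix squaring)
# and inflation (elementwise power followed by column renormalisation)
# until the flow matrix stops changing.  Clusters are read off the limit
# matrix as attractor systems; overlapping systems are merged so the
# output is a strict partition of the node set.

#' Filter all-against-all similarity hits for clustering
#'
#' Retains hits with E-value strictly below \code{max_evalue} that align
#' over at least \code{min_coverage} of the longer sequence of the pair.
#' Self-hits are removed.
#'
#' @param hits data.frame as from \code{\link{read_hits}}.
#' @param lengths named integer vector of sequence lengths (residues) for
#'   every gene occurring in \code{hits}.
#' @param max_evalue E-value cutoff (strict \code{<}), default \code{1e-5}.
#' @param min_coverage minimum \code{aln_length / max(len_q, len_s)},
#'   default 0.5.
#' @return filtered hits data.frame.
#' @export
filter_hits <- function(hits, lengths, max_evalue = 1e-5, min_coverage = 0.5) {
  genes <- unique(c(hits$qseqid, hits$sseqid))
  miss <- setdiff(genes, names(lengths))
  if (length(miss) > 0L) {
    stop("no length for gene(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  lq <- lengths[hits$qseqid]
  ls <- lengths[hits$sseqid]
  keep <- hits$qseqid != hits$sseqid &
    hits$evalue < max_evalue &
    hits$length / pmax(lq, ls) >= min_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the protein similarity graph from filtered hits
#'
#' Edge weight is \code{min(200, -log10(evalue))}, with E-value 0 mapped to
#' the cap 200 (the standard protein-clustering convention); reciprocal
#' hits are merged keeping the larger weight.  Hits whose weight would be
#' non-positive (E-value >= 1) are dropped.
#'
#' @param hits filtered hits data.frame.
#' @param nodes optional character vector of node ids to include even if
#'   they have no surviving edges (isolated nodes become singleton
#'   families).
#' @return object of class \code{similarity_graph}: list with
#'   \code{nodes} (sorted ids) and \code{edges} (data.frame a, b, weight
#'   with a < b).
#' @export
build_graph <- function(hits, nodes = NULL) {
  w <- ifelse(hits$evalue == 0, 200, pmin(200, -log10(hits$evalue)))
  keep <- w > 0 & hits$qseqid != hits$sseqid
  a <- hits$qseqid[keep]; b <- hits$sseqid[keep]; w <- w[keep]
  op <- .order_pair(a, b)
  key <- paste(op$a, op$b, sep = "\r")
  if (length(key) > 0L) {
    wmax <- tapply(w, key, max)
    parts <- strsplit(names(wmax), "\r", fixed = TRUE)
    edges <- data.frame(a = vapply(parts, `[[`, character(1L), 1L),
                        b = vapply(parts, `[[`, character(1L), 2L),
                        weight = as.numeric(wmax), stringsAsFactors = FALSE)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = character(), b = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  all_nodes <- sort(unique(c(edges$a, edges$b, nodes)))
  structure(list(nodes = all_nodes, edges = edges), class = "similarity_graph")
}

#' Markov clustering of a similarity graph
#'
#' @param graph a \code{similarity_graph}.
#' @param inflation inflation parameter r (elementwise power), default 2.1.
#' @param max_iter maximum expansion/inflation iterations.
#' @param prune_threshold matrix entries below this are zeroed (then the
#'   column renormalised) after each inflation; an approximation of the
#'   mcl binary's pruning schemes.
#' @param convergence_tol iteration stops when the largest elementwise
#'   change falls below this.
#' @return named list of character vectors (class \code{gene_families});
#'   families are a partition of the node set, members sorted, family ids
#'   \code{fam00001...} assigned by decreasing size then first member.
#'   Attribute \code{converged} is FALSE (with a warning) if
#'   \code{max_iter} was hit.
#' @export
mcl_cluster <- function(graph, inflation = 2.1, max_iter = 100L,
                        prune_threshold = 1e-5, convergence_tol = 1e-8) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) stop("empty graph")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges) > 0L) {
    ia <- match(graph$edges$a, nodes)
    ib <- match(graph$edges$b, nodes)
    A[cbind(ia, ib)] <- graph$edges$weight
    A[cbind(ib, ia)] <- graph$edges$weight
  }
  # self-loops: weight of a node's strongest edge (1 for isolated nodes),
  # dampening flow oscillation as in the standard MCL setup
  loop <- apply(A, 2L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune_threshold] <- 0
    cs <- colSums(M2)
    dead <- cs == 0                    # fully pruned column: restore self
    if (any(dead)) { M2[cbind(which(dead), which(dead))] <- 1; cs[dead] <- 1 }
    M2 <- sweep(M2, 2L, cs, "/")
    if (max(abs(M2 - M)) < convergence_tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) warning("MCL did not converge after ", max_iter, " iterations")
  fams <- .clusters_from_flow(M, nodes)
  attr(fams, "converged") <- converged
  class(fams) <- "gene_families"
  .assert_partition(fams, nodes)
  fams
}

# Interpret the limit flow matrix: node j is attracted to attractor row i
# whenever M[i, j] > eps; connected components of that support (made
# undirected) are the clusters.  Merging components implements the
# standard treatment of overlapping attractor systems.
.clusters_from_flow <- function(M, nodes, eps = 1e-6) {
  n <- length(nodes)
  supp <- (M > eps) | t(M > eps)
  diag(supp) <- TRUE
  comp <- integer(n)          # connected components by BFS
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(supp[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  fams <- split(nodes, comp)
  fams <- lapply(fams, sort)
  ord <- order(-lengths(fams), vapply(fams, `[[`, character(1L), 1L))
  fams <- fams[ord]
  names(fams) <- sprintf("fam%05d", seq_along(fams))
  fams
}

.assert_partition <- function(fams, nodes) {
  members <- unlist(fams, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, nodes)) {
    stop("internal error: clustering is not a partition of the node set")
  }
  invisible(TRUE)
}

#' Per-species family matrix and copy-number summary
#'
#' @param families \code{gene_families} (or any named list of gene-id
#'   vectors).
#' @param proteome data.frame with columns \code{gene_id} and
#'   \code{species} covering the full gene set (clustered or not).
#' @return list with \code{matrix} (family x species integer copy counts)
#'   and \code{summary}, a per-species data.frame of \code{n_single}
#'   (genes that are their species' only member in their family, plus
#'   unclustered genes are counted separately), \code{n_multi} (genes
#'   whose family holds >= 2 members of that species) and
#'   \code{n_unclustered}.
#' @export
summarize_families <- function(families, proteome) {
  species_levels <- sort(unique(proteome$species))
  gene_species <- stats::setNames(proteome$species, proteome$gene_id)
  member_df <- data.frame(
    family = rep(names(families), lengths(families)),
    gene = unlist(families, use.names = FALSE), stringsAsFactors = FALSE)
  miss <- setdiff(member_df$gene, names(gene_species))
  if (length(miss) > 0L) {
    stop("clustered gene(s) absent from proteome: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  member_df$species <- unname(gene_species[member_df$gene])
  mat <- table(factor(member_df$family, levels = names(families)),
               factor(member_df$species, levels = species_levels))
  mat <- matrix(as.integer(mat), nrow = nrow(mat), dimnames = dimnames(mat))
  copies <- mat[cbind(match(member_df$family, rownames(mat)),
                      match(member_df$species, colnames(mat)))]
  member_df$multi <- copies >= 2L
  n_multi <- tapply(member_df$multi,
                    factor(member_df$species, levels = species_levels), sum)
  n_multi[is.na(n_multi)] <- 0L
  clustered <- table(factor(member_df$species, levels = species_levels))
  total <- table(factor(proteome$species, levels = species_levels))
  n_unclustered <- as.integer(total) - as.integer(clustered)
  summary <- data.frame(
    species = species_levels,
    n_single = as.integer(clustered) - as.integer(n_multi),
    n_multi = as.integer(n_multi),
    n_unclustered = n_unclustered, stringsAsFactors = FALSE)
  list(matrix = mat, summary = summary)
}

#' Families restricted to a species group
#'
#' @param matrix family x species copy-count matrix.
#' @param group character vector of species (column names).
#' @return character vector of family ids with at least one member inside
#'   the group and none outside it.
#' @export
group_specific_families <- function(matrix, group) {
  miss <- setdiff(group, colnames(matrix))
  if (length(miss) > 0L) stop("unknown species: ", paste(miss, collapse = ", "))
  inside <- rowSums(matrix[, group, drop = FALSE])
  outside <- rowSums(matrix[, setdiff(colnames(matrix), group), drop = FALSE])
  rownames(matrix)[inside > 0 & outside == 0]
}

#' Divergence-normalised lineage-specific accumulation rate
#'
#' The number of group-specific genes (or families) divided by the group's
#' crown plus stem age: the length of the branch subtending the group's
#' most recent common ancestor plus the maximum root-ward depth of the
#' group below that ancestor.  For a single-species group the crown age
#' is 0 and the stem is the terminal branch.
#'
#' @param count number of group-specific genes (or families).
#' @param tree rooted \code{phylo} timetree.
#' @param group character vector of tip labels; must be monophyletic.
#' @return rate per relative-time unit.
#' @export
lineage_specific_rate <- function(count, tree, group) {
  miss <- setdiff(group, tree$tip.label)
  if (length(miss) > 0L) stop("species not in tree: ", paste(miss, collapse = ", "))
  ages <- crown_stem_age(tree, group)
  denom <- ages$stem + ages$crown
  if (denom <= 0) stop("crown plus stem age is zero for this group")
  count / denom
}

#' Crown and stem age of a monophyletic group
#'
#' @param tree rooted \code{phylo} timetree.
#' @param group character vector of tip labels.
#' @return list with \code{stem} (length of the branch subtending the
#'   group MRCA; errors if the MRCA is the root) and \code{crown} (maximum
#'   depth from the MRCA to a group tip; 0 for a single tip).
#' @export
crown_stem_age <- function(tree, group) {
  tips <- match(group, tree$tip.label)
  if (length(tips) == 1L) {
    mrca <- tips
  } else {
    if (!ape::is.monophyletic(tree, group)) {
      stop("group is not monophyletic in the tree")
    }
    mrca <- ape::getMRCA(tree, group)
  }
  edge_to <- which(tree$edge[, 2L] == mrca)
  if (length(edge_to) == 0L) stop("group MRCA is the root; stem age undefined")
  stem <- tree$edge.length[edge_to]
  depths <- ape::node.depth.edgelength(tree)   # distance from root
  crown <- if (length(tips) == 1L) 0 else max(depths[tips]) - depths[mrca]
  list(stem = stem, crown = crown)
}
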