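# Shared builders for small in-code fixtures.

# a well-formed 12-column hit row
make_hit <- function(q, s, pident = 90, len = 100, evalue = 1e-20,
                     bitscore = 200, qlen = len, slen = len) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = as.integer(len),
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = as.integer(qlen),
             sstart = 1L, send = as.integer(slen), evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

make_hits <- function(...) do.call(rbind, list(...))

write_fasta <- function(ids, seqs, path) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# brute-force global affine-gap alignment score by exhaustive enumeration
# of alignments (gap of length L costs open + L * ext), independent of the
# package's aligner
brute_force_align_score <- function(a, b, submat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + submat[ca[i], cb[j]], "M")
    }
    if (i <= length(ca)) {
      pen <- ext + if (prev == "I") 0 else open
      rec(i + 1, j, score - pen, "I")
    }
    if (j <= length(cb)) {
      pen <- ext + if (prev == "D") 0 else open
      rec(i, j + 1, score - pen, "D")
    }
  }
  rec(1, 1, 0, "start")
  best
}

# literal MCL recurrence on a dense matrix, no pruning: an independent
# oracle for the clustering
dense_mcl_oracle <- function(adj, inflation, max_iter = 200) {
  loop <- apply(adj, 2, max); loop[loop == 0] <- 1
  diag(adj) <- loop
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-12) { M <- M2; break }
    M <- M2
  }
  supp <- (M > 1e-6) | t(M > 1e-6)
  diag(supp) <- TRUE
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cid <- cid + 1
    stack <- s
    while (length(stack) > 0) {
      v <- stack[[1]]; stack <- stack[-1]
      comp[v] <- cid
      nb <- which(supp[v, ] & comp == 0)
      comp[nb] <- -1  # mark queued
      stack <- c(stack, nb)
    }
  }
  split(rownames(adj), comp)
}

# canonical form of a clustering for comparison
canon_clusters <- function(fams) {
  x <- lapply(fams, function(f) sort(unname(f)))
  x <- x[order(vapply(x, `[[`, character(1), 1))]
  unname(x)
}

# independent NG86 pathway enumeration for a single codon pair
oracle_pathway_counts <- function(ca, cb, code) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(0, 0))
  perms <- if (k == 1) matrix(pos, 1) else {
    do.call(rbind, lapply(seq_len(k), function(i) {
      sub <- Recall_perm(pos[-i])
      cbind(pos[i], sub)
    }))
  }
  syn <- 0; nonsyn <- 0; nvalid <- 0
  for (p in seq_len(nrow(perms))) {
    cur <- ca; s <- 0; n <- 0; ok <- TRUE
    for (q in perms[p, ]) {
      nxt <- cur
      substr(nxt, q, q) <- substr(cb, q, q)
      if (code[nxt] == "*") { ok <- FALSE; break }
      if (code[nxt] == code[cur]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { syn <- syn + s; nonsyn <- nonsyn + n; nvalid <- nvalid + 1 }
  }
  if (nvalid == 0) return(c(k / 2, k / 2))
  c(syn / nvalid, nonsyn / nvalid)
}

Recall_perm <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  do.call(rbind, lapply(seq_along(x), function(i) cbind(x[i], Recall_perm(x[-i]))))
}

# standard genetic code table for oracles (built from Biostrings, an
# independent source from the package's internal table)
std_code <- local({
  nts <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cods),
                                           no.init.codon = TRUE))
  stats::setNames(aa, cods)
})
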