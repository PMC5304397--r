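# Tandem gene arrays from gene positions plus family membership.

#' Call tandem gene arrays
#'
#' Genes of the same family on the same scaffold are joined into one array
#' when separated by at most \code{max_intervening} genes of other
#' families in scaffold order (transitive closure); arrays need at least
#' two members.  Strand is ignored, since tandem duplicates frequently
#' invert.  Each gene belongs to at most one array.
#'
#' @param positions data.frame from \code{\link{read_positions}}.
#' @param families named list of gene-id vectors.
#' @param max_intervening maximum number of intervening other-family
#'   genes, default 1 (the usual tandem convention).
#' @return data.frame with one row per tandem gene: \code{array_id},
#'   \code{family_id}, \code{scaffold}, \code{gene_id}, \code{start},
#'   \code{end}; plus attribute \code{spans}, a per-array data.frame with
#'   \code{array_id}, \code{family_id}, \code{scaffold}, \code{n_genes},
#'   \code{span} (bp from first start to last end).
#' @export
call_tandem_arrays <- function(positions, families, max_intervening = 1L) {
  fam_of <- stats::setNames(rep(names(families), lengths(families)),
                            unlist(families, use.names = FALSE))
  pos <- positions[order(positions$scaffold, positions$start,
                         positions$gene_id), , drop = FALSE]
  pos$family <- unname(fam_of[pos$gene_id])
  out <- list()
  for (scf in unique(pos$scaffold)) {
    p <- pos[pos$scaffold == scf, , drop = FALSE]
    p$rank <- seq_len(nrow(p))
    for (fam in unique(p$family)) {
      if (is.na(fam)) next
      q <- p[!is.na(p$family) & p$family == fam, , drop = FALSE]
      if (nrow(q) < 2L) next
      gap <- diff(q$rank)
      grp <- cumsum(c(1L, as.integer(gap > max_intervening + 1L)))
      for (g in split(seq_len(nrow(q)), grp)) {
        if (length(g) < 2L) next
        out[[length(out) + 1L]] <- data.frame(
          family_id = fam, scaffold = scf,
          gene_id = q$gene_id[g], start = q$start[g], end = q$end[g],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(array_id = character(), family_id = character(),
                      scaffold = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    attr(res, "spans") <- data.frame(array_id = character(),
                                     family_id = character(),
                                     scaffold = character(),
                                     n_genes = integer(), span = integer())
    return(res)
  }
  # deterministic array order: scaffold, then first start
  ord <- order(vapply(out, function(x) x$scaffold[1L], character(1L)),
               vapply(out, function(x) min(x$start), integer(1L)))
  out <- out[ord]
  res <- do.call(rbind, lapply(seq_along(out), function(i) {
    cbind(array_id = sprintf("arr%04d", i), out[[i]],
          stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  spans <- do.call(rbind, lapply(seq_along(out), function(i) {
    data.frame(array_id = sprintf("arr%04d", i),
               family_id = out[[i]]$family_id[1L],
               scaffold = out[[i]]$scaffold[1L],
               n_genes = nrow(out[[i]]),
               span = max(out[[i]]$end) - min(out[[i]]$start) + 1L,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(res$gene_id)) stop("internal error: gene in two arrays")
  attr(res, "spans") <- spans
  res
}
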