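# The differential-expression filter chain and qPCR quantification:
# expression-quantile pre-filter, a simple two-condition negative-binomial
# test, Benjamini-Hochberg FDR, fold-change call and 2^-deltaCt.
#
# The count test here is intentionally simple (method-of-moments
# dispersion, Wald test on the log difference of normalised condition
# means); externally computed (p, fold-change) tables can be supplied to
# de_call() so the filter chain also runs on output of a full NB
# regression framework.

#' Remove lowly expressed genes by mean-count quantile
#'
#' Genes are ranked by mean count across all samples and the lowest
#' \code{fraction} dropped (\code{floor(n * fraction)} genes); ties break
#' by gene id so the filter is deterministic.
#'
#' @param matrix genes x samples count matrix with rownames.
#' @param fraction quantile to drop, default 0.40.
#' @return character vector of retained gene ids.
#' @export
quantile_filter <- function(matrix, fraction = 0.40) {
  if (is.null(rownames(matrix))) stop("count matrix must have gene rownames")
  n_drop <- floor(nrow(matrix) * fraction)
  m <- rowMeans(matrix)
  ord <- order(m, rownames(matrix))
  sort(rownames(matrix)[ord][seq_len(nrow(matrix) - n_drop) + n_drop])
}

#' Median-of-ratios size factors
#'
#' @param matrix genes x samples count matrix.
#' @return numeric vector of per-sample size factors (median ratio to the
#'   per-gene geometric mean, over genes expressed in every sample).
#' @export
size_factors <- function(matrix) {
  keep <- rowSums(matrix == 0) == 0L
  if (!any(keep)) stop("no gene expressed in every sample; cannot normalise")
  loggeo <- rowMeans(log(matrix[keep, , drop = FALSE]))
  apply(matrix[keep, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - loggeo))
  })
}

#' Simple negative-binomial two-condition test
#'
#' Counts are normalised by median-of-ratios size factors; a common-scale
#' NB dispersion is estimated by method of moments (per-gene moment
#' estimates from the pooled within-condition variance, combined by their
#' median across genes), and a Wald test (t reference with \code{n - 2}
#' df) is applied to the difference of log normalised condition means
#' under the variance function \code{V(m) = m + phi m^2}.  Fold changes are computed on the
#' normalised means with a pseudocount of 0.5.
#'
#' @param matrix genes x samples count matrix (rownames = genes).
#' @param condition factor or character vector of length
#'   \code{ncol(matrix)} with exactly 2 levels, >= 2 replicates each.
#' @return data.frame with columns \code{gene}, \code{log2FC} (second
#'   level over first), \code{p}.
#' @export
nb_mm_test <- function(matrix, condition) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly 2 conditions required")
  if (any(table(condition) < 2L)) stop("at least 2 replicates per condition required")
  if (length(condition) != ncol(matrix)) stop("condition length must match samples")
  sf <- size_factors(matrix)
  norm <- sweep(matrix, 2L, sf, "/")
  ia <- which(condition == levels(condition)[1L])
  ib <- which(condition == levels(condition)[2L])
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  va <- apply(norm[, ia, drop = FALSE], 1L, stats::var)
  vb <- apply(norm[, ib, drop = FALSE], 1L, stats::var)
  pooled_var <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  grand <- (na * ma + nb * mb) / (na + nb)
  phi_g <- (pooled_var - grand) / grand^2
  phi_g <- phi_g[is.finite(phi_g) & grand > 1]
  phi <- max(0, stats::median(phi_g))
  var_ma <- (ma + phi * ma^2) / na
  var_mb <- (mb + phi * mb^2) / nb
  l2fc <- log2((mb + 0.5) / (ma + 0.5))
  se <- sqrt(var_ma / (ma + 0.5)^2 + var_mb / (mb + 0.5)^2)
  zstat <- (log(mb + 0.5) - log(ma + 0.5)) / se
  zstat[se == 0] <- 0
  # t reference with n - 2 df: small-sample guard against the mild
  # anticonservativeness of the plain Wald z at 2-3 replicates
  p <- 2 * stats::pt(-abs(zstat), df = na + nb - 2)
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  data.frame(gene = rownames(matrix), log2FC = unname(l2fc), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param pvals numeric vector of raw p-values.
#' @param alpha FDR level for the reject flags, default 0.10.
#' @return data.frame with \code{p}, \code{q} (BH-adjusted) and
#'   \code{reject} (\code{q <= alpha}).
#' @export
bh_fdr <- function(pvals, alpha = 0.10) {
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, reject = q <= alpha)
}

#' Differential-expression call
#'
#' A gene is differentially expressed when its BH-adjusted q-value is at
#' most \code{fdr} and its linear fold change at least \code{min_fc}
#' (\code{|log2FC| >= log2(min_fc)}).
#'
#' @param results data.frame with columns \code{gene}, \code{log2FC},
#'   \code{p} (e.g. from \code{\link{nb_mm_test}} or an external NB fit).
#' @param min_fc minimum linear fold change, default 1.5.
#' @param fdr FDR level, default 0.10.
#' @return \code{results} with columns \code{q} and \code{is_de}
#'   appended.
#' @export
de_call <- function(results, min_fc = 1.5, fdr = 0.10) {
  need <- c("gene", "log2FC", "p")
  if (!all(need %in% names(results))) {
    stop("results must have columns: ", paste(need, collapse = ", "))
  }
  results$q <- stats::p.adjust(results$p, method = "BH")
  results$is_de <- results$q <= fdr & abs(results$log2FC) >= log2(min_fc)
  results
}

#' Run the full DE filter chain
#'
#' Quantile pre-filter, NB test, BH FDR and fold-change call in one step.
#'
#' @param matrix genes x samples count matrix.
#' @param condition 2-level condition vector.
#' @param quantile fraction of lowly expressed genes to drop, default
#'   0.40.
#' @param min_fc,fdr passed to \code{\link{de_call}}.
#' @return the \code{\link{de_call}} result for the retained genes.
#' @export
run_de_pipeline <- function(matrix, condition, quantile = 0.40,
                            min_fc = 1.5, fdr = 0.10) {
  keep <- quantile_filter(matrix, quantile)
  de_call(nb_mm_test(matrix[keep, , drop = FALSE], condition),
          min_fc = min_fc, fdr = fdr)
}

#' Relative expression by the comparative 2^-deltaCt method
#'
#' @param ct_target cycle-threshold value(s) of the target gene.
#' @param ct_reference cycle-threshold value(s) of the reference
#'   (normaliser) gene from the same sample.
#' @return relative expression \code{2^-(ct_target - ct_reference)}.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  2^(-(ct_target - ct_reference))
}
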