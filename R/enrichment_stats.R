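# The enrichment-statistics battery: 2x2 Pearson chi-square, Mann-Whitney
# U, and the harness linking differentially expressed genes to gene
# categories.  Statistics are computed from first principles (no
# continuity correction by default, matching the convention needed to
# reproduce printed genome-scale comparisons).

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Statistic \eqn{N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]} with 1 degree of
#' freedom; Yates continuity correction available but off by default.
#'
#' @param a,b,c,d non-negative integer cell counts (rows = groups,
#'   columns = trait present/absent).  Alternatively \code{a} may be a
#'   2x2 matrix.
#' @param continuity apply the Yates correction, default FALSE.
#' @return object of class \code{test_result}: list with
#'   \code{statistic}, \code{df}, \code{p}, \code{method}.
#' @export
chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL, continuity = FALSE) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop("table must be 2x2")
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be >= 0")
  n <- sum(cells)
  if (n == 0) stop("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("zero marginal: chi-square test undefined")
  num <- abs(a * d - b * c)
  if (continuity) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(marg)
  structure(list(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 method = if (continuity) "Pearson chi-square (Yates)" else
                   "Pearson chi-square"),
            class = "test_result")
}

#' Mann-Whitney U test
#'
#' Two-tailed rank-sum test.  The reported U is the count of (x, y) pairs
#' with x > y (ties counted half).  Without ties and with
#' \code{min(n) <= 8} the exact null distribution is used; otherwise the
#' normal approximation with tie correction and 0.5 continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param exact force (TRUE) or suppress (FALSE) the exact computation;
#'   default NULL chooses automatically.
#' @return a \code{test_result} (statistic = U, \code{df} = NA).
#' @export
mannwhitney_u <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0L
  if (is.null(exact)) exact <- !has_ties && min(n1, n2) <= 8L
  if (exact && has_ties) {
    warning("exact Mann-Whitney p not available with ties; using normal approximation")
    exact <- FALSE
  }
  if (exact) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
    method <- "Mann-Whitney U (exact)"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(all_v)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  structure(list(statistic = U, df = NA_integer_, p = p, method = method),
            class = "test_result")
}

#' Enrichment of gene categories among differentially expressed genes
#'
#' For each category, builds the 2x2 table DE vs non-DE by in-category vs
#' not and applies the chi-square test.  The default \code{"de_vs_rest"}
#' convention excludes DE genes from the genome row:
#' a = |DE & cat|, b = |DE - cat|, c = |cat - DE|,
#' d = |genome - (DE | cat)|.  The \code{"overlap"} variant uses the raw
#' genome-wide fractions (c = |cat|, d = |genome - cat|) for sensitivity
#' analysis.
#'
#' @param de_genes character vector of differentially expressed gene ids.
#' @param category_members named list of gene-id vectors, one per
#'   category.
#' @param genome_genes character vector: the full gene universe.
#' @param convention \code{"de_vs_rest"} (default) or \code{"overlap"}.
#' @param continuity passed to \code{\link{chi2_2x2}}.
#' @return data.frame with one row per category: cell counts \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{chi2}, \code{df}, \code{p}.
#' @export
de_enrichment <- function(de_genes, category_members, genome_genes,
                          convention = c("de_vs_rest", "overlap"),
                          continuity = FALSE) {
  convention <- match.arg(convention)
  if (!all(de_genes %in% genome_genes)) stop("DE genes outside the genome universe")
  de_genes <- unique(de_genes)
  rows <- lapply(names(category_members), function(nm) {
    cat_genes <- unique(category_members[[nm]])
    if (!all(cat_genes %in% genome_genes)) {
      stop("category '", nm, "' has genes outside the genome universe")
    }
    a <- length(intersect(de_genes, cat_genes))
    b <- length(de_genes) - a
    if (convention == "de_vs_rest") {
      cc <- length(setdiff(cat_genes, de_genes))
      dd <- length(genome_genes) - length(union(de_genes, cat_genes))
    } else {
      cc <- length(cat_genes)
      dd <- length(genome_genes) - length(cat_genes)
    }
    tst <- chi2_2x2(a, b, cc, dd, continuity = continuity)
    data.frame(category = nm, a = a, b = b, c = cc, d = dd,
               chi2 = tst$statistic, df = tst$df, p = tst$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g\n", x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %d", x$df), x$p))
  invisible(x)
}
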