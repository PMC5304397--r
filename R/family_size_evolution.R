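# Birth-death modelling of gene family size on a species timetree:
# transition probabilities (lambda = mu linear birth-death, Bailey closed
# form), pruning likelihood over size states, maximum-likelihood rate
# fitting with nested-model likelihood-ratio tests, max-product ancestral
# size reconstruction, and per-taxon divergence-time normalisation.

#' Fitch-parsimony root-presence filter
#'
#' Families not inferred present in the last common ancestor of all taxa
#' (by Fitch small parsimony on presence/absence) violate the birth-death
#' model's root assumption and are removed.  A root tie (both states
#' optimal) counts as present, conservatively retaining borderline
#' families.
#'
#' @param matrix family x species copy-count matrix (columns = tip
#'   labels).
#' @param tree rooted \code{phylo}; tip labels must cover the columns.
#' @return character vector of retained family ids.
#' @export
parsimony_root_presence <- function(matrix, tree) {
  miss <- setdiff(colnames(matrix), tree$tip.label)
  if (length(miss) > 0L) stop("species not in tree: ", paste(miss, collapse = ", "))
  tr <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  nf <- nrow(matrix)
  # per node: can the state-set contain present / absent
  canP <- base::matrix(FALSE, nnode, nf)
  canA <- base::matrix(FALSE, nnode, nf)
  done <- logical(nnode)
  pres <- t(matrix[, tr$tip.label, drop = FALSE] > 0)   # tips x families
  canP[seq_len(ntip), ] <- pres
  canA[seq_len(ntip), ] <- !pres
  done[seq_len(ntip)] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    if (!done[p]) {       # first child: copy
      canP[p, ] <- canP[ch, ]
      canA[p, ] <- canA[ch, ]
      done[p] <- TRUE
    } else {              # fold in further children pairwise (Fitch)
      interP <- canP[p, ] & canP[ch, ]
      interA <- canA[p, ] & canA[ch, ]
      nonempty <- interP | interA
      canP[p, ] <- ifelse(nonempty, interP, canP[p, ] | canP[ch, ])
      canA[p, ] <- ifelse(nonempty, interA, canA[p, ] | canA[ch, ])
    }
  }
  root <- ntip + 1L
  rownames(matrix)[canP[root, ]]
}

#' Copy-number range filter
#'
#' Families whose copy number varies between species by more than
#' \code{max_range} genes cause numerical trouble in the likelihood and
#' are excluded; a range exactly at the bound is kept.
#'
#' @param matrix family x species copy-count matrix.
#' @param max_range maximum allowed \code{max - min}, default 200.
#' @return character vector of retained family ids.
#' @export
filter_copy_range <- function(matrix, max_range = 200) {
  rng <- apply(matrix, 1L, function(x) max(x) - min(x))
  rownames(matrix)[rng <= max_range]
}

#' Birth-death family-size transition probability
#'
#' Probability that a family of size \code{s} at the top of a branch of
#' length \code{t} has size \code{c} at the bottom, under a linear
#' birth-death process with equal per-gene gain and loss rate
#' \code{lambda}.  With \code{a = lambda t / (1 + lambda t)}:
#' \deqn{P(c|s,t) = \sum_{j=0}^{\min(s,c)} \binom{s}{j}
#'   \binom{s+c-j-1}{s-1} a^{s+c-2j} (1-2a)^j}
#' and \eqn{P(0|s,t) = a^s}; size 0 is absorbing.
#'
#' @param s parent size (scalar, >= 0).
#' @param c child size(s), vectorised.
#' @param t branch length (> 0; \code{t = 0} gives the identity).
#' @param lambda per-gene gain/loss rate (>= 0).
#' @return numeric vector of probabilities.
#' @export
bd_transition_prob <- function(s, c, t, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (s < 0 || any(c < 0)) stop("sizes must be >= 0")
  if (lambda == 0 || t == 0) return(as.numeric(c == s))
  if (s == 0) return(as.numeric(c == 0))
  a <- lambda * t / (1 + lambda * t)
  vapply(c, function(ci) {
    if (ci == 0) return(a^s)
    j <- 0:min(s, ci)
    terms <- exp(lchoose(s, j) + lchoose(s + ci - j - 1, s - 1) +
                   (s + ci - 2 * j) * log(a)) * (1 - 2 * a)^j
    max(0, sum(terms))
  }, numeric(1L))
}

# (S_max+1) x (S_max+1) transition matrix, rows = parent size 0..S_max.
# Same closed form as bd_transition_prob.  The combinatorial part of the
# summand does not depend on lambda or t, so the (s, c, j) index grid and
# log binomial coefficients are cached per state-space size; each call is
# then a single vectorised exponential plus a grouped sum.
.bd_tm_grid <- function(s_max) {
  key <- paste0("bdgrid", s_max)
  if (!is.null(.dupdyn_cache[[key]])) return(.dupdyn_cache[[key]])
  S1 <- s_max + 1L
  ss <- integer(0); cc <- integer(0); jj <- integer(0)
  for (s in seq_len(s_max)) {
    for (cv in seq_len(s_max)) {
      j <- 0:min(s, cv)
      ss <- c(ss, rep.int(s, length(j)))
      cc <- c(cc, rep.int(cv, length(j)))
      jj <- c(jj, j)
    }
  }
  grid <- list(
    lchoose_part = lchoose(ss, jj) + lchoose(ss + cc - jj - 1, ss - 1),
    apow = ss + cc - 2 * jj,
    j = jj,
    cell = ss + 1L + cc * S1)      # linear index of [s+1, c+1]
  .dupdyn_cache[[key]] <- grid
  grid
}

.bd_transition_matrix <- function(s_max, t, lambda) {
  S1 <- s_max + 1L
  P <- base::matrix(0, S1, S1)
  P[1L, 1L] <- 1
  if (lambda == 0 || t == 0) { diag(P) <- 1; return(P) }
  a <- lambda * t / (1 + lambda * t)
  g <- .bd_tm_grid(s_max)
  term <- exp(g$lchoose_part + g$apow * log(a)) * (1 - 2 * a)^g$j
  acc <- rowsum(term, g$cell)
  P[as.integer(rownames(acc))] <- pmax(0, acc)
  P[1L + seq_len(s_max)] <- a^seq_len(s_max)   # column c = 0
  P
}

#' Build a branch partition for rate classes
#'
#' Assigns every branch of the tree a rate-class label.  A branch belongs
#' to the first clade (in list order) whose tip set contains all tips
#' descending from the branch; remaining branches get the
#' \code{"background"} class.  The stem branch of each clade is included
#' in its class.
#'
#' @param tree rooted \code{phylo}.
#' @param clades named list of tip-label vectors (may be empty for a
#'   single global class).
#' @return named character vector: class label per branch, named by the
#'   branch's child node id.
#' @export
edge_partition <- function(tree, clades = list()) {
  ntip <- ape::Ntip(tree)
  tipsets <- .tips_below(tree)
  labels <- vapply(seq_len(nrow(tree$edge)), function(e) {
    below <- tree$tip.label[tipsets[[tree$edge[e, 2L]]]]
    for (nm in names(clades)) {
      if (all(below %in% clades[[nm]])) return(nm)
    }
    "background"
  }, character(1L))
  stats::setNames(labels, as.character(tree$edge[, 2L]))
}

.tips_below <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tr)
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Construct a birth-death model object
#'
#' @param partition named character vector from
#'   \code{\link{edge_partition}} (class per branch, named by child node
#'   id).
#' @param lambda named numeric vector of per-class rates (>= 0, finite).
#' @return object of class \code{bd_model}.
#' @export
bd_model <- function(partition, lambda) {
  if (!all(unique(partition) %in% names(lambda))) {
    stop("lambda missing for class(es): ",
         paste(setdiff(unique(partition), names(lambda)), collapse = ", "))
  }
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("lambda must be finite and >= 0")
  }
  structure(list(partition = partition, lambda = lambda), class = "bd_model")
}

# lambda per edge of `tree` (original edge order), from a bd_model
.lambda_by_edge <- function(tree, model) {
  cls <- model$partition[as.character(tree$edge[, 2L])]
  if (anyNA(cls)) stop("model partition does not cover every branch")
  unname(model$lambda[cls])
}

# Pruning log-likelihoods for all families at once.
# counts: families x tips matrix; returns numeric vector per family.
.bd_loglik_all <- function(counts, tree, model, s_max = NULL, root_max = NULL) {
  tr <- stats::reorder(tree, "postorder")
  lam <- .lambda_by_edge(tr, model)
  .bd_loglik_core(counts, tr, lam, s_max, root_max)
}

# core pruning over a postorder tree with per-edge rates
.bd_loglik_core <- function(counts, tr, lam, s_max = NULL, root_max = NULL) {
  if (any(rowSums(counts) == 0)) {
    stop("family with all-zero counts: run parsimony_root_presence() first")
  }
  maxobs <- max(counts)
  if (is.null(s_max)) s_max <- maxobs + max(10L, ceiling(maxobs / 2))
  if (is.null(root_max)) root_max <- max(1L, maxobs)
  if (any(counts > s_max)) stop("s_max smaller than an observed count")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  nf <- nrow(counts)
  S <- s_max + 1L
  tipc <- t(counts[, tr$tip.label, drop = FALSE])   # tips x fams
  partial <- vector("list", nnode)
  logscale <- rep(0, nf)
  for (i in seq_len(ntip)) {
    m <- matrix(0, S, nf)
    m[cbind(tipc[i, ] + 1L, seq_len(nf))] <- 1
    partial[[i]] <- m
  }
  tmat_cache <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    key <- paste0(format(lam[e], digits = 17), "_", format(tr$edge.length[e], digits = 17))
    Tm <- tmat_cache[[key]]
    if (is.null(Tm)) {
      Tm <- .bd_transition_matrix(s_max, tr$edge.length[e], lam[e])
      tmat_cache[[key]] <- Tm
    }
    msg <- Tm %*% partial[[ch]]
    sc <- colSums(msg)
    sc[sc == 0] <- 1        # impossible family under this lambda: logL -> -Inf
    msg <- sweep(msg, 2L, sc, "/")
    logscale <- logscale + log(sc)
    partial[[p]] <- if (is.null(partial[[p]])) msg else partial[[p]] * msg
  }
  root <- partial[[ntip + 1L]]
  lik <- colMeans(root[seq_len(root_max) + 1L, , drop = FALSE])
  log(lik) + logscale
}

#' Birth-death log-likelihood of one gene family
#'
#' Felsenstein-style pruning over size states 0..\code{s_max}; the root
#' likelihood is the mean over root sizes 1..\code{root_max} (uniform
#' prior conditioning on presence at the root).
#'
#' @param family_counts named integer vector (names = tip labels).
#' @param tree rooted \code{phylo} timetree.
#' @param model a \code{\link{bd_model}}.
#' @param s_max size-state cap; default max observed + buffer.
#' @param root_max largest root size in the prior; default max observed.
#' @return log-likelihood (scalar).
#' @export
family_loglik <- function(family_counts, tree, model, s_max = NULL,
                          root_max = NULL) {
  counts <- matrix(family_counts, nrow = 1L,
                   dimnames = list("fam", names(family_counts)))
  .bd_loglik_all(counts, tree, model, s_max, root_max)[[1L]]
}

#' Maximum-likelihood birth-death rate fitting
#'
#' Fits one lambda per rate class by maximising the summed pruning
#' log-likelihood over all families.  A single class is optimised by
#' golden-section search on log(lambda); multiple classes by Nelder-Mead
#' from a deterministic grid of starts around the single-rate optimum.
#'
#' @param matrix family x species copy-count matrix (pre-filtered with
#'   \code{\link{parsimony_root_presence}} and
#'   \code{\link{filter_copy_range}}).
#' @param tree rooted \code{phylo} timetree.
#' @param partition branch partition from \code{\link{edge_partition}};
#'   default a single global class.
#' @param s_max,root_max passed to the likelihood; defaults as there.
#' @param lambda_bounds search range for each lambda.
#' @return object of class \code{bd_fit}: list with \code{model}
#'   (\code{bd_model}), \code{logL}, \code{n_params}, \code{per_family}
#'   (per-family log-likelihoods at the optimum) and \code{convergence}.
#' @export
fit_lambda <- function(matrix, tree, partition = NULL, s_max = NULL,
                       root_max = NULL, lambda_bounds = NULL) {
  if (is.null(partition)) partition <- edge_partition(tree)
  classes <- sort(unique(partition))
  if (is.null(lambda_bounds)) {
    tbar <- mean(tree$edge.length)
    lambda_bounds <- c(1e-9 / tbar, 20 / tbar)
  }
  lb <- log(lambda_bounds)
  tr <- stats::reorder(tree, "postorder")
  cls_edge <- partition[as.character(tr$edge[, 2L])]
  if (anyNA(cls_edge)) stop("partition does not cover every branch")
  cls_idx <- match(cls_edge, classes)
  obj <- function(loglam) {
    lam <- exp(pmin(pmax(loglam, lb[1L]), lb[2L]))
    -sum(.bd_loglik_core(matrix, tr, lam[cls_idx], s_max, root_max))
  }
  single <- stats::optimize(function(x) obj(rep(x, length(classes))),
                            interval = lb, tol = 1e-4)
  best_par <- rep(single$minimum, length(classes))
  best_val <- single$objective
  convergence <- 0L
  if (length(classes) > 1L) {
    for (off in c(0, log(3))) {
      o <- stats::optim(rep(single$minimum + off, length(classes)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 600L, reltol = 1e-8))
      if (o$value < best_val) {
        best_val <- o$value
        best_par <- o$par
        convergence <- o$convergence
      }
    }
  }
  lam <- stats::setNames(exp(pmin(pmax(best_par, lb[1L]), lb[2L])), classes)
  model <- bd_model(partition, lam)
  perfam <- .bd_loglik_all(matrix, tree, model, s_max, root_max)
  structure(list(model = model, logL = sum(perfam),
                 n_params = length(classes),
                 per_family = stats::setNames(perfam, rownames(matrix)),
                 convergence = convergence),
            class = "bd_fit")
}

#' Likelihood-ratio test between nested birth-death models
#'
#' @param fit_simple,fit_complex \code{bd_fit} objects, the simpler model
#'   nested in the more complex one.
#' @return list with \code{statistic} (2 Delta logL, clamped at 0),
#'   \code{df} (parameter difference) and \code{p} (chi-square upper
#'   tail).
#' @export
lrt_nested <- function(fit_simple, fit_complex) {
  df <- fit_complex$n_params - fit_simple$n_params
  if (df <= 0L) stop("fit_complex must have more parameters than fit_simple")
  stat <- max(0, 2 * (fit_complex$logL - fit_simple$logL))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Maximum-likelihood ancestral family sizes
#'
#' Max-product (Viterbi-style) dynamic program over size states: the
#' jointly most probable assignment of sizes to internal nodes given the
#' tip counts and the fitted model.  Ties break to the smaller size.
#'
#' @param family_counts named integer vector (names = tip labels).
#' @param tree rooted \code{phylo} timetree.
#' @param model a \code{\link{bd_model}}.
#' @param s_max,root_max as in \code{\link{family_loglik}}.
#' @return list with \code{sizes} (integer vector indexed by node id; tips
#'   carry their observed counts), \code{changes} (data.frame per branch:
#'   \code{parent}, \code{child}, \code{change} = child - parent size) and
#'   counts \code{n_expansions}, \code{n_contractions}, \code{n_stable}.
#' @export
ancestral_sizes <- function(family_counts, tree, model, s_max = NULL,
                            root_max = NULL) {
  if (sum(family_counts) == 0) stop("family with all-zero counts")
  maxobs <- max(family_counts)
  if (is.null(s_max)) s_max <- maxobs + max(10L, ceiling(maxobs / 2))
  if (is.null(root_max)) root_max <- max(1L, maxobs)
  tr <- stats::reorder(tree, "postorder")
  lam <- .lambda_by_edge(tr, model)
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  S <- s_max + 1L
  V <- matrix(-Inf, nnode, S)       # log max-product partials
  tipc <- family_counts[tr$tip.label]
  for (i in seq_len(ntip)) V[i, tipc[i] + 1L] <- 0
  back <- vector("list", nrow(tr$edge))   # argmax child state per parent state
  internal_done <- logical(nnode)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2L]; p <- tr$edge[e, 1L]
    Tm <- .bd_transition_matrix(s_max, tr$edge.length[e], lam[e])
    score <- log(Tm) + matrix(V[ch, ], S, S, byrow = TRUE)  # [s_parent, s_child]
    score[is.nan(score)] <- -Inf
    bi <- max.col(score, ties.method = "first")
    back[[e]] <- bi
    contrib <- score[cbind(seq_len(S), bi)]
    if (!internal_done[p]) { V[p, ] <- contrib; internal_done[p] <- TRUE }
    else V[p, ] <- V[p, ] + contrib
  }
  root <- ntip + 1L
  rootstates <- seq_len(root_max) + 1L
  sizes <- integer(nnode)
  sizes[root] <- rootstates[which.max(V[root, rootstates])] - 1L
  for (e in rev(seq_len(nrow(tr$edge)))) {    # preorder = reverse postorder
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    sizes[ch] <- back[[e]][sizes[p] + 1L] - 1L
  }
  changes <- data.frame(parent = tr$edge[, 1L], child = tr$edge[, 2L],
                        change = sizes[tr$edge[, 2L]] - sizes[tr$edge[, 1L]])
  list(sizes = sizes, changes = changes,
       n_expansions = sum(changes$change > 0),
       n_contractions = sum(changes$change < 0),
       n_stable = sum(changes$change == 0))
}

#' Two-sided binomial test for asymmetric expansion
#'
#' Exact two-sided binomial test of \code{n_a} expansions against
#' \code{n_a + n_b} total at success probability 0.5: are expansions
#' split unevenly between two lineages?
#'
#' @param n_a,n_b expansion counts in the two lineages.
#' @return p-value.
#' @export
binomial_expansion_test <- function(n_a, n_b) {
  if (n_a < 0 || n_b < 0) stop("counts must be >= 0")
  if (n_a + n_b == 0) return(1)
  stats::binom.test(n_a, n_a + n_b, p = 0.5)$p.value
}

#' Normalise per-taxon expansion counts by divergence time
#'
#' Divides each taxon's count by its terminal branch length (the relative
#' divergence time from the taxon's MRCA with its sister), correcting
#' cross-taxon comparisons for unequal evolutionary time.
#'
#' @param per_taxon_counts named numeric vector (names = tip labels).
#' @param tree rooted \code{phylo} timetree.
#' @return named numeric vector of normalised counts.
#' @export
normalize_expansion <- function(per_taxon_counts, tree) {
  tips <- match(names(per_taxon_counts), tree$tip.label)
  if (anyNA(tips)) {
    stop("unknown taxa: ",
         paste(names(per_taxon_counts)[is.na(tips)], collapse = ", "))
  }
  bl <- tree$edge.length[match(tips, tree$edge[, 2L])]
  if (any(bl == 0)) {
    stop("zero terminal branch length for ",
         paste(names(per_taxon_counts)[bl == 0], collapse = ", "))
  }
  per_taxon_counts / bl
}
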