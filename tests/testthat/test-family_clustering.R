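test_that("hit filtering applies the strict E-value and coverage rules", {
  lens <- c(q = 100L, s = 80L)
  h <- make_hits(
    make_hit("q", "s", evalue = 1e-4, len = 90),    # evalue not < 1e-5
    make_hit("q", "s", evalue = 1e-20, len = 40),   # 40/100 < 0.5
    make_hit("q", "s", evalue = 1e-20, len = 60),   # keep: 60/100
    make_hit("q", "q", evalue = 0, len = 100))      # self-hit
  out <- filter_hits(h, lens)
  expect_equal(nrow(out), 1L)
  expect_equal(out$length, 60L)
  expect_error(filter_hits(make_hit("q", "x"), lens), "no length")
})

test_that("graph edges use capped -log10 E-value weights with reciprocal max-merge", {
  h <- make_hits(
    make_hit("A", "B", evalue = 1e-50),
    make_hit("B", "A", evalue = 1e-40),
    make_hit("A", "C", evalue = 0))
  g <- build_graph(h)
  expect_equal(g$edges$weight[g$edges$a == "A" & g$edges$b == "B"], 50)
  expect_equal(g$edges$weight[g$edges$a == "A" & g$edges$b == "C"], 200)
  expect_equal(nrow(g$edges), 2L)
})

test_that("MCL separates disconnected components and keeps isolated singletons", {
  tri <- function(p) make_hits(
    make_hit(paste0(p, 1), paste0(p, 2), evalue = 1e-30),
    make_hit(paste0(p, 1), paste0(p, 3), evalue = 1e-30),
    make_hit(paste0(p, 2), paste0(p, 3), evalue = 1e-30))
  g <- build_graph(rbind(tri("a"), tri("b")), nodes = "lonely")
  fams <- mcl_cluster(g)
  cc <- canon_clusters(fams)
  expect_equal(length(cc), 3L)
  expect_true(list(c("a1", "a2", "a3")) %in% cc)
  expect_true(list("lonely") %in% cc)
  # partition: disjoint and covering
  expect_setequal(unlist(fams), g$nodes)
  expect_equal(anyDuplicated(unlist(fams)), 0L)
})

test_that("MCL matches the dense literal-recurrence oracle on small graphs", {
  # 8-node barbell: two K4 blocks joined by one weak edge
  nodes <- c(paste0("x", 1:4), paste0("y", 1:4))
  adj <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (i in 1:4) for (j in 1:4) if (i < j) {
    adj[i, j] <- adj[j, i] <- 30
    adj[i + 4, j + 4] <- adj[j + 4, i + 4] <- 30
  }
  adj["x4", "y1"] <- adj["y1", "x4"] <- 2
  hits <- do.call(rbind, lapply(which(upper.tri(adj) & adj > 0), function(k) {
    ij <- arrayInd(k, dim(adj))
    make_hit(nodes[ij[1]], nodes[ij[2]], evalue = 10^(-adj[k]))
  }))
  fams <- mcl_cluster(build_graph(hits), inflation = 2.1)
  oracle <- dense_mcl_oracle(adj, inflation = 2.1)
  expect_equal(canon_clusters(fams), canon_clusters(oracle))
  expect_equal(length(fams), 2L)

  # random sparse graphs: package clustering equals the pruning-free oracle
  set.seed(42)
  for (rep in 1:5) {
    n <- 10
    nm <- paste0("g", 1:n)
    a <- matrix(0, n, n, dimnames = list(nm, nm))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.3) a[i, j] <- a[j, i] <- sample(5:60, 1)
    }
    if (all(a == 0)) next
    hh <- do.call(rbind, lapply(which(upper.tri(a) & a > 0), function(k) {
      ij <- arrayInd(k, dim(a))
      make_hit(nm[ij[1]], nm[ij[2]], evalue = 10^(-a[k]))
    }))
    fams <- mcl_cluster(build_graph(hh, nodes = nm), inflation = 2.1)
    oracle <- dense_mcl_oracle(a, inflation = 2.1)
    expect_equal(canon_clusters(fams), canon_clusters(oracle))
  }
})

test_that("clustering is invariant under node relabelling", {
  set.seed(7)
  nm <- paste0("n", 1:8)
  hits <- do.call(rbind, lapply(1:12, function(i) {
    p <- sample(nm, 2)
    make_hit(p[1], p[2], evalue = 10^(-sample(5:50, 1)))
  }))
  f1 <- mcl_cluster(build_graph(hits, nodes = nm))
  # relabel by permutation and shuffle row order
  perm <- setNames(paste0("z", sample(8)), nm)
  hits2 <- hits
  hits2$qseqid <- unname(perm[hits$qseqid])
  hits2$sseqid <- unname(perm[hits$sseqid])
  hits2 <- hits2[sample(nrow(hits2)), ]
  f2 <- mcl_cluster(build_graph(hits2, nodes = unname(perm)))
  relabelled <- canon_clusters(lapply(f1, function(m) unname(perm[m])))
  expect_equal(relabelled, canon_clusters(f2))
})

test_that("family summaries count single/multi-copy and unclustered genes", {
  fams <- list(f1 = c("A|g1", "A|g2", "B|g1"), f2 = c("B|g2"))
  proteome <- data.frame(
    gene_id = c("A|g1", "A|g2", "B|g1", "B|g2", "B|g3"),
    species = c("A", "A", "B", "B", "B"), stringsAsFactors = FALSE)
  s <- summarize_families(fams, proteome)
  expect_equal(s$matrix["f1", "A"], 2L)
  expect_equal(s$matrix["f1", "B"], 1L)
  sa <- s$summary[s$summary$species == "A", ]
  sb <- s$summary[s$summary$species == "B", ]
  expect_equal(sa$n_multi, 2L)        # both A genes share f1
  expect_equal(sa$n_single, 0L)
  expect_equal(sb$n_multi, 0L)
  expect_equal(sb$n_single, 2L)
  expect_equal(sb$n_unclustered, 1L)  # B|g3
})

test_that("recovered copy-number summary matches simulator ground truth", {
  world <- simulate_two_species_world(two_species_config(n_families = 15L), seed = 11)
  s <- summarize_families(world$true_families, world$proteins[, c("gene_id", "species")])
  truth <- world$families
  expect_equal(unname(s$matrix[truth$family, "Mper"]), truth$n_a)
  expect_equal(unname(s$matrix[truth$family, "Apis"]), truth$n_b)
  # genes in families with >= 2 same-species members are the multi-copy set
  for (sp in c("Mper", "Apis")) {
    col <- if (sp == "Mper") "n_a" else "n_b"
    expect_equal(s$summary$n_multi[s$summary$species == sp],
                 sum(truth[[col]][truth[[col]] >= 2]))
  }
})

test_that("group-specific families are exactly those confined to the group", {
  mat <- rbind(f1 = c(A = 2L, B = 1L, C = 0L),
               f2 = c(A = 3L, B = 0L, C = 0L),
               f3 = c(A = 0L, B = 0L, C = 4L),
               f4 = c(A = 1L, B = 1L, C = 1L))
  expect_equal(group_specific_families(mat, c("A", "B")), c("f1", "f2"))
  expect_equal(group_specific_families(mat, "A"), "f2")
  expect_equal(group_specific_families(mat, "C"), "f3")
  # family in all species specific to no proper group
  expect_false("f4" %in% group_specific_families(mat, c("A", "B")))
})

test_that("lineage-specific rates divide by crown plus stem age", {
  tr <- read_newick("((A:0.3,B:0.3):0.3,(C:0.4,D:0.4):0.2);")
  expect_equal(lineage_specific_rate(120, tr, c("A", "B")), 120 / 0.6)
  expect_equal(lineage_specific_rate(0, tr, c("C", "D")), 0)
  # single species: crown 0, stem = terminal branch
  expect_equal(lineage_specific_rate(10, tr, "A"), 10 / 0.3)
  expect_error(lineage_specific_rate(5, tr, c("A", "C")), "monophyletic")
})

.tips_below_oracle <- function(tr, node) {
  ntip <- ape::Ntip(tr)
  if (node <= ntip) return(node)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_below_oracle, tr = tr))
}

test_that("crown/stem ages agree with a brute-force path-sum oracle", {
  set.seed(3)
  for (rep in 1:5) {
    tr <- ape::rtree(10)
    tr$edge.length <- round(runif(nrow(tr$edge), 0.05, 1), 3)
    # brute-force depth of every node from the root via edge walks
    depth_of <- function(node) {
      d <- 0
      while (TRUE) {
        e <- which(tr$edge[, 2] == node)
        if (length(e) == 0) break
        d <- d + tr$edge.length[e]
        node <- tr$edge[e, 1]
      }
      d
    }
    node <- sample((ape::Ntip(tr) + 2):(ape::Ntip(tr) + tr$Nnode), 1)
    tips <- tr$tip.label[unlist(.tips_below_oracle(tr, node))]
    ages <- crown_stem_age(tr, tips)
    expect_equal(ages$stem, tr$edge.length[which(tr$edge[, 2] == node)])
    expect_equal(ages$crown,
                 max(vapply(match(tips, tr$tip.label), depth_of, numeric(1))) -
                   depth_of(node))
  }
})
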