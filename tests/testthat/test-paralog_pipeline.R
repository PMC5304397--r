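test_that("nearest-paralog selection follows best-hit and dedup rules", {
  h <- make_hits(
    make_hit("g1", "g2", bitscore = 300, len = 200, pident = 60),
    make_hit("g2", "g1", bitscore = 300, len = 200, pident = 60),  # reciprocal
    make_hit("g3", "g1", bitscore = 100, len = 200, pident = 40),
    make_hit("g3", "g3", bitscore = 999, len = 200, pident = 100), # self
    make_hit("g4", "g1", bitscore = 90, len = 100, pident = 60),   # aln < 150
    make_hit("g5", "g1", bitscore = 90, len = 200, pident = 20))   # ident < 30
  p <- nearest_paralogs(h)
  expect_equal(p, data.frame(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"),
                             stringsAsFactors = FALSE))
  # chain case: A's best is B, B's best is C -> both pairs kept
  h2 <- make_hits(
    make_hit("A", "B", bitscore = 200, len = 200, pident = 50),
    make_hit("B", "C", bitscore = 400, len = 200, pident = 70),
    make_hit("B", "A", bitscore = 200, len = 200, pident = 50),
    make_hit("C", "B", bitscore = 400, len = 200, pident = 70))
  p2 <- nearest_paralogs(h2)
  expect_equal(nrow(p2), 2L)
  expect_true(all(c("A", "B") %in% unlist(p2)))
})

test_that("pair set equals a hand-enumerated oracle and ignores hit order", {
  set.seed(13)
  genes <- paste0("g", 1:5)
  h <- do.call(rbind, lapply(1:20, function(i) {
    p <- sample(genes, 2)
    make_hit(p[1], p[2], bitscore = sample(50:500, 1), len = 200, pident = 50)
  }))
  # oracle: literal per-gene best then dedup
  oracle <- unique(do.call(rbind, lapply(unique(h$qseqid), function(g) {
    hh <- h[h$qseqid == g & h$sseqid != g, ]
    hh <- hh[order(-hh$bitscore, hh$sseqid), ]
    if (nrow(hh) == 0) return(NULL)
    pair <- sort(c(g, hh$sseqid[1]))
    data.frame(gene_a = pair[1], gene_b = pair[2], stringsAsFactors = FALSE)
  })))
  oracle <- oracle[order(oracle$gene_a, oracle$gene_b), ]
  rownames(oracle) <- NULL
  expect_equal(nearest_paralogs(h), oracle)
  expect_equal(nearest_paralogs(h[sample(nrow(h)), ]), oracle)
})

test_that("saturation and omega filters apply the stated thresholds", {
  pairs <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                      dN = c(0.1, 0.005, 0.2, 0.3, 0.02),
                      dS = c(2.5, 0.5, 2.0, 0.009, 0.5),
                      S_sites = c(100, 100, 100, 100, 49))
  sat <- filter_saturation(pairs)
  expect_equal(sat$gene_a, c("a2", "a3", "a4", "a5"))   # dS 2.0 kept, 2.5 dropped
  om <- filter_for_omega(sat)
  expect_equal(om$gene_a, "a3")   # a2: dN<0.01, a4: dS<0.01, a5: S<50
  # alternative conjunction reading drops only pairs failing both legs
  om2 <- filter_for_omega(sat, rule = "and_sites")
  expect_setequal(om2$gene_a, c("a2", "a3", "a4", "a5"))
  low_both <- data.frame(gene_a = "x", gene_b = "y", dN = 0.001, dS = 0.4,
                         S_sites = 10)
  expect_equal(nrow(filter_for_omega(low_both, rule = "and_sites")), 0L)
  # idempotence
  expect_equal(filter_for_omega(om), om)
  expect_equal(filter_saturation(sat), sat)
})

test_that("1:1 ortholog extraction keeps only single-copy-in-both families", {
  fams <- list(f1 = c("A|g1", "B|g1"),
               f2 = c("A|g2", "A|g3", "B|g2"),
               f3 = c("A|g4"),
               f4 = c("A|g5", "B|g5", "C|g1"))
  oo <- extract_one_to_one(fams, "A", "B")
  expect_equal(oo$family_id, c("f1", "f4"))
  expect_equal(oo$gene_a, c("A|g1", "A|g5"))
})

test_that("speciation threshold is the mean ortholog dS after saturation filter", {
  expect_equal(speciation_threshold(c(0.2, 0.3)), 0.25)
  expect_equal(speciation_threshold(c(0.2, 0.3, 2.5)), 0.25)  # 2.5 excluded
  expect_error(speciation_threshold(numeric()), "no ortholog")
})

test_that("age distributions bin half-open on the dS axis", {
  d <- age_distribution(numeric(), bin_width = 0.05)
  expect_equal(sum(d$count), 0L)
  d <- age_distribution(c(0.01, 0.07), bin_width = 0.05)
  expect_equal(d$count[1:2], c(1L, 1L))
  expect_equal(sum(d$count), 2L)
  # boundary value lands in the bin it opens
  d <- age_distribution(c(0.05), bin_width = 0.05)
  expect_equal(d$count[2], 1L)
  # pairs above max_ds excluded
  d <- age_distribution(c(0.01, 3), bin_width = 0.05, max_ds = 2)
  expect_equal(sum(d$count), 1L)
})

test_that("age distribution of continuing duplication is right-skewed", {
  set.seed(33)
  world <- simulate_two_species_world(
    two_species_config(n_families = 60L, p_young = 0.6, p_ancestral = 0.3,
                       n_codons = 60L), seed = 33)
  # within-species pairs with truth ages: young pairs dominate low-dS bins
  ds <- with(world, {
    prot <- stats::setNames(proteins$sequence, proteins$gene_id)
    cd <- stats::setNames(cds$cds, cds$gene_id)
    out <- c()
    for (fid in names(true_families)) {
      for (sp in config$species) {
        memb <- grep(paste0("^", sp), true_families[[fid]], value = TRUE)
        if (length(memb) >= 2) {
          g <- utils::combn(memb, 2)
          for (k in seq_len(ncol(g))) {
            out <- c(out, pair_dnds(prot[[g[1, k]]], prot[[g[2, k]]],
                                    cd[[g[1, k]]], cd[[g[2, k]]])$dS)
          }
        }
      }
    }
    out
  })
  dist <- age_distribution(ds, bin_width = 0.1, max_ds = 2)
  first_third <- sum(dist$count[dist$lo < 0.6])
  expect_gt(first_third, sum(dist$count) / 2)
})

test_that("ancestral loss rates recover planted pre-speciation losses", {
  # young duplications off and a wide dup-age margin so the planted dS
  # classes sit far from the threshold: recovery must then be exact
  cfg <- two_species_config(n_families = 50L, p_ancestral = 0.5,
                            p_young = 0, n_codons = 120L,
                            dup_age_margin = 0.15)
  world <- simulate_two_species_world(cfg, seed = 77)
  prot <- stats::setNames(world$proteins$sequence, world$proteins$gene_id)
  cd <- stats::setNames(world$cds$cds, world$cds$gene_id)
  est_pairs <- function(sp) {
    rows <- list()
    for (fid in names(world$true_families)) {
      memb <- grep(paste0("^", sp), world$true_families[[fid]], value = TRUE)
      if (length(memb) < 2) next
      g <- utils::combn(sort(memb), 2)
      for (k in seq_len(ncol(g))) {
        e <- pair_dnds(prot[[g[1, k]]], prot[[g[2, k]]], cd[[g[1, k]]], cd[[g[2, k]]])
        rows[[length(rows) + 1]] <- data.frame(
          gene_a = g[1, k], gene_b = g[2, k], dS = e$dS, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  pa <- est_pairs("Mper"); pb <- est_pairs("Apis")
  res <- ancestral_loss_rates(pa, pb, world$true_families, threshold = 0.26,
                              species_a = "Mper", species_b = "Apis")
  truth <- world$families
  # truth: ancestral duplicate detectable in A = anc dup and both copies kept
  anc_a_truth <- truth$ancestral_dup & !truth$lost_a
  anc_b_truth <- truth$ancestral_dup & !truth$lost_b
  expect_equal(res$n_ancestral_a, sum(anc_a_truth))
  expect_equal(res$n_ancestral_b, sum(anc_b_truth))
  expect_equal(res$n_lost_in_b, sum(anc_a_truth & truth$lost_b))
  expect_equal(res$n_lost_in_a, sum(anc_b_truth & truth$lost_a))
})

test_that("loss-rate and percent-increase arithmetic handle edge cases", {
  expect_equal(loss_rate(224, 382), 224 / 382)
  expect_error(loss_rate(1, 0), "undefined")
  expect_error(loss_rate(5, 4), "n_lost")
  expect_equal(percent_increase(3.55, 1.95), 100 * (3.55 - 1.95) / 1.95)
  expect_error(percent_increase(2, 0), "positive")
})
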