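test_that("windowed pi follows the per-site formula and matches brute force", {
  # monomorphic window -> 0
  mono <- toy_panel(matrix(0L, 4, 5))
  pm <- stats::setNames(rep("P", 2), mono$sample_ids)
  expect_equal(pi_windows(mono, pm, "P", size = 1000, step = 1000)$pi,
               rep(0, 1))
  # one site, c0 = c1 = 1, n = 2 -> pi = 1 / 50000 over a 50 kb window
  one <- hap_panel(matrix(c(0L, 1L), 2, 1), 100L, contig_length = 5e4,
                   sample_ids = "s")
  pm1 <- c(s = "P")
  expect_equal(pi_windows(one, pm1, "P", size = 5e4, step = 5e4)$pi, 1 / 5e4)
  # 5-site toy vs explicit pair counting
  m <- rbind(c(0, 1, 1, 0, 1), c(0, 1, 0, 0, 1),
             c(1, 0, 0, 1, 1), c(0, 0, 0, 1, 0))
  p <- toy_panel(m, positions = c(10L, 50L, 200L, 700L, 900L),
                 contig_length = 1000)
  pm2 <- stats::setNames(rep("P", 2), p$sample_ids)
  got <- pi_windows(p, pm2, "P", size = 500, step = 250)
  want <- oracle_pi_windows(p, 1:4, 500, 250)
  expect_equal(got$pi, want, tolerance = 1e-12)
})

test_that("pi agrees with the pair-counting oracle on a 1000-site panel", {
  sim <- small_cohort(seed = 55)
  p <- sim$panels$xiangnan
  pm <- stats::setNames(rep("P", length(p$sample_ids)), p$sample_ids)
  got <- pi_windows(p, pm, "P", size = 1e5, step = 1e5)
  want <- oracle_pi_windows(p, seq_len(n_haps(p)), 1e5, 1e5)
  expect_equal(got$pi, want, tolerance = 1e-10)
})

test_that("heterozygosity and inbreeding F follow their definitions", {
  # fully homozygous population at polymorphic sites: Ho = 0, F = 1
  m <- rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0))
  p <- toy_panel(m)
  pm <- stats::setNames(rep("P", 2), p$sample_ids)
  hf <- het_and_f(p, pm)
  expect_equal(hf$summary$Ho, 0)
  expect_equal(hf$summary$F, 1)

  # spreadsheet-style oracle on a 4-sample fixture
  m2 <- rbind(c(0, 1, 0), c(1, 1, 0),
              c(0, 0, 1), c(1, 0, 1),
              c(0, 1, 0), c(1, 1, 1),
              c(0, 0, 0), c(0, 1, 1))
  p2 <- toy_panel(m2)
  pm2 <- stats::setNames(rep("P", 4), p2$sample_ids)
  hf2 <- het_and_f(p2, pm2)
  d <- dosage_matrix(p2)
  ho_o <- mean(colMeans(d == 1))
  pfr <- colMeans(d) / 2
  he_o <- mean(2 * pfr * (1 - pfr) * 8 / 7)
  expect_equal(hf2$summary$Ho, ho_o, tolerance = 1e-12)
  expect_equal(hf2$summary$He, he_o, tolerance = 1e-12)
  expect_equal(hf2$summary$F, 1 - ho_o / he_o, tolerance = 1e-12)
  expect_equal(nrow(hf2$per_individual), 4)
})

test_that("ROH detection recovers implanted homozygous runs and obeys thresholds", {
  sim <- cached_cohort(77, seq_length = 3e6, mut_rate = 1e-3,
                       sizes = c(xiangnan = 5, indicine = 5, taurine = 4,
                                 banteng = 4, outgroup = 2),
                       intro_fraction = 1e-9)
  p <- sim$panels$xiangnan
  rows <- hap_rows(p, "XN_001")
  run <- c(1e6, 2e6)                                # 1 Mb homozygous run
  sites <- which(p$positions >= run[1] & p$positions < run[2])
  p$alleles[rows[2], sites] <- p$alleles[rows[1], sites]
  roh <- roh_detect(p, "XN_001")
  expect_equal(nrow(roh), 1)
  # bounds within one inter-SNP gap of the implanted run
  gap <- max(diff(p$positions))
  expect_lt(abs(roh$start - run[1]), gap + 1)
  expect_lt(abs(roh$end - run[2]), gap + 1)
  # run shorter than min_len_kb excluded
  expect_equal(nrow(roh_detect(p, "XN_001", min_len_kb = 1500)), 0)
  # fully heterozygous sample: empty
  k <- n_sites(p)
  het <- hap_panel(rbind(rep(0L, k), rep(1L, k)), p$positions,
                   contig_length = p$contig_length, sample_ids = "h")
  expect_equal(nrow(roh_detect(het, "h")), 0)
})

test_that("LD decay reports r2 = 1 for duplicated columns and a null near 1/(n-1)", {
  set.seed(9)
  base <- matrix(rbinom(30 * 40, 1, 0.5), nrow = 30)
  dup <- cbind(base[, 1], base[, 1], base[, -1])
  p <- toy_panel(dup, positions = c(10L, 110L, seq(1000L, by = 500L,
                                                   length.out = 39)))
  pm <- stats::setNames(rep("P", 15), p$sample_ids)
  ld <- ld_decay(p, pm, "P", max_dist = 2e4, bin_width = 200)
  expect_equal(ld$mean_r2[1], 1)                    # the duplicated pair
  # permuted-genotype null: mean r2 ~ 1/(n-1)
  set.seed(10)
  perm <- apply(base, 2, sample)
  p2 <- toy_panel(perm, positions = seq(100L, by = 100L, length.out = 40))
  pm2 <- stats::setNames(rep("P", 15), p2$sample_ids)
  ld2 <- ld_decay(p2, pm2, "P", max_dist = 5e3, bin_width = 5e3)
  n <- 15
  mu <- 1 / (n - 1)
  se <- sqrt(2) * mu                                 # ~sd of chi2_1 / (n-1)
  expect_lt(abs(ld2$mean_r2[1] - mu), 3 * se / sqrt(ld2$n_pairs[1]))
})

test_that("p-distance counts mismatching dosages with pairwise deletion", {
  m <- rbind(c(0, 1, 0, 1), c(0, 1, 0, 1),          # s1
             c(0, 1, 0, 1), c(0, 1, 0, 1),          # s2 identical
             c(1, 0, 1, 0), c(1, 0, 1, 0))          # s3 complementary
  p <- toy_panel(m)
  dm <- p_distance(p)
  expect_equal(unname(dm[1, 2]), 0)
  expect_equal(unname(dm[1, 3]), 1)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 3))
  # trio hand count on dosage with a missing entry
  m2 <- rbind(c(0, 1, NA, 1), c(0, 1, NA, 1),
              c(0, 0, 1, 1), c(1, 0, 1, 1),
              c(1, 1, 0, 0), c(1, 1, 0, 1))
  p2 <- toy_panel(m2)
  expect_equal(p_distance(p2), oracle_p_distance(dosage_matrix(p2)),
               ignore_attr = TRUE)
})

test_that("neighbor joining recovers additive trees exactly", {
  # additive 4-taxon distances from tree ((a:1,b:2):1,(c:3,d:4))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 5;  d["a", "d"] <- d["d", "a"] <- 6
  d["b", "c"] <- d["c", "b"] <- 6;  d["b", "d"] <- d["d", "b"] <- 7
  d["c", "d"] <- d["d", "c"] <- 7
  tr <- nj_tree(d)
  # topology: a,b sister
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
  # additive distances reproduced exactly by path lengths
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # label permutation gives an isomorphic tree
  perm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))[1], 0)
  # 3 taxa: closed-form star branches
  d3 <- d[1:3, 1:3]
  tr3 <- nj_tree(d3)
  expect_equal(sort(tr3$edge.length), sort(c((3 + 5 - 6) / 2, (3 + 6 - 5) / 2,
                                             (5 + 6 - 3) / 2)))
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
  d_bad <- d; d_bad[1, 2] <- NaN
  expect_error(nj_tree(d_bad), "NA")
})

test_that("NJ on an ultrametric matrix reproduces the UPGMA topology", {
  d <- matrix(c(0, 2, 6, 6, 2, 0, 6, 6, 6, 6, 0, 4, 6, 6, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- ape::unroot(nj_tree(d))
  up <- ape::unroot(ape::as.phylo(stats::hclust(stats::as.dist(d),
                                                "average")))
  expect_equal(ape::dist.topo(tr, up)[1], 0)
})

test_that("PCA separates diverged populations and reports sane variance shares", {
  sim <- small_cohort(seed = 81)
  sub <- subset_samples(sim$panel,
                        names(sim$popmap)[sim$popmap %in% c("xiangnan",
                                                            "taurine")])
  pc <- snp_pca(sub)
  pops <- sim$popmap[rownames(pc$scores)]
  s1 <- pc$scores[pops == "xiangnan", 1]
  s2 <- pc$scores[pops == "taurine", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))  # zero overlap on PC1
  expect_true(all(diff(pc$varprop) <= 1e-12))
  expect_lte(sum(pc$varprop), 1 + 1e-12)
  # duplicated sample lands on coincident scores
  dup <- sub
  rows <- hap_rows(sub, sub$sample_ids[1])
  dup$alleles <- rbind(dup$alleles, dup$alleles[rows, ])
  dup$sample_ids <- c(dup$sample_ids, "copy")
  dup <- hap_panel(dup$alleles, dup$positions, dup$chrom, dup$sample_ids,
                   dup$contig_length)
  pc2 <- snp_pca(dup)
  expect_equal(pc2$scores[sub$sample_ids[1], ], pc2$scores["copy", ],
               tolerance = 1e-8)
})
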