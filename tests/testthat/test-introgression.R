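freqs_from <- function(p_mat, positions = NULL, contig_length = NULL) {
  # build a site_freqs object directly from a populations x sites matrix
  k <- ncol(p_mat)
  if (is.null(positions)) positions <- seq_len(k) * 1000L
  if (is.null(contig_length)) contig_length <- max(positions) + 1000
  structure(list(p = p_mat, n = matrix(100L, nrow(p_mat), k,
                                       dimnames = dimnames(p_mat)),
                 positions = as.integer(positions), chrom = "1",
                 contig_length = contig_length, polarized = TRUE,
                 outgroup = "O", flipped = rep(FALSE, k),
                 tie_flag = rep(FALSE, k)), class = "site_freqs")
}

test_that("Patterson's D hits its forced, symmetric and antisymmetric cases", {
  # single site p1=0, p2=1, p3=1, pO=0 -> D = 1
  f1 <- freqs_from(matrix(c(0, 1, 1, 0), 4, 1,
                          dimnames = list(c("P1", "P2", "P3", "O"), NULL)))
  d1 <- suppressWarnings(patterson_d(f1, "P1", "P2", "P3", "O", 500))
  expect_equal(d1$D, 1)
  # p1 = p2 everywhere -> D = 0
  set.seed(5)
  pp <- runif(50)
  m <- rbind(P1 = pp, P2 = pp, P3 = runif(50), O = rep(0, 50))
  d0 <- suppressWarnings(patterson_d(freqs_from(m), "P1", "P2", "P3", "O",
                                     5000))
  expect_equal(d0$D, 0)
  # swapping P1 and P2 negates D exactly
  m2 <- rbind(P1 = runif(50), P2 = runif(50), P3 = runif(50),
              O = rep(0, 50))
  fa <- freqs_from(m2)
  da <- suppressWarnings(patterson_d(fa, "P1", "P2", "P3", "O", 5000))
  db <- suppressWarnings(patterson_d(fa, "P2", "P1", "P3", "O", 5000))
  expect_equal(da$D, -db$D, tolerance = 1e-12)
  expect_equal(da$n_abba, db$n_baba, tolerance = 1e-12)
})

test_that("D-statistic calibration: null within noise, donor pulse detected", {
  z_for <- function(seed, frac) {
    sim <- cached_cohort(seed, intro_fraction = frac)
    fr <- allele_freqs(sim$panel, sim$popmap, outgroup = "outgroup")
    patterson_d(fr, "indicine", "xiangnan", "banteng", "outgroup",
                block_size = 2.5e5)$z
  }
  z_null <- sapply(501:505, z_for, frac = 1e-9)
  z_pulse <- sapply(601:605, z_for, frac = 0.06)
  expect_gte(sum(abs(z_null) < 3), 4)
  expect_gte(sum(z_pulse > 3), 4)
})

test_that("U-statistic windows count exactly the pattern-matching sites", {
  thr <- u_thresholds(w = 0.01, x = 0.5, y = 1.0)
  # definition site: donor fixed, control absent, target common -> counted
  m <- rbind(control = c(0.0, 0.0, 0.005, 0.5, 0.02),
             target  = c(0.6, 0.5, 0.8,   0.9, 0.51),
             donor   = c(1.0, 1.0, 1.0,   1.0, 0.99))
  fr <- freqs_from(m)
  u <- u_stat_windows(fr, "control", "target", "donor", thr,
                      size = 6000, step = 6000)
  # site1 yes; site2 target = 0.5 exactly -> strict > excludes;
  # site3 yes; site4 control too common; site5 donor below y
  expect_equal(u$u[1], 2)
  # 30-site random fixture against the brute-force oracle
  set.seed(8)
  m2 <- rbind(control = runif(30, 0, 0.05), target = runif(30),
              donor = sample(c(1, 1, 0.99, 0.8), 30, replace = TRUE))
  fr2 <- freqs_from(m2)
  for (sz in c(5000, 12000)) {
    got <- u_stat_windows(fr2, "control", "target", "donor", thr,
                          size = sz, step = 5000)
    w <- make_windows(fr2$contig_length, sz, 5000)
    want <- oracle_u_counts(fr2$positions, m2["control", ], m2["target", ],
                            m2["donor", ], 0.01, 0.5, 1.0, w)
    expect_equal(got$u, want)
  }
  # undefined frequencies are skipped and counted
  m3 <- m2; m3["donor", 1:3] <- NA
  u3 <- u_stat_windows(freqs_from(m3), "control", "target", "donor", thr,
                       size = 5000, step = 5000)
  expect_equal(attr(u3, "n_skipped"), 3)
  expect_error(u_thresholds(0.5, 0.2, 1), "<=")
})

test_that("ILS probabilities follow the Gamma(2) survival law", {
  mod <- ils_model(r = 1e-8, t = 1e5)
  L <- mod$L
  expect_equal(L, 1 / (1e-8 * 1e5))
  # m -> 0 limit
  expect_gt(ils_probability(1e-6, mod), 1 - 1e-9)
  # closed form at m = L
  expect_equal(ils_probability(L, mod), 2 * exp(-1), tolerance = 1e-12)
  # matches the independent pgamma-based survival at many lengths
  ms <- c(10, 1e3, 5e3, 2e4, 1e5, 1e6)
  expect_equal(ils_probability(ms, mod), oracle_ils(ms, L),
               tolerance = 1e-10)
  # doubling the length never increases the probability
  expect_true(all(ils_probability(2 * ms, mod) <= ils_probability(ms, mod)))
  expect_error(ils_probability(0, mod), "positive")
  expect_error(ils_model(r = 0, t = 1), "positive")
})

test_that("tract filtering keeps long tracts and is monotone in alpha", {
  tracts <- data.frame(sample = "s", hap = 1L, chrom = "1",
                       start = 0, end = 0,
                       donor = "banteng",
                       length = c(100, 500, 2000, 1e4, 1e5, 1e6))
  tracts$end <- tracts$length
  mod <- ils_model(r = 1e-8, t = 1e3, alpha = 0.05)   # expected length 100 kb
  kept <- filter_tracts(tracts, mod)
  # survivors equal the closed-form per-tract rule
  expect_equal(kept$length,
               tracts$length[oracle_ils(tracts$length, mod$L) < 0.05])
  expect_equal(nrow(kept) + nrow(attr(kept, "discarded")), nrow(tracts))
  expect_true(all(!is.na(attr(kept, "discarded")$p_ils)))
  # alpha sweep: survivor count monotone, all pass near 1, none near 0
  alphas <- c(1e-9, 0.01, 0.05, 0.5, 1 - 1e-9)
  counts <- sapply(alphas, function(a)
    nrow(filter_tracts(tracts, ils_model(1e-8, 1e3, a))))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_equal(counts[length(counts)], nrow(tracts))
})

test_that("local ancestry labels verbatim donor copies and honours the margin rule", {
  set.seed(12)
  k <- 200
  refA <- toy_panel(matrix(rbinom(4 * k, 1, 0.5), 4, k))
  refB <- toy_panel(matrix(rbinom(4 * k, 1, 0.5), 4, k))
  # target hap 1 copies refA hap 1 over sites 1..100, refB hap 2 over 101..200
  tgt <- matrix(rbinom(2 * k, 1, 0.5), 2, k)
  tgt[1, 1:100] <- refA$alleles[1, 1:100]
  tgt[1, 101:200] <- refB$alleles[2, 101:200]
  target <- toy_panel(tgt)
  tr <- local_ancestry(target, list(A = refA, B = refB), window_snps = 25,
                       margin = 0.1)
  h1 <- tr[tr$hap == 1 & tr$sample == target$sample_ids[1], ]
  lab_at <- function(pos) h1$donor[h1$start <= pos & h1$end > pos]
  expect_equal(lab_at(2500), "A")                   # inside the A span
  expect_equal(lab_at(15000), "B")                  # inside the B span
  # equidistant reference panels leave windows unassigned
  same <- toy_panel(matrix(rbinom(2 * k, 1, 0.5), 2, k))
  tie <- local_ancestry(same, list(A = same, B = same), window_snps = 25,
                        margin = 0.05)
  expect_equal(nrow(tie), 0)
})

test_that("local ancestry reaches 95% per-bp accuracy on long implanted tracts", {
  sim <- cached_cohort(811, tract_len_mean = 2e5, intro_fraction = 0.08)
  la <- local_ancestry(sim$panels$xiangnan,
                       refs = list(taurine = sim$panels$taurine,
                                   indicine = sim$panels$indicine,
                                   banteng = sim$panels$banteng))
  truth <- sim$truth$tracts
  L <- sim$panel$contig_length
  acc <- num <- 0
  for (h in seq_len(n_haps(sim$panels$xiangnan))) {
    sid <- sim$panels$xiangnan$sample_ids[ceiling(h / 2)]
    hp <- ((h - 1) %% 2) + 1
    truth_iv <- truth[truth$sample == sid & truth$hap == hp, ]
    call_iv <- la[la$sample == sid & la$hap == hp & la$donor == "banteng", ]
    grid <- seq(0, L - 1, by = 1000)
    t_in <- rep(FALSE, length(grid)); c_in <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(truth_iv)))
      t_in <- t_in | (grid >= truth_iv$start[i] & grid < truth_iv$end[i])
    for (i in seq_len(nrow(call_iv)))
      c_in <- c_in | (grid >= call_iv$start[i] & grid < call_iv$end[i])
    acc <- acc + sum(t_in == c_in); num <- num + length(grid)
  }
  expect_gt(acc / num, 0.95)
})

test_that("introgression ratios aggregate tract lengths per sample", {
  samples <- c("s1", "s2")
  none <- data.frame(sample = character(0), donor = character(0),
                     length = numeric(0))
  r0 <- introgression_ratio(none, samples, 1e6, donors = "banteng")
  expect_equal(r0$per_sample$ratio, c(0, 0))
  # one haplotype fully donor -> ratio 0.5
  tr <- data.frame(sample = "s1", donor = "banteng", length = 1e6)
  r1 <- introgression_ratio(tr, samples, 1e6)
  expect_equal(r1$per_sample$ratio[r1$per_sample$sample == "s1"], 0.5)
  expect_equal(r1$summary$min, 0)
  expect_equal(r1$summary$max, 0.5)
  expect_equal(r1$summary$mean, 0.25)
  expect_error(introgression_ratio(tr, samples, 0), "positive")
})

test_that("no-gene-flow specificity: post-filter donor share stays below 1%", {
  mod <- ils_model(r = 1e-8, t = 3e5, alpha = 0.05)
  deep <- c(indicine_pool = 0.05, terminal = 0.02, taurine = 0.25,
            banteng = 0.7, outgroup = 0.7)
  ok <- 0
  for (seed in 701:706) {
    sim <- cached_cohort(seed, intro_fraction = 1e-9, drift = deep)
    la <- local_ancestry(sim$panels$xiangnan,
                         refs = list(taurine = sim$panels$taurine,
                                     indicine = sim$panels$indicine,
                                     banteng = sim$panels$banteng))
    kept <- filter_tracts(la[la$donor == "banteng", , drop = FALSE], mod)
    ir <- introgression_ratio(kept, sim$panels$xiangnan$sample_ids,
                              sim$panel$contig_length, donors = "banteng")
    if (mean(ir$per_sample$ratio) <= 0.01) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("region trees place introgressed target haplotypes with the donor", {
  sim <- cached_cohort(901, intro_fraction = 1e-9)
  # copy a banteng segment into every xiangnan haplotype over a known region
  reg <- c(2e6, 2.2e6)
  pans <- sim$panels
  sites <- which(pans$xiangnan$positions >= reg[1] &
                   pans$xiangnan$positions < reg[2])
  for (h in seq_len(n_haps(pans$xiangnan)))
    pans$xiangnan$alleles[h, sites] <-
      pans$banteng$alleles[1 + (h %% n_haps(pans$banteng)), sites]
  m <- bind_panels(pans)
  rc <- region_confirm(m$panel, m$popmap, reg[1], reg[2], "xiangnan",
                       "indicine", "outgroup", "banteng")
  expect_true(rc$donor_monophyly)
  expect_equal(rc$nearest_donor_fraction, 1)
  # leaf set equals the input haplotype set
  expect_setequal(rc$tree$tip.label, rownames(rc$distances))
  # without introgression the target nests with the control indicine
  m0 <- bind_panels(sim$panels)
  rc0 <- region_confirm(m0$panel, m0$popmap, reg[1], reg[2], "xiangnan",
                        "indicine", "outgroup", "banteng")
  expect_false(rc0$donor_monophyly)
  expect_lt(rc0$nearest_donor_fraction, 0.2)
  expect_error(region_confirm(m0$panel, m0$popmap, 0, 100, "xiangnan",
                              "indicine", "outgroup", "banteng"), ">= 5")
})
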