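# Independent brute-force / closed-form oracles. Each one recomputes a
# statistic by the most literal route available (explicit pair loops,
# site-by-site enumeration, stats:: distribution functions) so that the
# package implementations are checked against a different code path.

# windowed pi by explicit haplotype-pair counting
oracle_pi_windows <- function(panel, rows, size, step) {
  a <- panel$alleles[rows, , drop = FALSE]
  w <- make_windows(panel$contig_length, size, step)
  sapply(seq_len(nrow(w)), function(i) {
    js <- which(panel$positions >= w$start[i] & panel$positions < w$end[i])
    tot <- 0
    for (j in js) {
      x <- a[, j][!is.na(a[, j])]
      n <- length(x)
      if (n < 2) next
      diffs <- 0
      for (u in seq_len(n - 1)) for (v in (u + 1):n)
        diffs <- diffs + (x[u] != x[v])
      tot <- tot + diffs / choose(n, 2)
    }
    tot / size
  })
}

# Tajima's D from first principles on a complete (no-missing) matrix
oracle_tajima_d <- function(a) {
  n <- nrow(a)
  freqs <- colSums(a)
  seg <- freqs > 0 & freqs < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k <- 0
  for (u in seq_len(n - 1)) for (v in (u + 1):n)
    k <- k + sum(a[u, ] != a[v, ])
  k <- k / choose(n, 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham weighted theta over a set of sites, written from the
# published component formulas site by site
oracle_wc_fst <- function(d1, d2) {
  stopifnot(ncol(d1) == ncol(d2))
  num <- den <- 0
  for (j in seq_len(ncol(d1))) {
    g1 <- d1[, j][!is.na(d1[, j])]; g2 <- d2[, j][!is.na(d2[, j])]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 1 || n2 < 1 || (n1 + n2) / 2 <= 1) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  num / den
}

# Hudson FST estimator (Bhatia et al. 2013), ratio of averages
oracle_hudson_fst <- function(a1, a2) {
  num <- den <- 0
  for (j in seq_len(ncol(a1))) {
    x1 <- a1[, j][!is.na(a1[, j])]; x2 <- a2[, j][!is.na(a2[, j])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(x1); p2 <- mean(x2)
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

# p-distance by explicit double loop over units
oracle_p_distance <- function(m) {
  nu <- nrow(m)
  dm <- matrix(0, nu, nu)
  for (i in seq_len(nu)) for (j in seq_len(nu)) {
    if (i == j) next
    mism <- comp <- 0
    for (s in seq_len(ncol(m))) {
      if (is.na(m[i, s]) || is.na(m[j, s])) next
      comp <- comp + 1
      if (m[i, s] != m[j, s]) mism <- mism + 1
    }
    dm[i, j] <- if (comp == 0) NA_real_ else mism / comp
  }
  dm
}

# U-statistic window counts, site by site with explicit conditions
oracle_u_counts <- function(positions, pc, pt, pd, w, x, y, windows) {
  sapply(seq_len(nrow(windows)), function(i) {
    cnt <- 0
    for (s in seq_along(positions)) {
      if (positions[s] < windows$start[i] ||
          positions[s] >= windows$end[i]) next
      if (is.na(pc[s]) || is.na(pt[s]) || is.na(pd[s])) next
      if (pd[s] >= y && pc[s] < w && pt[s] > x) cnt <- cnt + 1
    }
    cnt
  })
}

# greedy LD pruning re-implemented as a plain loop over a dosage matrix
oracle_ld_prune <- function(d, pos, win, step, thr) {
  keep <- rep(TRUE, ncol(d))
  repeat {
    removed <- FALSE
    cur <- which(keep)
    i <- 1
    while (i <= length(cur)) {
      w <- cur[i:min(i + win - 1, length(cur))]
      w <- w[keep[w]]
      if (length(w) >= 2) {
        for (ai in seq_len(length(w) - 1)) {
          if (!keep[w[ai]]) next
          for (bi in (ai + 1):length(w)) {
            if (!keep[w[bi]]) next
            r <- suppressWarnings(stats::cor(d[, w[ai]], d[, w[bi]],
                                             use = "pairwise.complete.obs"))
            if (!is.na(r) && r^2 > thr) {
              keep[w[bi]] <- FALSE
              removed <- TRUE
            }
          }
        }
      }
      i <- i + step
    }
    if (!removed) break
  }
  which(keep)
}

# ILS survival via the Gamma(2, 1/L) distribution function in stats
oracle_ils <- function(m, L) 1 - stats::pgamma(m, shape = 2, rate = 1 / L)
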