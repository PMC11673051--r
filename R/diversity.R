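#' Windowed nucleotide diversity (theta-pi)
#'
#' Per-site pi is `2 * c0 * c1 / (n * (n - 1))` over called alleles; the
#' window value is the sum of per-site pi divided by the window size in bp
#' (VCFtools `--window-pi` semantics). Sites with fewer than two called
#' alleles are skipped.
#'
#' @param panel a [hap_panel()].
#' @param popmap named character vector sample -> population.
#' @param population population to analyse.
#' @param size,step window and step size in bp.
#' @return data.frame: chrom, start, end, n_sites, pi.
#' @export
pi_windows <- function(panel, popmap, population, size = 50000,
                       step = 20000) {
  rows <- hap_rows(panel, samples_of(popmap, population))
  a <- panel$alleles[rows, , drop = FALSE]
  n <- colSums(!is.na(a))
  c1 <- colSums(a == 1L, na.rm = TRUE)
  c0 <- n - c1
  pi_site <- ifelse(n >= 2, 2 * c0 * c1 / (n * (n - 1)), 0)
  w <- make_windows(panel$contig_length, size, step)
  ws <- window_sums(panel$positions[n >= 2], pi_site[n >= 2], w)
  data.frame(chrom = panel$chrom, start = w$start, end = w$end,
             n_sites = ws$n, pi = ws$sum / size)
}

#' Observed/expected heterozygosity and inbreeding coefficient F
#'
#' Per population: Ho is the mean observed heterozygote fraction across
#' sites, He the mean unbiased expected heterozygosity
#' `2 p (1 - p) * n / (n - 1)` (n = called allele count), and
#' `F = 1 - Ho / He`. A per-individual F (method-of-moments on homozygote
#' counts, VCFtools `--het` style) is also returned; the per-population
#' aggregate is the primary figure.
#'
#' @param panel a [hap_panel()].
#' @param popmap named character vector sample -> population.
#' @return list: `summary` data.frame (population, Ho, He, F, n_snps) and
#'   `per_individual` data.frame (sample, population, F_ind).
#' @export
het_and_f <- function(panel, popmap) {
  pops <- unique(unname(popmap[panel$sample_ids]))
  summ <- vector("list", length(pops)); names(summ) <- pops
  indiv <- vector("list", length(pops))
  for (pop in pops) {
    samples <- samples_of(popmap, pop)
    d <- dosage_matrix(subset_samples(panel, samples))
    n_gt <- colSums(!is.na(d))
    n_al <- 2L * n_gt
    c1 <- colSums(d, na.rm = TRUE)
    p <- ifelse(n_al > 0, c1 / n_al, NA_real_)
    ho_site <- ifelse(n_gt > 0, colSums(d == 1L, na.rm = TRUE) / n_gt, NA_real_)
    he_site <- ifelse(n_al >= 2, 2 * p * (1 - p) * n_al / (n_al - 1), NA_real_)
    ok <- !is.na(ho_site) & !is.na(he_site)
    poly <- ok & he_site > 0
    ho <- mean(ho_site[ok]); he <- mean(he_site[ok])
    f <- if (he > 0) 1 - ho / he else NA_real_
    summ[[pop]] <- data.frame(population = pop, Ho = ho, He = he, F = f,
                              n_snps = sum(poly))
    # per-individual: (observed hom - expected hom) / (sites - expected hom)
    e_hom <- 1 - he_site
    fi <- apply(d, 1, function(g) {
      called <- !is.na(g) & !is.na(e_hom)
      nn <- sum(called)
      eh <- sum(e_hom[called])
      oh <- sum(g[called] != 1L)
      if (nn - eh > 0) (oh - eh) / (nn - eh) else NA_real_
    })
    indiv[[pop]] <- data.frame(sample = samples, population = pop, F_ind = fi)
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       per_individual = do.call(rbind, c(indiv,
                                         list(make.row.names = FALSE))))
}

#' Detect runs of homozygosity for one sample (PLINK-style scan)
#'
#' Slides a `window_snps`-SNP window one SNP at a time; a window is
#' homozygous-compatible if it contains at most `max_het_per_window`
#' heterozygous calls. A SNP is in a run if the fraction of windows
#' overlapping it that are compatible exceeds `window_threshold` (PLINK
#' default 0.05). Maximal runs of such SNPs are reported when they span at
#' least `min_len_kb` kb and `min_snps` SNPs.
#'
#' @param panel a [hap_panel()].
#' @param sample sample id.
#' @param window_snps SNPs per scanning window.
#' @param max_het_per_window heterozygote allowance per window.
#' @param min_len_kb minimum run length, kb.
#' @param min_snps minimum SNPs per run.
#' @param window_threshold fraction of compatible windows needed per SNP.
#' @return data.frame: sample, chrom, start, end, n_snps, n_het.
#' @export
roh_detect <- function(panel, sample, window_snps = 50,
                       max_het_per_window = 1, min_len_kb = 500,
                       min_snps = 50, window_threshold = 0.05) {
  g <- dosage_matrix(subset_samples(panel, sample))[1, ]
  k <- length(g)
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_snps = integer(0), n_het = integer(0))
  if (k < window_snps) return(empty)
  het <- !is.na(g) & g == 1L
  cs <- c(0, cumsum(het))
  nw <- k - window_snps + 1L
  win_ok <- (cs[(window_snps + 1L):(k + 1L)] - cs[1:nw]) <= max_het_per_window
  # fraction of windows covering SNP j that are compatible
  ok_cs <- c(0, cumsum(win_ok))
  j <- seq_len(k)
  lo <- pmax(1L, j - window_snps + 1L)
  hi <- pmin(j, nw)
  n_win <- pmax(hi - lo + 1L, 0L)
  n_ok <- ifelse(n_win > 0, ok_cs[hi + 1L] - ok_cs[lo], 0)
  in_run <- n_win > 0 & n_ok / pmax(n_win, 1L) > window_threshold
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- which(r$values)
  out <- lapply(segs, function(s) {
    i1 <- starts[s]; i2 <- ends[s]
    st <- panel$positions[i1]; en <- panel$positions[i2] + 1
    if (en - st < min_len_kb * 1000 || i2 - i1 + 1L < min_snps) return(NULL)
    data.frame(sample = sample, chrom = panel$chrom, start = st, end = en,
               n_snps = i2 - i1 + 1L, n_het = sum(het[i1:i2]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' LD decay: mean r-squared by physical-distance bin
#'
#' Squared Pearson correlation of genotype dosages for all site pairs within
#' `max_dist`, averaged in distance bins. Monomorphic sites are excluded;
#' missing dosages are mean-imputed per site.
#'
#' @param panel a [hap_panel()].
#' @param popmap named character vector sample -> population.
#' @param population population to analyse.
#' @param max_dist maximum pair distance bp.
#' @param bin_width bin width bp.
#' @return data.frame: bin_start, bin_end, mean_r2, n_pairs.
#' @export
ld_decay <- function(panel, popmap, population, max_dist = 5e5,
                     bin_width = 2.5e4) {
  d <- dosage_matrix(subset_samples(panel, samples_of(popmap, population)))
  pos <- panel$positions
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  v <- apply(d, 2, stats::var)
  keep <- which(!is.na(v) & v > 0)
  d <- d[, keep, drop = FALSE]; pos <- pos[keep]
  k <- ncol(d)
  n <- nrow(d)
  x <- scale(d)                      # standardized dosages
  nb <- ceiling(max_dist / bin_width)
  ssum <- numeric(nb); cnt <- integer(nb)
  for (i in seq_len(max(k - 1L, 0L))) {
    jmax <- i
    while (jmax < k && pos[jmax + 1L] - pos[i] <= max_dist) jmax <- jmax + 1L
    if (jmax == i) next
    js <- (i + 1L):jmax
    r <- crossprod(x[, i], x[, js, drop = FALSE]) / (n - 1)
    r2 <- as.vector(r)^2
    b <- pmin(floor((pos[js] - pos[i]) / bin_width) + 1L, nb)
    for (u in seq_along(js)) {
      ssum[b[u]] <- ssum[b[u]] + r2[u]
      cnt[b[u]] <- cnt[b[u]] + 1L
    }
  }
  data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
             bin_end = seq_len(nb) * bin_width,
             mean_r2 = ifelse(cnt > 0, ssum / cnt, NA_real_),
             n_pairs = cnt)
}

#' Pairwise p-distance matrix
#'
#' Proportion of compared positions at which two units differ, with
#' pairwise deletion of missing entries. Units are diploid samples compared
#' on dosage (0/1/2; any dosage difference is a mismatch) or single
#' haplotypes compared on alleles.
#'
#' @param panel a [hap_panel()].
#' @param unit `"sample"` (dosage) or `"haplotype"` (alleles).
#' @return square symmetric numeric matrix with zero diagonal; a pair with
#'   zero comparable positions is NA.
#' @export
p_distance <- function(panel, unit = c("sample", "haplotype")) {
  unit <- match.arg(unit)
  m <- if (unit == "sample") dosage_matrix(panel) else {
    a <- panel$alleles
    rownames(a) <- paste0(rep(panel$sample_ids, each = 2), "_h",
                          rep(1:2, length(panel$sample_ids)))
    a
  }
  nu <- nrow(m)
  dm <- matrix(0, nu, nu, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nu - 1L)) {
    for (j in (i + 1L):nu) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      nc <- sum(ok)
      dm[i, j] <- dm[j, i] <-
        if (nc == 0) NA_real_ else sum(m[i, ok] != m[j, ok]) / nc
    }
  }
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero and the number of clamps reported as an attribute.
#'
#' @param d square symmetric distance matrix, >= 3 taxa, no NA/NaN.
#' @return an unrooted `phylo` tree with attribute `n_clamped`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(is.na(d))) stop("distance matrix contains NA/NaN")
  tr <- ape::nj(d)
  n_neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "n_clamped") <- n_neg
  tr
}

#' Principal component analysis of genotype dosages
#'
#' smartPCA-style: monomorphic sites dropped, missing dosages mean-imputed
#' per site, columns centred by `2 p` and scaled by `sqrt(p (1 - p))`
#' (Patterson normalization), then singular value decomposition of the
#' sample matrix. Explained-variance fractions are eigenvalue shares.
#'
#' @param panel a [hap_panel()].
#' @param n_pc number of components to return.
#' @return list: `scores` (samples x n_pc), `varprop` (explained-variance
#'   fractions, non-increasing), `n_sites_used`.
#' @export
snp_pca <- function(panel, n_pc = 10) {
  d <- dosage_matrix(panel)
  if (nrow(d) < 2) stop("need at least 2 samples")
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic sites")
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  x <- sweep(d, 2, 2 * p)
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  sv <- svd(x)
  n_pc <- min(n_pc, length(sv$d))
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  lambda <- sv$d^2
  list(scores = scores, varprop = (lambda / sum(lambda))[seq_len(n_pc)],
       n_sites_used = sum(keep))
}
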