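#' Patterson's D (ABBA-BABA) with block jackknife
#'
#' Frequency-based D over polarizable sites: per site,
#' `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)`;
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`. The standard error comes from
#' a delete-one block jackknife over contiguous bp blocks, and `Z = D / SE`.
#' A positive D indicates excess allele sharing between P2 and P3.
#'
#' @param freqs a `site_freqs` object from [allele_freqs()], polarized with
#'   an outgroup.
#' @param p1,p2,p3,outgroup population labels: ((P1, P2), P3), outgroup.
#' @param block_size jackknife block size in bp.
#' @return list of class `dstat`: D, n_abba, n_baba, se, z, n_blocks,
#'   n_sites, block_size, pops.
#' @export
patterson_d <- function(freqs, p1, p2, p3, outgroup, block_size = 5e6) {
  stopifnot(inherits(freqs, "site_freqs"))
  pops <- c(p1, p2, p3, outgroup)
  missing <- setdiff(pops, rownames(freqs$p))
  if (length(missing)) stop("populations absent: ",
                            paste(missing, collapse = ", "))
  f1 <- freqs$p[p1, ]; f2 <- freqs$p[p2, ]
  f3 <- freqs$p[p3, ]; fo <- freqs$p[outgroup, ]
  ok <- !is.na(f1) & !is.na(f2) & !is.na(f3) & !is.na(fo)
  abba <- (1 - f1[ok]) * f2[ok] * f3[ok] * (1 - fo[ok])
  baba <- f1[ok] * (1 - f2[ok]) * f3[ok] * (1 - fo[ok])
  denom <- sum(abba + baba)
  if (denom == 0) {
    return(structure(list(D = NA_real_, n_abba = 0, n_baba = 0,
                          se = NA_real_, z = NA_real_, n_blocks = 0,
                          n_sites = sum(ok), block_size = block_size,
                          pops = pops), class = "dstat"))
  }
  D <- sum(abba - baba) / denom
  pos <- freqs$positions[ok]
  block <- floor(pos / block_size)
  blocks <- unique(block)
  g <- length(blocks)
  if (g < 20)
    warning("only ", g, " jackknife blocks; SE may be unreliable")
  dj <- vapply(blocks, function(b) {
    keep <- block != b
    sum(abba[keep] - baba[keep]) / sum(abba[keep] + baba[keep])
  }, numeric(1))
  se <- if (g >= 2 && !anyNA(dj)) sqrt((g - 1) / g * sum((dj - mean(dj))^2))
        else NA_real_
  structure(list(D = D, n_abba = sum(abba), n_baba = sum(baba), se = se,
                 z = if (!is.na(se) && se > 0) D / se else NA_real_,
                 n_blocks = g,
                 n_sites = sum(ok), block_size = block_size, pops = pops),
            class = "dstat")
}

#' @exportS3Method base::print
print.dstat <- function(x, ...) {
  cat(sprintf("Patterson's D ((%s,%s),%s; outgroup %s): D = %.4f, SE = %.4f, Z = %.2f (%d sites, %d blocks)\n",
              x$pops[1], x$pops[2], x$pops[3], x$pops[4], x$D, x$se, x$z,
              x$n_sites, x$n_blocks))
  invisible(x)
}

#' Frequency thresholds for the windowed U statistic
#'
#' `w`: maximum derived-allele frequency in the control population (strict
#' `<`); `x`: minimum in the target (strict `>`); `y`: minimum in the donor
#' (non-strict `>=`, so `y = 1` means fixed in the donor).
#'
#' @param w,x,y thresholds with `0 <= w < x <= y <= 1`.
#' @return a `u_thresholds` list.
#' @export
u_thresholds <- function(w = 0.01, x = 0.5, y = 1.0) {
  if (!(0 <= w && w < x && x <= y && y <= 1))
    stop("need 0 <= w < x <= y <= 1")
  structure(list(w = w, x = x, y = y), class = "u_thresholds")
}

#' Windowed U statistic for adaptive introgression
#'
#' Counts, per sliding window, the sites at which the donor population
#' carries an allele at frequency >= y while that allele is rare (< w) in
#' the control population and common (> x) in the target population.
#' Sites with an undefined frequency in any of the three populations are
#' skipped and counted.
#'
#' @param freqs a `site_freqs` object from [allele_freqs()].
#' @param control,target,donor population labels.
#' @param thresholds a [u_thresholds()].
#' @param size,step window and step size bp.
#' @return data.frame (chrom, start, end, u) with attribute `n_skipped`.
#' @export
u_stat_windows <- function(freqs, control, target, donor,
                           thresholds = u_thresholds(), size = 50000,
                           step = 20000) {
  stopifnot(inherits(freqs, "site_freqs"),
            inherits(thresholds, "u_thresholds"))
  pc <- freqs$p[control, ]; pt <- freqs$p[target, ]; pd <- freqs$p[donor, ]
  def <- !is.na(pc) & !is.na(pt) & !is.na(pd)
  hit <- def & pd >= thresholds$y & pc < thresholds$w & pt > thresholds$x
  w <- make_windows(freqs$contig_length, size, step)
  ws <- window_sums(freqs$positions[def], as.numeric(hit[def]), w)
  out <- data.frame(chrom = freqs$chrom, start = w$start, end = w$end,
                    u = ws$sum)
  attr(out, "n_skipped") <- sum(!def)
  out
}

#' Window-based local-ancestry assignment against reference panels
#'
#' A transparent distance classifier standing in for CRF-based local
#' ancestry: each non-overlapping window of `window_snps` sites assigns
#' every target haplotype to the reference panel containing its
#' nearest-neighbour haplotype (minimum mean per-site Hamming distance),
#' but only if the runner-up panel is at least `margin` further away;
#' otherwise the window is unassigned. Consecutive same-label windows merge
#' into tracts whose bp bounds are midpoints between boundary SNPs.
#'
#' @param target a phased [hap_panel()].
#' @param refs named list of reference [hap_panel()]s sharing the target's
#'   site map (each >= 2 haplotypes).
#' @param window_snps SNPs per classification window; a trailing remainder
#'   shorter than this is folded into the last window.
#' @param margin minimum distance gap to the runner-up panel.
#' @return data.frame of tracts: sample, hap, chrom, start, end, donor
#'   (panel label), length, margin (mean distance gap over merged windows).
#' @export
local_ancestry <- function(target, refs, window_snps = 20, margin = 0.1) {
  stopifnot(length(refs) >= 2, !is.null(names(refs)))
  for (r in refs) {
    if (!identical(r$positions, target$positions))
      stop("reference panels must share the target site map")
    if (n_haps(r) < 2) stop("each reference panel needs >= 2 haplotypes")
  }
  k <- n_sites(target)
  if (k == 0) stop("target panel has no sites")
  nw <- max(1L, k %/% window_snps)
  starts <- (seq_len(nw) - 1L) * window_snps + 1L
  ends <- c(starts[-1L] - 1L, k)
  pos <- target$positions
  wb_start <- numeric(nw); wb_end <- numeric(nw)
  wb_start[1] <- pos[1]
  if (nw > 1) {
    mids <- (pos[ends[-nw]] + pos[starts[-1L]]) %/% 2
    wb_start[-1L] <- mids
    wb_end[-nw] <- mids
  }
  wb_end[nw] <- pos[k] + 1
  tm <- target$alleles
  nt <- nrow(tm)
  labels <- matrix(NA_character_, nrow = nt, ncol = nw)
  gaps <- matrix(NA_real_, nrow = nt, ncol = nw)
  for (wi in seq_len(nw)) {
    js <- starts[wi]:ends[wi]
    tw <- tm[, js, drop = FALSE]
    dpanel <- sapply(refs, function(r) {
      rw <- r$alleles[, js, drop = FALSE]
      # mismatches between each target hap and each ref hap, ignoring NA
      tn <- !is.na(tw); rn <- !is.na(rw)
      t0 <- tw == 0L & tn; t1 <- tw == 1L & tn
      r0 <- rw == 0L & rn; r1 <- rw == 1L & rn
      mism <- t0 %*% t(r1) + t1 %*% t(r0)
      comp <- (t0 + t1) %*% t(r0 + r1)
      rate <- ifelse(comp > 0, mism / comp, NA_real_)
      apply(rate, 1, function(x) if (all(is.na(x))) NA_real_
            else min(x, na.rm = TRUE))
    })
    if (is.null(dim(dpanel))) dpanel <- matrix(dpanel, nrow = nt)
    colnames(dpanel) <- names(refs)
    for (h in seq_len(nt)) {
      dh <- dpanel[h, ]
      if (all(is.na(dh))) next
      o <- order(dh)
      best <- dh[o[1]]; second <- if (length(dh) > 1) dh[o[2]] else Inf
      if (!is.na(second) && second - best >= margin) {
        labels[h, wi] <- names(refs)[o[1]]
        gaps[h, wi] <- second - best
      }
    }
  }
  tracts <- list()
  for (h in seq_len(nt)) {
    lab <- labels[h, ]
    lab[is.na(lab)] <- ".unassigned"
    r <- rle(lab)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    for (i in which(r$values != ".unassigned")) {
      tracts[[length(tracts) + 1L]] <- data.frame(
        sample = target$sample_ids[ceiling(h / 2)],
        hap = ((h - 1L) %% 2L) + 1L,
        chrom = target$chrom,
        start = wb_start[s[i]], end = wb_end[e[i]],
        donor = r$values[i],
        margin = mean(gaps[h, s[i]:e[i]]))
    }
  }
  out <- do.call(rbind, tracts)
  if (is.null(out))
    out <- data.frame(sample = character(0), hap = integer(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), donor = character(0),
                      margin = numeric(0))
  out$length <- out$end - out$start
  out
}

#' Incomplete-lineage-sorting model for tract-length filtering
#'
#' Under recombination rate `r` (per bp per generation) and `t` generations
#' since donor/recipient divergence, ancestral segments surviving as shared
#' polymorphism have expected length `L = 1 / (r * t)`; the probability that
#' an ILS tract is at least `m` bp long follows the Gamma(shape 2,
#' rate 1/L) survival function `exp(-m/L) * (1 + m/L)`.
#'
#' @param r recombination rate per bp per generation.
#' @param t generations since divergence.
#' @param alpha filter level: tracts with ILS probability below `alpha`
#'   are accepted as introgressed.
#' @return an `ils_model` list with derived expected length `L`.
#' @export
ils_model <- function(r = 1e-8, t = 6.8e5, alpha = 0.05) {
  if (r <= 0 || t <= 0) stop("r and t must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(r = r, t = t, L = 1 / (r * t), alpha = alpha),
            class = "ils_model")
}

#' Probability that a tract of length m arose by incomplete lineage sorting
#'
#' `P(m) = exp(-m/L) * (1 + m/L)` with `L = 1/(r t)`: the survival function
#' at `m` of a Gamma(shape 2, rate 1/L) tract-length law. Monotone
#' decreasing in `m`; tends to 1 as `m` tends to 0.
#'
#' @param m tract length(s) in bp, positive.
#' @param model an [ils_model()].
#' @return probability vector, same length as `m`.
#' @export
ils_probability <- function(m, model) {
  stopifnot(inherits(model, "ils_model"))
  if (any(m <= 0)) stop("tract length must be positive")
  x <- m / model$L
  exp(-x) * (1 + x)
}

#' Filter ancestry tracts by ILS probability
#'
#' Records the ILS probability on every tract and retains those with
#' probability below `model$alpha`; discarded tracts are kept in the
#' `discarded` attribute.
#'
#' @param tracts data.frame from [local_ancestry()] with a `length` column.
#' @param model an [ils_model()].
#' @return retained tracts with an added `p_ils` column; discarded tracts
#'   (also with `p_ils`) in `attr(, "discarded")`.
#' @export
filter_tracts <- function(tracts, model) {
  if (!nrow(tracts)) {
    tracts$p_ils <- numeric(0)
    attr(tracts, "discarded") <- tracts
    return(tracts)
  }
  tracts$p_ils <- ils_probability(tracts$length, model)
  keep <- tracts$p_ils < model$alpha
  out <- tracts[keep, , drop = FALSE]
  attr(out, "discarded") <- tracts[!keep, , drop = FALSE]
  out
}

#' Per-sample introgression ratio and population summary
#'
#' Per sample and donor: total tract length over both haplotypes divided by
#' twice the callable genome length. Samples without tracts count as zero.
#'
#' @param tracts filtered tract data.frame (columns sample, donor, length).
#' @param samples character vector of all analysed samples.
#' @param callable_length callable genome length in bp (> 0).
#' @param donors donor labels to report (default: those present in
#'   `tracts`); a donor without tracts reports ratio 0 for every sample.
#' @return list: `per_sample` data.frame (sample, donor, ratio) and
#'   `summary` data.frame (donor, min, mean, max over samples).
#' @export
introgression_ratio <- function(tracts, samples, callable_length,
                                donors = unique(tracts$donor)) {
  if (callable_length <= 0) stop("callable_length must be positive")
  if (!length(donors)) donors <- "none"
  per <- expand.grid(sample = samples, donor = donors,
                     stringsAsFactors = FALSE)
  per$ratio <- mapply(function(s, d) {
    sum(tracts$length[tracts$sample == s & tracts$donor == d]) /
      (2 * callable_length)
  }, per$sample, per$donor)
  summ <- do.call(rbind, lapply(split(per, per$donor), function(g)
    data.frame(donor = g$donor[1], min = min(g$ratio),
               mean = mean(g$ratio), max = max(g$ratio))))
  list(per_sample = per, summary = `rownames<-`(summ, NULL))
}

#' Haplotype and tree confirmation of a candidate introgressed region
#'
#' Extracts region haplotypes from target, donor, control and outgroup
#' populations, orders them by hierarchical clustering on haplotype
#' p-distance, builds a neighbor-joining tree rooted on the outgroup, and
#' reports whether the target-plus-donor haplotypes form a monophyletic
#' clade, plus the fraction of target haplotypes whose nearest non-target
#' neighbour is a donor haplotype.
#'
#' @param panel merged [hap_panel()] holding all populations.
#' @param popmap named character vector sample -> population.
#' @param start,end 0-based half-open region bounds (>= 5 SNPs inside).
#' @param target,control,outgroup population labels.
#' @param donors character vector of donor population labels.
#' @return list: `tree` (rooted `phylo`), `order` (haplotype labels in
#'   clustering order), `donor_monophyly` (logical),
#'   `nearest_donor_fraction`, `distances` (haplotype p-distance matrix).
#' @export
region_confirm <- function(panel, popmap, start, end, target, control,
                           outgroup, donors) {
  reg <- subset_region(panel, start, end)
  if (n_sites(reg) < 5)
    stop("region holds ", n_sites(reg), " SNPs; need >= 5")
  keep_pops <- c(target, control, outgroup, donors)
  samples <- names(popmap)[popmap %in% keep_pops &
                             names(popmap) %in% reg$sample_ids]
  reg <- subset_samples(reg, samples)
  dm <- p_distance(reg, unit = "haplotype")
  hap_pop <- rep(unname(popmap[samples]), each = 2)
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  tr <- nj_tree(dm)
  og_tips <- rownames(dm)[hap_pop == outgroup]
  tr <- ape::root(tr, outgroup = og_tips, resolve.root = TRUE)
  dt_tips <- rownames(dm)[hap_pop %in% c(target, donors)]
  mono <- ape::is.monophyletic(tr, tips = dt_tips)
  tgt <- which(hap_pop == target)
  don <- which(hap_pop %in% donors)
  non_tgt <- setdiff(seq_len(nrow(dm)), tgt)
  nearest_donor <- vapply(tgt, function(i) {
    j <- non_tgt[which.min(dm[i, non_tgt])]
    j %in% don
  }, logical(1))
  list(tree = tr, order = hc$labels[hc$order], donor_monophyly = mono,
       nearest_donor_fraction = mean(nearest_donor), distances = dm)
}
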