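#' Windowed Tajima's D
#'
#' Standard Tajima (1989) D per window from the segregating-site count S and
#' the mean pairwise difference, with the a1, a2, b1, b2, c1, c2, e1, e2
#' constants computed from the haplotype count n. Sites with missing calls
#' are skipped; windows with S = 0 are reported NA.
#'
#' @param panel a [hap_panel()].
#' @param popmap named character vector sample -> population.
#' @param population population to analyse (needs >= 4 haplotypes).
#' @param size,step window and step size bp.
#' @return data.frame: chrom, start, end, n_sites (segregating), D.
#' @export
tajimas_d_windows <- function(panel, popmap, population, size = 50000,
                              step = 20000) {
  rows <- hap_rows(panel, samples_of(popmap, population))
  n <- length(rows)
  if (n < 4) stop("Tajima's D needs >= 4 haplotypes")
  a <- panel$alleles[rows, , drop = FALSE]
  full <- colSums(is.na(a)) == 0
  c1 <- colSums(a == 1L, na.rm = TRUE)
  seg <- full & c1 > 0 & c1 < n
  pos <- panel$positions[seg]
  c1 <- c1[seg]; c0 <- n - c1
  pairdiff <- c1 * c0 / (n * (n - 1) / 2)   # per-site mean pairwise diff
  w <- make_windows(panel$contig_length, size, step)
  sums <- window_sums(pos, pairdiff, w)
  S <- sums$n
  khat <- sums$sum
  cons <- tajima_constants(n)
  varD <- cons$e1 * S + cons$e2 * S * (S - 1)
  D <- ifelse(S > 0, (khat - S / cons$a1) / sqrt(varD), NA_real_)
  data.frame(chrom = panel$chrom, start = w$start, end = w$end,
             n_sites = S, D = D)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Returns per-site a, b, c vectors given diploid counts, alt frequencies and
# observed heterozygote fractions for each population.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 > 0 & n2 > 0 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) /
                                                 (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  list(a = a, b = b, c = cc, usable = ok)
}

pop_site_stats <- function(panel, popmap, population) {
  d <- dosage_matrix(subset_samples(panel,
                                    samples_of(popmap, population)))
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Windowed Weir-Cockerham F_ST between two populations
#'
#' Per-site variance components a, b, c (Weir & Cockerham 1984, diploid,
#' including the heterozygosity term); the window statistic is
#' `sum(a) / sum(a + b + c)` (VCFtools weighted F_ST). Negative windows are
#' permitted; windows with no usable site are NA.
#'
#' @param panel a [hap_panel()].
#' @param popmap named character vector sample -> population.
#' @param pop_a,pop_b the two populations (>= 2 diploids each).
#' @param size,step window and step size bp.
#' @return data.frame: chrom, start, end, n_sites, fst.
#' @export
fst_windows <- function(panel, popmap, pop_a, pop_b, size = 50000,
                        step = 20000) {
  sa <- pop_site_stats(panel, popmap, pop_a)
  sb <- pop_site_stats(panel, popmap, pop_b)
  if (max(sa$n) < 2 || max(sb$n) < 2)
    stop("both populations need >= 2 diploids")
  wc <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  w <- make_windows(panel$contig_length, size, step)
  num <- window_sums(panel$positions, wc$a, w)$sum
  den <- window_sums(panel$positions, wc$a + wc$b + wc$c, w)$sum
  nuse <- window_sums(panel$positions, as.numeric(wc$usable), w)$sum
  data.frame(chrom = panel$chrom, start = w$start, end = w$end,
             n_sites = nuse, fst = ifelse(den != 0, num / den, NA_real_))
}

#' Genome-wide weighted Weir-Cockerham F_ST
#' @inheritParams fst_windows
#' @return single numeric value `sum(a) / sum(a + b + c)` over all sites.
#' @export
fst_weighted <- function(panel, popmap, pop_a, pop_b) {
  sa <- pop_site_stats(panel, popmap, pop_a)
  sb <- pop_site_stats(panel, popmap, pop_b)
  wc <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  sum(wc$a) / sum(wc$a + wc$b + wc$c)
}

#' Cross-population extended haplotype homozygosity (XP-EHH) window scan
#'
#' For every core SNP with pooled minor-allele frequency of at least
#' `min_maf`, EHH of each population is extended in both directions until
#' the pooled-sample EHH falls below `cutoff` (or extension exceeds
#' `max_extend` bp or an inter-SNP gap exceeds `max_gap` bp); iHH is the
#' trapezoidal integral of EHH over bp, the raw score is
#' `ln(iHH_A / iHH_B)`, scores are z-normalized genome-wide, and the window
#' statistic is the mean normalized score of cores inside the window.
#' Positive scores indicate longer haplotypes (a sweep) in population A.
#'
#' @param panel a phased [hap_panel()] without missing calls in A and B.
#' @param popmap named character vector sample -> population.
#' @param pop_a,pop_b target and reference populations.
#' @param size,step window and step size bp.
#' @param cutoff EHH decay cutoff (selscan default 0.05).
#' @param max_extend maximum extension from the core, bp.
#' @param max_gap maximum tolerated inter-SNP gap, bp.
#' @param min_maf minimum pooled minor-allele frequency for a core.
#' @return list: `windows` data.frame (chrom, start, end, n_cores, xpehh),
#'   `scores` data.frame per core (pos, raw, norm), `n_skipped` cores with
#'   undefined iHH.
#' @export
xpehh_scan <- function(panel, popmap, pop_a, pop_b, size = 50000,
                       step = 20000, cutoff = 0.05, max_extend = 1e6,
                       max_gap = 2e5, min_maf = 0.05) {
  ra <- hap_rows(panel, samples_of(popmap, pop_a))
  rb <- hap_rows(panel, samples_of(popmap, pop_b))
  ha <- panel$alleles[ra, , drop = FALSE]
  hb <- panel$alleles[rb, , drop = FALSE]
  pooled <- rbind(ha, hb)
  pfreq <- colMeans(pooled, na.rm = TRUE)
  cores <- which(pmin(pfreq, 1 - pfreq) >= min_maf)
  raw <- rep(NA_real_, n_sites(panel))
  if (length(cores)) {
    raw[cores] <- xpehh_raw_cpp(ha, hb, as.numeric(panel$positions),
                                as.integer(cores - 1L), cutoff, max_extend,
                                max_gap)
  }
  defined <- !is.na(raw)
  n_skipped <- length(cores) - sum(defined)
  norm <- rep(NA_real_, length(raw))
  if (sum(defined) >= 2) {
    mu <- mean(raw[defined]); sdv <- stats::sd(raw[defined])
    norm[defined] <- (raw[defined] - mu) / sdv
  }
  w <- make_windows(panel$contig_length, size, step)
  ws <- window_sums(panel$positions[defined], norm[defined], w)
  windows <- data.frame(chrom = panel$chrom, start = w$start, end = w$end,
                        n_cores = ws$n,
                        xpehh = ifelse(ws$n > 0, ws$sum / ws$n, NA_real_))
  list(windows = windows,
       scores = data.frame(pos = panel$positions[defined],
                           raw = raw[defined], norm = norm[defined]),
       n_skipped = n_skipped)
}

#' Empirical-tail candidate windows
#'
#' Selects the `tail_fraction` extreme windows of a scan (low tail for
#' diversity-like statistics, high tail for differentiation-like ones);
#' ties at the cut value are included. Windows with undefined values are
#' ignored.
#'
#' @param stats data.frame with columns chrom, start, end and a statistic.
#' @param value_col name of the statistic column.
#' @param tail_fraction empirical tail size (default 0.005 = the 0.5% tail).
#' @param direction `"low"` or `"high"`.
#' @return subset of `stats` rows in the tail, with an added `rank` column
#'   (empirical quantile rank in [0, 1], extreme = small for the selected
#'   direction).
#' @export
empirical_candidates <- function(stats, value_col, tail_fraction = 0.005,
                                 direction = c("high", "low")) {
  direction <- match.arg(direction)
  v <- stats[[value_col]]
  def <- which(!is.na(v))
  if (length(def) < 1 / tail_fraction) {
    warning("too few windows (", length(def), ") for a ", tail_fraction,
            " tail; returning empty set")
    out <- stats[0, , drop = FALSE]; out$rank <- numeric(0)
    return(out)
  }
  x <- v[def]
  k <- max(1L, floor(tail_fraction * length(def)))
  sorted <- sort(x, decreasing = (direction == "high"))
  cut <- sorted[k]
  sel <- if (direction == "high") def[x >= cut] else def[x <= cut]
  out <- stats[sel, , drop = FALSE]
  r <- rank(x, ties.method = "min") / length(x)
  out$rank <- if (direction == "high") 1 - r[match(sel, def)] +
    1 / length(x) else r[match(sel, def)]
  out[order(out$start), , drop = FALSE]
}

#' Intersect candidate windows across methods into supported regions
#'
#' Takes one candidate-window set per method, finds the base pairs covered
#' by at least `min_methods` distinct methods, and merges them into maximal
#' regions, recording the union of supporting methods per region.
#'
#' @param candidates named list of data.frames with chrom, start, end.
#' @param min_methods minimum distinct supporting methods.
#' @return data.frame: chrom, start, end, methods (comma-joined), n_methods.
#' @export
intersect_methods <- function(candidates, min_methods = 2) {
  stopifnot(length(candidates) >= 2, !is.null(names(candidates)))
  iv <- do.call(rbind, lapply(names(candidates), function(m) {
    d <- candidates[[m]]
    if (!nrow(d)) return(NULL)
    data.frame(chrom = d$chrom, start = d$start, end = d$end, method = m)
  }))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), methods = character(0),
                      n_methods = integer(0))
  if (is.null(iv) || !nrow(iv)) return(empty)
  out <- lapply(split(iv, iv$chrom), function(ivc) {
    bounds <- sort(unique(c(ivc$start, ivc$end)))
    segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
    support <- lapply(seq_len(nrow(segs)), function(i) {
      hit <- ivc$start < segs$end[i] & ivc$end > segs$start[i]
      unique(ivc$method[hit])
    })
    keep <- vapply(support, length, integer(1)) >= min_methods
    if (!any(keep)) return(NULL)
    segs <- segs[keep, , drop = FALSE]
    support <- support[keep]
    # merge touching/overlapping qualifying segments
    merged <- list()
    cur <- c(segs$start[1], segs$end[1]); meth <- support[[1]]
    if (nrow(segs) > 1) for (i in 2:nrow(segs)) {
      if (segs$start[i] <= cur[2]) {
        cur[2] <- max(cur[2], segs$end[i])
        meth <- union(meth, support[[i]])
      } else {
        merged[[length(merged) + 1]] <- list(cur, meth)
        cur <- c(segs$start[i], segs$end[i]); meth <- support[[i]]
      }
    }
    merged[[length(merged) + 1]] <- list(cur, meth)
    do.call(rbind, lapply(merged, function(m)
      data.frame(chrom = ivc$chrom[1], start = m[[1]][1], end = m[[1]][2],
                 methods = paste(sort(m[[2]]), collapse = ","),
                 n_methods = length(m[[2]]))))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Read a BED file of gene intervals
#'
#' @param path BED with at least 4 columns: chrom, start, end, name
#'   (0-based half-open).
#' @return data.frame: chrom, start, end, gene.
#' @export
read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 4)
      stop("malformed BED line ", i, ": expected >= 4 fields")
    st <- suppressWarnings(as.numeric(f[2]))
    en <- suppressWarnings(as.numeric(f[3]))
    if (is.na(st) || is.na(en) || en <= st)
      stop("malformed BED line ", i, ": bad interval")
    data.frame(chrom = f[1], start = st, end = en, gene = f[4])
  })
  do.call(rbind, out)
}

#' Genes overlapping candidate regions
#'
#' Reports genes with at least 1 bp overlap with each region, using
#' half-open interval semantics (a gene abutting a region end does not
#' overlap).
#'
#' @param regions data.frame with chrom, start, end.
#' @param genes data.frame from [read_gene_bed()] (or a path to a BED file).
#' @return data.frame: region_index, chrom, start, end, gene.
#' @export
genes_in_regions <- function(regions, genes) {
  if (is.character(genes)) genes <- read_gene_bed(genes)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    if (!any(hit)) return(NULL)
    data.frame(region_index = i, chrom = regions$chrom[i],
               start = regions$start[i], end = regions$end[i],
               gene = genes$gene[hit])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(region_index = integer(0), chrom = character(0),
               start = numeric(0), end = numeric(0), gene = character(0))
  else `rownames<-`(out, NULL)
}
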