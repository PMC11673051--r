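#' Read a phased VCF and population map into a haplotype panel
#'
#' Biallelic SNP records are retained; multiallelic, indel and non-SNP
#' records are dropped with a count reported in the result. Positions are
#' converted from 1-based VCF POS to the 0-based internal convention.
#' The panel covers one contig; a VCF with several chromosomes is rejected
#' (split upstream with bcftools if needed).
#'
#' @param path VCF file (v4.x, optionally gzipped).
#' @param popmap_path TSV `sample<TAB>population`; every VCF sample must be
#'   mapped.
#' @param require_phased error if any called genotype is unphased.
#' @return list: `panel` ([hap_panel()]), `popmap` (named character vector),
#'   `n_excluded` (records dropped by the biallelic-SNP filter).
#' @export
read_vcf <- function(path, popmap_path, require_phased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!snp)
  fix <- fix[snp, , drop = FALSE]
  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) > 1)
    stop("panel covers one contig; VCF has: ", paste(chroms, collapse = ", "))
  gt <- vcfR::extract.gt(v)[snp, , drop = FALSE]
  samples <- colnames(gt)
  pm <- read_popmap(popmap_path)
  missing_map <- setdiff(samples, names(pm))
  if (length(missing_map))
    stop("samples absent from population map: ",
         paste(missing_map, collapse = ", "))
  if (require_phased) {
    unphased <- grepl("/", gt) & !gt %in% c("./.", ".")
    if (any(unphased, na.rm = TRUE))
      stop("unphased genotypes present but phased GT required (",
           sum(unphased, na.rm = TRUE), " calls)")
  }
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  k <- nrow(gt); ns <- length(samples)
  al <- matrix(NA_integer_, nrow = 2L * ns, ncol = k)
  al[seq(1L, 2L * ns, 2L), ] <- t(matrix(a1, nrow = k))
  al[seq(2L, 2L * ns, 2L), ] <- t(matrix(a2, nrow = k))
  pos <- as.integer(fix[, "POS"]) - 1L
  ord <- order(pos)
  contig_length <- NULL
  meta <- v@meta
  cl <- regmatches(meta, regexec("##contig=<ID=[^,>]+,length=([0-9]+)", meta))
  cl <- unlist(lapply(cl, function(x) if (length(x) == 2) x[2] else NULL))
  if (length(cl)) contig_length <- as.numeric(cl[1])
  panel <- hap_panel(al[, ord, drop = FALSE], pos[ord],
                     chrom = if (k) fix[1, "CHROM"] else "1",
                     sample_ids = samples, contig_length = contig_length)
  list(panel = panel, popmap = pm[samples], n_excluded = n_excluded)
}

#' Read a sample-to-population map TSV
#' @param path TSV with two columns: sample, population (no header).
#' @return named character vector, sample -> population.
#' @export
read_popmap <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character")
  if (ncol(d) < 2) stop("popmap must have two tab-separated columns")
  if (any(!nzchar(d[[2]]))) stop("empty population labels in popmap")
  stats::setNames(d[[2]], d[[1]])
}

#' Filter sites on missingness and minor-allele frequency
#'
#' @param panel a [hap_panel()].
#' @param max_missing maximum fraction of missing alleles allowed per site.
#' @param min_maf minimum minor-allele frequency over called alleles.
#' @return a [hap_panel()] with surviving sites, original coordinates kept.
#' @export
site_filter <- function(panel, max_missing = 1, min_maf = 0) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5)
  a <- panel$alleles
  n_tot <- nrow(a)
  miss <- colSums(is.na(a)) / n_tot
  n_called <- n_tot - colSums(is.na(a))
  p <- colSums(a == 1L, na.rm = TRUE) / pmax(n_called, 1)
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing & (min_maf == 0 | (n_called > 0 & maf >= min_maf))
  if (!any(keep))
    warning("all sites removed by site_filter")
  subset_sites(panel, which(keep))
}

#' Sliding genomic windows
#'
#' Windows are `[k*step, k*step + size)` for every k with `k*step <
#' contig_length`; the last window may overhang the contig end.
#'
#' @param contig_length contig length bp.
#' @param size window size bp.
#' @param step step size bp (0 < step <= size).
#' @return data.frame with 0-based half-open `start`, `end`.
#' @export
make_windows <- function(contig_length, size, step = size) {
  stopifnot(contig_length > 0, size > 0, step > 0, step <= size)
  starts <- (seq_len(ceiling(contig_length / step)) - 1) * step
  starts <- starts[starts < contig_length]
  data.frame(start = starts, end = starts + size)
}

# per-window sum and count of per-site values, via cumulative sums
window_sums <- function(positions, values, windows) {
  cs <- c(0, cumsum(values))
  cn <- c(0, seq_along(values))
  i1 <- findInterval(windows$start - 0.5, positions) + 1L
  i2 <- findInterval(windows$end - 0.5, positions)
  list(sum = cs[i2 + 1L] - cs[i1], n = cn[i2 + 1L] - cn[i1])
}

#' PLINK-style greedy LD pruning
#'
#' Within each window of `snp_window` surviving SNPs, advancing by
#' `snp_step`, one of every pair with squared dosage correlation above
#' `r2_threshold` is removed (the later-position SNP); passes repeat until
#' no removal occurs. Matches `--indep-pairwise 50 10 0.1` semantics with
#' genotype-dosage r-squared.
#'
#' @param panel a [hap_panel()] with at least 2 sites.
#' @param snp_window window size in SNPs.
#' @param snp_step step in SNPs.
#' @param r2_threshold removal threshold on r-squared.
#' @return pruned [hap_panel()].
#' @export
ld_prune <- function(panel, snp_window = 50, snp_step = 10,
                     r2_threshold = 0.1) {
  k <- n_sites(panel)
  if (k < 2) return(panel)
  d <- dosage_matrix(panel)
  keep <- rep(TRUE, k)
  repeat {
    removed <- FALSE
    cur <- which(keep)
    i <- 1L
    while (i <= length(cur)) {
      win <- cur[i:min(i + snp_window - 1L, length(cur))]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r <- suppressWarnings(stats::cor(d[, win, drop = FALSE],
                                         use = "pairwise.complete.obs"))
        r2 <- r^2
        for (ai in seq_len(length(win) - 1L)) {
          if (!keep[win[ai]]) next
          for (bi in seq((ai + 1L), length(win))) {
            if (!keep[win[bi]]) next
            v <- r2[ai, bi]
            if (!is.na(v) && v > r2_threshold) {
              keep[win[bi]] <- FALSE     # later-position SNP removed
              removed <- TRUE
            }
          }
        }
      }
      i <- i + snp_step
    }
    if (!removed) break
  }
  subset_sites(panel, which(keep))
}

#' Per-population allele frequencies, optionally polarized by an outgroup
#'
#' Computes per-site alternate-allele frequency `p` and called allele count
#' `n` for every population in the map. If `outgroup` is given, sites are
#' polarized so that the outgroup major allele is ancestral: where the
#' outgroup alternate frequency exceeds 0.5 all frequencies are complemented
#' (derived = reference allele). Exact 0.5 ties keep the alternate allele as
#' derived and are flagged.
#'
#' @param panel a [hap_panel()].
#' @param popmap named character vector sample -> population.
#' @param outgroup optional population label used for polarization.
#' @return object of class `site_freqs`: list with matrices `p`, `n`
#'   (populations x sites), `positions`, `chrom`, logical `flipped` and
#'   `tie_flag` per site, and `polarized` flag.
#' @export
allele_freqs <- function(panel, popmap, outgroup = NULL) {
  pops <- unique(unname(popmap[panel$sample_ids]))
  if (anyNA(pops)) stop("panel samples missing from popmap")
  if (!is.null(outgroup) && !outgroup %in% pops)
    stop("outgroup population not in panel: ", outgroup)
  k <- n_sites(panel)
  pm <- matrix(NA_real_, nrow = length(pops), ncol = k,
               dimnames = list(pops, NULL))
  nm <- matrix(0L, nrow = length(pops), ncol = k, dimnames = list(pops, NULL))
  for (pop in pops) {
    rows <- hap_rows(panel, samples_of(popmap, pop))
    a <- panel$alleles[rows, , drop = FALSE]
    n <- colSums(!is.na(a))
    c1 <- colSums(a == 1L, na.rm = TRUE)
    pm[pop, ] <- ifelse(n > 0, c1 / n, NA_real_)
    nm[pop, ] <- n
  }
  flipped <- rep(FALSE, k)
  tie_flag <- rep(FALSE, k)
  if (!is.null(outgroup)) {
    po <- pm[outgroup, ]
    flipped <- !is.na(po) & po > 0.5
    tie_flag <- !is.na(po) & po == 0.5
    pm[, flipped] <- 1 - pm[, flipped]
  }
  structure(list(p = pm, n = nm, positions = panel$positions,
                 chrom = panel$chrom, contig_length = panel$contig_length,
                 polarized = !is.null(outgroup), outgroup = outgroup,
                 flipped = flipped, tie_flag = tie_flag),
            class = "site_freqs")
}
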