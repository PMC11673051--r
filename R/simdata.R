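#' Founder haplotype pool
#'
#' Draws a pool of founder haplotypes on a single contig. The number of
#' polymorphic sites is Poisson(`seq_length * mut_rate_per_bp`); positions
#' are uniform without replacement (0-based); each site gets a base allele
#' frequency drawn uniformly on (0.05, 0.95) and founder alleles are
#' independent Bernoulli draws at that frequency. Founders are in linkage
#' equilibrium by construction; linkage disequilibrium in descendant
#' populations arises from mosaic copying out of this finite pool
#' (see [descend_population()]).
#'
#' @param n_founders number of founder haplotypes (even, >= 2).
#' @param seq_length contig length in bp.
#' @param mut_rate_per_bp expected polymorphic sites per bp.
#' @param seed integer seed; identical seeds give bit-identical pools.
#' @return a [hap_panel()].
#' @export
make_founders <- function(n_founders, seq_length, mut_rate_per_bp, seed) {
  if (n_founders < 2 || n_founders %% 2 != 0)
    stop("n_founders must be an even number >= 2")
  if (seq_length <= 0) stop("seq_length must be positive")
  if (mut_rate_per_bp < 0) stop("mut_rate_per_bp must be non-negative")
  set.seed(seed)
  k <- stats::rpois(1, seq_length * mut_rate_per_bp)
  k <- min(k, seq_length)
  if (k == 0) {
    return(hap_panel(matrix(integer(0), nrow = n_founders, ncol = 0),
                     integer(0), contig_length = seq_length))
  }
  pos <- sort(sample.int(seq_length, k)) - 1L
  p <- stats::runif(k, 0.05, 0.95)
  al <- matrix(stats::rbinom(n_founders * k, 1L, rep(p, each = n_founders)),
               nrow = n_founders, ncol = k)
  hap_panel(al, pos, contig_length = seq_length)
}

#' Population specification for descent from a founder pool
#'
#' @param name unique population label.
#' @param n_diploids number of diploid samples to generate (>= 1).
#' @param drift_F Balding-Nichols divergence from the founder allele
#'   frequencies, in `[0, 1)`. 0 means copying from the pool as-is.
#' @param private_mut_rate per-bp per-haplotype rate of private allele flips
#'   at existing sites.
#' @return a `population_spec` list.
#' @export
population_spec <- function(name, n_diploids, drift_F = 0,
                            private_mut_rate = 0) {
  if (n_diploids < 1) stop("n_diploids must be >= 1")
  if (drift_F < 0 || drift_F >= 1) stop("drift_F must be in [0, 1)")
  if (private_mut_rate < 0) stop("private_mut_rate must be non-negative")
  structure(list(name = as.character(name), n_diploids = as.integer(n_diploids),
                 drift_F = drift_F, private_mut_rate = private_mut_rate),
            class = "population_spec")
}

# Balding-Nichols frequency drift applied to a copy of the pool: per site,
# draw the population frequency from Beta(p(1-F)/F, (1-p)(1-F)/F) around the
# pool frequency p, then flip the minimum number of pool alleles to match.
# Flipping (rather than redrawing alleles i.i.d.) keeps founder haplotype
# segments mostly intact, so descendants still carry pool LD.
drift_pool <- function(pool, F_st) {
  if (F_st == 0 || ncol(pool) == 0) return(pool)
  n <- nrow(pool)
  p0 <- colMeans(pool)
  shape_scale <- (1 - F_st) / F_st
  pt <- p0
  seg <- p0 > 0 & p0 < 1
  pt[seg] <- stats::rbeta(sum(seg), p0[seg] * shape_scale,
                          (1 - p0[seg]) * shape_scale)
  target <- round(pt * n)
  cur <- as.integer(round(p0 * n))
  for (j in which(target != cur)) {
    d <- target[j] - cur[j]
    if (d > 0) {
      zeros <- which(pool[, j] == 0L)
      pool[sample(zeros, min(d, length(zeros))), j] <- 1L
    } else {
      ones <- which(pool[, j] == 1L)
      pool[sample(ones, min(-d, length(ones))), j] <- 0L
    }
  }
  pool
}

#' Descend a population from a founder pool by mosaic copying
#'
#' Generates `2 * n_diploids` haplotypes, each a crossover mosaic of pool
#' haplotypes: crossover count per haplotype is
#' Poisson(`recomb_rate * contig_length * generations`), breakpoints uniform,
#' and each segment copies a uniformly chosen pool haplotype. Optional
#' Balding-Nichols drift (`drift_F`) perturbs pool allele frequencies first;
#' private mutations then flip alleles at existing sites at rate
#' `private_mut_rate` per bp per haplotype.
#'
#' With `recomb_rate = 0`, `private_mut_rate = 0` and `drift_F = 0`, every
#' output haplotype is an exact copy of one founder.
#'
#' @param founders a [hap_panel()] acting as the copying pool.
#' @param spec a [population_spec()].
#' @param recomb_rate crossovers per bp per meiosis.
#' @param generations generations since the pool; scales crossover counts.
#' @param seed integer seed.
#' @return a [hap_panel()] with sample ids `<name>_001 ...`.
#' @export
descend_population <- function(founders, spec, recomb_rate, generations, seed) {
  if (n_haps(founders) == 0) stop("founder panel is empty")
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  L <- founders$contig_length
  pool <- drift_pool(founders$alleles, spec$drift_F)
  n_out <- 2L * spec$n_diploids
  k <- ncol(pool)
  out <- matrix(0L, nrow = n_out, ncol = k)
  lambda_cx <- recomb_rate * L * generations
  pos <- founders$positions
  for (h in seq_len(n_out)) {
    ncx <- stats::rpois(1, lambda_cx)
    if (ncx == 0 || k == 0) {
      out[h, ] <- pool[sample.int(nrow(pool), 1), ]
    } else {
      bp <- sort(stats::runif(ncx, 0, L))
      seg <- findInterval(pos, bp) + 1L           # segment index per site
      src <- sample.int(nrow(pool), ncx + 1L, replace = TRUE)
      for (s in unique(seg))
        out[h, seg == s] <- pool[src[s], seg == s]
    }
  }
  if (spec$private_mut_rate > 0 && k > 0) {
    for (h in seq_len(n_out)) {
      nm <- min(stats::rpois(1, spec$private_mut_rate * L), k)
      if (nm > 0) {
        j <- sample.int(k, nm)
        out[h, j] <- 1L - out[h, j]
      }
    }
  }
  hap_panel(out, founders$positions, chrom = founders$chrom,
            sample_ids = sprintf("%s_%03d", spec$name,
                                 seq_len(spec$n_diploids)),
            contig_length = L)
}

new_truth_set <- function(tracts = NULL, sweeps = NULL) {
  if (is.null(tracts))
    tracts <- data.frame(sample = character(0), hap = integer(0),
                         chrom = character(0), start = numeric(0),
                         end = numeric(0), donor = character(0))
  if (is.null(sweeps))
    sweeps <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
  structure(list(tracts = tracts, sweeps = sweeps), class = "truth_set")
}

#' Implant donor tracts of known location into a recipient panel
#'
#' Copies donor haplotype segments into recipient haplotypes until the total
#' implanted length reaches `fraction` of the recipient's total haploid
#' genome length (`n_haps * contig_length`). Tract lengths are exponential
#' with mean `tract_len_mean`; the last tract is trimmed so the realised
#' genome share equals `fraction` to within 1 bp. Tracts never overlap on a
#' haplotype. Every tract is recorded in the returned truth set.
#'
#' @param recipient,donor [hap_panel()]s sharing one site map.
#' @param fraction target genome share of donor ancestry, in (0, 1).
#' @param tract_len_mean mean tract length in bp.
#' @param seed integer seed.
#' @param donor_label label recorded in the truth set.
#' @return list with elements `panel` (modified recipient) and `truth`
#'   (a truth set whose `tracts` data frame has columns
#'   sample, hap, chrom, start, end, donor; 0-based half-open).
#' @export
implant_introgression <- function(recipient, donor, fraction, tract_len_mean,
                                  seed, donor_label = "donor") {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  if (!identical(recipient$positions, donor$positions))
    stop("recipient and donor must share the site map")
  set.seed(seed)
  L <- recipient$contig_length
  nh <- n_haps(recipient)
  target_total <- fraction * nh * L
  if (target_total < 1)
    return(list(panel = recipient, truth = new_truth_set()))
  tracts <- vector("list", 0)
  per_hap <- vector("list", nh)      # existing intervals per haplotype
  implanted <- 0
  attempts <- 0
  while (implanted < target_total && attempts < 1e5) {
    attempts <- attempts + 1
    h <- sample.int(nh, 1)
    len <- max(1, round(stats::rexp(1, 1 / tract_len_mean)))
    len <- min(len, L)
    start <- floor(stats::runif(1, 0, L - len + 1))
    end <- start + len
    iv <- per_hap[[h]]
    if (!is.null(iv) && any(start < iv[, 2] & end > iv[, 1])) next
    if (implanted + len > target_total) {          # trim final tract
      len <- round(target_total - implanted)
      if (len < 1) break
      end <- start + len
      if (!is.null(iv) && any(start < iv[, 2] & end > iv[, 1])) next
    }
    d <- sample.int(n_haps(donor), 1)
    sites <- which(recipient$positions >= start & recipient$positions < end)
    if (length(sites))
      recipient$alleles[h, sites] <- donor$alleles[d, sites]
    per_hap[[h]] <- rbind(iv, c(start, end))
    tracts[[length(tracts) + 1L]] <-
      data.frame(sample = recipient$sample_ids[ceiling(h / 2)],
                 hap = ((h - 1L) %% 2L) + 1L,
                 chrom = recipient$chrom, start = start, end = end,
                 donor = donor_label)
    implanted <- implanted + len
  }
  truth <- new_truth_set(tracts = do.call(rbind, tracts))
  list(panel = recipient, truth = truth)
}

#' Implant a hard sweep: one core haplotype shared by a carrier fraction
#'
#' Overwrites the region `[start, end)` of a random subset of haplotypes
#' (rounded `carrier_fraction * n_haps`) with one identical core haplotype
#' drawn from the panel, and records the region in a truth set.
#'
#' @param panel a [hap_panel()].
#' @param start,end 0-based half-open sweep region bounds in bp.
#' @param carrier_fraction fraction of haplotypes carrying the core, in (0, 1].
#' @param seed integer seed.
#' @return list with elements `panel` and `truth`.
#' @export
implant_sweep <- function(panel, start, end, carrier_fraction, seed) {
  if (start < 0 || end > panel$contig_length || start >= end)
    stop("sweep region outside contig bounds")
  if (carrier_fraction <= 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in (0, 1]")
  set.seed(seed)
  nh <- n_haps(panel)
  sites <- which(panel$positions >= start & panel$positions < end)
  core <- panel$alleles[sample.int(nh, 1), sites]
  carriers <- sample.int(nh, round(carrier_fraction * nh))
  for (h in carriers) panel$alleles[h, sites] <- core
  truth <- new_truth_set(sweeps = data.frame(chrom = panel$chrom,
                                             start = start, end = end))
  list(panel = panel, truth = truth)
}

#' Write panels as a phased VCF v4.2 plus a population map TSV
#'
#' Consecutive haplotype pairs form diploid samples; genotypes are emitted
#' phased (`0|1`). Internal 0-based positions become 1-based VCF POS. All
#' records are biallelic SNPs (REF A, ALT T). Reading the files back with
#' [read_vcf()] reproduces the allele matrices exactly.
#'
#' @param panels named list of [hap_panel()]s sharing one site map; names
#'   become population labels.
#' @param vcf_path,popmap_path output file paths.
#' @return invisibly, the merged panel + popmap (as from [bind_panels()]).
#' @export
export_vcf <- function(panels, vcf_path, popmap_path) {
  m <- bind_panels(panels)
  p <- m$panel
  ns <- length(p$sample_ids)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", p$chrom,
            as.integer(p$contig_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", p$sample_ids), collapse = "\t"))
  a1 <- p$alleles[seq(1L, 2L * ns, 2L), , drop = FALSE]
  a2 <- p$alleles[seq(2L, 2L * ns, 2L), , drop = FALSE]
  g1 <- ifelse(is.na(a1), ".", a1)
  g2 <- ifelse(is.na(a2), ".", a2)
  gt <- matrix(paste0(g1, "|", g2), nrow = ns)
  body <- vapply(seq_len(n_sites(p)), function(j) {
    paste(c(p$chrom, p$positions[j] + 1L, ".", "A", "T", ".", "PASS", ".",
            "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)
  utils::write.table(data.frame(sample = p$sample_ids, pop = m$popmap),
                     popmap_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(m)
}

#' Write a truth set's tracts as a BED-like file
#'
#' Columns: chrom, start, end, `sample|hap`, donor, `.` (0-based half-open).
#' @param truth a truth set from [implant_introgression()].
#' @param path output path.
#' @export
write_truth_bed <- function(truth, path) {
  tr <- truth$tracts
  utils::write.table(
    data.frame(tr$chrom, tr$start, tr$end, paste0(tr$sample, "|", tr$hap),
               tr$donor, "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Simulate a multi-population bovine cohort with truth-tracked introgression
#'
#' Builds the study design end to end: a founder pool; an indicine ancestral
#' pool; five terminal populations — recipient ("xiangnan"-like) and control
#' indicine descending from the indicine pool, plus taurine, donor
#' (banteng-like) and outgroup (buffalo-like) descending from the founders at
#' increasing Balding-Nichols divergence — then an optional donor pulse into
#' the recipient and an optional hard sweep.
#'
#' Default divergence settings (drift F): indicine pool 0.05; recipient and
#' control 0.02 each on top of the pool; taurine 0.25; donor 0.5 (species
#' level); outgroup 0.7. Default sizes follow the study design at reduced
#' scale: 16 recipient,
#' 15 control, 10 taurine, 8 donor, 2 outgroup diploids.
#'
#' @param seed integer master seed; every stage derives its own stream.
#' @param seq_length contig length bp.
#' @param mut_rate polymorphic-site rate per bp.
#' @param n_founders founder haplotype count.
#' @param recomb_rate crossovers per bp per meiosis.
#' @param generations generations of mosaic descent per branch.
#' @param intro_fraction donor genome share to implant into the recipient
#'   (0 disables the pulse).
#' @param tract_len_mean mean implanted tract length bp.
#' @param sweep_region optional `c(start, end)` for a hard sweep in the
#'   recipient (NULL disables).
#' @param sweep_carrier carrier fraction for the sweep.
#' @param donor_sub_rate per-bp density of donor-lineage substitution sites:
#'   positions fixed for the derived allele in the donor and ancestral in
#'   every other population (a scaled-down stand-in for the ~0.006/bp
#'   divergence between banteng and domestic cattle). These are the
#'   diagnostic sites that the U statistic and local-ancestry assignment
#'   rely on.
#' @param sizes named integer vector of diploid counts per population.
#' @param drift named numeric vector of drift F per branch.
#' @return list: `panels` (named list of [hap_panel()]), `panel` + `popmap`
#'   (merged), `truth` (tracts + sweeps), `params` (echo of all settings).
#' @export
simulate_cohort <- function(seed,
                            seq_length = 5e6,
                            mut_rate = 2e-3,
                            n_founders = 100,
                            recomb_rate = 1e-8,
                            generations = 200,
                            intro_fraction = 0.06,
                            tract_len_mean = 5e4,
                            sweep_region = NULL,
                            sweep_carrier = 0.9,
                            donor_sub_rate = 2e-4,
                            sizes = c(xiangnan = 16, indicine = 15,
                                      taurine = 10, banteng = 8, outgroup = 2),
                            drift = c(indicine_pool = 0.05, terminal = 0.02,
                                      taurine = 0.25, banteng = 0.5,
                                      outgroup = 0.7)) {
  seeds <- seed + seq(0, 9) * 1009L
  founders <- make_founders(n_founders, seq_length, mut_rate, seeds[1])
  ind_pool <- descend_population(
    founders, population_spec("indpool", 30, drift[["indicine_pool"]]),
    recomb_rate, generations, seeds[2])
  panels <- list(
    xiangnan = descend_population(
      ind_pool, population_spec("XN", sizes[["xiangnan"]],
                                drift[["terminal"]]),
      recomb_rate, generations, seeds[3]),
    indicine = descend_population(
      ind_pool, population_spec("IND", sizes[["indicine"]],
                                drift[["terminal"]]),
      recomb_rate, generations, seeds[4]),
    taurine = descend_population(
      founders, population_spec("TAU", sizes[["taurine"]],
                                drift[["taurine"]]),
      recomb_rate, generations, seeds[5]),
    banteng = descend_population(
      founders, population_spec("BAN", sizes[["banteng"]],
                                drift[["banteng"]]),
      recomb_rate, generations, seeds[6]),
    outgroup = descend_population(
      founders, population_spec("OUT", sizes[["outgroup"]],
                                drift[["outgroup"]]),
      recomb_rate, generations, seeds[7]))
  if (donor_sub_rate > 0) {
    set.seed(seeds[10])
    k_sub <- stats::rpois(1, seq_length * donor_sub_rate)
    free <- setdiff(seq_len(seq_length) - 1L, founders$positions)
    sub_pos <- sort(sample(free, min(k_sub, length(free))))
    panels <- lapply(names(panels), function(nm)
      insert_fixed_sites(panels[[nm]], sub_pos,
                         allele = if (nm == "banteng") 1L else 0L))
    names(panels) <- c("xiangnan", "indicine", "taurine", "banteng",
                       "outgroup")
  }
  truth <- new_truth_set()
  if (intro_fraction > 0) {
    imp <- implant_introgression(panels$xiangnan, panels$banteng,
                                 intro_fraction, tract_len_mean, seeds[8],
                                 donor_label = "banteng")
    panels$xiangnan <- imp$panel
    truth$tracts <- imp$truth$tracts
  }
  if (!is.null(sweep_region)) {
    sw <- implant_sweep(panels$xiangnan, sweep_region[1], sweep_region[2],
                        sweep_carrier, seeds[9])
    panels$xiangnan <- sw$panel
    truth$sweeps <- sw$truth$sweeps
  }
  m <- bind_panels(panels)
  list(panels = panels, panel = m$panel, popmap = m$popmap, truth = truth,
       params = list(seed = seed, seq_length = seq_length,
                     mut_rate = mut_rate, n_founders = n_founders,
                     recomb_rate = recomb_rate, generations = generations,
                     intro_fraction = intro_fraction,
                     tract_len_mean = tract_len_mean,
                     sweep_region = sweep_region,
                     sweep_carrier = sweep_carrier,
                     donor_sub_rate = donor_sub_rate,
                     sizes = sizes, drift = drift))
}
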