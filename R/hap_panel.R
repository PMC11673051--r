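#' Phased haplotype panel
#'
#' The universal carrier between pipeline stages: a haplotypes x sites matrix
#' of 0/1 alleles (NA = missing), with strictly increasing 0-based positions,
#' a single chromosome label, and sample identifiers. Haplotype rows `2i-1`
#' and `2i` belong to diploid sample `i`, so truth tracts and VCF samples map
#' to rows deterministically.
#'
#' Internal coordinates are 0-based half-open throughout; conversion to
#' 1-based happens only at the VCF boundary.
#'
#' @param alleles integer matrix (haplotypes x sites) over \{0, 1, NA\}.
#' @param positions integer vector of 0-based site positions, strictly
#'   increasing, one per matrix column.
#' @param chrom single chromosome label.
#' @param sample_ids character vector; `length(sample_ids) * 2 == nrow(alleles)`.
#' @param contig_length total contig length in bp (used for windowing and
#'   tract accounting); defaults to one past the last site.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(alleles, positions, chrom = "1", sample_ids = NULL,
                      contig_length = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (ncol(alleles) != length(positions))
    stop("column count (", ncol(alleles), ") != number of positions (",
         length(positions), ")")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("alleles must be 0, 1 or NA")
  if (is.null(sample_ids)) {
    if (nrow(alleles) %% 2L != 0L)
      stop("odd haplotype count with no sample_ids given")
    sample_ids <- sprintf("S%03d", seq_len(nrow(alleles) %/% 2L))
  }
  if (length(sample_ids) * 2L != nrow(alleles))
    stop("sample_ids length * 2 must equal haplotype count")
  if (is.null(contig_length))
    contig_length <- if (length(positions)) max(positions) + 1L else 1L
  structure(
    list(alleles = alleles, positions = positions, chrom = as.character(chrom),
         sample_ids = as.character(sample_ids),
         contig_length = as.numeric(contig_length)),
    class = "hap_panel")
}

#' @exportS3Method base::print
print.hap_panel <- function(x, ...) {
  cat("hap_panel:", nrow(x$alleles), "haplotypes (",
      length(x$sample_ids), "diploids ) x", ncol(x$alleles),
      "sites on", x$chrom, "( contig", x$contig_length, "bp )\n")
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel a `hap_panel`.
#' @return integer count.
#' @export
n_haps <- function(panel) nrow(panel$alleles)

#' @rdname n_haps
#' @export
n_sites <- function(panel) ncol(panel$alleles)

#' Subset a panel by site index or genomic region
#'
#' @param panel a `hap_panel`.
#' @param sites integer site indices to keep (in order).
#' @return a `hap_panel` with the selected columns.
#' @export
subset_sites <- function(panel, sites) {
  hap_panel(panel$alleles[, sites, drop = FALSE], panel$positions[sites],
            chrom = panel$chrom, sample_ids = panel$sample_ids,
            contig_length = panel$contig_length)
}

#' @rdname subset_sites
#' @param start,end 0-based half-open interval bounds in bp.
#' @export
subset_region <- function(panel, start, end) {
  keep <- which(panel$positions >= start & panel$positions < end)
  subset_sites(panel, keep)
}

#' Keep only the named samples (both haplotypes of each)
#' @param panel a `hap_panel`.
#' @param samples character vector of sample ids to keep.
#' @return a `hap_panel`.
#' @export
subset_samples <- function(panel, samples) {
  idx <- match(samples, panel$sample_ids)
  if (anyNA(idx))
    stop("samples not in panel: ",
         paste(samples[is.na(idx)], collapse = ", "))
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  hap_panel(panel$alleles[rows, , drop = FALSE], panel$positions,
            chrom = panel$chrom, sample_ids = samples,
            contig_length = panel$contig_length)
}

#' Diploid dosage matrix (samples x sites)
#'
#' Sums the two haplotype rows of each sample; a dosage is NA if either
#' allele is missing.
#' @param panel a `hap_panel`.
#' @return integer matrix samples x sites with values 0/1/2 or NA.
#' @export
dosage_matrix <- function(panel) {
  ns <- length(panel$sample_ids)
  a <- panel$alleles
  d <- a[seq(1L, 2L * ns, by = 2L), , drop = FALSE] +
       a[seq(2L, 2L * ns, by = 2L), , drop = FALSE]
  rownames(d) <- panel$sample_ids
  d
}

#' Row indices of the haplotypes belonging to given samples
#' @param panel a `hap_panel`.
#' @param samples character vector of sample ids.
#' @return integer vector of row indices into `panel$alleles`.
#' @export
hap_rows <- function(panel, samples) {
  idx <- match(samples, panel$sample_ids)
  if (anyNA(idx))
    stop("samples not in panel: ", paste(samples[is.na(idx)], collapse = ", "))
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Bind several panels sharing one site map into a single panel
#'
#' @param panels named list of `hap_panel` objects with identical positions
#'   and chromosome.
#' @return list with elements `panel` (the merged `hap_panel`) and `popmap`
#'   (named character vector sample -> population, populations taken from
#'   the list names).
#' @export
bind_panels <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 1, !is.null(names(panels)))
  ref <- panels[[1]]
  for (p in panels[-1]) {
    if (!identical(p$positions, ref$positions) ||
        !identical(p$chrom, ref$chrom))
      stop("panels do not share a site map")
  }
  ids <- unlist(lapply(panels, function(p) p$sample_ids), use.names = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sample ids across panels")
  al <- do.call(rbind, lapply(panels, function(p) p$alleles))
  pops <- rep(names(panels), vapply(panels, function(p)
    length(p$sample_ids), integer(1)))
  popmap <- stats::setNames(pops, ids)
  list(panel = hap_panel(al, ref$positions, chrom = ref$chrom,
                         sample_ids = ids,
                         contig_length = ref$contig_length),
       popmap = popmap)
}

# insert monomorphic columns (all `allele`) at new positions, keeping the
# site map sorted; used for lineage-specific substitution sites
insert_fixed_sites <- function(panel, positions, allele) {
  if (!length(positions)) return(panel)
  newm <- matrix(as.integer(allele), nrow = n_haps(panel),
                 ncol = length(positions))
  all_pos <- c(panel$positions, as.integer(positions))
  ord <- order(all_pos)
  hap_panel(cbind(panel$alleles, newm)[, ord, drop = FALSE], all_pos[ord],
            chrom = panel$chrom, sample_ids = panel$sample_ids,
            contig_length = panel$contig_length)
}

samples_of <- function(popmap, population) {
  s <- names(popmap)[popmap == population]
  if (!length(s)) stop("population not in map: ", population)
  s
}
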