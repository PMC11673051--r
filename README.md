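# bovintro

Selection scans and adaptive-introgression detection for bovine
population genomics.

Indigenous cattle breeds of tropical South China carry ancestry from wild
bovine species — banteng (*Bos javanicus*) and gaur (*Bos gaurus*) —
acquired through ancient hybridization, and this introgressed variation is
a candidate substrate for adaptation to heat, humidity and local
pathogens. `bovintro` packages the statistical machinery needed to study
such a system from a phased multi-sample VCF: who is related to whom, what
has been selected, and which haplotypes came from the wild donors rather
than from shared ancestral polymorphism.

The package is aimed at population geneticists who want every statistic in
one auditable code base, together with a simulator that plants known
truth — so calibration, power and parameter recovery are measurable
properties, not hopes.

## What it computes

**Diversity and structure** — windowed nucleotide diversity
θπ (VCFtools `--window-pi` semantics, 50 kb / 20 kb default), observed and
expected heterozygosity with the inbreeding coefficient *F* = 1 − Ho/He,
PLINK-style runs of homozygosity, LD decay in distance bins, p-distance
matrices with neighbor-joining trees, and smartPCA-style PCA on
Patterson-normalized dosages.

**Selection scans** — windowed Tajima's *D*; Weir–Cockerham
*F*<sub>ST</sub> (window value Σa / Σ(a+b+c)); XP-EHH with a C++ EHH
kernel (raw score ln(iHH<sub>A</sub>/iHH<sub>B</sub>), z-normalized
genome-wide, averaged per 50 kb window); empirical-tail candidate windows
(the 0.5% tail) intersected across methods into supported regions, with
gene overlap from a BED file.

**Adaptive introgression** — Patterson's *D* (ABBA–BABA) with a
delete-one block jackknife and *Z* score; the windowed
*U*<sub>control, target, donor</sub>(w, x, y) site count (default: donor
allele fixed, <1% in the control, >50% in the target); window-based local
ancestry against reference panels (a transparent nearest-haplotype
classifier with a margin rule); an incomplete-lineage-sorting filter that
keeps a tract of length *m* only when the Gamma(2) survival
e^(−m/L)(1 + m/L), with L = 1/(rt), falls below 0.05; per-sample
introgression ratios; and haplotype/NJ-tree confirmation of candidate
regions.

**Synthetic cohorts** — `simulate_cohort()` builds a five-population
design (recipient, control indicine, taurine, banteng-like donor,
outgroup) as haplotype mosaics with Balding–Nichols drift, donor-private
substitution sites, an admixture pulse of known genome share with
truth-recorded tract locations, and optional hard sweeps; `export_vcf()`
writes phased VCF v4.2 + population map that round-trip exactly through
`read_vcf()`.

## Worked example

Simulate the default cohort (5 Mb, ~10,000 SNPs, 51 diploids, a 6% banteng
pulse into the recipient), test for gene flow, and recover the implanted
fraction:

```r
library(bovintro)

sim <- simulate_cohort(seed = 11)
fr  <- allele_freqs(sim$panel, sim$popmap, outgroup = "outgroup")
patterson_d(fr, "indicine", "xiangnan", "banteng", "outgroup",
            block_size = 2.5e5)
#> Patterson's D ((indicine,xiangnan),banteng; outgroup outgroup):
#>   D = 0.0872, SE = 0.0102, Z = 8.53 (11009 sites, 20 blocks)

la   <- local_ancestry(sim$panels$xiangnan,
                       refs = list(taurine  = sim$panels$taurine,
                                   indicine = sim$panels$indicine,
                                   banteng  = sim$panels$banteng))
kept <- filter_tracts(la[la$donor == "banteng", ],
                      ils_model(r = 1e-8, t = 3e5))
introgression_ratio(kept, sim$panels$xiangnan$sample_ids,
                    sim$panel$contig_length, donors = "banteng")$summary
#>     donor       min       mean       max
#> 1 banteng 0.0212517 0.05674641 0.0889714
```

The *Z* = 8.53 rejects the no-gene-flow tree for the recipient; the
recovered mean donor share of 5.7% sits next to the 6.0% actually
implanted (the truth set records every tract, so the comparison is exact),
with per-sample ratios spanning 2–9% — the same order as the 5–8% banteng
ancestry reported in real South-Chinese cattle.

Selection scans follow the same pattern: `pi_windows()`,
`tajimas_d_windows()`, `fst_windows()` and `xpehh_scan()` emit per-window
tables; `empirical_candidates()` takes a tail; `intersect_methods()` and
`genes_in_regions()` turn multi-method support into annotated candidate
regions.

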