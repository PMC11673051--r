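---
title: "Methods: selection scans and adaptive-introgression detection in bovintro"
author: "bovintro maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans and adaptive-introgression detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bovintro` implements the statistical core of a cattle population-genomics
study design: diversity and structure statistics, four selection-scan
statistics with empirical-tail candidate calling, and an
adaptive-introgression stack (Patterson's D, the windowed U statistic,
window-based local ancestry, an incomplete-lineage-sorting tract filter,
per-sample introgression ratios, and haplotype/tree confirmation of
candidate regions). A haplotype-mosaic simulator with truth-tracked
introgressed tracts and sweeps makes every stage verifiable offline; all
analyses run from a phased multi-sample VCF plus a sample-to-population
map.

The intended system is a recipient domestic population (a South-Chinese
indicine breed, called "xiangnan" throughout the simulator), a control
indicine population, taurine cattle, wild donor species (banteng/gaur),
and a distant outgroup (buffalo-like) used to polarize alleles.

# The synthetic cohort generator

The generator is deliberately not a coalescent simulator. It is a
haplotype-mosaic model whose every feature maps to a quantity some
downstream statistic consumes, and whose ground truth (tract locations,
sweep regions) is recorded exactly.

1. **Founder pool** (`make_founders`): a Poisson(`L * mu`) number of
   biallelic sites at uniform positions; per-site base frequencies uniform
   on (0.05, 0.95); founder alleles i.i.d. Bernoulli. Founders are in
   linkage equilibrium; LD in descendants arises from copying out of this
   finite pool.
2. **Population descent** (`descend_population`): Balding–Nichols drift
   first perturbs pool frequencies — the population frequency at a site is
   Beta-distributed around the pool frequency with variance
   `F p (1 - p)` — implemented as minimal allele flips so founder segments
   stay intact; then each output haplotype is a crossover mosaic of pool
   haplotypes with Poisson(`r * L * generations`) breakpoints. Two
   populations drifted independently at the same `F` have expected
   Weir–Cockerham F_ST close to `F`, which is what the F_ST calibration
   test checks.
3. **Donor substitutions** (`simulate_cohort(donor_sub_rate = 2e-4)`):
   sites fixed for the derived allele in the donor and ancestral
   everywhere else, emulating the private substitutions a wild species
   accumulates after its split from domestic cattle. Real banteng–cattle
   divergence implies roughly 0.006 such differences per bp; the default
   2e-4 is a desk-scale density that still gives the U statistic and the
   local-ancestry classifier the diagnostic sites they rely on.
4. **Admixture pulse** (`implant_introgression`): donor haplotype segments
   with exponential lengths overwrite recipient haplotypes until the
   implanted share of the recipient genome equals the requested fraction
   (the last tract is trimmed, so the realised share is exact to 1 bp);
   every tract is recorded in the truth set. Tracts never overlap within a
   haplotype.
5. **Hard sweep** (`implant_sweep`): one core haplotype is copied into a
   chosen fraction of haplotypes over a region.

Default study conditions: contig 5 Mb; site density 2e-3/bp (about 10,000
SNPs); 100 founder haplotypes; recombination 1e-8 per bp per meiosis over
200 generations per branch; drift F of 0.05 for the shared indicine pool,
0.02 for each terminal indicine branch, 0.25 for taurine, 0.5 for the
donor and 0.7 for the outgroup (species-level divergence); 16 recipient,
15 control, 10 taurine, 8 donor and 2 outgroup diploids, mirroring the
motivating cohort at reduced scale. The admixture pulse defaults to 6%
with 50 kb mean tracts, inside the 5–8% range reported for real
banteng/gaur ancestry in South-Chinese cattle.

What the generator does **not** emulate: demographic histories (growth,
bottlenecks), mutation at new sites post-split (other than the donor
substitution layer), sequencing error, unphased or missing genotypes, and
multi-chromosome genomes. Tests passing on this cohort therefore show the
statistics are computed correctly and are well calibrated under clean
conditions; they do not certify behaviour under real-data pathologies
(genotyping error, phasing switch errors, reference bias).

# Diversity and structure statistics

- **Windowed nucleotide diversity**: per-site
  `pi = 2 c0 c1 / (n (n - 1))` over called alleles, summed per window and
  divided by the window size in bp (VCFtools `--window-pi` semantics).
  Windows default to 50 kb with a 20 kb step everywhere in the package.
- **Heterozygosity and F**: `Ho` is the mean observed heterozygote
  fraction, `He` the mean unbiased expected heterozygosity
  `2 p (1-p) n/(n-1)`, and `F = 1 - Ho/He`. The unbiased `n/(n-1)`
  correction is a package choice; the defining formula leaves it open.
  Because "inbreeding per variety" can be read per-population or
  per-individual, both are emitted; the per-population aggregate is
  labelled primary.
- **Runs of homozygosity**: a PLINK-style scan with 50-SNP windows, at
  most 1 heterozygote per window, a 0.05 window-hit threshold per SNP,
  and 500 kb / 50 SNP minimums — PLINK v1.9 defaults, surfaced as
  arguments since the motivating analysis names the tool without flags.
- **LD decay**: squared Pearson correlation of dosages binned by physical
  distance; missing dosages are mean-imputed per site.
- **p-distance, NJ, PCA**: pairwise mismatch proportion on diploid dosage
  (0/1/2) with pairwise deletion — dosage, not sequence, because the tree
  is built from SNP genotypes; neighbor joining via `ape::nj` with
  negative branches clamped to zero (count reported); PCA on
  Patterson-normalized dosages (centre `2p`, scale `sqrt(p(1-p))`,
  mean-imputed missing values), eigenvalue shares as explained variance.

# Selection scans

- **Tajima's D**: the standard 1989 statistic per window from S and the
  mean pairwise difference, with the a1/a2/b/c/e constants from the
  haplotype count; windows with S = 0 are NA, never zero.
- **Weir–Cockerham F_ST**: per-site a/b/c variance components including
  the heterozygosity term; the window value is `sum(a)/sum(a+b+c)`
  (VCFtools weighted F_ST). Negative windows are legitimate and kept.
- **XP-EHH**: per core SNP (pooled MAF >= 0.05), EHH of each population
  extends outward until the *pooled-sample* EHH drops below 0.05 — the
  source description does not say which sample the cutoff applies to, and
  the pooled rule matches selscan, whose defaults (cutoff 0.05, 1 Mb
  extension cap, 200 kb gap cap) are adopted because the motivating
  analysis names the tool without flags. iHH is the trapezoidal integral
  over bp, the raw score `ln(iHH_A/iHH_B)`, and scores are z-normalized
  genome-wide (not per chromosome; the choice is configurable in
  principle and stated here because the source is silent). The window
  statistic is the mean normalized score of cores inside. The EHH kernel
  is implemented in C++ (Rcpp) as haplotype-group refinement.
- **Candidates**: "p < 0.005" is read as the 0.5% empirical tail of the
  window distribution (standard outlier-scan usage; no parametric p-value
  exists for these statistics); ties at the cut are included. Candidate
  windows from different statistics are intersected at the bp level;
  regions supported by at least two methods are merged into maximal
  intervals and annotated with overlapping genes (half-open semantics).
  A composite-likelihood-ratio scan is deliberately not implemented; the
  within-population arm relies on the low-pi tail plus Tajima's D, so
  "four methods" here means pi, Tajima's D, F_ST and XP-EHH.

# The introgression stack

- **Patterson's D**: frequency-based ABBA/BABA with
  `ABBA = (1-p1) p2 p3 (1-pO)`, `BABA = p1 (1-p2) p3 (1-pO)`, a
  delete-one block jackknife over contiguous bp blocks for the SE, and
  `Z = D/SE`. The default block size is 5 Mb (not stated by the source;
  chosen to exceed LD range on real data) and is an argument — the tests
  use 250 kb blocks on the 5 Mb toy genome to keep 20 blocks.
- **U statistic**: per window, the count of sites with donor frequency
  >= y, control frequency < w and target frequency > x. Strictness
  follows the verbal pattern exactly: "frequency of 100%" is `>= 1`
  evaluated on called alleles, "less than 1%" is strict `<`, "greater
  than 50%" is strict `>` (a target frequency of exactly 0.5 does not
  count). The textual label "(1%, 20%, and 100%)" conflicts with the
  stated ">50%" execution pattern; the execution pattern
  (w, x, y) = (0.01, 0.5, 1.0) is the default and the alternative
  (0.01, 0.2, 1.0) is available through `u_thresholds`.
- **Local ancestry**: a transparent stand-in for CRF-based inference —
  per non-overlapping 20-SNP window, each target haplotype is assigned to
  the reference panel containing its nearest haplotype (minimum per-site
  mismatch rate; nearest-neighbour rather than panel-average, because a
  single matching donor haplotype is the relevant evidence), accepted
  only when the runner-up panel is at least `margin = 0.1` further away.
  The margin is the classifier's operating point: at species-level donor
  divergence it keeps per-bp accuracy above 95% on implanted tracts while
  holding the no-gene-flow false-positive genome share below 1%.
  Consecutive same-label windows merge into tracts; tract bounds are
  midpoints between boundary SNPs (outermost SNP positions at chromosome
  ends), so boundary error is of order half a window.
- **ILS filter**: an introgressed-vs-shared-ancestral-polymorphism tract
  length argument. With recombination rate `r` per bp per generation and
  `t` generations since donor/recipient divergence, ancestral (ILS)
  segments have expected length `L = 1/(r t)` and the probability that an
  ILS tract reaches length `m` is the Gamma(shape 2, rate 1/L) survival
  `exp(-m/L) (1 + m/L)`. Tracts with probability below `alpha = 0.05` are
  accepted as introgression. Defaults `r = 1e-8`, `t = 3e5` generations
  (about 2 Myr at a 6–7 year generation interval, the banteng/cattle
  split) give `L` around 330 bp, so the filter removes sub-kilobase
  calls; both parameters are reported with the output because the source
  prints neither.
- **Ratios and confirmation**: per sample, total filtered tract length
  over both haplotypes divided by twice the callable length, summarized
  min/mean/max per donor. `region_confirm` rebuilds a candidate region's
  haplotype p-distance matrix, an outgroup-rooted NJ tree, a
  donor-plus-target monophyly check, and the fraction of target
  haplotypes whose nearest non-target neighbour is a donor haplotype
  (nearest *non-target*, because haplotypes carrying the same
  introgressed segment match each other before they match the donor
  panel).

# Numerical conventions and edge cases

- Coordinates are 0-based half-open internally and 1-based only in VCF
  records; windows are `[k*step, k*step + size)` for all `k*step <
  contig length`, so the last window may overhang.
- Missing alleles are excluded from frequency denominators; an
  all-missing site has an undefined (NA, flagged) frequency, never zero.
- LD pruning is the PLINK greedy pass (50-SNP window, 10-SNP step, r² >
  threshold removes the later-position SNP, repeat until stable) on
  dosage correlation; the later-position tie-break makes it
  deterministic.
- Polarization uses the outgroup major allele as ancestral; an exact
  50/50 outgroup tie keeps the alternate allele as derived and flags the
  site.
- Undefined window statistics (S = 0, no usable site, zero iHH) propagate
  as NA with counters, never as silent zeros.
- Every simulator operation is a pure function of its arguments and seed;
  the cohort builder derives one sub-seed per stage from the master seed.

# Problem sizes

The shipped tests run the full stack on 5 Mb single-contig cohorts with
roughly 10,000 SNPs and 51 diploids (20 seeded replicates for the D
calibration and sweep-power checks, 10 for fraction recovery), and on
1 Mb cohorts for structural checks. These sizes were chosen so the whole
suite exercises every seeded-replicate property in a few minutes on one
CPU while leaving each statistic with hundreds of windows to rank.

# Known limitations

Single contig per panel (split multi-chromosome VCFs upstream); phased
input required for haplotype statistics; no sequencing-error or
missingness model in the simulator; the local-ancestry classifier is a
labelled stand-in for CRF/random-forest methods and inherits the margin
rule's insensitivity to tracts shorter than about one window; the ILS
filter's `r` and `t` are analyst inputs, not estimates.
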