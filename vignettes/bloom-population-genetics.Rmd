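---
title: "Models and methods: clonality, recombination and differentiation in bloom time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: clonality, recombination and differentiation in bloom time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomclone)
```

# The scientific problem

Blooming phytoplankton alternate between long stretches of mitotic (clonal)
division and episodic sexual reproduction. In a heterothallic diatom the
sexual phase additionally requires the encounter of the two mating types
(MT+ and MT−), and MT+ is determined by the presence of one specific allele
("allele A") at a length-polymorphic marker upstream of the sex-determining
gene. Whether a given bloom is a clonal expansion of one genotype or a
recombining, genotypically rich population leaves quantitative fingerprints:
collapsed genotypic richness, multilocus linkage disequilibrium, skewed
mating-type ratios, and uniform pooled allele frequencies. `bloomclone`
computes all of these from the two complementary data types such studies
produce — diploid microsatellite genotypes of isolated strains, and pooled
amplicon sequencing of whole environmental samples (Microsatellite Pool-seq
Barcoding, MPB).

# Statistics on strain genotypes

## Multilocus genotypes and richness

Two strains share an MLG iff their unordered allele pairs are identical at
*every* scored locus. Strains with any missing locus are excluded from
MLG-based statistics rather than matched on the remaining loci: lenient
matching would create false clonemates, and with five highly polymorphic loci
exclusion is the conservative error. Genotypic richness is
$R_{MLG} = (\mathrm{MLG}-1)/(N-1)$, which is 0 for a monoclonal sample and 1
when every strain is distinct. For a single-strain date the ratio is 0/0 and
is reported as `NA` — one strain is evidence of nothing.

Allele identity is the integer fragment length in base pairs, taken at face
value; no binning or rounding is applied (fragment calling happens upstream).
Unbiased expected heterozygosity applies the small-sample correction
$uHe = \frac{2N}{2N-1}\left(1-\sum_i p_i^2\right)$ per locus, with $N$ the
individuals genotyped there.

## The standardized index of association

For every pair of complete-genotype strains we count the number of loci $K$
at which the two genotypes differ; a locus differs when the unordered allele
pairs are not identical (A/B equals B/A; sharing one allele is still a
difference — no partial credit, the simplest reading of a mismatch count).
With $d_j$ the proportion of pairs differing at locus $j$,

$$V_e=\sum_j d_j(1-d_j), \qquad
I_A^S=\frac{1}{n-1}\left(\frac{V_d}{V_e}-1\right)$$

where $V_d$ is the *population* variance of the $K$ values (denominator =
number of pairs) and $n$ the number of loci. $I_A^S \approx 0$ indicates
linkage equilibrium (free recombination); significantly positive values
indicate clonal structure. Significance comes from a Monte Carlo permutation
test (default 1000 iterations): each locus column is shuffled independently
across strains, which preserves every $d_j$ (and hence $V_e$) exactly while
destroying between-locus association, and $V_d$ is recomputed. The p-value
uses the add-one estimator $p=(1+\#\{V_d^{perm}\ge V_d^{obs}\})/(1+B)$ so it
can never be 0. All strains of a date are used as sampled — no clone
correction — and the per-date seed is derived deterministically from one
master seed.

Two implementation notes. First, the permutation loop computes $V_d$ from
pair-count algebra (joint genotype-class tabulations and
inclusion–exclusion) rather than materializing all $\binom{m}{2}$ pairs;
this is what makes 500-dataset calibration experiments feasible, and its
exact agreement with naive pair enumeration is asserted by oracle tests.
Second, the estimator conventions ($V_d$ population variance; $d_j$ from
observed pairs) are isolated in one function so that exact variants of other
implementations can be swapped in.

## Mating-type ratios

MT is assigned by the dominant presence rule: MT+ iff allele A is among the
1–2 fragments of the MT marker. The concrete size of allele A is
population-specific and therefore a required configuration value with no
default. Ratios are summarized per date, and range summaries average the
per-date ratios *unweighted* (a `pooled` switch gives the strain-weighted
alternative); the exact two-sided binomial test against 0.5 attached to each
date is an extension beyond plain ratio reporting and can be ignored.

# Differentiation and ordination

Pairwise differentiation uses Nei's multilocus $G_{ST}$ on allele-frequency
profiles: per shared locus $H_s$ is the unweighted mean of the two
within-sample gene diversities and $H_t$ the gene diversity of the
unweighted mean frequency vector, with
$F_{ST}=\sum_l (H_t-H_s) / \sum_l H_t$. One estimator serves both the
genotype-derived and the MPB-derived profiles, keeping the two matrices
comparable; the unweighted mean for $H_t$ is deliberate because sample sizes
differ wildly between dates. Small negative estimates are clipped to 0 with
a warning; when $\sum H_t=0$ (both samples fixed for the same alleles) the
distance is 0 by convention, flagged.

PCoA is classical metric scaling: square the distances, double-centre with
$-\tfrac12 J D^2 J$, eigendecompose, scale eigenvectors by the square root
of their eigenvalues. Negative eigenvalues are reported but excluded from
the variance denominator; no Lingoes/Cailliez correction is applied, since
F_ST matrices of this kind are near-Euclidean and corrections would obscure
comparisons between analyses.

The percolation network keeps, for a distance matrix over sampling dates,
every edge at or below the smallest threshold that leaves the graph
connected. That threshold equals the largest edge of the minimum spanning
tree (asserted against a brute-force threshold scan in the tests); edge
display weight is the genetic similarity $1-F_{ST}$. Zero distances are
legitimate edges — genetically identical dates stay maximally connected.

Evanno's $\Delta K$ post-processes replicate ln-likelihoods of an external
Bayesian clustering run:
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}(L(K))$,
defined for interior $K$ with positive replicate standard deviation; the
supported cluster number is the argmax. The statistic is invariant to
constant shifts of all ln-likelihoods, and a linear likelihood profile gives
$\Delta K \equiv 0$ (no spurious peak). The clustering MCMC itself is out of
scope.

# The MPB caller

Input begins at merged, primer-trimmed, demultiplexed amplicons — upstream
read processing belongs to standard external tools — as dereplicated FASTA
with `;size=` annotations or long-format count tables. The filter chain runs
in a fixed order, each stage logged with reads removed:

1. **Singletons** (dataset-wide total count of 1) are discarded; a count of
   1 in each of two samples survives.
2. **Repeat filter**: the repeat-unit count of a sequence is the length of
   its longest uninterrupted, in-frame run of exact motif copies;
   interrupted repeats count only the longest clean run. Sequences with
   fewer than 3 units (configurable) are removed. This exact-tandem rule is
   reproducible and oracle-checkable; fuzzier definitions exist but are not
   published in a testable form.
3. **Allele calling**: sequences are grouped by fragment length; distinct
   sequences of one length are homoplastic alleles named `length.index`
   with the index by descending dataset-wide count, ties broken
   lexicographically — names cannot drift between runs.
4. **Normalization and abundance filter**: samples under 1000 raw amplicons
   are excluded (not an error); retained libraries are scaled to the median
   raw total; frequencies are percentages of the per-sample total (columns
   sum to 100 before thresholding). The locus-specific threshold (e.g.
   0.65% / 1.65%) zeroes an allele *per sample*, removing erroneous alleles
   while retaining genuinely rare ones elsewhere; a `global` switch instead
   drops alleles whose maximum frequency anywhere is below threshold.
   Frequencies are *not* renormalized to 100 after filtering by default
   (switch provided) — whether to renormalize before F_ST is genuinely open,
   and not renormalizing reports what was actually observed.
5. **Replicate merging**: same-date samples are averaged allele by allele,
   zeros included.

Flank typing decomposes each allele as 5′ flank + longest repeat run + 3′
flank. Exact flank sequences define types, labelled by descending total
abundance. The canonical partner of a 5′ type is the 3′ type it co-occurs
with at the highest total read abundance (and vice versa); an allele whose
two flank types both occur elsewhere but whose combination is neither
flank's canonical pairing is flagged recombinant — the signature of
intralocus recombination. The decision rule is the simplest one consistent
with "most alleles share flank types, a few combine them novelly", and it is
isolated in one function. Flanks shorter than 10 nt (configurable) make that
side untypable, and alleles with an untyped side are never called
recombinant.

# The synthetic world

The simulator generates exactly the statistical structure the analyses
consume, not bloom ecology. Its stated defaults, chosen once:

| parameter | default | why |
|---|---|---|
| census per date (`pop_size`) | 10 000 | blooms have enormous census sizes; census ≫ sample keeps sampled strains essentially unrelated, so sibship cannot masquerade as LD |
| strains sampled per date | 100 | order of real isolation campaigns |
| dates | 6, weekly | one bloom season |
| loci | 5 dinucleotide/trinucleotide microsatellites, 8 founder alleles each, Exp-weighted founder frequencies | matches marker panels of such studies |
| stepwise mutation | 10⁻³ per allele per meiosis | standard microsatellite SMM order |
| MT locus | 4 alleles; allele A founder frequency $1-\sqrt{0.5}$ | makes the expected MT ratio exactly 50:50 |
| read depth | 10⁴ per sample per locus | MiSeq amplicon scale |
| PCR slippage | 0.02 per read, ±1 unit | typical dinucleotide stutter |
| substitution | 2×10⁻⁴ per base per read | *effective post-merge* error of overlapping, quality-filtered paired reads; a raw-read rate (~10⁻³) would be wrong for merged amplicons and would contradict quantitative mixture recovery at ±2 pp |

Between dates, each offspring is clonal (copy of a parent drawn from a
skewed multinomial whose weights are Gamma(shape = 1/`clonal_skew`); the
effective concentration is `pop_size`/`clonal_skew`, so one clone dominates
as `clonal_skew` approaches the census) or, with probability `sex_rate`, a
Mendelian recombinant of a random MT+ × MT− pair. If sex is requested while
one mating type is absent the offspring falls back to clonal copying and the
event is logged — in a single-MT population sex cannot occur. Clonal copying
is mutation-free; stepwise mutation acts at meiosis. Generations are
non-overlapping with fixed census size: growth dynamics are deliberately not
modelled.

The "clonal bloom" regime used in the acceptance contrast is
`sex_rate = 0, clonal_skew = 2000` (concentration 5 at the default census):
post-inoculum richness collapses below 0.1 while a handful of background
genotypes persists, mirroring a bloom ~90% dominated by one clone with a
small tail — a fully monoclonal regime would make $I_A^S$ degenerate
($V_e=0$), which real clonal blooms are not. The founding date *is* the
diverse inoculum, so regime statistics are assessed on subsequent dates, and
a run counts as "in LD" when the majority of its post-inoculum dates are
individually significant.

What the generator does **not** emulate: PCR-cycle-resolved error
accumulation (error is per read), chimeras, index hopping, length-dependent
amplification bias, overlapping generations, selection, or spatial
structure. A green test therefore establishes that the *statistics and
filters* behave as specified on data with known truth — not that any given
field dataset satisfies the generator's assumptions.

# Numerical choices and degenerate inputs

- Permutation comparisons use `Vd_perm >= Vd_obs - 1e-12`; both sides come
  from the same integer-tally arithmetic, so exact ties are exact.
- $V_e = 0$ (all loci monomorphic) yields an explicitly flagged undefined
  result, not an exception; a single polymorphic locus is an error
  (the $n-1$ denominator).
- Pearson correlations drop undefined positions pairwise and require ≥3
  complete pairs; zero variance returns `NA` with a warning.
- PCoA treats eigenvalues above `1e-9 · max|λ|` as positive.
- MLG labels are assigned by first occurrence, so they are order-dependent;
  the partition itself is permutation-invariant (tested).
- All report files carry `# key: value` provenance headers (version, seed,
  config hash) and report bundles are written atomically — complete or
  absent.
- In the filter report, the abundance stage counts normalized (median-scaled)
  reads, since thresholding happens after normalization.

# Known limitations

- The MPB abundance thresholds are calibration inputs; their derivation from
  fragment-analysis heteroplasticity counts is outside the package.
- Reproducing published counts from the original study (e.g. 523 MLGs among
  1133 strains, the −0.91 richness–LD correlation) requires its
  supplementary tables, which cannot be redistributed here; the
  corresponding acceptance test runs only when `BLOOMCLONE_SUPPLEMENTARY`
  points at the genotype CSV. MPB allele counts per date from the archived
  sequencing runs additionally depend on unpublished upstream preprocessing
  and are treated as best-effort, not asserted.
- Whether strain-level linkage testing should be clone-corrected is left at
  "no correction" (all strains as sampled); with clone correction the
  richness–LD correlation may differ.
- The Weir–Cockerham F_ST family is not implemented; `pairwise_fst` is the
  single hook where such an estimator would plug in.
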