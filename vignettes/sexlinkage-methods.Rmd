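---
title: "Inferring ZW sex linkage from RAD-seq catalogues: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ZW sex linkage from RAD-seq catalogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radzw)
```

## The inference model

`radzw` tests an explicit chromosomal model of sex determination
against marker-by-individual RAD-seq data. Under female heterogamety,
males are ZZ and every female (or hermaphrodite) carries at least one
W; the W acts as a dominant feminizing factor, so in an androdioecious
population hermaphrodites are either amphigenic (ZW, whose selfed
broods segregate 1 WW : 2 ZW : 1 ZZ, i.e. three hermaphrodites per
male) or monogenic (WW, selfing true). The male-heterogametic mirror
(XY) is obtained by swapping the sexes' roles, which gives the package
its model-comparison mode: data generated by a ZW system produce no
candidates when screened under XY.

Three evidence streams identify completely sex-linked markers.

1. **Presence–absence with copy-number-consistent depth.** A marker
   whose restriction site exists only on one sex chromosome is present
   in every carrier of that chromosome and yields no reads otherwise.
   Because read depth is proportional to copy number, the carrier's
   *normalized* depth (below) should sit near 0.5 when it holds one
   copy of the focal chromosome and near 1.0 when it holds two, and a
   single-copy carrier can only show one allele.
2. **SNP segregation.** A marker present on both Z and W may carry a
   W-diagnostic allele: every ZW individual is then heterozygous for an
   allele never observed in ZZ males, every ZZ male homozygous for
   Z-linked alleles, and every WW hermaphrodite homozygous for the W
   allele. `find_sexlinked_alleles()` applies exactly this predicate
   and records the inferred W/Z phase.
3. **Genotypic LD.** Markers that are sex-linked but violate the strict
   patterns (e.g. through within-chromosome polymorphism) still travel
   with the sex-linked block, so they surface as pairs in significant
   genotypic association with confirmed sex-linked markers
   (`ld_screen()` + `summarize_sexlinked_pairs()`).

The canonical stage order, wired into `evaluate_model()` and
`run_pipeline()`, is: W-specific discovery → hermaphrodite karyotype
classification (androdioecious populations) → Z-specific discovery →
segregation-based discovery → LD screen. The ordering is not cosmetic:
Z-specific markers are only identifiable where some individuals carry
no Z at all, so their discovery *requires* the monogenic (WW)
hermaphrodites found in the classification step, and in a purely
dioecious population presence–absence is uninformative for the Z
because both sexes carry it.

## Coverage normalization and its filters

Raw depths are not comparable between individuals (library sizes
differ), so all depth evidence uses `normalize_depths()`: each
individual's depths are divided by that individual's median depth over
a reference set of markers, by default the markers genotyped in every
individual — a large, overwhelmingly autosomal set. On this scale a
diploid marker has expectation 1 and a hemizygous one 0.5 regardless of
library size; the test-suite checks both expectations on simulated
data (means within ±0.05).

Upstream of normalization two catalogue-level filters reproduce
standard RAD practice. `filter_high_coverage()` keeps markers with
depth strictly greater than 20 reads in at least 6 individuals (the
size of the smallest sex class in the motivating design); the
boundary semantics (21 reads in exactly 6 individuals passes, 20 reads
anywhere does not count) are pinned by tests. `remove_repetitive()`
drops markers whose mean depth over genotyped cells exceeds the grand
mean of marker means by more than two standard deviations, in a single
pass — repetitive elements attract reads from many genomic copies and
would otherwise masquerade as high-confidence markers. Applying the
two-standard-deviation rule at catalogue level on marker means is a
deliberate simplification: assembly pipelines apply it per individual
during stack formation, but a finished catalogue only exposes
marker-level information. Medians use the standard midpoint convention
for even counts.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `call_threshold` | 15 | reads | minimum identical reads to call a RAD allele |
| `min_depth`, `min_individuals` | 20, 6 | reads, individuals | the ">20 reads in ≥6 individuals" catalogue filter |
| `absent_max_depth` | 5 | reads | guard band: below this a marker is cleanly absent; 5–14 reads is indeterminate and disqualifies a marker from chromosome-specific status, so low-level contamination is never scored as presence |
| `hemi_window` | [0.25, 0.75] | normalized depth | accepted as hemizygous; centred on the 0.5 expectation |
| `hom_window` | (0.75, 1.5] | normalized depth | accepted as diploid; centred on 1.0 |
| `threshold_lo`, `threshold_hi` | 0.70, 0.80 | normalized depth | hermaphrodite classification: ≤0.70 amphigenic, ≥0.80 monogenic, between is an explicit `ambiguous` dead zone around the 0.75 midpoint |
| `alpha`, `n_perm` | 0.05, 10000 | — | LD screen: raw p-values by default (a Benjamini–Hochberg option exists) |

Thresholding the hermaphrodite means was chosen over 2-means
clustering deliberately: with 15 individuals a clustering step can
split a single cloud, whereas fixed thresholds with a declared dead
zone are deterministic, auditable, and robust at small n.

Coverage windows are applied to *marker-level means* per
expected-copy-number group of carriers (the mean over ZW carriers must
be hemizygous-like, the mean over WW carriers diploid-like; carriers of
unknown karyotype are accepted anywhere between the windows' outer
bounds). Judging each individual cell against the windows would make
the procedure reject essentially every true marker at realistic depth
noise — the two windows share the 0.75 boundary, so a single diploid
cell drawn at 0.74 would veto an otherwise perfect marker — and the
marker-level mean is also how coverage plots of candidate markers are
read in practice. The per-individual requirement that survives is
zygosity: every single-copy carrier must show exactly one allele, which
depends only on genotype calls, not on depth noise.

## The simulator: what it emulates, and what it does not

`simulate_population()` is a forward simulator whose defaults mirror
the validation design: a dioecious population (12 females + 14 males)
and an androdioecious one (15 hermaphrodites + 6 males), a catalogue of
3822 markers of which 18 are W-specific, 11 Z-specific, 21 shared
sex-linked and 3 flanking, per-individual mean depth drawn uniformly
from 200–450 reads (bracketing typical observed per-marker medians of
high-coverage RAD libraries), and genotype calls at ≥15 reads.

Mechanics worth knowing:

* **Depth** is negative-binomial with mean `copies/2 × lambda_i` and
  size (dispersion) 150, i.e. a coefficient of variation of about 10%
  at 300×. This represents marker-level depth noise in a high-coverage,
  PCR-duplicate-removed library. Real libraries can be substantially
  more overdispersed; at much heavier noise (size near 10) window-based
  coverage classification degrades badly, so users applying the windows
  to their own data should first inspect the empirical spread of
  normalized coverage at markers found in all individuals.
* **Dioecious populations** are drawn directly as random unions of
  gametes at the founder allele frequencies (Hardy–Weinberg,
  linkage-equilibrium autosomes), which is the stationary state of
  obligate outcrossing with obligate male × female pairing.
* **Androdioecious populations** are founded by `n_founders`
  hermaphrodite lineages which self for `selfing_generations` discrete
  generations; the sampled individuals come from a final selfed brood,
  so males (ZZ, from amphigenic mothers) appear in the sample while the
  maintained lineages stay hermaphroditic — each line persists through
  a selfed offspring of its founder's karyotype, so amphigenic lines
  remain amphigenic during maintenance. Selfing plus the small founder
  number produce exactly the two population-level signatures the
  analysis modules are tested against: reduced polymorphism and
  elevated genome-wide genotypic LD relative to a matched outcrossing
  population. Sampling can either target phenotype counts or an exact
  karyotype composition (e.g. 4 WW + 11 ZW + 6 ZZ), the latter being
  used wherever a test needs both hermaphrodite karyotypes present at
  any seed.
* **Null alleles** (restriction-site loss) can segregate on autosomes
  and, on request, among Z copies of shared sex-linked markers. The
  latter reproduces a documented blind spot of the strict criteria: a
  ZW individual whose Z carries the null is genotyped as homozygous for
  the W allele, so the marker fails the all-heterozygous predicate and
  is correctly *not* reported as completely sex-linked — the test-suite
  pins this negative behaviour.
* **Flanking markers** sit on the sex-chromosome pair outside the
  fully sex-linked block, recombining with it at fraction `r` per
  meiosis; at `r = 0` they are in complete gametic association with the
  sex-determining locus and are then, by construction, genuinely
  completely sex-linked — recovery tests therefore plant them only when
  exercising the LD module, and the marker-recovery tests use
  architectures without them.
* Not modelled: sequence-level reads, sequencing error, barcode or
  assembly artefacts, mutation during the simulation, overlapping
  generations, or a literal selfing *rate* (selfing generations is a
  knob, not an estimate of any real population's rate).

Determinism: all stochastic draws flow from R's RNG seeded once with
the config's seed, so equal configurations give byte-identical
catalogues, truth tables and pipeline outputs.

## The LD test

`genotypic_ld_test()` is a permutation test of independence on the
two-locus genotype contingency table, summarized by the G
(log-likelihood-ratio) statistic, with the add-one-corrected p-value
`(1 + #{G* ≥ G}) / (n_perm + 1)`. Individuals missing either genotype
are dropped pairwise; loci monomorphic among the remaining individuals
are not testable and are excluded from screen denominators.
Observations are sorted into a canonical order before permuting, so
p-values are invariant to how the input rows happened to be ordered.
This replaces the Markov-chain machinery of classic population-genetics
LD software (dememorisation/batches/iterations) with a plain
permutation scheme targeting the same null; the G statistic itself is
cross-checked in the tests against an independent log-linear-model
fit, and the permutation core (compiled C++ driven by R's RNG) holds
its nominal type-I error within ±0.01 at α = 0.05 in a 5000-replicate
calibration run in the test-suite.

## Region-size arithmetic

`site_probability()` uses an i.i.d. base model: with GC content g, a
motif with n~GC~ G/C bases and n~AT~ A/T bases occurs per position with
probability (g/2)^n~GC~ ((1−g)/2)^n~AT~; expected spacing is its
reciprocal. The SbfI site (CCTGCAGG) is its own reverse complement, so
a single-strand scan counts each physical cut site exactly once and no
double-counting correction applies. Since each cut site yields two RAD
markers, marker counts convert to site counts by halving with
ties-to-even rounding (41 markers → 20 sites), and extents multiply
sites by the spacing *rounded to the nearest 100 kb* (minimum 100 kb) —
the resolution at which such back-of-envelope estimates are honest;
the exact unrounded value is reported alongside. GC heterogeneity is
deliberately out of scope: an 8-bp GC-rich cutter targets GC-rich
regions, and nothing in a catalogue says whether sex-linked regions
share the genome-wide base composition, so the estimates should be
read as order-of-magnitude.

## Numerical and format choices

* Catalogue TSV dialect: one row per marker, one column per individual,
  cells `alleleA/alleleB:depth` with `./.:depth` for no call — missing
  genotypes are explicit and survive a write/read round trip
  bit-for-bit. Depth may be positive with the genotype missing (a
  failed call); "absence" is a property defined by the discovery
  stage, not the file format.
* Genepop export uses 3-digit allele coding (so up to 99 alleles per
  marker), `Pop` separators and the `id , ` prefix exactly, and by
  default refuses markers with missing genotypes among exported
  individuals, mirroring the found-in-all-individuals restriction of
  population LD screens.
* F~ST~ is the Weir–Cockerham (1984) variance-components estimator,
  ratio-of-sums across loci, multi-allelic, with negative estimates
  reported as computed; loci monomorphic across both populations
  contribute zero components. The test-suite fixes it against a fully
  hand-worked two-population example (F~ST~ = 1/3) and checks
  invariance to allele relabelling and population order. Note that
  between-population F~ST~ on real catalogues depends on the real
  data; nothing in this package claims to reproduce any particular
  published value of it.
* Markers genotyped in only part of a group are disqualified from
  "completely sex-linked" status (strict reading of *all*); they remain
  visible as unclassified presence-pattern hits with their evidence
  flags, rather than being silently dropped.
* No special-case logic exists for markers whose presence–absence
  pattern is merely *incompatible* with complete linkage; they simply
  fail the predicates.

## Validation problem sizes

The shipped tests validate on deliberately compact instances: study
simulations of 47 individuals with 40–800 autosomal markers; 20-seed
recovery sweeps (planted 5 W-specific / 4 Z-specific / 5 shared
markers each); 10 paired selfing/outcrossing seeds for the LD and
polymorphism contrasts; 5000 replicates for LD type-I error; 100 × 1 Mb
Monte-Carlo genomes for the spacing oracle. The default 3822 × 47
configuration runs in about a second, so scaling any of these up is a
matter of patience, with the single exception of `ld_screen()`, which
is quadratic in the number of polymorphic markers (a full
351-polymorphic-marker screen is ~60k pairs; budget accordingly or
pre-filter).

## Known limitations

* Complete-linkage criteria are all-or-nothing: one mis-genotyped
  individual removes a true marker (no error tolerance parameter is
  offered, by design — relaxations belong in the LD stage).
* Within-sex-chromosome polymorphism, including null alleles on the Z,
  hides markers from the strict criteria; they are recoverable only
  via the LD screen.
* The hemizygosity windows and hermaphrodite thresholds presume depth
  noise comparable to the simulator's (cv ≈ 10%); noisier libraries
  need wider windows and will pay for it in specificity.
* The region-size arithmetic inherits every caveat of the i.i.d.
  genome model and of assuming physically contiguous sex-linked
  markers.
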