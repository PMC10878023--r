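---
title: "Methods: screening CRISPR-edited clone comparisons for genetic confounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening CRISPR-edited clone comparisons for genetic confounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneconfound)
```

## The problem

Claims of transgenerational epigenetic inheritance that rest on comparing a
CRISPR/Cas9-edited clonal cell line against a wild-type sister clone are
vulnerable to genetic confounds: off-target mutagenesis by the nuclease,
copy-number changes and translocations arising during editing, and ordinary
clonal heterogeneity accumulated over months of passaging. `cloneconfound`
packages the analyses needed to audit such comparisons: an off-target
landscape scan, clone-unique INDEL definition, a resampling-based test for
INDEL enrichment at predicted off-target sites, allele-frequency drift and
differential-genotype screens, binned read-depth copy-number screening, and
strain-matched methylation pairing — together with a seeded generator that
plants known truth for every stage so the whole pipeline is testable without
any external download.

Coordinates are 0-based half-open internally (BED convention); VCF positions
and coverage-track positions are 1-based on disk. CNV and SV tables are read
as 1-based inclusive and converted on input.

## Off-target landscape scan

A guide is a protospacer (typically 20 nt, PAM-proximal end last) plus an
IUPAC PAM pattern 3' of it (`NGG`, `NAG`, or their union `NRG`). The scanner
enumerates, on both strands, every genomic window whose PAM matches the
pattern exactly (no PAM mismatches are tolerated — the convention of the
standard prediction tools, whose mismatch budget refers to the protospacer
only) and whose protospacer alignment needs at most `max_mismatches`
substitutions (0–7). With `bulge_size = 1` the alignment may additionally use
one 1-bp bulge: an RNA bulge (an unpaired guide base; the genomic footprint
is one base shorter) or a DNA bulge (an extra genomic base; one longer).
Bulge placements are restricted to the protospacer interior — a terminal
"bulge" is just a shifted ungapped alignment and would duplicate sites.

**Site identity is PAM-anchored.** The PAM is the physically fixed element
of Cas9 recognition, so candidate alignments sharing one PAM position and
strand are treated as explanations of a single site. The minimal-mismatch
explanation wins; at equal mismatch counts the precedence is no bulge, then
RNA bulge, then DNA bulge. Windows containing any N are excluded. Output is
ordered by (chromosome, start, strand) and is deterministic.

Categorisation is by *exact* mismatch count crossed with PAM class and bulge
status, the way off-target enrichment panels are labelled; an `NRG` category
is the union of `NGG` and `NAG` matches. The test suite holds the scanner to
exact site-set equality with a brute-force oracle that re-derives every site
by per-offset string surgery, across the full mismatch/PAM/bulge grid on
seeded 20-kb genomes.

The implementation is a column-sweep: mismatch counts for all window
positions are accumulated one guide position at a time, and the bulge
placements are folded in with prefix/suffix mismatch sums, so the scan is a
few hundred vectorised passes over each chromosome rather than a per-window
loop. A linear scan is entirely adequate at the megabase scale this package
targets; genome indexing is out of scope.

## Hard filtering and clone-unique INDELs

Raw jointly-genotyped calls are hard-filtered with the standard cutoffs:
INDELs fail on FS > 200, ReadPosRankSum < −20, QUAL < 30 or QD < 2; SNVs on
QD < 2, QUAL < 30, SOR > 3, FS > 60, MQ < 40, MQRankSum < −12.5 or
ReadPosRankSum < −8. All inequalities are strict, and a record missing a
statistic passes that statistic's test — missing is not failing.

An INDEL of clone A counts as *A-unique* when (i) no INDEL call of clone B
overlaps its REF span, (ii) every base of that span has depth ≥ 10 in B's
per-base coverage, and (iii) B's unfiltered callset shows no record with
alternate-allele support overlapping the span — the operational reading of
"no single read supporting an alternate allele". Condition (iii) considers
only records with alternate evidence because jointly-genotyped VCFs contain
explicit 0/0 rows for the other sample at every site. Overlap is interval
overlap of REF spans; because positional representation of INDELs is
caller-dependent, `normalize_variants()` provides canonical left-alignment
(shared-suffix borrowing plus leading-base trimming) and should be applied
when the two callsets come from different caller runs. Records whose span
has positions absent from the coverage track are excluded and tallied
separately rather than silently dropped.

## Enrichment of unique INDELs at off-target sites

For each off-target category the observed statistic is the number of
A-unique INDELs whose REF span overlaps at least one site region (a variant
overlapping several regions counts once). Two nulls are built, each with 5
draws by default:

* **random-region null** — the same INDELs counted in an equal number of
  equally-sized regions placed uniformly over the genome (chromosome chosen
  proportional to its eligible starts). Regions with more than 100 Ns are
  rejected and redrawn, mirroring the bin-masking rule; draws may overlap
  one another (a no-overlap mode exists).
* **wild-type null** — `|unique A|` variants sampled without replacement
  from all WT INDELs, counted in the *same* category regions.

Each null is compared against the observed count with a two-sided one-sample
t-test (df = draws − 1); a one-sided mode is available. Zero-variance nulls
are flagged degenerate with `NA` statistics instead of fabricating a
p-value. No multiple-testing correction is applied across categories, which
matches how such per-category panels are usually reported; the p-values are
per-category statements.

Because the padding of "off-target regions" around a cut site is a free
choice, `run_enrichment(pad = )` exposes it; site footprints are used as
emitted by default. Note one geometric fact visible in dense categories
(thousands of high-mismatch background sites): clustered, overlapping site
regions have a smaller union than equally many independently placed random
regions, which can push the random null *above* the observed count. Power
and size of the test are therefore assessed on sparse planted categories,
where the spec of the statistic is clean: with 500+ unique INDELs placed at
3× density inside planted regions the random-region p is below 0.05 in at
least 9 of 10 seeds.

The test's size deserves an honest caveat. The one-sample t treats the
observed count as a fixed hypothesized mean, but over replications of the
experiment the observed count carries binomial sampling variance comparable
to a single null draw's. The statistic's denominator is the null draws'
standard error (σ/√5) while the numerator's true spread is σ√(1 + 1/5), so
even with no enrichment the two-sided rejection rate at nominal 0.05 is
roughly 25% — and half of those rejections are in the *deficit* direction,
which is meaningless as an enrichment finding. Measured over seeded
no-enrichment replicates the package reproduces exactly this inflation (the
test suite records it). Per-category p-values from this statistic should
therefore be read as descriptive strength-of-separation measures in the
figure-panel tradition, not calibrated hypothesis tests; a calibrated
alternative would compare the observed count against the null draws'
*predictive* distribution or use many-draw permutation p-values (the draw
count is configurable for exactly that purpose).

## Binned read-depth screening

The genome is tiled with 50-kb bins (terminal bins truncated); bins with
more than 100 Ns are masked and excluded. Per-bin mean depth averages over
every position of the bin, counting positions absent from the coverage file
as zero and keeping N bases in the denominator (masked bins are discarded
anyway, and this matches a positions-file average). Bin comparison reports
the signed percent change (a − b)/b × 100, excludes bins with zero depth in
the reference clone (tallied), and flags |change| above a threshold (50% for
the headline screen; 35% in the recovery property). Depths are rescaled by
the library-size ratio before comparison by default, since two sequencing
runs rarely have identical yields; raw mode (`normalize = FALSE`) restores
direct comparison and is what the planted-CNV recovery tests use, because at
desk scale the planted CNVs occupy a non-negligible genome fraction and
would themselves shift the scale factor — a distortion that is negligible on
a real genome.

Chromosome-level screening reports each chromosome's mean depth, flags
chromosomes below 60% of the genome-wide median (an exposed parameter — the
cutoff itself is a pragmatic screen, not an estimate), and returns a
cumulative depth-fraction profile along each chromosome for arm-truncation
plots. External CNV calls are matched between clones by same-type reciprocal
overlap (default fraction 0.5); depth-flagged bins are concordant with a
unique CNV call at ≥ 1 bp overlap. Translocation candidates are kept when
supported by strictly more than 2 reads and no same-type candidate in the
other clone has both breakpoints within 1 kb (either breakpoint
orientation).

## Strain-matched methylation pairs

Samples are stratified by (tissue, sex); within a stratum one 129Sv sample
is paired with one B6 sample, each sample used at most once, and a pair is
admissible only when the age difference is at most 60 days (inclusive — the
boundary is asserted in tests). The default matcher computes the
maximum-cardinality, minimum-total-age-difference assignment exactly by
dynamic programming over subsets (deterministic, ties resolved by sample-id
order). A greedy mode — repeatedly take the smallest remaining age
difference — is also shipped. Greedy was the initially attractive choice,
but it provably fails the invariant that pair count equals the maximum
matching: under a cutoff, a locally closest pair can block two admissible
pairs (ages A = {0, 100}, B = {55, 160} yield one greedy pair but two
optimal ones), and on random strata this costs pairs in roughly one stratum
in seven. Since discarding matched samples both loses power and is the kind
of silent analytic choice this package exists to audit, the exact matcher is
the default; the test suite checks it against an independent enumeration
oracle on 50 seeded strata.

Per probe and tissue, the strain effect is a two-sided paired t-test of the
B6 − 129Sv beta differences, dropping pairs with a missing value at that
probe. Fewer than two complete pairs is undefined; numerically constant
nonzero differences are flagged degenerate; exactly identical paired values
report p = 1. Benjamini–Hochberg adjustment is applied across the whole
emitted (tissue × probe) table by default — the most conservative reasonable
family — with a per-probe-across-tissues mode available; undefined rows are
excluded before adjustment.

## The synthetic-data generator

Every generator is a pure function of its seed (byte-identical reruns), and
every dataset ships a truth record sufficient to compute each stage's
expected output without re-derivation. The default conditions are desk-scale
stand-ins for a two-clone whole-genome comparison at ~30× with a >1000-sample
array cohort behind the methylation arm:

* **Genome** — 3 chromosomes × 1 Mb, i.i.d. uniform bases, two N blocks
  (200 bp and 80 bp) so that exactly one 50-kb bin trips the >100-N mask.
* **Off-target sites** — ~320 planted guide-derived sites across mismatch
  (0–7) × PAM (NGG/NAG) × bulge categories, each placed well-separated,
  rejection-checked by rescanning so the recovered category equals the
  planted one; all remaining scan hits are recorded as background truth.
  Each site's "region" is its footprint ± 100 bp, the scale over which
  nuclease-induced INDELs concentrate around a cut site.
* **Callsets** — one jointly-genotyped two-sample VCF (the shape the
  upstream caller emits, and what gives implied 0/0 genotypes meaning):
  1,200 shared SNVs and 200 shared INDELs; 600 clone-unique INDELs per
  clone, the edited clone's placed with 3× density inside off-target
  regions; 100 differential biallelic genotypes at guaranteed depth ≥ 20;
  30 drifted allele frequencies (|Δaf| drawn 0.55–0.95) at het genotype in
  both clones. Depth is Poisson(30); site statistics are drawn inside the
  hard-filter pass ranges except a 10% fraction of shared records planted to
  violate exactly one threshold each.
* **Allele counts** — `alt_reads = round(af × depth)` by default (exact
  model), with a binomial mode available. The exact model makes planted
  truth exactly recoverable: binomial noise at 30× would smear a planted
  frequency change of 0.55 below the 0.5 screen threshold in roughly a third
  of cases, so "exactly the planted sites are returned" would be untestable.
  Differential-genotype sites get even depths so heterozygous fractions are
  exactly 0.5 and genotype switches sit on, not across, the drift boundary.
* **Coverage** — per-position Poisson around 30× multiplied inside planted
  CNVs: a 5-bin 0.45× deletion (the ~53%-reduced signature of a
  heterozygous deletion), a 1-bin 1.3× gain, two single-bin 0.45× depth
  artifacts without CNV calls, and two CNVs shared by both clones (which
  must cancel in the comparison). N positions report depth 0. A constant
  (noise-free) mode supports exact-recovery tests.
* **Methylation** — 7 tissues × 2 sexes × 8 samples per strain per stratum,
  ages uniform on [0, 365] days; 12 probes with baselines uniform on
  [0.1, 0.7]; a +0.15 beta strain effect planted at 2 probes in 2 tissues;
  Gaussian noise with SD 0.04 (typical array replicate noise); values
  clipped to [0, 1].

What the generator does *not* emulate — and what passing tests therefore do
not certify on real data: mutation spectra and sequence-context effects,
GC-coverage bias, mapping artifacts and repeat-driven false calls, linkage
between variants, array probe cross-reactivity, or batch effects. The
generator validates the *logic* of every stage against planted truth; it
does not validate variant calling, which this package deliberately consumes
rather than re-implements.

## Numerical and design choices

* Sub-seeds for every stochastic stage are derived from the user seed with a
  fixed linear-congruential step, all below 2³¹; seeded code never perturbs
  the caller's RNG state.
* Random-region placement retries N-heavy draws up to a cap (default 1000)
  and then fails loudly; an all-N genome is an error, not an empty result.
* Degenerate statistics (zero-variance nulls, < 2 complete pairs) are
  flagged, never imputed.
* The drift screen's ">50% change" is read as an absolute difference of
  more than 0.5 in frequency units, the natural reading of a frequency
  scatter; a relative mode is provided. Sites biallelic in both clones with
  different ALT alleles are excluded from drift and counted separately.
* Differential genotyping includes one-sided sites as implied 0/0 when the
  other clone's depth supports it (from its callset row or coverage track);
  a flag restricts to sites called in both.
* Test problem sizes: scanner-oracle equivalence on 20-kb genomes (48
  configurations over 24 seeds), enrichment power/size on 2 × 200-kb
  genomes over 10 seeds per condition, CNV recovery on 2-Mb chromosomes,
  determinism on a 2 × 120-kb end-to-end run; the acceptance script runs
  the full 3 × 1 Mb defaults. These sizes were chosen so each property is
  measured where its signal is clean while the whole suite stays fast.

## Limitations

The scanner is a literal mismatch/bulge enumerator: it implements no cleavage
propensity scoring, and a genome larger than a few hundred megabases would
want an indexed search. The enrichment t-test on 5 draws is retained for
fidelity to the figure-style analysis it reproduces; with so few draws it
leans on approximate normality of region counts, and an empirical permutation
p-value would need more draws (the draw count is configurable). CNV and SV
calling are consumed, not performed. The methylation arm assumes the beta
matrix is already preprocessed and normalised.
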