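---
title: "Methods: array design and sex-specific linkage maps in Nile tilapia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: array design and sex-specific linkage maps in Nile tilapia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`onilmap` re-implements, as a tested and reusable pipeline, the analysis
chain behind a high-density SNP genotyping array and sex-specific genetic
linkage maps for Nile tilapia (*Oreochromis niloticus*): filtering of
discovery variants from whole-genome resequencing of a founder cohort,
selection of an equidistant, MAF-maximizing marker panel, array genotype
quality control, parentage assignment in factorial full-sib families by
opposing-homozygote exclusion, fixed physical-order map estimation with
Kosambi distances, recombination-desert detection, and mapping of the XY
sex-determining locus. Every stage runs on a bundled synthetic-data
generator with known ground truth, so the whole chain is testable without
any external sequencing data.

This vignette explains the models and algorithms, the tunable parameters,
what the generator does and does not emulate, and the design choices made
where the original tooling left the procedure under-specified.

## The filtering cascade

Discovery variants are screened by site quality (phred QUAL ≤ 20 removed),
proximity to indels (a SNP is removed when its position falls within the
indel's reference span padded by 5 bp on both sides; an anchor-base mode is
available via `filter_config(indel_anchor_only = TRUE)`), multi-allelism
(more than one alternate allele), total sequencing depth (summed across
samples, > 700 reads removed — with ~32 founders at ~20× this flags
collapsed repeats; a per-sample mode is available), and A/T or C/G allele
pairs (these need twice the probes on strand-symmetric arrays). Individual
genotypes with GQ < 30 are then masked — masking the genotype rather than
the site lets the subsequent call-completeness rule (≥ 28 of 32 samples
called) do its work; removing whole sites at the first low-GQ call would
make that rule redundant. Finally markers with minor allele frequency
below 0.05, markers where every called genotype is heterozygous (a classic
paralog signature), and markers failing an exact Hardy–Weinberg test at
α = 0.05 are removed. All violated rules are recorded per marker, in
cascade order.

The Hardy–Weinberg test is the exact conditional test on the heterozygote
count given the allele counts: with $N$ diploids and minor-allele count
$n_A$,

$$P(n_{AB} = k \mid N, n_A) =
  \frac{N!}{n_{AA}!\,k!\,n_{BB}!}\; 2^{k}\;
  \frac{n_A!\,n_B!}{(2N)!},$$

and the p-value sums the probabilities of all heterozygote counts no more
probable than the observed one (two-sided probability-mass ordering,
no mid-p). The implementation enumerates in log space; the test suite
checks it against an independent full enumeration for all counts up to 100
samples, and that the conditional distribution sums to one.

One caveat worth knowing: relaxing any *site-level* threshold can only grow
the kept set (property-tested), but the GQ-masking threshold interacts with
the call-completeness and MAF rules through the masked genotypes, so
monotonicity in `min_gq` is not guaranteed in pathological cases.

## Array selection

Selection happens in two passes. First, HIGH/MODERATE-impact candidates
(from an external effect-annotation table) are taken greedily left-to-right
per chromosome, subject to a 10 kb minimum spacing and a global budget of
10,000; past the budget, picks are kept by higher MAF then lower position.
Second, gap filling: target positions are laid on a fixed lattice
(12 kb on linkage groups, 33 kb on unmapped scaffolds longer than 50 kb —
shorter scaffolds get nothing), and a target not already covered by a
selected marker within half an interval is filled with the highest-MAF
candidate inside that window (ties: closest to the target, then smaller
position). Unfillable targets are reported. The original selection script
was not published, so three details are fixed here as package policy, all
configurable: the lattice is anchored at the chromosome start (a moving,
re-anchoring grid is available behind `moving_grid = TRUE`), the window is
± half the interval, and effect picks count as satisfying nearby targets.
A reject-list rescue pass (emulating external probe-scoring rejections)
re-runs the fill over windows whose pick was rejected. Manually curated
markers (e.g. mitochondrial) are appended via an include list. The fill is
tested against a brute-force per-target argmax oracle on random instances.

## Genotype QC

Per-sample and per-SNP call rates use an inclusive 0.97 threshold. SNPs are
classified into cluster categories computable from genotype codes alone:
`PolyHighResolution` (all three genotype classes), `NoMinorHom` (one
homozygote class absent), `MonoHighResolution` (a single homozygote
cluster), `CallRateBelowThreshold`, and `Other`. The intensity-based
off-target-variant (OTV) category and dish QC cannot be computed from
codes; when such exclusions exist they are consumed as pre-applied lists.
The mapping-ready subset is `PolyHighResolution ∪ NoMinorHom`, further
restricted to MAF > 0.05 before map construction.

## Parentage

Candidate parents are excluded by opposing homozygotes — marker genotypes
where parent and offspring are homozygous for opposite alleles, impossible
without genotyping error. The acceptance threshold defaults to a fraction
0.0024 of the pair's jointly called markers, mirroring the published
convention of 100 permitted conflicts on a 43,014-SNP panel (≈ 0.24% of
genotypes); an absolute threshold is available. With candidate sexes known
the assigned pair is the lowest-conflict accepted male and female; without
sexes, the two lowest-conflict candidates whose trio passes a Mendelian
consistency check (≤ 1% inconsistent markers by default). Offspring with
fewer than two accepted candidates stay unresolved — an expected outcome,
not an error. Families are full-sib groups by (sire, dam); groups below 8
offspring are dropped from the mapping set but reported.

The exclusion statistic needs a large panel to separate true parents from
unrelated candidates: the true-pair conflict rate is driven by the
genotyping error rate (≈ ε/2 × the parent homozygote fraction), while
unrelated pairs conflict at ≈ Σ2p²q² per marker. At a 0.5% error rate the
margin between the 0.24% threshold and the true-pair rate is only ~0.08%
of markers, so the z-separation grows like √(panel size) — with ~40k
markers assignments are essentially always correct; on a few-thousand
marker panel the same threshold misclassifies. This is why the package's
recovery study runs parentage on the full filtered panel rather than the
array subset.

## Map estimation under a fixed physical order

Markers are kept in assembly order (the "integrated physical" build); no
marker-order search is performed. For each parent and linkage group:

1. **Transmission resolution.** At markers where the parent is
   heterozygous, the transmitted allele is resolved whenever the offspring
   genotype and the other parent's genotype determine it uniquely;
   both-parents-het with a het offspring stays unknown, and
   Mendelian-impossible trios are flagged and left unknown.
2. **Phasing.** A phase bit per informative marker is chosen to minimise
   total crossovers over the parent's offspring. The 2-state chain
   decouples: between adjacent informative markers the cost is `d` flips
   under equal phase or `n − d` under opposite phase, so the optimum takes
   `min(d, n − d)` per link (tie → no flip); this equals exhaustive
   minimisation over all $2^M$ phase vectors (property-tested for
   M ≤ 12). Links supported by fewer than 3 jointly resolved offspring, or
   with an exact cost tie, are marked *broken*: the relative phase across
   them is unidentifiable (with a single mate, certain parental phase
   configurations make the joint-resolution set empty by construction),
   and haplotype comparisons across a broken link would inject spurious
   crossovers.
3. **Error masking.** Within each offspring's resolved haplotype-of-origin
   sequence, maximal blocks of short runs (≤ 2 markers per run) bounded by
   agreeing runs of ≥ 2 markers — or by the sequence edge — are masked as
   genotyping errors, the analog of an error-model parameter in HMM-based
   mappers. A genuine double crossover confined to two adjacent markers
   has probability ~r² per meiosis, far below the error rate; a genuine
   crossover flanked by a masked error block still yields exactly one flip
   across the gap. Toggle with `mask_flips`.
4. **Crossover counting.** Crossovers are observed as flips between
   *consecutive resolved* markers of each meiosis; each flip is assigned
   once to its bracketing span (skipping spans that cross a broken phase
   link) and distributed over the spanned physical intervals in proportion
   to their length. Per-interval recombination fractions pool the meioses
   of each parental sex (events / covering meioses, capped at 0.5 − 10⁻⁶);
   intervals never covered get a zero increment and a gap flag. When every
   marker is resolved in every meiosis this reduces to the textbook
   adjacent-pair estimator, but unlike that estimator its total-length
   sampling error scales with the meiosis count (σ ≈ √(R/N) Morgans)
   rather than with the much smaller count of meioses resolved at both
   flanking markers — the difference between a ~3–5% and a ~15% standard
   error at ~640 meioses per sex.
5. **Distances.** Interval distances come from the Kosambi function
   $d = 25\,\ln\frac{1+2r}{1-2r}$ (cM) by default; Haldane
   ($d = -50\,\ln(1-2r)$) is available so that recovery experiments can
   pair the interference-free simulator with its exactly matching mapping
   function. Cumulative sums give the female, male and sex-averaged
   tracks; the sex-averaged track pools meioses of both sexes rather than
   averaging the two cM tracks.

`map_summary()` produces the per-LG table (marker counts, physical length,
per-track lengths, F:M ratio to 2 decimals, densities per Mb and per cM,
and Marey correlations — product-moment by default, Spearman optionally,
since the original correlation method is not stated), and
`map_table_totals()` its totals/averages row.

## Recombination deserts and the sex locus

Deserts are maximal runs of intervals with recombination rate ≤ 0.05 cM/Mb
spanning ≥ 1 Mb, flagged terminal when they touch an LG end. High-rate
stretches accumulating ≤ 0.25 cM are bridged into the surrounding desert:
residual (unmaskable) genotyping-error events otherwise split a genuine
5 Mb desert into fragments, while a real recombining region is never this
flat over that much sequence.

Phenotypic sex (coded 12 = male, 11 = female) is treated as a test marker
at which sires are heterozygous (XY) and dams homozygous (XX); only sire
meioses are informative. For each marker, the recombination fraction with
sex pools over sires the minimum over the two possible marker-versus-Y
phases of the mismatch count between the sire's phased indicators and
offspring sex (the per-sire phase is unknown; the `min` has a small
downward bias at few offspring but does not move the peak). Tied minimal
markers form runs, and the peak is the run with the largest
informative-meiosis support — so an isolated, weakly informative zero
cannot outrank the true locus region. Inside a zero-recombination run the
locus is unlocalizable beyond cM resolution, exactly as in the published
tie run around the *amh* region; positional error should therefore be read
on the cM scale.

## The synthetic-data generator

The generator emulates the study's structure at a desk scale chosen once:

* **Genome:** three linkage groups of 35/30/40 Mb plus two unmapped
  scaffolds (120 kb and 30 kb), standing in for the 22 tilapia LGs; the
  scaffolds exercise the 33 kb / >50 kb selection rules.
* **Candidate variants:** Poisson-placed at a mean spacing of 2 kb, with
  founder minor-allele frequencies Uniform(0.02, 0.5); the fractions of
  indel records (5%), MNPs (1%), A/T-C/G SNPs (5%), multi-allelic sites
  (2%), sub-20 QUAL (5%) and sub-30 GQ (10%) draws exist to exercise the
  filter rules at rates that leave a realistic majority of clean sites.
* **Recombination:** per-LG sigmoid Marey curves (piecewise linear) with
  5 Mb terminal zero-recombination deserts, male rate 1.57 cM/Mb of
  physical length and a female:male total ratio of 1.2 — the published
  genome-wide averages. Crossovers per meiosis are Poisson with the
  sex-specific map length in Morgans as mean, positions uniform in cM and
  placed in bp by inverse Marey interpolation. The crossover process has
  no interference even though Kosambi estimation implies some; recovery
  experiments therefore run both sides with Haldane, and Kosambi remains
  the analysis default (for the small per-interval distances of a dense
  map the two agree to third order in r).
* **Families and sex:** a factorial pool of 17 sires × 16 dams, 41
  distinct full-sib families with sizes Poisson(16.81) floored at 8
  (expected total ≈ 689 offspring). Every sire carries Y on one haplotype;
  offspring sex is determined by the sire-transmitted allele at the
  configured locus (default: the largest LG at 86% of its length, i.e.
  34.5 Mb on the 40 Mb LG — just outside the terminal desert, as in the
  real *amh* region), so sex-locus mapping has a true answer.
* **Noise:** after transmission, each offspring genotype is flipped to a
  uniformly chosen different code with probability ε (default 0.2% — the
  study reports no error estimate; this is a typical post-QC array error
  rate) and set missing with probability 1%. Parents' genotypes can be
  noised too (`noise_scope = "all"`); the default noises offspring only,
  which is the regime in which the 100-conflict parentage convention has
  its published behaviour.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure among founders (sites are drawn independently),
selection history, batch or plate effects, intensity-level artefacts
(OTV clusters, dish QC), and assembly errors. Consequently, passing
recovery tests demonstrate the correctness of the algorithms under the
stated stochastic model — not robustness to misassembly or cluster-calling
artefacts in real data.

## Problem sizes and numerical choices

The bundled recovery study (`recovery_study()`) runs the full chain on the
default genome with 40 families × 16 offspring: ~52k candidate sites, ~31k
filtered SNPs, an ~8.5k-marker array panel for mapping, and the full
filtered panel for parentage. At 640 meioses per sex the irreducible
sampling error of a per-sex per-LG map length is ≈ 5%, of a sex-averaged
per-LG length ≈ 3.3%; recovery checks are therefore phrased on the
sex-averaged track per LG and on per-sex genome totals. Determinism: every
stage draws from a single seed; two runs with the same configuration are
identical byte for byte. Recombination fractions are capped at
0.5 − 10⁻⁶ before mapping-function transforms; percentages and ratios in
summary tables round half-away-from-zero to 2 decimals, with raw values
kept alongside.

## Known limitations

* The phasing/counting machinery assumes diploid, unphased genotypes and
  full-sib families with both parents genotyped; half-sib designs without
  one parent are out of scope.
* `Other` is a pattern-based proxy for the vendor's geometry-based
  category of the same name.
* The spacing of informative markers bounds crossover localisation: event
  positions inside a span are distributed by physical length, which
  smooths the local recombination profile at the ~50 kb scale (harmless at
  the ≥ 1 Mb scale of desert calls).
* Parentage with the default fractional threshold needs tens of thousands
  of markers to have its published operating characteristics; on small
  panels use an absolute threshold chosen for the panel.
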