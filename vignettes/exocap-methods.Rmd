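---
title: "Capture design and cross-platform concordance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capture design and cross-platform concordance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocap)
```

`exocap` bundles two workflows that in practice meet in the middle of an
exome-sequencing project: designing the hybridization capture probes that
define an exome panel, and auditing the variant calls that come back from
that panel against matched whole-genome sequencing. This vignette explains
the models and procedures, the parameters that matter, and the choices made
where the published description of the method leaves the design open.

## Target consolidation

Both halves of the toolkit operate on a single consolidated target set.
Coding features (CDS by default) are read from GFF3/GTF, converted once at
parse time to 0-based half-open coordinates, and merged into a sorted,
strand-agnostic union (`consolidate_targets()`). Book-ended intervals are
merged: since no adjacency rule is implied by a "non-overlapping" target
set, we produce the canonical minimal set, which also makes consolidation
idempotent — a property the test suite checks directly. Strand is carried
on features but ignored for merging, because capture hybridization is
strand-symmetric. `adjust_regions()` grows or shrinks the set symmetrically
(clipping at chromosome bounds and re-merging), and the same mechanism
serves the ±30 bp probe-selection flank, the +100 bp alignment-restriction
flank, and the −2 bp variant trimming described below.

## Probe design

The design algorithm scores and selects from a dense pool of candidates:

1. **Tiling.** Variable-length probes (50–100 bases) are tiled at a 5-base
   step across each target plus a 30-base flank allowance on both sides.
   By default lengths are enumerated at a 10-base step (50, 60, …, 100)
   rather than all 51 lengths; this keeps the candidate pool roughly
   an order of magnitude smaller while preserving the length diversity the
   selection needs. `probe_len_step = 1` restores full enumeration.
2. **Repetitiveness.** A genome-wide 15-mer histogram is built once
   (`build_kmer_index()`); a probe's repetitiveness is the mean count of
   its 15-mers, and any probe averaging above 100 is removed before any
   further characterization. K-mers are counted in canonical
   (strand-collapsed) form by default — hybridization cannot distinguish a
   k-mer from its reverse complement — with forward-only counting available
   via `canonical_kmers = FALSE`. Because the averaging window equals k,
   per-k-mer counting and windowed averaging coincide.
3. **Uniqueness.** A close match is a genome locus where any 30-base window
   of the probe aligns with at most 5 edits, on either strand. Probes with
   more than 5 close-match loci are discarded. The search is exact
   seed-and-verify: by pigeonhole, any 30-base alignment with ≤5 edits
   contains an exact 5-base seed from the 6 non-overlapping pieces, so
   exact 5-mer hits anchor a banded (±5-diagonal) semi-global DP whose
   reported match ends are provably identical to an exhaustive scan — the
   test suite verifies this equivalence against an independent full-DP
   oracle over hundreds of random probes. Overlapping hits on the same
   strand merge into one locus, so a single diffuse similarity cannot
   inflate the count, and the probe's own origin locus is included
   (`count_origin_locus = FALSE` flips that reading).
4. **Scoring.** Eligible probes get a combined score (lower is better):
   `w_rep·log10(1 + repetitiveness) + w_uni·max(0, close_matches − 1) +
   w_tm·|Tm − tm_target| + w_comp·composition`. The published description
   names the four ingredients but no combination rule; a weighted sum with
   weights (1, 1, 0.2, 1) is the simplest monotone combination, and the Tm
   weight of 0.2 puts a 5 °C deviation on the same footing as one extra
   close match. Melting temperature comes from nearest-neighbor
   thermodynamics with the unified parameter set at 50 mM monovalent salt
   and 250 pM per-strand concentration (verified against an independent
   implementation to within 0.5 °C); `tm_target` defaults to 75 °C, roughly
   the median Tm of mid-GC 50–100-mers under those conditions, so the
   penalty is symmetric around typical probes. The composition penalty,
   `w_gc·|GC − 0.5| + w_homo·max(0, longest_homopolymer − 5)`, penalises
   skewed base composition and synthesis-hostile homopolymers; both terms
   are reverse-complement invariant.
5. **Selection.** A 20-base window starts at the target start minus the
   flank allowance; among eligible candidates starting in the window the
   best-scoring is selected (ties broken leftmost start, then shortest
   length, for full determinism), and the window advances 40 bases until it
   passes the flanked target end. Windows with no eligible candidate
   contribute nothing, and targets that end up with zero probes are
   reported in the selection log rather than silently dropped.
6. **Coverage.** Target bases are classified as *direct* (under a selected
   probe), *indirect* (within `indirect_reach` of a probe terminus), or
   *uncovered*. "Indirect" coverage has no published definition; we define
   it by proximity with a default reach of 100 bp — about the span over
   which a captured fragment extends beyond its probe — and expose the
   reach as a parameter. With the default reach (≥ the 40-base window
   advance), any target base coverable by an eligible candidate ends up
   direct or indirect.

## Paired-platform concordance

Variant records from two platforms (conventionally exome capture as
platform a and whole-genome sequencing as platform b) are compared at site
level:

- **Classification before filtering.** A variant is *common* when the other
  platform has a record with identical chromosome, position, reference and
  alternate alleles; otherwise *platform-exclusive*. Classification runs on
  the unfiltered sets, and hard filters are applied per platform
  afterwards; this reproduces the published order and is why downstream
  common counts can differ slightly between platforms. Indel equality is
  exact string equality after upper-casing — inputs are assumed
  left-aligned by the caller.
- **Hard filtering.** GATK-style site filters: SNVs fail on QD < 2.0,
  FS > 60.0, SOR > 3.0, ReadPosRankSum < −8.0, MQ < 40.0 or
  MQRankSum < −12.5; indels on QD < 2.0, FS > 200.0, SOR > 10.0 or
  ReadPosRankSum < −20.0. Any matching rule fails the record. A missing
  statistic makes its rule inapplicable rather than failing the record,
  matching standard hard-filter practice (rank-sum annotations are absent
  at sites without heterozygotes); per-rule counts are attached so the
  choice is auditable. Nothing is deleted — records are tagged.
- **Target restriction.** Variants flanking the targets by ±2 bp are
  removed, implemented as shrinking each target by 2 bases per side and
  keeping strictly interior records. The alternative reading (keep targets
  *plus* 2 bp) is a sign flip away via `flank_trim = -2`.
- **Tables and spectra.** Consequence tables count common/exclusive
  variants per (impact, consequence) category among biallelic,
  filter-passing records of one type, with percentages of the row total at
  one decimal and "All" rollups; multi-allelic and non-SNV/indel records
  are excluded throughout. Ti/Tv uses the standard transition set
  (A↔G, C↔T) and reports an undefined ratio (NA) rather than infinity when
  no transversions exist. Allele counts sum alternate alleles over all
  samples at a site.

## Bias statistics

Per-gene counts come in two flavours: site-level per platform, and
per-individual, where an individual counts as carrying a site if they have
at least one alternate allele. Carrier counting is the natural reading of
"variants per individual" (allele-dose counting is available via
`dose = TRUE`). Platform bias per gene is the signed difference
(platform b − platform a, positive when the whole-genome side finds more),
with outliers defined as the largest positive differences — a difference,
not a ratio, because the quantity of interest is excess variant yield.
Sex bias per gene is `log2((mean_male + 1)/(mean_female + 1))`; the
pseudo-count keeps genes with zero counts in one sex finite and
antisymmetric under label swap. The sex-difference summary reports, for
each gene grouping × platform × chromosome class, the male and female
means, their absolute difference, and the difference as a percentage of
the male mean (the male denominator matches the published convention).
Chromosome class is a single configurable X name; everything else is
autosomal. Whether per-individual counts are taken before or after target
restriction is not specified in the published description; the package
computes them on whatever record set it is handed, and the shipped
workflows restrict first.

## What the synthetic fixtures emulate

`fixture_spec()` + `simulate_reference()` + `simulate_platform_pair()`
generate everything the test suite needs with no downloads:

- a uniform-random background genome (three chromosomes, one X-like, 12 kb
  each by default) with a 150-copy tandem repeat family — enough to trip
  the repetitiveness filter by an order of magnitude — and a five-gene
  paralog cluster at 2% divergence, the mechanism behind genuine
  close-match ambiguity (olfactory-receptor-like families);
- 18 four-exon genes (100-base exons), giving a 7.2 kb consolidated target;
- a ten-individual cohort with four males, matching the published matched
  cohort's composition;
- shared sites at a controlled shared fraction (default 0.9 — lower than
  the ≈0.99 observed in the real comparison so that exclusive classes are
  populated at toy scale), with allele frequencies uniform on (0.05, 0.5)
  and binomial genotypes;
- platform-exclusive singletons (allele count 1) at per-kb rates with a
  2.5:1 excess on the whole-genome side, emulating the error-driven
  singleton spikes;
- transition probabilities 0.797 for shared and 0.603 for exclusive SNVs,
  chosen so Ti/Tv recovers ≈3.92 and ≈1.52;
- male-only platform-b sites concentrated in 3 designated X genes at
  15 sites per gene, all four males heterozygous — an allele-count peak at
  exactly 4 — emulating degraded-Y gametolog mis-mapping; 15 sites per gene
  is deliberately larger than the per-gene shared background so the
  engineered genes separate cleanly in fold-change and outlier rankings;
- per-rule hard-filter failures injected at a configurable fraction
  (default 2%).

One global seed drives a named RNG stream per component (genome, paralogs,
sites, alleles, genotypes, stats, annotation), so changing one spec field
perturbs only its own stream, and all outputs are byte-identical across
reruns under a fixed seed.

The generator is deliberately not a population-genetic simulator: no
coalescent structure, no linkage, no X hemizygosity in the genotype model,
no read-level error process, and no capture-efficiency model. Passing
tests therefore demonstrate that the algorithms recover the structure they
are specified to recover, not that real capture data will behave this way.

## Numerical and scale choices

- All randomness in the package lives in the fixture generator; the design
  and analysis paths are fully deterministic, with explicit tie-breaks.
- Close-match verification uses banded DP with an early exit when a row's
  minimum exceeds the edit budget; the band is provably sufficient for
  seed-anchored alignments.
- Degenerate inputs: empty annotations give empty designs (not errors);
  targets shorter than the minimum probe length, windows with no eligible
  candidates, and regions that vanish under negative padding are reported
  with warnings/logs; zero transversions and single-sex cohorts yield NA
  statistics rather than infinities.
- Test problem sizes: oracle-equivalence suites use ≤6 kb genomes with 200
  randomized probes (exact agreement required); parameter-recovery suites
  use a ~67 kb-target cohort (~13,000 sites) for spectral quantities and
  the default 7.2 kb-target cohort for structural ones; the full design
  path runs on the default three-chromosome fixture. These sizes keep the
  entire suite in the low minutes on one CPU while leaving every algorithm
  on its genome-scale code path.

## Known limitations

- Close-match counting at whole-mammalian-genome scale would want a
  compressed index and a C-level batch interface per chromosome; the
  current implementation is tuned for the multi-kilobase fixtures it ships
  with, though nothing in the algorithm is desk-scale-specific.
- Indel comparison assumes caller-normalized alleles; no left-alignment is
  performed.
- The consequence annotation is consumed, never computed: the package
  expects an external predictor's output keyed by (chrom, pos, ref, alt).
- Y-chromosome probe content is accepted as extra FASTA records but gets
  no dedicated logic.
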