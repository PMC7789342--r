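---
title: "Methods and design notes for ssrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ssrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpipe)
```

# Scope

`ssrpipe` implements a genome-survey-to-SSR-marker workflow for species
without a reference genome, of the kind used for large, repetitive,
polyploid grasses: paired-end read quality filtering, k-mer-spectrum
genome characterization, perfect microsatellite (SSR) mining with motif
canonicalization, primer screening with in-silico single-/multi-locus
classification, and a marker evaluation suite (allelic diversity, PIC,
Nei distance, UPGMA, PCoA, AMOVA/PhiPT, Mann-Whitney marker-system
comparison). Everything runs at desk scale on synthetic inputs with known
ground truth; the simulators are first-class, tested code.

# Read filtering

A read pair is removed when either mate (i) has 10% or more uncalled
bases (N), (ii) has more than 10 of its 3' bases aligning to the adapter
with at most 10% mismatches, or (iii) has more than 50% of bases below
phred 5. Exact duplicate pairs (putative PCR duplicates) are removed when
deduplication is on. The N rule is strict (`>= max_n_fraction` drops) and
the low-quality rule inclusive (`> max_lowq_fraction` drops), matching the
usual phrasing "less than 10% N" and "at most 50% low-quality bases". The
adapter check is an ungapped 3'-suffix overlap against a configurable
adapter sequence; no aligner is specified by convention, so the simplest
end-overlap model is used and exposed through `read_filter_params()`.
Filtering is idempotent.

# K-mer survey

`kmer_histogram()` counts canonical 25-mers (strand-collapsed,
N-containing k-mers skipped) in compiled code and reports the
depth-to-distinct-count table; `kmer_num` is the total occurrence count,
`sum(depth * count)`, an invariant asserted in the tests.

Genome size follows the standard survey identity

$$\hat G = \frac{\text{k-mer num}}{\text{peak depth}}$$

with the peak taken as the histogram maximum beyond the error region. The
error boundary is the first depth at which the count stops decreasing: an
error spike always decays from depth 1, and no method is conventionally
stated for the boundary, so the first local minimum is used and exposed.
A monotone-decreasing histogram has no coverage peak and is an error.

Heterozygosity and repeat content are deliberately heuristic:
heterozygous k-mers accumulate near half the peak depth, so the distinct
mass in `[0.4, 0.6] x peak` over the total non-error distinct mass,
divided by `2k`, approximates the per-base heterozygosity (a heterozygous
site creates about `k` new k-mers per haplotype). Repetitive content is
the occurrence mass beyond `1.8 x peak` over the total non-error
occurrence mass. Both windows are configurable and validated only by
simulation (factor-two accuracy for heterozygosity; about 0.05 absolute
for the repeat fraction); they are survey figures, not measurements.

Assembly statistics (N50/N90, threshold counts, base composition) are
conventional; GC content is computed over called bases only,
`(C+G)/(A+C+G+T)`, because assemblies carry N gaps. Per-library depth is
`clean yield / genome size`, reported to two decimals.

# SSR mining

Perfect SSRs are maximal non-extendable runs of a primitive 1-6 nt motif
meeting per-length minimum repeat numbers (defaults: 8 for
mononucleotides, 5 otherwise — the MISA convention, reading "more than 5"
as "5 or more" since repeat number 5 is the first bin of the motif
frequency distributions this reproduces). Runs are reported once, under
the primitive motif in its leftmost phase, with 1-based inclusive
coordinates; partial trailing copies are not counted; runs never span an
N. Compound or interrupted SSRs are not merged: the motif statistics are
pure-class counts. The implementation is regex-based (backreference
repetition per motif length) and is cross-checked in the tests against an
independent period-vector enumerator on random sequences.

Motif classes collapse cyclic rotation and reverse complement
(`canonical_motif()`). The representative is the lexicographically
smallest rotation over the motif and its reverse complement, with one
refinement: when the class contains a rotation that equals its own
reverse complement (e.g. CATG), the smallest such palindromic rotation is
preferred, so the class renders "CATG/CATG" as in the field's tables
rather than splitting the palindrome into "ATGC/GCAT". Published tables
sometimes rotate the complement for display (e.g. "TTTTA" for "ATTTT")
or use the most frequently observed form (e.g. "CTC/GAG" where the
canonical representative is "AGG/CCT"); those are aliases of the same
class, and class membership — tested exhaustively for all primitive
motifs up to length 6 — is invariant under rotation and reverse
complement.

A scaffold is a single-locus SSR candidate (`single_ssr_scaffolds()`)
when it carries exactly one SSR whose 100 bp flanks each occur at exactly
one site in the assembly (exact match, either strand). "Unique in the
assembly" is not precisely defined by convention; flank uniqueness is the
property that actually predicts single-site amplification, so it is the
implemented reading.

# Primer screening

Candidates are enumerated from the SSR flanks under the usual SSR-marker
constraints (18-27 bp, Tm 55-65 °C, GC 30-70%, product 100-300 bp, all
configurable), plus a homopolymer cap of 4 to avoid slippage-prone
oligos. Melting temperatures use unified nearest-neighbor thermodynamics
(SantaLucia's 1998 parameter set) with 50 mM monovalent salt via the
entropic correction `0.368 (n-1) ln[Na+]` and 50 nM total oligo under the
`R ln(C_T/4)` term; the tests pin three Tm values against an independent
implementation of the same model. Pairs are ranked by Tm balance, then by
product-length centrality, ties broken by leftmost forward position for
determinism.

In-silico PCR reports every site where the primers bind opposite strands
with converging 3' ends, at most `max_mismatches` per primer (default 0,
the strictest reading of mapping primers back to the assembly), an exact
match over the 3'-terminal 3 bases (standard e-PCR behaviour), and a
product of at most 1 kb. Both primer-role orientations are searched.
One site classifies the marker single-locus, several multi-locus, none
"none"; the gel-data analogue counts bands: at most 2 bands in a diploid
and polymorphic = single-locus, more than 2 and polymorphic =
multi-locus, monomorphic = discarded.

# Marker evaluation

For a codominant locus with allele frequencies $p_i$ over non-missing
genotypes: $N_a$ = observed alleles, $N_e = 1/\sum p_i^2$,
$I = -\sum p_i \ln p_i$, $H_o$ = observed heterozygote fraction,
$H_e = 1 - \sum p_i^2$ (uncorrected, matching the software convention
these tables come from; an unbiased variant is available by flag), and
Botstein's
$\mathrm{PIC} = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2 \le H_e$.
Missing genotypes are excluded locus-wise, which is required to reproduce
observed heterozygosities with odd denominators (e.g. 2/23). Group
summaries average over loci within groups; the percentage of polymorphic
loci (PP) counts loci with $N_a \ge 2$; the final Mean row is the
unweighted mean over groups, which is what reproduces the published mean
rows. Dominant (0/1 band) data get the standard band indices: per band
frequency $f$, $\mathrm{PIC_{dom}} = 2f(1-f)$, band informativeness
$I_b = 1 - 2|0.5 - f|$, $BI = \overline{I_b}$, resolving power
$R_p = \sum I_b$ (Prevost-Wilkinson), and marker index
$MI = \overline{\mathrm{PIC_{dom}}} \times$ polymorphic band count. These
dominant formulas are documented choices: the corresponding published
per-primer values are in supplementary material only and cannot be
cross-checked here.

Nei's (1972) standard distance is computed between accessions on their
per-accession allele profiles (codominant) or as one minus Dice
similarity (dominant) — the source method states only "Nei's genetic
distance", so the classical codominant formula and the usual binary
analogue are used. UPGMA is average-linkage agglomeration (ultrametric by
construction; root height = max cophenetic distance / 2); bootstrap
resamples loci, and clade support is reported in `node.label` as
percentages. PCoA is the Gower double-centering
$B = -\tfrac12 J D^{(2)} J$ with eigendecomposition; coordinates are
scaled by the square root of the positive eigenvalues and negative
eigenvalues are reported, not corrected.

## AMOVA

Squared inter-individual distances are half squared Euclidean distances
between allele-count vectors (the Smouse-Peakall codominant genotype
distance: shared-allele pairs score 1, AA-vs-BB 4, AB-vs-CD 2), or plain
squared Euclidean distances on band vectors. With $k$ groups of sizes
$n_i$, $N = \sum n_i$:

$$SS_{tot} = \tfrac1N \sum_{i<j} d^2_{ij}, \qquad
  SS_{within} = \sum_g \tfrac1{n_g}\sum_{i<j \in g} d^2_{ij}, \qquad
  SS_{among} = SS_{tot} - SS_{within}$$

$$n_0 = \frac{N - \sum n_i^2/N}{k-1}, \qquad
  \sigma^2_a = \frac{MS_a - MS_w}{n_0}, \qquad
  \Phi_{PT} = F_{st} = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_w}$$

Negative among-group components are truncated at zero with a warning
(standard practice). The permutation p-value permutes individuals across
groups, `(1 + #{Fst* >= Fst}) / (permutations + 1)`, default 999.
Gene flow uses the island-model translation `Nm = (1 - Fst)/(4 Fst)`;
published Nm values for these tables are not reproduced by that formula
on their own Fst values, so Nm is reported from the formula and the
published numbers are not targeted. Where a published total sequencing
depth or GC figure is inconsistent with its own row-level data, the
row-level definition is implemented and the total left alone.

The Mann-Whitney comparison of marker systems uses exhaustive enumeration
of all group assignments for up to 10 observations per side (a
permutation test on `|U - n1 n2 / 2|`, exact under ties; identical
samples give p = 1, complete separation at 3 vs 3 gives p = 0.1) and the
tie-corrected normal approximation otherwise.

# Synthetic data: the stated world

`simulate_genome()` builds i.i.d. background at the requested GC
(default 0.44, a typical grass genome), plants perfect SSRs at given or
random positions, and then *repairs* the background: any detected run
that is not exactly a planted locus is broken by a point substitution
outside the planted intervals, iterating until detection recovers the
truth table exactly. This keeps ground truth exhaustive, so
recall/precision tests are exact rather than probabilistic.
`duplication_fraction` appends verbatim scaffold copies, creating
genuine multi-locus sites with known provenance.

`simulate_reads()` draws fixed-size fragments (default insert 270 bp,
read length 150 bp — the short-insert survey library layout) uniformly
along scaffolds, with independent per-base substitution errors, per-base
N masking, a two-state (high/low) phred model so the phred-5 filter rule
is exercisable, and optional exact duplicate pairs (a
`duplicate_fraction` of 0.5 makes about half the output pairs members of
identical twins). It does not model indels, quality decay along the
read, or GC bias; a green filter/survey test therefore establishes
correctness of the bookkeeping and the estimators under the stated
model, not robustness to real instrument artefacts.

`simulate_population()` draws group allele frequencies from a common
ancestral Dirichlet vector by a Balding-Nichols draw. The calibration is
the one genuinely open design point: the package's AMOVA estimates
PhiPT from *diploid genotype* distances, and under a Balding-Nichols
draw with parameter $\theta$ the expected PhiPT is $2\theta/(1+\theta)$,
not $\theta$ (the within-group genotypic variance is $2\bar p\bar
q(1-\theta)$ while the among-group variance of genotype means is
$4\theta\bar p\bar q$). Since `target_fst` is defined as the
differentiation the pipeline itself measures, the generator uses
$\theta = F/(2-F)$ so that the expected AMOVA-estimated Fst equals
`target_fst`; with the naive parameterization the documented recovery
property (0.25 recovered within 0.05, bias under 0.02 at 500 loci) is
structurally unattainable (simulated PhiPT converges to 0.40). Genotypes
are drawn under Hardy-Weinberg within groups, with 2-5 alleles per locus
and uniform missingness — the missingness pattern of real panels is
unknowable, so uniform is the stated choice. Loci are independent (no
linkage disequilibrium) and there is no selfing model.

The UPGMA topology-recovery property is evaluated on two groups of 8 at
`target_fst` 0.25 with 100 loci: panels of about a hundred SSR loci are
the scale at which average-linkage clustering of Nei distances becomes a
consistent group separator at moderate differentiation (at the strong
differentiation of the motivating study, about 0.55, ten loci suffice,
which is why such small published panels still resolve geographic
groups).

# Numerical notes and limitations

* The histogram peak is an integer depth, so genome-size estimates are
  granular at about `1/peak` relative; tests use bounds that accommodate
  this.
* Nei distances are infinite for accession pairs sharing no alleles
  anywhere; such entries are capped at 1.1 times the largest finite
  distance with a warning so clustering remains defined.
* All generators are pure functions of their seeds; the CLI derives all
  stage seeds from one root seed, and manifests record parameters (but
  no timestamps) so outputs are byte-reproducible.
* In-silico PCR treats any non-ACGT template base as a mismatch and
  requires the 3-base 3' anchor to match exactly; it does not model
  primer-dimer or secondary-structure effects.
* The genome-scale published figures (total yield, 6.86 Gb genome size,
  assembly GC, 67,833 primer pairs, heterozygosity 0.01%, repeats
  73.23%) require the raw sequencing runs and are covered here by the
  property-based substitutes in `tests/testthat/test-acceptance.R`
  (estimator accuracy on simulations with known truth), not by
  re-measurement.
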