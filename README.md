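# ssrpipe

Developing microsatellite (SSR) markers for a species with no reference
genome usually starts from a low-coverage "genome survey": short-read
sequencing, a k-mer spectrum to size the genome, a rough assembly mined
for perfect repeats, primer design around candidate loci, and an
in-silico screen separating *single-locus* markers (one amplification
site; at most two bands in a diploid) from *multi-locus* ones (several
homoeologous/paralogous sites) — a distinction that matters greatly in
large, repetitive, polyploid genomes such as forage grasses. The new
markers are then evaluated on an accession panel with the standard
population-genetics toolkit.

`ssrpipe` implements that whole workflow as a tested R package:

* **simdata** — seeded simulators with exact ground truth: genomes with
  planted SSRs (background repaired so the truth table is exhaustive),
  paired-end reads (errors, N bases, two-state qualities, PCR
  duplicates), and structured diploid genotype/band panels calibrated so
  the AMOVA-estimated Fst matches a target.
* **kmer_survey** — read filtering (N / adapter / low-quality rules,
  deduplication), canonical k-mer histograms (compiled counting kernel),
  genome size = k-mer num / peak depth, heuristic heterozygosity and
  repeat-content estimates, assembly N50/GC statistics, library depths.
* **ssr_mining** — perfect-SSR detection (MISA-style thresholds: mono >= 8
  repeats, di- to hexa- >= 5), motif canonicalization by rotation +
  reverse complement (`"AG/CT"`, `"A/T"`, `"CATG/CATG"`), motif summary
  tables, and unique-flank single-locus candidate scaffolds.
* **primer_screen** — primer candidates under the classic constraints
  (18–27 bp, Tm 55–65 °C by nearest-neighbor thermodynamics, GC 30–70%,
  product 100–300 bp), exhaustive in-silico PCR with a 3'-anchor rule,
  and single/multi/none verdicts (plus the 0–2-band gel rule).
* **popgen** — Na/Ne/I/Ho/He/PIC per locus and per group, dominant-band
  indices (PIC, BI, Rp, MI), Nei (1972) distances, UPGMA with locus
  bootstrap, PCoA, one-level AMOVA with PhiPT/Fst, permutation p-values
  and gene flow Nm = (1 − Fst)/(4 Fst), and an exact Mann-Whitney test.
* **cli** — `simulate | filter | survey | mine | primers | epcr |
  evaluate` subcommands over plain text formats with JSON run manifests
  (`run_subcommand()`, or `inst/exec/ssrpipe` with `Rscript`).

The AMOVA at the heart of the marker evaluation partitions squared
genotype distances among and within groups:

    n0  = (N − Σ nᵢ²/N) / (k − 1)
    σ²a = (MS_among − MS_within) / n0,   σ²w = MS_within
    Fst = ΦPT = σ²a / (σ²a + σ²w)

## Worked example

The published AMOVA design this package reproduces has 27 accessions in
three geo-groups of 8, 6 and 13, with printed sums of squares 74.960
(among) and 78.003 (within):

```r
library(ssrpipe)
amova_components(ss_among = 74.960, ss_within = 78.003,
                 group_sizes = c(8, 6, 13))
#> AMOVA: df 2/24  SS 74.960/78.003  PMV 55.28%/44.72%  Fst 0.553  Nm 0.2022  p NA
```

`n0 = 8.5185`, `σ²a = 4.0183`, `σ²w = 3.2501`: 55.28% of molecular
variance lies among geo-groups, i.e. strong differentiation
(`Fst = 0.553`). A marker scored on that panel as 26 heterozygotes and
one homozygote gives the printed diversity entries:

```r
m <- matrix(c(rep("1/2", 26), "1/1"), ncol = 1,
            dimnames = list(NULL, "SL10"))
locus_stats(m)[, c("n", "Na", "Ho", "PIC")]
#>    n Na       Ho       PIC
#> 1 27  2 0.962963 0.3746568
```

(`Ho = 0.963`, `PIC = 0.375` at the printed precision.) An end-to-end
synthetic run:

```r
run_subcommand("simulate", c("--out", "run/sim", "--seed", "5",
                             "--scaffolds", "20", "--length", "5000",
                             "--depth", "30", "--groups", "8,6,13"))
run_subcommand("survey",   c("--r1", "run/sim/reads_1.fastq",
                             "--r2", "run/sim/reads_2.fastq",
                             "--out", "run/survey", "--k", "25",
                             "--assembly", "run/sim/genome.fasta"))
run_subcommand("mine",     c("--assembly", "run/sim/genome.fasta",
                             "--out", "run/mine"))
run_subcommand("evaluate", c("--genotypes", "run/sim/genotypes.tsv",
                             "--groups", "run/sim/groups.tsv",
                             "--out", "run/eval"))
```

Every output is a TSV/FASTA/FASTQ/newick/JSON text file with a
`# columns:` schema header, byte-identical across runs at a fixed seed.
A small synthetic worked-example panel ships in `inst/extdata/`
(`worked_genotypes.tsv`, `worked_groups.tsv`).

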