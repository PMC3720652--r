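---
title: "gobylite: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gobylite: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gobylite)
```

gobylite reimplements, at desk scale, the analysis core of a
grid-based high-throughput sequencing pipeline: a chunked
scatter/gather execution engine, RNA-seq quantification and
differential-expression statistics, bisulfite methylation analysis,
and pathogen-contamination screening, together with a simulator that
provides ground truth for all of them. This vignette explains the
models and procedures, the parameters that matter, and the choices
made where the design was genuinely open.

## Chunked scatter/gather execution

Large read files are processed as emulated *array jobs*: the file is
split into byte ranges of `chunk_size` bytes (default 50,000,000,
about 50 MB), each range becomes one task, and task `i` covers the
inclusive byte range `[(i-1)*chunk_size, i*chunk_size - 1]`. The
number of tasks is `ceiling(file_size / chunk_size)`; a 30 GiB reads
file therefore plans 645 chunks. We clamp the final task's end offset
to `file_size - 1`; the arithmetic upstream of the clamp is otherwise
exactly the task-index formula.

A *plugin* supplies four functions — plan the split, count chunks,
process one chunk, combine part results — and the engine guarantees:

* every chunk yields exactly one task result (`completed` or
  `failed`);
* `combine` runs over the completed parts in task order even when some
  tasks failed, so a run with partial failures still produces output
  for the data that could be processed;
* only an all-task failure marks the run failed.

Tasks run on a local forked worker pool. Results are combined in
task order regardless of completion order, which makes the output
deterministic and byte-identical to single-threaded processing for
any order-preserving `combine`. Gathering uses
`recursive_concat()`, which merges at most `fan_in` (default 100)
pieces at a time and recurses over intermediate merges; the output is
byte-identical to a direct concatenation — the recursion exists only
to bound simultaneously open file handles.

**Record boundaries.** Text FASTQ/SAM have no chunk-aligned records,
so a record belongs to the chunk containing its *first byte*. A worker
seeks to its chunk start, skips a partial line, locates the four-line
FASTQ phase (a `@` line whose third successor is a `+` line with
matching sequence/quality lengths, cross-checked against the following
record because quality strings may begin with `@`), and reads records
until the first one starting beyond the chunk end. This partitions the
file's records across chunks with no duplication, which the tests
verify against a whole-file parse for several chunk sizes.

## Expression quantification and testing

**Fragments and counting.** One mapped primary alignment record is one
fragment; secondary and supplementary records are ignored. A fragment
counts toward every annotation it overlaps by at least one base,
strand-blind by default (`stranded = TRUE` restricts to the
annotation's strand). Junction counting keys each `N` CIGAR operation
by chromosome and the intronic interval it skips; a read spanning
*k* junctions increments *k* counters.

**RPKM.** With count `c`, annotation length `L` (bases) and
normalization factor `N`:

$$ r = \frac{c + 1}{(L/1000)\,(N/10^6)} $$

The +1 pseudocount keeps `log2(r)` finite at zero counts. `N` is
either the sample's total aligned fragments (classic RPKM) or the
75th percentile of the sample's annotation counts (upper-quartile
normalization, which removes the dominance of a few very highly
expressed genes). We use the nearest-rank percentile over annotations
with nonzero counts; zero-count annotations carry no information about
sequencing depth and would drag the quartile toward zero in sparse
annotations sets.

**Heptamer weights.** Random-hexamer priming biases the base
composition of read starts. Each read is weighted by
`f_distal(h) / f_start(h)`, where `h` is the read's initial heptamer,
`f_start` its frequency among read starts, and `f_distal` its
frequency among heptamers starting at read positions 24–30, a window
distal enough for the priming bias to have decayed. Weighted counts
are the sum of weights of overlapping fragments; unit weights
reproduce unweighted counting exactly. Reads shorter than 36 bases
(position 30 + 7 − 1) cannot supply a distal heptamer and keep weight
1 with a warning.

**Statistics.** Differential expression between two groups reports
both a two-sided Fisher exact test on pooled raw counts
(`[[cA, TA−cA], [cB, TB−cB]]`) and a pooled-variance (non-moderated)
Student t test on per-sample `log2(RPKM)` — log scale because
expression is reported on it and group variances are more comparable
there. The Fisher test always uses unweighted integer counts, because
exact tests require integers even when weighted counts are reported
alongside. Both p-value families receive Benjamini–Hochberg step-up
adjustment. Groups with fewer than two samples make the t statistic
undefined; it is flagged `NA`, never zero.

The Fisher test's sampling model is binomial draws from pooled
fragment totals. Its type-I calibration is checked under exactly that
null — Poisson counts (`dispersion = 0`), no effect — where the
rejection rate at α = 0.05 must sit inside the 99% binomial confidence
band over 2,000 simulated genes. With biological overdispersion the
pooled-count Fisher test is anti-conservative by construction; that is
a known property of the statistic, not of this implementation, and is
why the simulator's default dispersion (0.1, a typical RNA-seq value)
is *not* used for the calibration check.

## Bisulfite methylation analysis

Bisulfite treatment converts unmethylated cytosines to uracil (read as
T) and leaves methylated cytosines intact. At a plus-strand cytosine
(reference C), forward-aligned reads showing C are methylated evidence
(`Cm`) and T converted evidence (`Cu`); at a minus-strand cytosine
(reference G), reverse-aligned reads showing G/A play the same roles
in reference-forward orientation. Any other base is non-informative
and ignored; reads on the non-interrogating strand never contribute.
Only sites with at least one informative observation are emitted. The
methylation rate is `Cm/(Cm+Cu)` with **no** pseudocount; a site with
zero informative coverage is a no-call (`NA`), never 0.

Cytosine context (CpG/CHG/CHH) is assigned from the reference only and
reported but never filtered on. Region-level aggregation sums counts
over member sites and recomputes the rate from the sums
(count-weighted, not a mean of site rates, so deep sites dominate as
they should).

**Differential methylation.** Samples are organized in up to 10
groups with an arbitrary list of pairwise comparisons. Counts are
pooled by summing within each group — the procedure tests groups, not
samples — and each site gets a two-sided Fisher exact test on
`[[Cm₁, Cu₁], [Cm₂, Cu₂]]` per comparison. BH adjustment runs across
all tested sites *within* each comparison; comparisons are separate
hypothesis families. Sites with zero pooled coverage in either group
are flagged missing and excluded from the family. No minimum-coverage
threshold beyond nonzero pooled coverage is applied by default; the
BH family size always equals the number of non-missing statistics.

**Output.** Base-level results are written as VCF 4.1: REF is the
cytosine's reference base (C plus strand, G minus strand), per-sample
`MR:MC:UC` genotype fields carry rate and counts, and per-comparison
`FP_*`/`FQ_*` INFO fields carry the statistics. The writer refuses
unsorted input rather than silently reordering. Region-level results
use the tab-delimited `.igv` track dialect (chromosome, 0-based start,
end, feature, one rate column per sample). Internally all coordinates
are 1-based closed intervals held in `GRanges` — the native
convention of the genomic containers this package builds on — and the
BED (0-based half-open) and GTF (1-based inclusive) conversions are
delegated to `rtracklayer` and covered by round-trip tests in both
directions. Duplicate reads are not collapsed: deduplication is
protocol-dependent (RRBS fragments legitimately stack) and belongs
upstream.

## Pathogen screening

Reads with no mapped alignment are candidate contamination. The
screening chain is: extract unmapped reads (exact id-set difference,
order preserved), optionally trim a 3' adapter, assemble (delegated;
a passthrough stub treats each read as a contig for desk tests), and
filter contig-vs-database matches. A match is *annotated* only if its
alignment length strictly exceeds 150 bp **and** its E-value is
strictly below 1e-6; the filter is applied per match record, is
idempotent and order-preserving. The species summary reports, per
organism, the number of distinct samples with at least one annotated
contig — duplicated contigs within a sample never inflate it — plus
per-sample contig counts, sorted by sample count then name.

**Adapter rule.** The longest exact suffix of the read matching a
prefix of the adapter is removed *only if* the match exceeds four
bases; a 4-base terminal match is left untouched (too likely by
chance), a 5-base match is trimmed. Qualities are trimmed in lockstep.
The match model is exact (no mismatches) by default.

## The simulator

The generators define the study conditions every test runs under:

* `simulate_genome()` — i.i.d. bases at a target GC fraction
  (default 0.5).
* `simulate_methylome()` — an independent uniform rate per cytosine on
  both strands (any distribution can be substituted).
* `simulate_bisulfite_reads()` — fixed-length (default 100 bp),
  error-free, single-end reads placed uniformly on both strands at a
  target mean coverage; at each covered cytosine the emitted base is
  unconverted with probability equal to the site's true rate.
  Alignments encoding the true placements (CIGAR `<len>M`, MAPQ 60, no
  soft clips, one alignment per read) are emitted alongside, so
  methylation calling is testable without an aligner. The generator
  records the per-site informative tallies its bases actually carry;
  site calling must recover those *exactly* (conservation), and rate
  estimates must be unbiased within 3 standard errors at depth ≥ 50.
  Sequencing error is off by default and available as a uniform
  substitution rate; conversion efficiency defaults to 1.
* `simulate_count_table()` — log-normal gene baselines (sdlog 1 around
  a median of 50), negative-binomial counts at dispersion 0.1 by
  default (Poisson at 0), with a flagged 10% of genes carrying a fold
  effect in group B when an effect is requested.
* `simulate_contig_matches()` — per organism, a known subset of
  samples receives passing matches, and every sample receives boundary
  decoys (lengths 149–152 crossed with E-values 1e-5 to 1e-8) with
  recorded pass/fail truth.

All generators are bit-reproducible for a fixed seed. What they do
*not* emulate — positional coverage biases, RRBS fragment-size
selection, paired ends, indels, quality decay, empirical error
profiles — bounds what passing tests show: correctness of the
counting, testing and serialization machinery under its own sampling
assumptions, not robustness to real-library artifacts.

**Problem sizes.** The methylation-recovery protocol runs on a 100 kb
genome at 50X and 250X (roughly 50,000 cytosine sites and up to
250,000 reads), large enough that the coverage-dependent error
contrast (mean absolute error at 250X strictly below 50X, both near
the binomial sampling floor) is unambiguous; the statistical
calibrations use 2,000 genes and 1,000 random p-vectors. A 5 Mb
region behaves identically per-site and can be produced by the same
generators when wanted.

## Numerical and degenerate-input choices

* Fisher p-values use the conventional two-sided rule: the sum of
  hypergeometric outcome probabilities not exceeding the observed
  one (with relative tolerance 1e-7 for ties); tests verify equality
  with full fixed-margin enumeration.
* `bh_adjust` caps at 1 and passes `NA` through without counting it
  toward the family size.
* Zero-coverage methylation sites, sub-minimum t-test groups, and
  empty region aggregates are all `NA`-flagged, never zeroed.
* An all-zero sample under upper-quartile normalization is an error
  (the factor would be 0), not a silent fallback.
* Empty inputs produce structurally valid empty outputs (0-task
  plans, header-only VCFs, empty summaries); the one-chunk plan and
  singleton combine are identities.
* Byte offsets are doubles (exact for file sizes far beyond 2^31);
  task ids and genomic positions are integers.

## Known limitations

* SAM parsing handles the eleven mandatory columns and M/I/D/N/S/H/=
  /X CIGARs; BAM input should be converted to SAM text (or processed
  with `Rsamtools`) first.
* The engine chunks text formats only; coordinate-chunking of BAM is
  out of scope.
* The pooled Fisher test ignores within-group biological variability —
  by design, with the anti-conservativeness documented above; the
  moderated alternatives live in dedicated packages.
* Adapter trimming is exact-match suffix/prefix only.
* The species summary trusts the provided organism labels; taxonomy
  resolution is out of scope.
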