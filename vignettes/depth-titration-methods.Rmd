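---
title: "Depth titration and assembly completeness metrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth titration and assembly completeness metrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titrasm)
```

# Motivation

How much long-read sequencing does a repeat-rich plant genome need, and
how long do the reads have to be? The classic design for answering this
is a titration: sequence one genotype deeply (the maize inbred NC358 was
sequenced to 75-fold with a 21.2-kb subread N50), assemble nested subsets
of the data at descending depths and shifted read-length distributions,
and measure what each assembly recovers — overall contiguity, gene space,
and, hardest of all, the tandem-repeat space of knobs, centromeric
satellite, rDNA and telomeres. `titrasm` implements the measurement half
of that design as reusable components: the two downsampling procedures,
the assembly metrics, the repeat-space evaluation, and the compute-cost
scaling model, together with a synthetic-genome generator that provides
ground truth so every metric can be validated end to end without a
sequencing budget.

The assemblers themselves (Falcon, Canu and their hybrids), polishing,
optical-map scaffolding and gene annotation are deliberately out of
scope: `titrasm` evaluates read sets and assemblies, it does not produce
assemblies from reads.

# Serial depth titration

`serial_downsample()` draws a descending ladder of depth subsets such
that **each subset is a superset of the next smaller one**: the largest
subset is drawn from the full read set by seeded uniform sampling of
reads without replacement, accumulating reads until the base total
crosses `depth * genome_size` (the crossing read is included), and each
subsequent subset is drawn the same way from the previous subset. Nesting
ensures that differences between depth conditions are attributable to
depth, not to sampling noise between independent draws. Because reads
are sampled uniformly, each subset inherits the full set's length
distribution; the tests quantify this with a Kolmogorov–Smirnov distance
below 0.05 against the full set on fixtures of several thousand reads.
The base-total tolerance defaults to 0.5% overshoot; with read lengths
of tens of kb against targets of tens of Mb and up, the crossing read
changes the total by far less than that.

# Read-length distribution shifting

To isolate read *length* from depth, a read set is resampled onto an
empirical target length distribution by sample-and-clip
(`match_length_distribution()`): target lengths are processed in
descending order; for each target length one pool read at least that
long is chosen uniformly at random and clipped to exactly that length,
and the unused remainder returns to the pool for further use with
shorter targets. Choices the procedure leaves open, decided here once:

* **Cut position.** The clip keeps the read prefix; the remnant is the
  suffix. The cut position is not biologically meaningful for a length
  distribution, and a prefix cut keeps the provenance arithmetic
  (`source_id`, 0-based `source_offset`) trivial to verify — every
  output read is checkable as a contiguous substring of its source.
* **Eligibility at equal length.** A pool read exactly equal to the
  target is eligible (`>=`, not `>`); otherwise a source could not
  reproduce its own distribution.
* **Remnant floor.** Remnants shorter than `min_remnant` (default
  1,000 bp, the order of the shortest alignment lengths long-read
  pipelines use) are discarded rather than returned to the pool.
  Remnants that do return are ordinary pool members and may be clipped
  again.
* **Infeasible targets** (no pool read long enough) are skipped and
  counted, never fatal; the fulfilled output's length multiset equals
  the fulfilled subset of the targets exactly, so the output N50 equals
  the target N50 whenever nothing was skipped.

The pool is kept sorted by length so eligibility is a binary search;
selection among eligible reads is uniform via the seeded RNG.

# Assembly metrics

Contigs are derived from scaffolds by splitting at runs of at least
`min_gap_run` N (default 10, so the 13-bp N gaps written by optical-map
hybrid scaffolding always split; shorter N runs are retained).

* `nxx()` / `length_stats()`: N(x) is the length of the element where
  the descending-sorted cumulative sum first reaches x% of the total.
* `ngx()`: identical but against an external genome-size estimate, and
  undefined (`NA`) when the assembly total falls short of the threshold
  — at low depth an assembly may simply not contain 50% of the genome.
  Ties at the threshold resolve by `>=` (the first contig reaching it).
* `assembled_pct()` is total contig length over the genome-size
  estimate (reported to one decimal); `gap_pct()` is the N fraction of
  the scaffolds as given, since gap content describes the scaffolded
  assembly, not re-split contigs.
* `effective_size()` counts k-mers (default k = 150) occurring exactly
  once in the assembly — a proxy for uniquely mappable sequence.
  Windows containing N are excluded. K-mers are counted in the given
  orientation by default, as a k-mer counter run with default
  parameters would; `canonical = TRUE` collapses reverse complements,
  since conventions differ between counters. The count is exact: keys
  are 2-bit packed in compiled code and verified in the tests against
  an exhaustive position-hash oracle for k in {5, 31, 150}.

# Repeat-space evaluation

Satellite arrays are found by **rotation-aware Hamming scanning**
(`scan_monomer_hits()`): every window of monomer length is scored
against all cyclic rotations of the monomer and of its reverse
complement (a tandem array matches some rotation at every offset), and
windows at or above `min_identity` merge into maximal runs that are
emitted as per-monomer-length hits. The default `min_identity = 0.8`
tolerates the 5–10% per-copy divergence typical of satellite arrays
while rejecting random sequence (a random window matches a rotation at
~25% plus fluctuation). This trades blast's seed heuristics for an
exact, dependency-free scan; externally produced hits can be supplied
as BED wherever a hit table is accepted. Two consequences to be aware
of: array edges are fuzzy by up to the few tens of bases over which a
boundary window still clears the threshold, and very long monomers
(e.g. an ~11-kb rDNA unit) admit proportionally more flanking sequence
into their terminal hits, so scanned array sizes can slightly exceed
the truth size — completeness is reported against truth without
clamping.

`cluster_arrays()` implements the array definition used for maize
repeat accounting: single-linkage clustering along a chromosome where
consecutive same-class hits with **less than 100 kb interspace** join
one array. `quantify_array()` then accounts every base of an array span
to exactly one of repeat (hit union, N excluded), gap (N bases), or
other, so the three always sum to the span length.

Telomeres are counted by exact motif (`TTTAGGG` and its reverse
complement `CCCTAAA`) at every offset; these 7-mers cannot self-overlap,
so overlapping and non-overlapping scans agree, and the count is
invariant under reverse complementation of the input.
`detect_subtelomere_boundary()` finds the terminal subtelomere hit
cluster (it must start within `terminal_window` of the chromosome end;
default 2 Mb, scaled down proportionally on small synthetic genomes)
and reports its innermost edge as the boundary and the sequence between
its outer edge and the chromosome end as the telomere region.
Chromosome ends without a terminal cluster report as absent — real
genomes do lack subtelomeres at some ends.

`locate_locus_by_flanks()` reproduces flank-based locus sizing: both
~2-kb flanks are matched on either strand and the same-chromosome,
consistent-orientation pair spanning the locus is reported in 1-based
inclusive coordinates, so length is `end - start + 1` (which is how a
printed span like chr9:11,625,031–11,914,133 yields 289,103 bp). When
several consistent pairs exist the smallest spanning interval is
reported; an inconsistent or missing pair returns a not-found result
carrying the per-flank matches as diagnostics.

# Compute-cost scaling

Assembly CPU cost versus depth follows a four-parameter logistic,
`y(x) = y_inf + (y_0 - y_inf) / (1 + (x/c)^b)`. `fourpl_eval()` is the
exact formula; `fit_fourpl()` is Levenberg–Marquardt least squares
(default initialization `y_0 = min(y)`, `y_inf = 10 max(y)`,
`c = median(x)`, `b = 2`; relative tolerance 1e-10, iteration cap 1024).
A caution built into the tests: published cost curves of this shape can
place the upper asymptote orders of magnitude above the observed depths
(the shipped Falcon model's asymptote is ~2 x 10^10 CPU hours at a
midpoint depth of ~1,900-fold). In that regime the *coefficients* are
not identifiable from half a dozen points and no claim of recovering
them is made; *predictions* inside the data range are identifiable, and
the log-space option (`log_y = TRUE`, with non-negative asymptote
bounds) stabilizes exactly this regime. Parameter recovery to within 1%
is asserted only on well-conditioned simulations whose midpoint lies
inside the data.

# The synthetic genome and what it does (not) emulate

`genome_spec()` / `build_genome()` generate a genome of seeded random
background carrying the feature classes the metrics target, each
recorded in a truth interval table (0-based half-open): gene-like unique
segments; LTR elements as terminal repeat + internal + terminal repeat;
tandem arrays of knob180 (180 bp), TR-1 (350 bp), CentC (156 bp) and an
rDNA-like ~11-kb unit; subtelomere arrays (monomer drawn from 300–1,300
bp) inside each chromosome end; and telomere motif runs touching both
ends, `CCCTAAA` on the left and `TTTAGGG` on the right, matching the
strand layout of assembled pseudomolecules (the detector counts both
regardless). Monomer sequences are generated once per genome from the
seed — except the telomere 7-mer, which is fixed biology — and each
array copy receives independent substitutions at the divergence rate
(default 5%, the order of within-array divergence of these satellites).
The two subtelomere arrays of a chromosome are independent realizations
of the same monomer, so at nonzero divergence they share no exact
150-mers.

The default genome is two 1-Mb chromosomes; tests use 200-kb
chromosomes. These sizes keep the full test suite and the acceptance
script within minutes on one CPU while leaving every feature class
large enough to measure; they are three orders of magnitude below a
real maize genome, so absolute values (e.g. NG50 in the hundreds of kb)
are not comparable to real assemblies — only the relative degradation
patterns are.

`simulate_reads()` draws uniform substrings with log-normal lengths.
The shape parameter defaults to sigma = 0.52, which reproduces the
N25/N50 ratio (~30.1/21.2 ≈ 1.42) of deep Sequel subread sets; the
location parameter is calibrated by root finding on the closed-form
tail-mass equation of the truncated log-normal so the distribution-level
N50 equals the requested target (realized N50 lands within 5% at depth
10-fold and above). Substitution errors are optional and uniform;
PacBio's indel-dominant error profile is *not* emulated — the package
never aligns reads, so only lengths and exact-substring provenance
matter. Heterozygosity and chimeric reads are likewise out of scope.

`degrade_assembly()` stands in for the assembler: it fragments the true
genome with a Poisson breakpoint process whose intensity is higher
inside repeat truth intervals than in unique sequence
(`breaks_per_mb_repeat >= breaks_per_mb_unique`, modeling preferential
collapse of repeats at low depth), deleting at each break an
exponentially sized segment with expected size `drop_fraction` times
the local feature length. The `ngap` policy replaces each deletion with
a 13-bp N run (a scaffolded assembly); `remove` splits into N-free
contigs. Two properties are by construction rather than by chance:

* **Coupling.** Candidate breaks are generated at a fixed ceiling
  intensity (512/Mb) and thinned to the requested rates, so for a fixed
  seed the breakpoint set at a higher rate is a superset of the set at
  a lower rate. Degradation is therefore monotone per seed — NG50,
  effective size and array completeness can tie but never improve as
  rates rise — which is what the monotonicity tests assert. Without
  coupling, independent draws would violate this stochastically.
* **Conservation.** Retained plus deleted bases equal the original
  chromosome length, and the retained-truth table reports per-feature
  retained bp against the truth oracle.

No quantitative claim is made that a given break rate corresponds to a
given sequencing depth; the demo's severity mapping (rates proportional
to depth^-1.5) is an explicit stand-in that produces the qualitative
pattern — fragmentation and repeat loss concentrated at the lowest
depths — not a fitted model of assembler behavior. Consequently,
passing tests validate the *metrics* and the *procedures* on structured
ground truth; they do not certify assembler-specific contig counts or
BUSCO-type gene scores, which require the real pipelines.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally (BED-compatible);
  1-based inclusive appears only in human-facing locus reports.
* Lower-case input is uppercased; only N participates in gap logic;
  non-ACGT letters never match a monomer or k-mer window.
* `ngx()` on an empty contig list, or a total below the threshold, is
  `NA`, not an error; `length_stats()` on an empty set is an error.
* All generators are pure functions of (spec/config, seed); the
  caller's RNG state is saved and restored around every seeded
  operation.
* `fit_fourpl()` flags an all-equal response as a degenerate fit
  (`y_0 = y_inf`, zero residuals) and reports non-convergence as a
  status with the best-found model rather than an error.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale:
titration on a simulated 10-Mb genome (several thousand reads),
distribution shifting on 5,000-read fixtures, k-mer oracles on
assemblies up to ~100 kb, and degradation/monotonicity sweeps on 400-kb
to 2-Mb synthetic genomes across 10 seeds. The acceptance script also
recomputes the self-contained arithmetic of the published NC358 summary
table from its printed cells (assembled percentages, coverage folds,
contig-count fold changes) and the bz-locus coordinate arithmetic,
which are scale-independent.
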