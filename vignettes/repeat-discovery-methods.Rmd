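---
title: "Repeat discovery and quantification from low-pass sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat discovery and quantification from low-pass sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replowpass)
```

# The problem and the sampling model

A genome sequenced at far below 1x coverage (here around 0.05x) contains
almost no information about single-copy loci — most of them are hit by zero
or one read — but a repeat family present in thousands of copies is sampled
thousands of times over. Two consequences drive everything in this package:

* **Repeat discovery.** Reads drawn from different copies of the same family
  are mutually similar, so in a graph whose nodes are reads and whose edges
  are strong pairwise overlaps, repeat families appear as dense clusters
  while single-copy reads stay isolated.
* **Repeat quantification.** The fraction of a uniformly sampled read set
  attributable to a family estimates the family's genome proportion, with
  binomial sampling error. Comparing two samples (here a male and a female
  genome of a dioecious plant) therefore reveals sequences with different
  abundance on the X and Y chromosomes without any assembly.

`replowpass` implements the full chain — simulation, read cleaning,
similarity-graph clustering, tag-based quantification with spike-in
calibration, satellite consensus reconstruction from k-mer spectra, and
windowed annotation of query sequences — with every stage testable against
a synthetic genome pair of known composition.

# The synthetic genome pair

`repeat_family()` + `genome_sim_spec()` + `build_genome_pair()` plant
repeat families of four kinds into a male/female genome pair:

* `tandem` — one contiguous head-to-tail array of a monomer (satellite DNA);
* `dispersed` — individual copies scattered through single-copy background
  (retroelement-like);
* `rdna_like` — a tandem array of a composite unit whose spacer half embeds
  its own short tandem subrepeat block, emulating satellites that arise
  inside the rDNA intergenic spacer;
* `spike_in` — foreign control sequences never placed in the genome, added
  to read pools at known mass fractions.

All copies of a family derive from one master sequence mutated at the
family's divergence (substitutions only, i.i.d. per site). Crucially, the
two sexes **share** the background sequence and the placement layout, as
two genomes of one species share their autosomes; copy-number differences
become sex-specific insertions and any surplus male genome size becomes
male-specific (Y-like) background. An early version of the generator drew
the two backgrounds independently, which made every single-copy locus
sex-specific and swamped the male/female comparison with artifactual
extreme ratios — a useful reminder that the comparison rests on the two
samples differing *only* in their repeat complements.

The truth table reports exact proportions (`copies x unit_length /
genome_1C`), and a fixed seed reproduces genomes byte-for-byte.

What the generator deliberately does not model: flowgram/homopolymer error
structure of pyrosequencing, paired ends, chromosome-scale karyotypes, and
biological divergence structure within families beyond i.i.d. substitutions
and explicit planted variants. Tests passing on these simulations therefore
demonstrate correctness of the algorithms under the stated sampling model,
not robustness to every artefact of real libraries.

## Read simulation

`simulate_reads()` draws read start positions uniformly (or with
GC-dependent odds `exp(slope * GC)` to emulate library-preparation bias),
samples both strands with probability 0.5, and applies per-base
substitution/indel errors. Long reads have Gaussian lengths truncated at
`[50, 2 * mean]`; a configurable fraction are exact duplicates of earlier
reads, emulating amplification artifacts. Short reads are fixed at 36 nt
with per-position Phred qualities drawn around a profile (read-level SD 5,
positional SD 2), and substitution errors coupled to quality
(`10^(-q/10)`) unless disabled for controlled experiments.

The default per-sample quality profiles (interior expected quality 15.35
for the male library, 18.0 for the female, with degraded first two and
last four cycles) encode the study condition that the female library was
the better sequencing run: combined with a 1.443-fold higher raw read
count, quality filtering yields about 1.7-fold more accepted tags from the
female sample. These interiors were calibrated analytically against the
binomial acceptance rule once, when the defaults were chosen.

`add_spike_ins()` appends control reads so the expected *base* fraction of
each control equals its requested mass fraction — 3% of the sample split
3:1 between two controls gives 2.25% and 0.75%. Expectations are always
computed from the requested fractions.

# Read cleaning

`dedup_long_reads()` removes exact full-length duplicates (first occurrence
kept). `trim_and_filter()` extracts positions 3–32 (1-based, inclusive —
exactly 30 nt) of each 36-nt read and accepts the tag if at least 90% of
its positions — `ceiling(0.9 * 30) = 27` — have quality at or above 10;
the quality floor is read as "at least 10", and the 90% rule rounds up.
`subsample_tags()` draws a seeded uniform sample without replacement so
both libraries contribute equal tag counts.

# The read-similarity graph

`find_overlaps()` places an edge between two reads when their best local
alignment on either strand has identity (matching columns / alignment
columns) at least 0.90 over at least 55% of the shorter read. Scoring is
match +1, mismatch −1, gap −2 (Smith–Waterman, linear gaps). The seeded
method aligns only pairs sharing an exact 14-mer; the exhaustive method
aligns every pair, and the test suite asserts the two produce identical
edge sets, with kernel scores cross-checked against
`Biostrings::pairwiseAlignment()`. Among co-optimal alignments the
reported extent is implementation-defined, which is why the oracle
comparison keeps a single kernel.

`build_clusters()` computes connected components first and splits a
component by greedy modularity maximisation (`igraph::cluster_fast_greedy`)
only when *both* its edge density is below 0.3 *and* the split's modularity
exceeds 0.05. The density gate matters: a single family whose unit is
longer than about half a read produces a ring- or band-shaped component
(density 0.35–1.0 in our simulations) that naive modularity splitting cuts
into arbitrary arcs, whereas components genuinely bridging two families
through shared flanking reads are sparse (about 0.2) and split cleanly
along family lines. Clusters are labelled `CL1, CL2, ...` by decreasing
size with ties broken by smallest member id, making labels invariant to
input order.

Family-to-cluster correspondence is exact only when reads span the repeat
unit (tandem monomers below roughly 0.55 read lengths, dispersed units up
to about one read length). Kilobase-scale elements fragment into several
clusters at low-pass coverage — as happens with real data, where one
family's reads can span several clusters and the rDNA unit itself split
across two — and downstream steps (family databases, proportion sums)
therefore aggregate clusters by family label.

`classify_graph_shape()` reads the genomic organisation off the graph:
**circular** when a dominant long cycle exists (diameter path of at least 6
hops whose endpoints stay connected after removing the path's interior) —
the signature of tandem units much longer than a read; **globular** when
edge density is at least 0.2 — short-monomer satellites, where every read
pair aligns; otherwise **linear** — dispersed elements. The hop diameter of
a ring is set by unit length relative to read overlap reach, not by read
count, so the threshold is absolute rather than size-relative; rings are
resolvable for units of roughly 2 kb and above at 250-nt reads.

`detect_tandem_period()` scans all lags up to a third of the sequence and
reports the smallest lag at which the sequence matches itself with at
least 80% identity in the best 30-bp (or `2p`) window. The windowed maximum
— rather than full-overlap identity — keeps the statistic robust to single
indels, which otherwise shift the register of everything downstream.

# Tag quantification

`assign_tags()` maps each 30-nt tag to the cluster of the clustered read
with minimal edit distance (substitutions and gaps all cost 1; the tag is
aligned end-to-end against any read substring), accepting distance at most
2. Ties across clusters go to the larger cluster, then the smaller id — a
deterministic proxy for "best similarity" that biases toward abundant
repeats. The accelerated path resolves exact hits through a 30-mer window
hash and inexact hits through pigeonhole seeding (three disjoint 10-mers:
any tag within 2 edits of a read shares at least one exactly) with banded
verification; the test suite proves it identical to an exhaustive
edit-distance scan.

`quantify()` reports per-cluster tag fractions per library (spike-in tags
count against the totals, exactly as controls are part of a sequenced
sample), the mean GC of the cluster's long reads (longer sequences estimate
GC with less noise than 30-nt tags), and the relative-abundance statistic

\[ r = \frac{p_M}{p_M + p_F} \]

which is 0.5 at equal abundance, 0.67/0.75 at two-/three-fold male excess
and 0.33/0.25 at the female equivalents. Estimates below a mean proportion
of 0.005% are flagged unreliable.

`calibrate_with_controls()` turns the spike-ins into a decision rule: the
flagging envelope is the most extreme control deviation of \(r\) from 0.5
(asymmetric controls contribute their full deviation plus their miss of the
expectation), and any non-control cluster deviating further is called
sex-differential. Control material can fragment into several clusters at
desk scale; `control_clusters()` therefore returns every cluster dominated
by control reads, all of which carry the control's expected ratio and all
of which are excluded from flagging.

`copy_number()` is the plain conversion `proportion * genome_1C /
unit_length`; `genome_coverage()` is `bases / genome_1C`; defaults for the
1C sizes are 2.925/2.865 Gb (halves of the published 2C values).
`sex_linked_abundance_ratio()` packages the density argument for
chromosome-biased repeats: with X and Y at 7.5% and 10% of the male genome,
a ten-fold Y density excess yields only a 1.9-fold male/female total
abundance difference — the detection limit context for the comparison.

`gc_bias_diagnostic()` reports the Spearman correlation between cluster GC
and \(r - 0.5\) with a seeded permutation p-value (999 permutations,
two-sided). Negative correlation means GC-rich clusters shift female-ward,
the pattern expected when the female library sequences GC-rich template
more efficiently.

# Satellite consensus reconstruction

`kmer_census()` counts every k-mer window of a cluster's tags (k between 10
and 17; both strands by default, making the spectrum strand-symmetric).
`reconstruct_monomer()` walks greedily from the most frequent k-mer (on its
lexicographically smaller strand), always extending by the highest-count
k-mer overlapping by k−1 and ignoring k-mers below 1% of the spectrum
maximum — a floor that suppresses sequencing-error k-mers while keeping 5%
variants visible. Revisiting a used k-mer closes the circular consensus of
the tandem monomer; a dead end yields a linear fragment. All ties are
lexicographic, so the result is a pure function of the spectrum; circular
consensi are reported in canonical form (lexicographically smallest
rotation over both strands), giving probes reproducible coordinates.

Per-position support compares the counts of consensus windows spanning a
position with the same windows carrying each alternative base;
`call_variants()` reports positions where an alternative reaches the
relative-frequency threshold (default 5%), merging adjacent positions into
variant records. Monomer regions duplicated in a subset of copies are
reported as variants rather than expanded into multiple consensus lengths.
`design_probe()` selects the 26–50-nt window maximising minimum support
(ties: longest, then leftmost), optionally constrained to cover a variant
with the variant bases substituted — the construction behind
consensus-specific versus subfamily-specific hybridisation probes.

On error-free tags the reconstruction is exact for all monomer lengths in
{43, 159, 165, 200, 313} and all k in {12, 14, 17}, is rotation- and
strand-invariant, and does not change when more tags from the same array
are added. Per-family tuning of k and the floor remains available because
the best settings genuinely differ between repeat families.

# Windowed annotation

`build_family_dbs()` pools clustered reads by family label (unlabelled
clusters as `"unclassified"`). `profile_sequence()` aligns every database
read to a query on both strands, keeps local alignments scoring at least
50 (about what a highly significant hit of a 250-nt read achieves under
the +1/−1/−2 scheme; an absolute score replaces a tool-specific e-value),
lets a read contribute one hit per distinct alignment (found greedily:
best alignment, then recurse left and right of its footprint), and
converts per-base alignment depth to copy number by dividing by the
sequencing fold-coverage: depth at a position present once per haploid
genome equals the coverage, so `depth / coverage` estimates local copy
number — 2.352 mean hits per window at 0.056x is 42 copies. Windows
(default 1 kb, step 100 bp; the window average is the mean per-base depth)
smooth the profile. Copy numbers at the edges of short elements are
diluted because reads there carry mostly flanking sequence; peaks at
element centres are unbiased.

# Numerical and reproducibility choices

* Every stochastic step takes an explicit integer seed; the pipeline
  driver (`run_all()`) derives per-stage seeds from one master seed and
  rerunning a config reproduces byte-identical output tables (checked by
  md5 in the manifest).
* Degenerate inputs are explicit: zero requested reads warns and returns
  an empty set; an empty edge set clusters nothing; a constant-GC table
  makes the GC diagnostic undefined rather than zero; tags shorter than
  the trim window are rejected with a distinct reason code.
* Desk-scale problem sizes used throughout the test suite — genomes of
  0.2–3 Mb, 500–1,600 long reads, 50k–100k tags per sample, spike-in
  controls of 1.5–2 kb — preserve the statistical structure of the study
  (low-pass genomic coverage, high family coverage, binomial tag
  sampling) at a size a desk machine reproduces in minutes. Spike-in
  controls are scaled to stay well covered by the long-read sample;
  phage-genome-sized controls at these depths would be only fractionally
  covered, an artefact of miniaturisation rather than of the method.

# Known limitations

* Identity is computed over alignment columns; the alternative (over the
  shorter read) would be slightly stricter for gapped overlaps.
* The community-splitting rule (density gate + modularity threshold) is a
  heuristic; pathological mixtures of a sparse family band with a genuine
  two-family bridge at matching densities would be resolved arbitrarily.
* The profiler reports the best alignment per read per query segment;
  near-exact internal duplications inside a query are counted through
  distinct alignments, but overlapping alternative placements of the same
  read are not enumerated.
* Proportions are fractions of sampled tags, not absolute genome
  fractions; with spike-ins present the two differ by the spike-in total.
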