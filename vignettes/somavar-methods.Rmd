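---
title: "Methods: models, parameters, and design choices in somavar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in somavar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

somavar compares three sources of genomic change in crop genomes —
standing inter-cultivar variation, fast-neutron (FN) mutagenesis, and
*Agrobacterium*-mediated transformation — through four analyses: copy
number from tiling-array CGH, substitutions private to one individual of
a cohort, T-DNA insertion loci from paired-end reads, and repair-junction
anatomy. This vignette explains each model, the tunable parameters and
why their defaults are what they are, the synthetic data the tests rest
on, and the numerical decisions taken where the design was genuinely
open. Nothing here reports an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Copy-number segmentation

A CGH probe track is a vector of per-probe log2(test/reference)
intensity ratios ordered along each chromosome. Copy-neutral probes
scatter around 0; a hemizygous deletion shifts the local mean toward
about −1, a homozygous duplication upward. Segmentation assumes
piecewise-constant means with approximately homoskedastic, independent
probe noise — reasonable after upstream spatial correction and
normalization, which this package does not reimplement
(`center_track()` offers only median re-centering, which is idempotent
and exact for a mostly copy-neutral genome).

`segment_track()` splits recursively. Within the current interval every
sub-interval is scored with the two-boundary changepoint statistic

> |mean(in) − mean(out)| · sqrt(n_in · n_out / n)

and the best candidate (leftmost start, then shortest, on ties) is
accepted when two conditions hold:

* its raw in/out mean difference is at least `min_segment_difference`
  (default **0.1** log2 units), and
* the weighted statistic strictly exceeds the `acceptance_percentile`
  (default **0.99**) quantile of the maximal statistic over
  `n_permutations` (default **10**) random shufflings of the interval's
  values.

Accepted candidates split the interval into up to three pieces, each
recursed; every probe belongs to exactly one final segment. Chromosomes
with fewer than `2 * min_probes_segment` probes are one segment.

Two numerical choices deserve explanation.

*Interval scan rather than half-vs-half cuts.* A binary cut scores an
embedded event only through the dilution it causes in one half, so a
short contiguous run of shifted probes barely outscores shuffled
arrangements of the same values; in simulation, 5-probe events at
realistic geometries were missed more than 80% of the time by
half-mean-difference splitting, at any chromosome size. The two-boundary
statistic — the standard device in the circular-binary-segmentation
family — isolates the run directly; an end-anchored interval degenerates
to the ordinary binary split. With it, planted 5-probe events at shift
±1.0 and noise 0.15 are recovered essentially always (the acceptance
suite measures this).

*Gumbel tail fit for the permutation threshold.* A max-statistic over
shuffles follows an extreme-value law. With only 10 permutations the
empirical 0.99 sample quantile cannot be resolved: the observed maximum
is exchangeable with the permuted ones under the null, so pure-noise
intervals would accept a split about 1 time in 11 (measured 8.6%). The
threshold is therefore the 0.99 quantile of a Gumbel distribution
moment-matched to the 10 permuted maxima, which realizes the intended
specificity (measured 1.3% on noise) without changing the published
permutation count. The permutation RNG is seeded per (sample,
chromosome) from the run seed, so results are reproducible and
independent of evaluation order.

## Classification and heterogeneity

`classify_segments()` applies calibrated thresholds: mean log2 ratio
strictly above **0.3484** is UpCNV, strictly below **−0.5257** DownCNV;
a mean exactly at a threshold is not a call, and calls need at least
`min_probes_call = 3` probes (single- and two-probe excursions are
noise at these arrays' error rates). The thresholds derive from
empirical distributions of characterized hemizygous deletions and
duplications in FN plants; hemizygous and homozygous deletions are not
distinguished. `candidate_review()` mechanizes the manual
visual-inspection step as a sub-threshold report (thresholds scaled by
`relax_factor`) and never alters calls.

Plants regenerated from one cultivar background can share segregating
variation that masquerades as induced change. `filter_heterogeneity()`
flags a call when at least `min_recurrence = 2` samples of the
background group carry a same-class call at the same location. The
default `"exact"` mode matches identical chromosome/start/end — on a
shared probe grid this equals identical probe indices — because arrays
of one design place boundaries deterministically at probe positions; a
`"reciprocal"` mode (pairwise reciprocal overlap, default 1.0) is
provided for designs where replicate boundary reproduction is
imperfect. Flags are retained for audit; all downstream accounting
(`genes_overlapping()`, `summarize_class()`) excludes flagged calls.

Gene overlap needs only ≥ 1 bp of intersection between a call span and
an annotated gene interval (both 1-based inclusive), each gene counted
once per sample per class; interval arithmetic is delegated to
GenomicRanges. A call on a chromosome absent from the annotation is an
error naming the chromosome, since silent zero-counting there would
corrupt class summaries. Segment spans run from first to last probe
position and include inter-probe gaps — probe spacing, not the
segmentation, limits boundary resolution; exact event sizes belong to
junction sequencing.

## Private homozygous substitutions

The substitution filter assumes a jointly genotyped cohort in which a
true de novo mutation appears as a homozygous alternate call in exactly
one individual. `apply_site_filters()` keeps a site iff:

* every sample has depth ≥ `min_depth` (default **5** reads),
* no sample is heterozygous or missing,
* exactly one sample is homozygous-alternate
  (`max_alt_carriers = 1`) and the rest homozygous-reference,
* the site is not monomorphic (for the reference or any single allele —
  neither can be private).

The depth rule is applied site-wise across all samples: the filter list
is site-level, and dropping a site whenever any cohort member is
under-covered is the conservative reading (an under-covered non-carrier
could hide a second carrier). A per-carrier-only variant is available
as `depth_scope = "carrier"`. Only biallelic single-base records are
eligible; indels and multiallelic records are counted and skipped —
how such sites were treated upstream is not recoverable, and skipping
is neutral. Genotype classes come from the VCF GT field; depth from
FORMAT/DP with fallback to the AD sum; a missing depth fails the depth
rule rather than passing silently.

Known heterogeneous regions are subtracted after filtering
(`apply_region_exclusion()`, 1-based inclusive bounds, optionally
sample-restricted); the 10–23 Mb interval of chromosome Gm12, shipped
as the default-off preset `gm12_heterogeneity_region()`, is the
motivating case. Ti/Tv counts A↔G and C↔T as transitions and reports
the ratio as absent when there are no transversions — small private
call sets make the ratio unstable, which is why it is reported per
sample rather than compared.

## T-DNA insertion mapping

`locate_insertion()` follows the orphaned-mate strategy: align both
ends of every pair to the construct sequence between the left border
(LB) and right border (RB) — only that interval, since vector backbone
rarely integrates and its paralogs mislead; collect ends whose mate
aligned but which themselves did not (*orphans*); align orphans to the
host genome; cluster.

The built-in matcher uses exact 21-mer seeds at staggered offsets and
ungapped extension, accepting an alignment at ≥ 90% identity over ≥ 90%
of the read on either strand; a unique best diagonal scores
pseudo-MAPQ 60, ties 0. At fixture scale this replaces an external
aligner without changing the module's surface — alignments parsed from
SAM into the same per-end tibble are consumed identically. The 90%
thresholds make a clean read align robustly while a junction-spanning
chimera (which must *fail*, to surface as unmapped evidence) is
rejected once the foreign portion exceeds ~10 bases.

Forward-strand orphans approach the insertion from the left flank,
reverse-strand from the right. Each flank is clustered at a
`2 × insert_size_mean` gap; a call pairs a left-flank cluster with the
nearest compatible right-flank cluster up to `max_pair_gap` (default
20 kb) away — the two flanks of a real insertion are separated by any
insertion-adjacent deletion, so requiring them to co-cluster at insert
scale would veto exactly the loci of interest. Both flanks need
`min_support = 3` pairs at `min_mapq ≥ 20`. Orientation follows from
which flank's mates sit nearer the construct LB; the reported
coordinate is the innermost host base on the LB side, refined to base
precision by junction reads when present. Calls whose supporting mates
derive mostly (> 50%) from construct elements with known genomic
paralogs *and* whose coordinate falls in a listed paralog region are
flagged, not deleted, preserving auditability; the >50% mate-fraction
rule is this package's quantification of "prior knowledge" filtering.

Insertion-adjacent deletions are detected from two independent
footprints: a depth hole (≥ `min_gap_bp = 200` consecutive bases below
`depth_ratio = 0.2`× the flanking median — a homozygous expectation)
and host–host pairs whose apparent spacing exceeds
`insert_size_mean + 3·sd`. The depth bounds are trimmed to the interior
zero-coverage run because partial coverage ramps over roughly a read
length at each junction; junction-read refinement then fixes the bounds
exactly. Flanking depth below 5× returns status `"undetermined"`.
`count_spanning_pairs()` covers the converse situation — construct
copies missing an internal element — by counting pairs that flank the
element with an apparent insert too short to have contained it
(`< element length + mean + 3·sd`); interpretation (hemizygous
excision vs re-mobilization) is left to the caller.

## Junction resolution

`resolve_junction()` takes a junction sequence (Sanger product or read
consensus — assumed error-free, hence exact matching) and the two
reference flanks with genomic anchors. It finds the maximal exact
prefix match into the left flank and suffix match into the right flank,
each seeded on 15 terminal bases (`min_match`, also the minimum
acceptable match — junctions matched more weakly are `"unresolved"`).
Bases between the matched blocks are filler, by definition matching
neither flank continuation. When the blocks overlap, the junction point
is ambiguous within the overlap: the overlap length is the
microhomology, and breakpoints are reported left-aligned with the
window length attached so either convention can be reconstructed.
Shifting the breakpoint within the window moves both ends together and
never changes the event size.

Under exact matching, a filler-free junction exposes a *single* shared
tract visible from both ends of the event, so the per-side fields
`mh_left_bp` and `mh_right_bp` are equal by construction; the schema
keeps both so that data sources that do distinguish sides fit without
change. `simulate_junction()` therefore requires equal per-side inputs
and plants one tract; when filler is present, the resolvable
microhomology is 0 and the recorded truth says so. Deletion size is
the count of reference bases absent between retained flanks
(`breakpoint_right − breakpoint_left − 1`); a resolution implying no
absent base is rejected as a no-event.

For insertion junctions the LB-adjacent host coordinate is reported at
the consistent position that keeps the construct full-length (ambiguity
assigned to the host). This single convention is orientation-symmetric
and makes refined coordinates on simulated truth exact in both
orientations.

## What the synthetic data do and do not show

The generators plant every quantity the analyses must recover: CGH
tracks with evenly spaced probes, Gaussian noise, private and shared
mean-shift events (≥ 3 probes by construction); cohorts with
per-sample private substitution counts plus shared-polymorphism,
heterozygous, missing, and low-depth distractors; insertion loci with
construct, orientation, adjacent deletion, filler, LB microhomology,
and error-free 100 bp read pairs at Normal insert sizes truncated above
two read lengths; junctions with planted tract or filler and guard
bases that prevent accidental match extension. Determinism is strict:
one seed, byte-identical output.

They deliberately omit: probe-density variation and GC/wave artifacts
on arrays; sequencing errors, base qualities, PCR duplicates, and
mapping ambiguity from repeats; genome-scale reference complexity
(hosts are i.i.d. random sequence, so paralogy only enters through the
explicit homologous-element fixtures). Passing tests therefore
demonstrate correctness of the inference logic under the stated noise
models — boundary arithmetic, filter semantics, orientation and
coordinate conventions — not robustness to artifacts that upstream
normalization, trimming, and alignment tools exist to handle.

Problem sizes in the suite and acceptance script were chosen to
exercise the conditions fully while staying desk-sized: 20-sample CGH
recovery at 2 chromosomes × 250–300 probes with events of 5–30 probes;
50 cohorts of 10,000 sites × 5 samples for exact count recovery;
insertion fixtures of 30 kb hosts, 2.5 kb constructs, 1.5 kb adjacent
deletions across both orientations, 10× and 30× coverage, and five
seeds; 1,000 randomized junctions up to 200 bp against a brute-force
decomposition oracle.

## Known limitations

* Segmentation resolution is bounded by probe spacing; reported spans
  include inter-probe gaps and should be refined by sequencing for
  exact sizes.
* The permutation test inherits the variance of 10 shuffles; an
  occasional spurious boundary in long noise stretches survives (about
  1% of intervals), which the calling thresholds then almost always
  drop.
* The built-in matcher is ungapped and exact-seeded: it is intended
  for fixture-scale, error-free reads; production data should arrive
  as external alignments.
* Junction resolution is exact-match only; a sequencing error inside
  the microhomology window shifts the reported breakpoint, which is
  why consensus or Sanger-grade junction sequence is assumed.
* Hemizygous insertions halve orphan support and leave reference-allele
  depth across the deletion; depth-based deletion detection assumes the
  homozygous case, and the hemizygous mode of the simulator exists to
  exercise exactly that caveat.
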