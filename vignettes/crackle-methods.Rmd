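---
title: "Micro-deletion CRAC analysis with crackle: models, parameters and design choices"
author: "crackle maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-deletion CRAC analysis with crackle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

crackle analyses CRAC (UV crosslinking and analysis of cDNA) sequencing
libraries of protein--RNA interactions, built around one central signal:
when reverse transcriptase reads through a nucleotide that was covalently
crosslinked to protein, it frequently skips that base, leaving a
single-nucleotide *micro-deletion* in the cDNA. Micro-deletions are rare
products of ordinary RT, PCR or sequencing error, so a position where a
large fraction of covering reads carry a 1-nt deletion pinpoints a
protein--RNA contact at nucleotide resolution. Everything else in the
package exists to get from multiplexed raw reads to that statistic and
its downstream summaries: demultiplexing with embedded random
nucleotides, adapter trimming, PCR-duplicate collapsing, alignment with
single-gap tolerance, per-nucleotide pileups, site calling and
between-strain comparison, metagene profiles over mRNAs, non-templated
oligo(A) detection, comparison of binding with RNA abundance and
ribosome occupancy, and polysome-gradient trace quantification.

The package ships a synthetic-data generator that plants all of these
signals with known ground truth. Every stage of the pipeline is tested
against that truth table or against an independent oracle (brute-force
CIGAR walking, hash-set duplicate counting, rank-then-Pearson
correlation, textbook t statistics, analytic Gaussian areas).

# The synthetic study system

`build_transcriptome()` generates a small genome with non-overlapping
mRNAs (explicit UTRs around a CDS divisible by 3, optional single
introns) and, optionally, a 6.9-kb polycistronic rRNA-operon-like
feature containing an 1800-nt small-subunit-like sub-feature at offset
700 -- the geometry of the yeast RDN37 pre-rRNA locus. The paper-like
fixture (`operon_fixture()`) plants crosslink hotspots at small-subunit
positions 1490--1492 (the major, three-nucleotide site) and 494 and 1362
(the minor sites), the coordinates at which the ribosome-associated
quality-control factor Hel2 crosslinks 18S rRNA. The bases at and
immediately left of each hotspot are pinned so that no hotspot base
repeats its left neighbour: a deletion there then has a unique
leftmost-aligned coordinate, which keeps truth, aligner and pileup in
exact agreement (see *Coordinate conventions* below).

`simulate_library()` draws fragments per transcript:

* **Fragment lengths** are triangular (20, 35, 60) nt. Real RNase
  digests of ribosome-associated RNA yield footprint-scale fragments
  with a mode near 30--40 nt; no published length distribution exists
  for these libraries, so a simple unimodal stand-in was chosen once.
* **Positional occupancy** weights the fragment *center*: `"uniform"`,
  or `"hel2like"` -- weight 0.1 over the first 150 nt of the CDS, 4.0 in
  the windows [-90, -30] and [+50, +110] nt around the stop codon, 0 in
  a 30-nt valley centred on the stop, 1.0 elsewhere. This reproduces,
  qualitatively, start-proximal depletion, strong stop-flanking peaks
  and the footprint-width valley over the stop codon itself.
* **Crosslink events**: each fragment overlapping a planted site is
  crosslinked there with probability `xl_prob`; a crosslinked fragment
  then carries a 1-nt deletion with `del_prob` or a substitution with
  `sub_prob`. Uniform per-base background deletion/substitution rates
  (default 0.005) model ordinary RT/PCR/sequencing noise.
* **Reads** are barcode + fragment + oligo(A) tail + 3' adapter,
  truncated to the read length, at constant quality Q37. The in-line
  barcode's `N` positions carry the unique molecular identifier (UMI;
  three random nucleotides by default). PCR duplication is geometric
  (multiplicity 1 + Geom(p), mean 3 at the default p = 1/3); duplicates
  are exact copies.
* **oligo(A) tails**: a configurable fraction (default 0.6) of
  fragments whose 3' end reaches the transcript's pA site receives a
  non-templated A-run of uniform length 5--15 nt.
* The **untagged control** (`simulate_control()`) uses the same
  generative model with crosslinking disabled and 5-fold fewer
  fragments; no generative model for control libraries has been
  published, so background-only at reduced depth is the package's
  choice.

Each library has one RNG stream seeded from its own config, so
libraries are independently reproducible. What the generator does *not*
emulate -- position-dependent quality, ligation bias, sequence-dependent
RT drop-off, paired ends, spliced fragments -- bounds what the green test
suite can show about real data: passing tests demonstrate the *methods*
are implemented correctly against their stated contracts, not that real
libraries satisfy those contracts.

# Coordinate conventions

All coordinates are 1-based closed, the native convention of GFF3, SAM
and the R/Bioconductor ranges stack; user-facing site reports are
therefore directly comparable to published coordinates (the major 18S
site prints as 1490--1492). Deletions in homopolymer runs are
left-aligned (standard SAM practice) *both* in the aligner and in the
simulator's truth: a planted deletion is normalized to the leftmost base
of its run, and a deletion whose run touches a fragment boundary is
unobservable in any alignment (the alignment merely shortens) and is
dropped from the truth. Without this normalization roughly a quarter of
planted deletions would disagree with their aligned coordinate by one
base for no biological reason.

# Preprocessing

`demultiplex()` matches the fixed positions of each 5' in-line barcode
template (default `max_mismatch = 0`; whether the original workflow
tolerated mismatches is unstated, so the strict choice is the default),
extracts the UMI from the `N` positions, and sends ties and short reads
to an unassigned bin. `trim_and_filter()` mirrors a standard adapter
trimmer at its published settings: 3' quality trimming below Q30 first,
then removal of the first full internal adapter occurrence or an exact
3' suffix/prefix overlap of at least 4 nt, then discarding reads with
more than 3 uncalled bases or shorter than 17 nt. `collapse_reads()`
merges reads identical in (sequence, UMI) -- PCR copies of one cDNA --
keeping the first occurrence and recording the multiplicity in the
`serial_UMI_xN` FASTA header dialect. Collapsing is idempotent, and two
distinct fragments that happen to produce the same sequence and UMI are
indistinguishable in principle; the simulator's truth table therefore
defines duplicate groups on the same key, making the collapsed count an
exact, testable quantity.

# Alignment

`align_reads()` is a deliberately small seed-and-extend aligner standing
in for the external aligner of the original workflow: exact 12-mer
seeds at up to three offsets, ungapped extension allowing at most 2
substitutions, plus at most one single-nucleotide reference deletion
(the crosslink signature), evaluated in O(read length) via prefix/suffix
mismatch cumsums. Unaligned reads are shortened from the 3' end by 1 nt
and retried down to 17 nt -- the published shortening policy -- which in
passing removes oligo(A) tails and adapter remnants. Scoring prefers
fewest mutations, then the longest aligned reference span, then a
seeded uniform choice among equal-best loci (count recorded as
`n_hits`). The reference-span tie-break matters: a deletion at the edge
of a read is score-equivalent to a substitution explanation, and
preferring the longer span resolves the tie deterministically in favour
of the deletion, without which exact deletion recovery would be capped
around 95%. The external aligner's scoring is not reproduced bit for
bit; this emulation is documented and its policies are tested instead.

`ingest_alignments()` is the boundary to any external aligner: SAM/BAM
in (via Rsamtools), unmapped records skipped, CIGAR/sequence length
mismatches rejected, deletions and insertions taken from the CIGAR and
substitutions called by laying the read into reference space and
comparing with the genome. Output is canonically sorted, so ingestion
is invariant to record order.

# Pileups and crosslink sites

`pileup_feature()` counts, per nucleotide of a feature: covering reads
(M *and* D CIGAR operations -- the deleted base is covered by its read,
so deletion fractions are bounded by 1; the original tooling does not
define coverage at deleted bases), substitution events, and single-nt
deletion events. Deletions of length >= 2 are recorded in a side
channel and excluded from the headline micro-deletion statistic, which
concerns single-nucleotide events; whether the original pileup counted
longer deletions once or per base is unstated, so the side channel
counts per deleted base. Size fractions of one sample are summed
*before* normalization (`combine_fractions()`), and
`normalize_track()` scales each array to unit sum -- the published
normalization -- while keeping raw counts, which site calling needs.

`call_sites()` operationalizes "high-frequency micro-deletions". A
position is kept when (i) its deletion fraction of coverage is at least
`min_fraction` (default 0.02 -- an order of magnitude above the 0.005
background and an order below the ~0.3 seen at planted sites) and (ii)
its normalized deletion share is at least `min_fold_over_median`
(default 10) times the feature's average deletion density over covered
positions. The average -- not the median -- is the reference because at
desk-scale coverage most covered positions carry zero deletions, making
a median-based threshold vacuous; for a unit-sum array the average is
simply 1/n_covered, so the criterion reads "ten times the gene-average
deletion density". Both criteria are ratios, so calls are invariant
under rescaling. Kept positions within 3 nt merge into one site, and
sites are ranked by their *total* deletion share, which is what makes a
three-nucleotide major site outrank stronger-per-base singletons. The
original sites were identified by inspection, with no numeric
definition published; these thresholds are this package's calibration,
chosen so the planted paper-like fixture yields exactly the planted
sites at deep coverage, and both are exposed parameters -- at ~25-40x
coverage a higher `min_fraction` (0.1--0.15) is appropriate because
two-deletion noise positions otherwise qualify.

`compare_conditions()` sums the normalized deletion share over each
site span per replicate and compares conditions against the reference
with the classic equal-variance two-tailed two-sample Student's t test
(the published method names Student, not Welch; `welch = TRUE` is
available), fold change = median(reference)/median(test). Identical
samples return p = 1; degenerate cases (zero test median, single
replicates) are flagged, not fatal. Multiple-testing correction across
sites exists (`p_adjust`) but is off by default, as only three named
sites are tested in the motivating analysis.

# Metagene analyses

`make_hittable()` assigns each read to the feature containing its
leftmost aligned base on the matching strand (the original counter's
overlap rule is unpublished; smallest feature wins for nested
annotations), in raw (multiplicity-weighted) or collapsed mode, and
`class_enrichment()` compares within-library class fractions against an
untagged control. `build_tracks()` produces per-strand genome vectors
of read coverage or single-nt deletion events plus their non-strand-
specific sum, exported as bedGraph -- the merged view feeds all metagene
computation, mirroring the original strand-merged wig tracks.

`reference_point_matrix()` anchors genes at the start codon, the first
base of the stop codon, the TSS or the pA site, strand-aware, at 1-nt
or 10-nt bins. `scaled_region_matrix()` implements the published
scaled-region layout: 100 nt upstream of the start codon (10 bins),
250 nt unscaled CDS (25 bins), a body scaled into 50 bins between start
codon +250 and stop codon -100 (linear coordinate interpolation with
fractional bin edges, so a constant track yields bins proportional to
width), 100 nt unscaled CDS ending at the stop codon (10 bins) and
250 nt downstream (25 bins): 120 bins in total. Genes whose CDS is not
longer than 350 nt cannot be scaled and are excluded and reported --
the same rule that reduces the 275 analysed transcripts to 252 in the
motivating study. Bins beyond a chromosome end are missing values and
are excluded from aggregation rather than zero-filled, avoiding edge
artefacts.

`normalize_and_aggregate()` follows the published recipe exactly: each
gene's row is divided by that gene's total, rows are summed, and either
(`wt_ratio`) each profile is scaled by the ratio of its data set's
total signal to the wild-type's and all profiles are divided by the
wild-type area (wild-type AUC = 1, mutants keep their relative
magnitude), or (`auc1`) every profile's own area is set to 1 (shape
only). Replicate data sets aggregate by the bin-wise median.
`smooth_profile()` is the 9-nt centred rolling average used for 1-nt
deletion metagenes, with shrinking windows at the edges (the edge
policy is unpublished). `region_sums()` sums exactly six 10-nt bins per
window: [0, 60) after the start codon, [-90, -30) before the stop and
[+50, +110) after it.

`select_top_bound()` ranks genes per replicate by hits per million per
kilobase and defines "reproducible" membership as the intersection of
per-replicate top-N lists (N = 300, then transcripts >= 500 nt). The
reproducibility criterion behind the published "top 300 reproducible"
set is unstated; intersection is this package's documented choice. The
ambiguity in whether tag+control normalization applies per gene or per
profile is resolved per profile.

# oligo(A) tails

Only reads whose 3' adapter was found are eligible -- for them the true
cDNA 3' end is known. `detect_and_strip_tails()` removes trailing As
from *every* eligible read, because a terminal A cannot be attributed
to tail or template from the read alone; stripping all of them gives
tailed and untailed reads the same mapped 3'-end convention (the last
non-A base), which keeps the pA-site oligo(A) percentage unbiased
(stripping only tailed candidates depresses it by several points, as
tailed reads ending in templated As exit the pA bin while their
untailed counterparts do not). A candidate is a terminal run >=
`min_tail` (default 4; the original script's threshold is unpublished,
and the acceptance suite sweeps 3--6 to show the calls are stable).
After realignment, `classify_tails()` calls a candidate non-templated
iff the next tail-length genomic bases 3' of the stripped alignment are
not all A -- i.e. at least one tail base cannot be templated.
`pa_fraction()` divides oligo(A) reads mapping at a pA site by all
adapter-containing reads mapping there (`window = 0`, the exact pA
nucleotide, per the published definition; a window option exists for
annotation slop), and `internal_background()` reports the fraction of
calls mapping > 50 nt from any pA site, which in simulations sits at
the detection false-positive level (< 1%).

# Expression comparison

`build_mature_db()` concatenates 5' UTR, spliced exons and 3' UTR and
appends exactly 10 adenines -- the published "arbitrary" poly(A) stub --
per transcript. Abundances are normalized to 1 kb per million
(`normalize_abundance()`: coverage x 1000/length x 1e6/library), per-
type medians are log2-transformed (zero-median genes dropped and
reported rather than pseudo-counted; a pseudo-count would distort the
low end of the log scale), Spearman correlations use average ranks for
ties via `stats::cor`, and `quintile_ratios()` splits genes into five
equal groups by CRAC signal (empirical quantile boundaries, stable
ties) and summarizes the RiboSeq/RNASeq ratio per quintile with
median, quartiles, 1.5 x IQR whiskers and outliers.
`simulate_expression()` provides the matched lognormal tables: RNASeq
lognormal, RiboSeq = RNASeq x lognormal TE, CRAC tracking either
RiboSeq (the planted positive binding--translation relation) or RNASeq
(the null) under multiplicative lognormal noise.

# Polysome gradients

`simulate_polysome_profile()` renders a flat dead-volume segment plus
Gaussian peaks of specified areas and optional noise;
`align_and_normalize()` detects the trace start as the first sample
exceeding baseline + 5 x noise estimated from the first 5% of samples
(the published alignment was manual; this rule is the package's
algorithmic stand-in), removes the dead volume and normalizes the area
to 1; `median_smooth()` applies the 5-point sliding median with
symmetrically shrinking edge windows (keeping the filter centred and
monotone-preserving at the boundaries); `peak_quantify()` sums values
within user-supplied peak boundaries, as in the original manual
pooling. The processing order -- align, normalize, smooth, quantify --
follows the published order; smoothing after normalization perturbs
total area by well under 1e-3 on simulated traces.

# Problem sizes and numerical tolerances

The test and acceptance suites run at desk scale, sizes chosen so the
statistics are decisive yet the whole suite completes in minutes:
site-recovery replicates use 100,000 fragments over the operon (about
580x coverage, 20 seeds), strain comparisons 40,000--80,000 fragments
per replicate (4 vs 4), oligo(A) analyses about 60,000 fragments over
short transcripts so that over 2,000 adapter reads map at pA sites,
metagenes 15,000--20,000 fragments over a 12-gene panel, and expression
tables 500--1,000 genes. Unit-sum and AUC contracts are asserted to
1e-9; closed-form oracles (Spearman, medians, matrix scaling) to 1e-12;
the t test against the textbook pooled-variance formula to 1e-10;
stochastic recoveries at 3-sigma binomial/multinomial bounds or the
planted-value tolerances stated alongside each test.

# Known limitations

* The aligner tolerates one deletion per read: reads carrying two
  crosslink deletions (frequent across the adjacent major-site
  nucleotides at high `del_prob`) fail to align and thin the observed
  per-nucleotide deletion fraction there. The truth-alignment path
  quantifies this; real pipelines built on single-gap aligners share
  the effect.
* Spliced alignment is out of scope; simulated fragments never cross
  exon junctions.
* UMI error correction (directional networks) is not implemented;
  duplicate identity is exact string identity.
* Site-calling thresholds are calibrated for deep coverage and are
  exposed precisely because shallow libraries need stricter deletion-
  fraction floors.
* The gradient noise model is Gaussian; the true instrument noise is
  unknown.
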