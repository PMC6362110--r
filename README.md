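# crackle

Crosslink-site mapping and metagene analysis for CRAC/CLIP sequencing
libraries, with a ground-truth synthetic-data generator.

## The problem

CRAC (UV crosslinking and analysis of cDNA) maps where an RNA-binding
protein touches RNA in living cells: protein–RNA complexes are UV
crosslinked, purified under denaturing conditions, and the bound RNA
fragments are sequenced. The key positional signal is the
**micro-deletion**: reverse transcriptase reading through a crosslinked
nucleotide frequently skips it, so a position where a large fraction of
covering reads carry a single-nucleotide deletion marks the protein–RNA
contact at nucleotide resolution — for the ribosome-associated
quality-control factor Hel2, the major contact at 18S rRNA nucleotides
1490–1492 and minor contacts at 494 and 1362.

crackle implements the full computational path for such data, for
analysts who want every stage testable against a planted ground truth:

* **simulation** — synthetic genomes/annotations, CRAC libraries with
  planted crosslink sites, oligo(A) tails, PCR duplicate structure and an
  untagged control, plus matched RNASeq/RiboSeq/CRAC abundance tables and
  polysome-gradient A260 traces (`build_transcriptome`,
  `operon_fixture`, `simulate_library`, `simulate_expression`,
  `simulate_polysome_profile`);
* **preprocessing** — in-line barcode demultiplexing with embedded
  random nucleotides (UMIs), adapter/quality trimming, PCR-duplicate
  collapsing on (sequence, UMI) (`demultiplex`, `trim_and_filter`,
  `collapse_reads`);
* **alignment** — a seeded short-read aligner tolerating up to one
  single-nucleotide deletion (the crosslink signature) and two
  substitutions, with 3'-shortening retries and seeded multimapper
  resolution, plus SAM/BAM ingestion with mutation-event extraction
  (`align_reads`, `ingest_alignments`);
* **pileups and sites** — per-nucleotide read/substitution/deletion
  tracks with unit-sum normalization, crosslink-site calling from
  deletion fractions, and between-strain comparison of site-level
  deletion fractions with Student's t tests (`pileup_feature`,
  `normalize_track`, `call_sites`, `compare_conditions`);
* **metagenes** — hittables and RNA-class enrichment, bedGraph genome
  tracks, reference-point and 120-bin scaled-region matrices with the
  wild-type-ratio / unit-area normalization schemes, 9-nt smoothing,
  6-bin region sums around start and stop codons, and selection of
  reproducibly top-bound transcripts (`make_hittable`, `build_tracks`,
  `scaled_region_matrix`, `normalize_and_aggregate`, `region_sums`,
  `select_top_bound`);
* **oligo(A) tails** — non-templated tail detection on
  adapter-containing reads, pA-site oligo-adenylation percentages and
  internal background (`detect_and_strip_tails`, `classify_tails`,
  `pa_fraction`, `internal_background`);
* **expression comparison** — mature-transcript database (UTRs +
  spliced exons + 10 adenines), 1 kb-per-million normalization, log2
  medians, Spearman correlation, translation-efficiency quintiles
  (`build_mature_db`, `normalize_abundance`, `spearman_rho`,
  `quintile_ratios`);
* **gradients** — A260 trace start alignment, unit-area normalization,
  5-point median smoothing, per-peak sums (`align_and_normalize`,
  `median_smooth`, `peak_quantify`).

## Worked example

Plant the three 18S crosslink hotspots, simulate a deep library, pile up
micro-deletions and call sites:

```r
library(crackle)

fx  <- operon_fixture(seed = 1)       # operon + hotspots 494/1362/1490-1492
cfg <- library_config(n_fragments = 100000, seed = 11, polyA_frac = 0)
lib <- simulate_library(fx$txome, fx$xl_sites, cfg, emit_reads = FALSE)

ssu   <- fx$txome$transcripts[fx$txome$transcripts$tx_id == "18S-like", ]
track <- normalize_track(pileup_feature(lib$alignments, ssu))
call_sites(track)
#>    feature start  end peak_pos peak_fraction site_fraction peak_del_fraction rank
#> 1 18S-like  1490 1492     1492    0.03232798    0.09481669         0.3113043    1
#> 2 18S-like  1362 1362     1362    0.02998013    0.02998013         0.2730263    2
#> 3 18S-like   494  494      494    0.02925772    0.02925772         0.2867257    3
```

The three planted sites come back at their exact 1-based coordinates;
the three-nucleotide major site ranks first by total deletion share, and
the per-position deletion fraction of coverage (~0.3) matches the
planted crosslink deletion probability.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `08_profiles.R`) that runs the same machinery as a
narrative study — multiplexed FASTQ through demultiplexing, collapsing
(exactly matching the planted duplicate-group counts), alignment,
site calling (fold change 4.5 at a site planted with a 5-fold
deletion-fraction difference, p < 1e-6), rRNA class enrichment over the
untagged control (1.8-fold), scaled metagene profiles with ~17-fold
stop-flanking enrichment, a 59.4% oligo(A) fraction at pA sites against
a planted 60%, Spearman(CRAC, RiboSeq) = 0.96 with strictly increasing
translation-efficiency quintiles, and polysome-collapse quantification
from gradient traces — writing its tables under `results/`.

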