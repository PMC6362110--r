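#!/usr/bin/env Rscript
## Align collapsed reads to the synthetic genome (seeded extension with
## single-deletion tolerance), write SAM, and build per-nucleotide
## read/substitution/deletion pileups over the 18S-like rRNA.

suppressMessages(library(crackle))
dir.create("results/align", showWarnings = FALSE, recursive = TRUE)

txome <- read_transcriptome("results/data/genome.fa",
                            "results/data/genome.gff3",
                            "results/data/genome_utrs.tsv")
ssu <- txome$transcripts[txome$transcripts$tx_id == "18S-like", ]
barcodes <- read.delim("results/data/barcodes.tsv")
gi <- genome_index(txome$genome)

for (s in barcodes$sample) {
  col <- read_collapsed_fasta(sprintf("results/preprocess/%s.fasta", s))
  aln <- align_reads(col, gi, seed = 42, sample = s)
  cat(sprintf("%-10s aligned %d / %d collapsed reads (%d unaligned)\n",
              s, nrow(aln$alignments), nrow(col),
              attr(aln, "n_unaligned")))
  write_sam(aln, txome$genome, sprintf("results/align/%s.sam", s))
  tr <- normalize_track(pileup_feature(aln, ssu,
                                       meta = list(sample = s)))
  write_track_tsv(tr, sprintf("results/align/%s_18S_track.tsv", s))
}
cat("per-nucleotide 18S tracks written under results/align/\n")
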