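#!/usr/bin/env Rscript
## Build the synthetic study system: an rRNA-operon-like locus carrying the
## three 18S crosslink hotspots (major site 1490-1492, minor sites 494 and
## 1362), a panel of mRNAs with hel2-like occupancy (stop-flanking peaks, a
## valley over the stop codon), and three multiplexed CRAC libraries: two
## tagged replicates and one untagged control at 1/5 depth.

suppressMessages(library(crackle))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

txome <- build_transcriptome(n_genes = 15, seed = 501, minus_frac = 0.4,
                             include_rrna_operon = TRUE)
paths <- write_transcriptome(txome, "results/data", "genome")
cat("genome:", sum(Biostrings::width(txome$genome)), "nt over",
    length(txome$genome), "chromosomes;", nrow(txome$transcripts),
    "annotated features\n")

ssu <- txome$transcripts[txome$transcripts$tx_id == "18S-like", ]
xl <- crosslink_spec("chrR",
                     ssu$tx_start + c(494L, 1362L, 1490L, 1491L, 1492L) - 1L,
                     xl_prob = 1, del_prob = 0.3, sub_prob = 0.1)
write.table(xl, "results/data/planted_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

set.seed(502)
w <- setNames(rlnorm(nrow(txome$transcripts)), txome$transcripts$tx_id)
w["RDN37-like"] <- sum(w) * 1.5   # rRNA dominates recovery, as in real CRAC
# the untagged control recovers relatively less rRNA (background RNA
# composition rather than ribosome-bound RNA)
w_ctl <- w
w_ctl["RDN37-like"] <- sum(w[names(w) != "RDN37-like"]) * 0.5

barcodes <- data.frame(sample = c("hel2_rep1", "hel2_rep2", "untagged"),
                       template = c("NNNTAAGC", "NNNGTGGC", "NNNCCAAC"))
write.table(barcodes, "results/data/barcodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

libs <- list(
  simulate_library(txome, xl,
                   library_config(n_fragments = 12000, seed = 510,
                                  barcode_template = "NNNTAAGC",
                                  occupancy = "hel2like"),
                   sample = "hel2_rep1", tx_weights = w),
  simulate_library(txome, xl,
                   library_config(n_fragments = 12000, seed = 511,
                                  barcode_template = "NNNGTGGC",
                                  occupancy = "hel2like"),
                   sample = "hel2_rep2", tx_weights = w),
  simulate_control(txome,
                   library_config(n_fragments = 12000, seed = 512,
                                  barcode_template = "NNNCCAAC",
                                  occupancy = "hel2like"),
                   sample = "untagged", tx_weights = w_ctl)
)

pool <- do.call(rbind, lapply(seq_along(libs), function(i) {
  r <- libs[[i]]$reads
  r$id <- paste0("L", i, ":", r$id)
  r
}))
set.seed(503)
write_fastq(pool[sample(nrow(pool)), ], "results/data/multiplexed.fastq")

for (lib in libs) {
  write.table(lib$truth,
              sprintf("results/data/truth_%s.tsv", lib$sample),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_sam(lib$alignments, txome$genome,
            sprintf("results/data/truth_%s.sam", lib$sample))
  cat(sprintf("%-10s %6d fragments -> %6d reads (mean multiplicity %.2f)\n",
              lib$sample, nrow(lib$truth), nrow(lib$reads),
              nrow(lib$reads) / nrow(lib$truth)))
}
cat("multiplexed FASTQ:", nrow(pool), "reads\n")
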