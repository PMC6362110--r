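#!/usr/bin/env Rscript
## Hittables and RNA-class enrichment over the untagged control, genome
## browser tracks, and scaled-region metagene profiles with the 6-bin
## region sums around the start and stop codons.

suppressMessages(library(crackle))
dir.create("results/metagene", showWarnings = FALSE, recursive = TRUE)

txome <- read_transcriptome("results/data/genome.fa",
                            "results/data/genome.gff3",
                            "results/data/genome_utrs.tsv")
samples <- c("hel2_rep1", "hel2_rep2", "untagged")
alns <- lapply(setNames(nm = samples), function(s) {
  ingest_alignments(sprintf("results/align/%s.sam", s), txome$genome,
                    sample = s)
})

## hittables (collapsed) + class enrichment of tagged over control
hits <- lapply(alns, make_hittable, txome = txome)
for (s in samples) {
  write.table(hits[[s]]$features,
              sprintf("results/metagene/hittable_%s.tsv", s),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
ce <- class_enrichment(hits$hel2_rep1, hits$untagged)
write.table(ce, "results/metagene/class_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("class enrichment over the untagged control:\n")
print(ce)

## genome tracks (reads and deletions), merged across strands
for (s in c("hel2_rep1", "hel2_rep2")) {
  sig <- build_tracks(alns[[s]], txome$genome, count = "reads")
  export_bedgraph(sig, sprintf("results/metagene/%s_reads.bedgraph", s))
  del <- build_tracks(alns[[s]], txome$genome, count = "deletions")
  export_bedgraph(del, sprintf("results/metagene/%s_dels.bedgraph", s))
}

## reproducibly bound mRNAs, scaled-region profiles, 6-bin region sums
suppressWarnings(
  top <- select_top_bound(hits[c("hel2_rep1", "hel2_rep2")], txome,
                          top_n = 10, min_tx_len = 500))
cat("reproducibly top-bound mRNAs (>= 500 nt):", length(top), "\n")

mats <- lapply(c("hel2_rep1", "hel2_rep2"), function(s) {
  scaled_region_matrix(build_tracks(alns[[s]], txome$genome), txome,
                       genes = top)
})
names(mats) <- c("hel2_rep1", "hel2_rep2")
profs <- normalize_and_aggregate(mats, wt = "hel2_rep1", mode = "wt_ratio")
med <- aggregate_profiles(profs)
write.table(data.frame(bin = seq_along(med),
                       rep1 = profs$hel2_rep1, rep2 = profs$hel2_rep2,
                       median = med),
            "results/metagene/scaled_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
rs <- t(vapply(profs, function(p)
  region_sums(p, attr(profs, "segments"), bin = attr(profs, "bin")),
  numeric(3)))
write.table(data.frame(sample = rownames(rs), rs),
            "results/metagene/region_sums.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("region sums (6 bins each):\n")
print(rs)
cat(sprintf("stop-flanking enrichment over the post-start region: %.1fx / %.1fx\n",
            rs[1, "before_stop"] / rs[1, "after_start"],
            rs[1, "after_stop"] / rs[1, "after_start"]))
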