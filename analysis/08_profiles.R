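#!/usr/bin/env Rscript
## Quantify polysome gradient A260 traces: dead-volume start alignment,
## unit-area normalization, 5-point median smoothing and per-peak sums.
## Two simulated strains: a wild-type-like trace with a strong polysome
## region and a mutant-like trace with collapsed polysomes.

suppressMessages(library(crackle))
dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)

strains <- list(
  wildtype = data.frame(center = c(60, 120, 170, 230, 330, 430),
                        width = c(10, 8, 8, 12, 25, 35),
                        area = c(0.5, 0.6, 0.4, 1.0, 1.2, 0.8)),
  mutant = data.frame(center = c(60, 120, 170, 230, 330, 430),
                      width = c(10, 8, 8, 12, 25, 35),
                      area = c(0.7, 0.9, 0.6, 1.6, 0.4, 0.2)))
labels <- c("free", "40S", "60S", "80S", "light_poly", "heavy_poly")

out <- list()
for (s in names(strains)) {
  tr <- simulate_polysome_profile(strains[[s]], n = 520, dead_volume = 45,
                                  noise_sd = 5e-4,
                                  seed = match(s, names(strains)) + 800)
  write_gradient_tsv(tr, sprintf("results/profiles/%s_raw.tsv", s))
  al <- align_and_normalize(tr)
  sm <- median_smooth(al, 5)
  write_gradient_tsv(sm, sprintf("results/profiles/%s_smoothed.tsv", s))
  start <- attr(al, "start")
  b <- data.frame(name = labels,
                  start = c(start, 100, 146, 196, 271, 391) - start + 1,
                  end = c(99, 145, 195, 270, 390, 520) - start + 1)
  sums <- peak_quantify(sm, b)
  out[[s]] <- sums
  cat(sprintf("%-9s start detected at sample %d (truth %d); area %.6f\n",
              s, start, attr(tr, "truth")$start, sum(al$a260)))
}
tab <- data.frame(peak = labels,
                  wildtype = as.numeric(out$wildtype),
                  mutant = as.numeric(out$mutant))
tab$mutant_over_wt <- tab$mutant / tab$wildtype
write.table(tab, "results/profiles/peak_quantification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab)
poly <- tab$peak %in% c("light_poly", "heavy_poly")
cat("polysome collapse in the mutant: light+heavy polysome share",
    sprintf("%.2f -> %.2f\n",
            sum(tab$wildtype[poly]), sum(tab$mutant[poly])))
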