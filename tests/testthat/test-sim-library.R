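test_that("empty library request yields empty outputs without error", {
  fx <- fx_operon()
  cfg <- library_config(n_fragments = 0, seed = 1)
  lib <- simulate_library(fx$txome, fx$xl_sites, cfg)
  expect_equal(nrow(lib$reads), 0L)
  expect_equal(nrow(lib$events), 0L)
  expect_equal(nrow(lib$alignments$alignments), 0L)
})

test_that("planted deletion counts follow the binomial oracle", {
  tx <- build_transcriptome(n_genes = 1, cds_len = c(1800, 1800),
                            minus_frac = 0, seed = 21)
  tr <- tx$transcripts
  # pick a site whose base differs from both neighbours, so planted
  # deletions keep their coordinate under leftmost normalization
  ch <- as.character(tx$genome[["chrI"]])
  pos <- NA
  for (p in (tr$tx_start + 500):(tr$tx_start + 600)) {
    b <- substr(ch, p, p)
    if (substr(ch, p - 1, p - 1) != b && substr(ch, p + 1, p + 1) != b) {
      pos <- p; break
    }
  }
  xl <- crosslink_spec("chrI", pos, xl_prob = 1, del_prob = 0.3,
                       sub_prob = 0)
  cfg <- library_config(n_fragments = 10000, seed = 77, bg_del_rate = 0,
                        bg_sub_rate = 0, polyA_frac = 0)
  lib <- simulate_library(tx, xl, cfg, emit_reads = FALSE)
  covered <- sum(lib$truth$gstart < pos & lib$truth$gend > pos)
  planted <- sum(lib$events$ref_pos == pos & lib$events$kind == "del")
  expected <- 0.3 * covered
  sd3 <- 3 * sqrt(covered * 0.3 * 0.7)
  expect_lt(abs(planted - expected), sd3)
})

test_that("geometric PCR duplication hits the requested mean multiplicity", {
  fx <- fx_operon()
  cfg <- library_config(n_fragments = 10000, seed = 31, pcr_dup_p = 1 / 3,
                        polyA_frac = 0)
  lib <- simulate_library(fx$txome, fx$xl_sites, cfg)
  expect_lt(abs(nrow(lib$reads) / nrow(lib$truth) - 3), 0.15)
  # duplicate copies are true PCR copies: identical sequence per fragment
  sp <- split(lib$reads$seq, sub("/.*$", "", lib$reads$id))
  expect_true(all(vapply(sp, function(s) length(unique(s)) == 1L,
                         logical(1))))
})

test_that("fragment centers follow the requested occupancy profile", {
  tx <- build_transcriptome(n_genes = 1, cds_len = c(1500, 1500),
                            minus_frac = 0, seed = 8)
  cfg <- library_config(n_fragments = 20000, seed = 41, occupancy = "uniform",
                        polyA_frac = 0)
  lib <- simulate_library(tx, NULL, cfg, emit_reads = FALSE)
  L <- tx$transcripts$spliced_len
  # multinomial check on 10 equal windows of the center distribution
  bins <- cut(lib$truth$center_sp, breaks = seq(0, L, length.out = 11))
  n <- nrow(lib$truth)
  p0 <- 1 / 10
  sd3 <- 3 * sqrt(n * p0 * (1 - p0))
  expect_true(all(abs(table(bins) - n * p0) < sd3))
})

test_that("emitted reads equal an independent reconstruction from the truth", {
  lib <- fx_operon_lib()
  fx <- fx_operon()
  cfg <- lib$config
  ch <- as.character(fx$txome$genome[["chrR"]])
  idx <- sample(seq_len(nrow(lib$truth)), 60)
  for (i in idx) {
    t <- lib$truth[i, ]
    ev <- lib$events[lib$events$frag_id == t$frag_id, ]
    x <- substr(ch, t$gstart, t$gend)           # operon is plus strand
    # oracle: apply substitutions then deletions, 5'->3'
    xs <- strsplit(x, "")[[1]]
    for (j in seq_len(nrow(ev))) {
      off <- ev$ref_pos[j] - t$gstart + 1L
      if (ev$kind[j] == "sub") xs[off] <- ev$read_base[j]
    }
    del_off <- ev$ref_pos[ev$kind == "del"] - t$gstart + 1L
    if (length(del_off) > 0) xs <- xs[-del_off]
    insert <- paste0(paste(xs, collapse = ""), strrep("A", t$tail_len))
    expected <- substr(paste0(strsplit(cfg$barcode_template, "")[[1]] |>
                                (\(tpl) {
                                  tpl[tpl == "N"] <-
                                    strsplit(t$umi, "")[[1]]
                                  paste(tpl, collapse = "")
                                })(),
                              insert, cfg$adapter), 1, cfg$read_len)
    got <- lib$reads$seq[lib$reads$id == paste0(t$frag_id, "/1")]
    expect_identical(got, expected)
  }
})

test_that("library generation is deterministic under its seed", {
  fx <- fx_operon()
  cfg <- library_config(n_fragments = 500, seed = 13)
  l1 <- simulate_library(fx$txome, fx$xl_sites, cfg)
  l2 <- simulate_library(fx$txome, fx$xl_sites, cfg)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
})

test_that("crosslink sites outside every transcript are rejected", {
  fx <- fx_operon()
  bad <- crosslink_spec("chrR", 10L)   # upstream of the operon
  expect_error(simulate_library(fx$txome, bad, library_config(seed = 1)),
               "outside")
})

test_that("an adapter occurring in the genome triggers a warning", {
  tx <- build_transcriptome(n_genes = 1, seed = 2)
  cfg <- library_config(n_fragments = 10, seed = 1)
  ch <- as.character(tx$genome[["chrI"]])
  substr(ch, 50, 49 + nchar(cfg$adapter)) <- cfg$adapter
  tx$genome <- Biostrings::DNAStringSet(setNames(ch, "chrI"))
  expect_warning(simulate_library(tx, NULL, cfg), "ambiguous")
})

test_that("untagged control libraries carry background only, at 1/5 depth", {
  fx <- fx_operon()
  cfg <- library_config(n_fragments = 5000, seed = 3, polyA_frac = 0)
  ctl <- simulate_control(fx$txome, cfg, emit_reads = FALSE)
  expect_equal(nrow(ctl$truth), 1000L)
  # no hotspot enrichment: deletions at hotspots comparable to background
  hot <- fx$xl_sites$pos
  n_hot <- sum(ctl$events$ref_pos %in% hot & ctl$events$kind == "del")
  expect_lt(n_hot, 10)
})

test_that("expression simulator obeys its planted correlation structure", {
  e0 <- simulate_expression(n_genes = 200, noise_sd = 0, seed = 5)
  expect_equal(spearman_rho(e0$crac, e0$ribo), 1)
  # degenerate TE: CRAC~RiboSeq and CRAC~RNASeq correlate identically
  e1 <- simulate_expression(n_genes = 200, sdlog_te = 0, noise_sd = 0.3,
                            seed = 6)
  expect_equal(spearman_rho(e1$crac, e1$ribo),
               spearman_rho(e1$crac, e1$rna))
  # stated noise: rho as recomputed by an independent rank oracle
  e2 <- simulate_expression(n_genes = 1000, noise_sd = 0.3, seed = 7)
  oracle <- cor(rank(e2$crac), rank(e2$ribo))
  expect_lt(abs(spearman_rho(e2$crac, e2$ribo) - oracle), 1e-12)
  expect_gt(oracle, 0.9)
})

test_that("polysome trace simulator is deterministic and flat without peaks", {
  pk <- data.frame(center = numeric(0), width = numeric(0),
                   area = numeric(0))
  tr <- simulate_polysome_profile(pk, n = 200, dead_volume = 30,
                                  noise_sd = 0, seed = 1)
  expect_true(all(tr$a260 == 0))
  pk2 <- data.frame(center = c(100, 200), width = c(8, 8), area = c(1, 2))
  t1 <- simulate_polysome_profile(pk2, n = 400, noise_sd = 0.01, seed = 9)
  t2 <- simulate_polysome_profile(pk2, n = 400, noise_sd = 0.01, seed = 9)
  expect_identical(t1$a260, t2$a260)
})
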