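## a controlled two-gene transcriptome with mirror-image geometry
symmetric_txome <- function() {
  set.seed(33)
  L <- 3000L
  ch <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = "")
  tr <- data.frame(
    tx_id = c("plusG", "minusG"), chrom = "chrS", strand = c("+", "-"),
    tx_start = c(201L, 1801L), tx_end = c(1000L, 2600L),
    cds_start = c(301L, 1901L), cds_end = c(900L, 2500L),
    pA_site = c(1000L, 1801L), rna_class = "mRNA", n_exons = 1L,
    utr5 = c(100L, 100L), utr3 = c(100L, 100L), stringsAsFactors = FALSE)
  ex <- data.frame(tx_id = tr$tx_id, exon_rank = 1L,
                   start = tr$tx_start, end = tr$tx_end)
  tiny_txome(c(chrS = ch), tr, ex)
}

## a signal object from explicit per-chromosome vectors
mksignal <- function(plus, minus = NULL) {
  if (is.null(minus)) minus <- lapply(plus, function(v) numeric(length(v)))
  structure(list(plus = plus, minus = minus,
                 merged = Map(`+`, plus, minus), count = "reads"),
            class = "crac_signal")
}

test_that("hittable counts follow the leftmost-base assignment rule", {
  tx <- symmetric_txome()
  a <- data.frame(
    qname = c("in_plus", "in_minus", "outside"),
    rname = "chrS", pos = c(400L, 2000L, 1200L),
    strand = c("+", "-", "+"), cigar = "30M", mult = c(2L, 1L, 1L),
    umi = "AAA", sample = "S", n_hits = 1L, seq_ref = "*",
    stringsAsFactors = FALSE)
  aln <- new_alignments(a, crackle:::empty_mutation_df())
  h <- make_hittable(aln, tx, mode = "collapsed")
  expect_equal(h$features$count[h$features$tx_id == "plusG"], 1)
  expect_equal(h$features$count[h$features$tx_id == "minusG"], 1)
  expect_equal(h$unannotated, 1)
  expect_equal(h$total, 3)
  hr <- make_hittable(aln, tx, mode = "raw")
  expect_equal(hr$features$count[hr$features$tx_id == "plusG"], 2)
  expect_equal(hr$total, 4)
})

test_that("hittable counts equal truth per-transcript counts exactly", {
  tx <- fx_mrna()
  cfg <- library_config(n_fragments = 5000, seed = 91, polyA_frac = 0)
  lib <- simulate_library(tx, NULL, cfg, emit_reads = FALSE)
  h <- make_hittable(lib$alignments, tx, mode = "collapsed")
  truth_counts <- table(lib$truth$tx_id)
  for (id in names(truth_counts)) {
    expect_equal(h$features$count[h$features$tx_id == id],
                 as.numeric(truth_counts[[id]]))
  }
  expect_equal(h$unannotated, 0)
  # empty alignment set
  h0 <- make_hittable(new_alignments(crackle:::empty_alignment_df(),
                                     crackle:::empty_mutation_df()), tx)
  expect_true(all(h0$features$count == 0))
})

test_that("class enrichment is the ratio of within-library fractions", {
  mk_hit <- function(counts, classes, total) {
    structure(list(
      features = data.frame(tx_id = names(counts), rna_class = classes,
                            count = as.numeric(counts)),
      classes = local({
        tt <- tapply(counts, classes, sum)
        data.frame(rna_class = names(tt), count = as.numeric(tt))
      }),
      total = total, unannotated = total - sum(counts),
      mode = "collapsed"), class = "crac_hittable")
  }
  s <- mk_hit(c(g1 = 40, g2 = 10), c("mRNA", "rRNA"), 100)
  ctl <- mk_hit(c(g1 = 10, g2 = 30), c("mRNA", "rRNA"), 100)
  ce <- class_enrichment(s, ctl)
  expect_equal(ce$fold[ce$rna_class == "mRNA"], 4)
  same <- class_enrichment(s, s)
  expect_true(all(same$fold == 1))
  # simulated tagged vs untagged: folds match hand-computed truth ratios
  fx <- fx_operon()
  cfg <- library_config(n_fragments = 3000, seed = 51, polyA_frac = 0)
  tag <- simulate_library(fx$txome, fx$xl_sites, cfg, emit_reads = FALSE)
  ctl2 <- simulate_control(fx$txome, cfg, emit_reads = FALSE)
  h1 <- make_hittable(tag$alignments, fx$txome)
  h2 <- make_hittable(ctl2$alignments, fx$txome)
  ce2 <- class_enrichment(h1, h2)
  hand <- (sum(h1$features$count[h1$features$rna_class == "rRNA"]) /
             h1$total) /
    (sum(h2$features$count[h2$features$rna_class == "rRNA"]) / h2$total)
  expect_equal(ce2$fold[ce2$rna_class == "rRNA"], hand)
})

test_that("signal tracks count coverage or deletions and merge by sum", {
  tx <- symmetric_txome()
  a <- data.frame(qname = "q1", rname = "chrS", pos = 400L, strand = "+",
                  cigar = "10M1D10M", mult = 1L, umi = "AAA", sample = "S",
                  n_hits = 1L, seq_ref = "*", stringsAsFactors = FALSE)
  m <- data.frame(qname = "q1", rname = "chrS", ref_pos = 410L,
                  strand = "+", kind = "del", len = 1L, read_base = "",
                  ref_base = "G", stringsAsFactors = FALSE)
  aln <- new_alignments(a, m)
  reads <- build_tracks(aln, tx$genome, count = "reads")
  expect_equal(which(reads$plus$chrS == 1), 400:420)
  dels <- build_tracks(aln, tx$genome, count = "deletions")
  expect_equal(which(dels$merged$chrS == 1), 410L)
  # conservation on simulated data
  lib <- simulate_library(fx_mrna(), NULL,
                          library_config(n_fragments = 2000, seed = 15,
                                         polyA_frac = 0),
                          emit_reads = FALSE)
  sig <- build_tracks(lib$alignments, fx_mrna()$genome, count = "reads")
  expect_equal(sum(sig$merged$chrI),
               sum(sig$plus$chrI) + sum(sig$minus$chrI))
  # bedgraph export round-trips through rtracklayer
  bg <- tempfile(fileext = ".bedgraph")
  export_bedgraph(sig, bg, view = "merged")
  back <- rtracklayer::import(bg, format = "bedGraph")
  expect_equal(sum(back$score * GenomicRanges::width(back)),
               sum(sig$merged$chrI))
  unlink(bg)
})

test_that("reference-point rows are anchored and strand-aware", {
  tx <- symmetric_txome()
  v <- numeric(3000)
  # delta signal 10 nt downstream of each stop codon (first stop base:
  # plus 898, minus 1903); downstream means +10 genomic on plus,
  # -10 genomic on minus
  v[898 + 10] <- 7
  v[1903 - 10] <- 7
  sig <- mksignal(list(chrS = v))
  mm <- reference_point_matrix(sig, tx, anchor = "stop", upstream = 50,
                               downstream = 50, bin = 1)
  expect_equal(dim(mm$values), c(2L, 100L))
  # offset +10 is column 61 (columns are -50..49)
  expect_equal(unname(mm$values["plusG", 61]), 7)
  expect_equal(unname(mm$values["minusG", 61]), 7)
  expect_identical(mm$values["plusG", ], mm$values["minusG", ])
})

test_that("scaled-region matrices have the documented 120-bin structure", {
  tx <- fx_mrna()
  ones <- lapply(setNames(nm = names(tx$genome)),
                 function(cc) rep(1, length(tx$genome[[cc]])))
  sig <- mksignal(ones)
  mm <- scaled_region_matrix(sig, tx)
  expect_equal(ncol(mm$values), 120L)
  expect_equal(unname(mm$segments), c(10L, 25L, 50L, 10L, 25L))
  # constant signal: unscaled bins sum to 10, body bins to L_body/50
  seg <- mm$segments
  for (g in rownames(mm$values)) {
    row <- mm$values[g, ]
    expect_true(all(abs(row[1:35] - 10) < 1e-9))          # up + u5
    expect_true(all(abs(row[96:120] - 10) < 1e-9))        # u3 + down
    tr <- tx$transcripts[tx$transcripts$tx_id == g, ]
    Lb <- (tr$cds_end - tr$cds_start + 1) - 350
    expect_true(all(abs(row[36:85] - Lb / 50) < 1e-9))
  }
})

test_that("genes with short CDS are excluded from scaled matrices", {
  tx <- symmetric_txome()
  tr <- tx$transcripts
  tr$cds_end[1] <- tr$cds_start[1] + 339L   # CDS 340 < 250 + 100
  tx$transcripts <- tr
  ones <- list(chrS = rep(1, 3000))
  mm <- scaled_region_matrix(mksignal(ones), tx)
  expect_equal(attr(mm, "excluded"), "plusG")
  expect_equal(rownames(mm$values), "minusG")
})

test_that("normalization modes satisfy their closed-form contracts", {
  set.seed(77)
  vals <- matrix(rexp(20 * 120) + 0.1, nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  mk <- function(v) crackle:::new_metagene(
    v, "scaled-region", 10L,
    segments = c(up = 10L, u5 = 25L, body = 50L, u3 = 10L, down = 25L))
  half <- mk(vals * 0.5)
  noisy <- mk(vals * matrix(runif(20 * 120, 0.5, 1.5), nrow = 20))
  p <- normalize_and_aggregate(list(WT = mk(vals), HALF = half,
                                    OTHER = noisy), wt = "WT",
                               mode = "wt_ratio")
  expect_lt(abs(sum(p$WT) - 1), 1e-9)
  expect_lt(abs(sum(p$HALF) - 0.5), 1e-9)
  expect_equal(p$HALF * 2, p$WT)
  p2 <- normalize_and_aggregate(list(WT = mk(vals), HALF = half),
                                wt = "WT", mode = "auc1")
  expect_lt(abs(sum(p2$HALF) - 1), 1e-9)
  expect_equal(p2$HALF, p2$WT)
  med <- aggregate_profiles(list(p$WT, p$WT, p$HALF))
  expect_equal(med, p$WT)
})

test_that("rolling-average smoothing behaves like a 9-nt mean filter", {
  expect_equal(smooth_profile(rep(3, 50), 9), rep(3, 50))
  delta <- numeric(41); delta[21] <- 9
  sm <- smooth_profile(delta, 9)
  expect_equal(sm[17:25], rep(1, 9))
  expect_true(all(sm[c(1:16, 26:41)] == 0))
  set.seed(5)
  x <- runif(100)
  sm2 <- smooth_profile(x, 9)
  conv <- stats::filter(x, rep(1 / 9, 9), sides = 2)
  inner <- 5:96
  expect_equal(sm2[inner], as.numeric(conv)[inner])
  expect_error(smooth_profile(x, 8), "window")
  expect_error(smooth_profile(runif(5), 9), "window")
})

test_that("region sums cover exactly six 10-nt bins per window", {
  seg <- c(up = 10L, u5 = 25L, body = 50L, u3 = 10L, down = 25L)
  const <- structure(rep(2, 120), segments = seg, bin = 10L)
  rs <- region_sums(const)
  expect_equal(unname(rs), c(12, 12, 12))
  zero <- structure(rep(0, 120), segments = seg, bin = 10L)
  expect_equal(unname(region_sums(zero)), c(0, 0, 0))
  # window placement: mark the exact expected bins
  probe <- rep(0, 120)
  probe[11:16] <- 1     # [0, 60) after start codon (first CDS bins)
  probe[87:92] <- 10    # [-90, -30) before stop
  probe[101:106] <- 100 # [+50, +110) after stop
  rs2 <- region_sums(structure(probe, segments = seg, bin = 10L))
  expect_equal(unname(rs2), c(6, 60, 600))
  expect_error(region_sums(rep(1, 30),
                           segments = c(up = 10L, u5 = 2L, body = 0L,
                                        u3 = 10L, down = 8L), bin = 10))
})

test_that("hel2like occupancy shows stop-flanking enrichment and a valley", {
  tx <- fx_mrna()
  cfg <- library_config(n_fragments = 20000, seed = 19,
                        occupancy = "hel2like", polyA_frac = 0)
  lib <- simulate_library(tx, NULL, cfg, emit_reads = FALSE)
  sig <- build_tracks(lib$alignments, tx$genome, count = "reads")
  prof <- normalize_and_aggregate(
    list(WT = scaled_region_matrix(sig, tx)), wt = "WT", mode = "wt_ratio")
  rs <- region_sums(prof$WT, attr(prof, "segments"), bin = attr(prof, "bin"))
  expect_gt(rs[["before_stop"]], 3 * rs[["after_start"]])
  expect_gt(rs[["after_stop"]], 3 * rs[["after_start"]])
  # stop-anchored profile: minimum inside the planted 30-nt valley
  rp <- reference_point_matrix(sig, tx, anchor = "stop", upstream = 120,
                               downstream = 120, bin = 1)
  agg <- smooth_profile(colSums(rp$values, na.rm = TRUE), 9)
  offsets <- seq(-120, 119)
  expect_true(abs(offsets[which.min(agg[90:150]) + 89]) <= 15)
})

test_that("metagene profiles are invariant under strand reversal", {
  tx <- fx_mrna()
  cfg <- library_config(n_fragments = 8000, seed = 23,
                        occupancy = "hel2like", polyA_frac = 0)
  lib <- simulate_library(tx, NULL, cfg, emit_reads = FALSE)
  mir <- mirror_fixture(tx, lib$alignments)
  p1 <- normalize_and_aggregate(
    list(WT = scaled_region_matrix(
      build_tracks(lib$alignments, tx$genome), tx)),
    wt = "WT", mode = "wt_ratio")
  p2 <- normalize_and_aggregate(
    list(WT = scaled_region_matrix(
      build_tracks(mir$aln, mir$txome$genome), mir$txome)),
    wt = "WT", mode = "wt_ratio")
  expect_equal(p2$WT, p1$WT, tolerance = 1e-12)
})

test_that("top-bound selection intersects per-replicate density rankings", {
  tx <- fx_mrna()
  w <- setNames(rlnorm(nrow(tx$transcripts), 0, 1), tx$transcripts$tx_id)
  mk_hit <- function(seed) {
    cfg <- library_config(n_fragments = 6000, seed = seed, polyA_frac = 0)
    lib <- simulate_library(tx, NULL, cfg, tx_weights = w,
                            emit_reads = FALSE)
    make_hittable(lib$alignments, tx)
  }
  h1 <- mk_hit(1); h2 <- mk_hit(2)
  suppressWarnings(sel <- select_top_bound(list(h1, h2), tx, top_n = 6,
                                           min_tx_len = 500))
  # brute-force oracle: per-replicate density ranking, intersection,
  # length filter
  lens <- setNames(tx$transcripts$tx_len, tx$transcripts$tx_id)
  top_of <- function(h) {
    d <- h$features$count / (lens[h$features$tx_id] / 1000) /
      (h$total / 1e6)
    head(h$features$tx_id[order(-d, h$features$tx_id)], 6)
  }
  oracle <- intersect(top_of(h1), top_of(h2))
  oracle <- oracle[lens[oracle] >= 500]
  expect_setequal(sel, oracle)
  # identical replicates reduce to one replicate's top list
  suppressWarnings(sel2 <- select_top_bound(list(h1, h1), tx, top_n = 6,
                                            min_tx_len = 500))
  o2 <- top_of(h1); o2 <- o2[lens[o2] >= 500]
  expect_setequal(sel2, o2)
})

test_that("transcript length filter applies at the 500-nt boundary", {
  tr <- data.frame(
    tx_id = c("short", "exact"), chrom = "chrX", strand = "+",
    tx_start = c(1L, 1001L), tx_end = c(499L, 1500L),
    cds_start = NA_integer_, cds_end = NA_integer_,
    pA_site = c(499L, 1500L), rna_class = "mRNA", n_exons = 1L,
    utr5 = 0L, utr3 = 0L, tx_len = c(499L, 500L),
    spliced_len = c(499L, 500L), stringsAsFactors = FALSE)
  mk_hit <- function() {
    structure(list(
      features = data.frame(tx_id = tr$tx_id, rna_class = "mRNA",
                            count = c(100, 100)),
      classes = data.frame(rna_class = "mRNA", count = 200),
      total = 200, unannotated = 0, mode = "collapsed"),
      class = "crac_hittable")
  }
  suppressWarnings(sel <- select_top_bound(list(mk_hit(), mk_hit()), tr,
                                           top_n = 2, min_tx_len = 500))
  expect_equal(sel, "exact")
})
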