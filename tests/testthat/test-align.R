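test_that("an exact substring aligns full-length with no mutations", {
  fx <- fx_operon()
  ch <- as.character(fx$txome$genome[["chrR"]])
  read <- substr(ch, 2001, 2040)
  aln <- align_reads(data.frame(seq = read), fx$txome$genome, seed = 1)
  a <- aln$alignments
  expect_equal(nrow(a), 1L)
  expect_equal(a$pos, 2001L)
  expect_equal(a$cigar, "40M")
  expect_equal(a$strand, "+")
  expect_equal(nrow(aln$mutations), 0L)
})

test_that("a single-base deletion yields the correct CIGAR and coordinate", {
  fx <- fx_operon()
  ch <- as.character(fx$txome$genome[["chrR"]])
  # manual alignment oracle on a constructed string: remove base 11 of a
  # 30-mer at a site where leftmost placement is unambiguous
  start <- NA
  for (s in 3000:3200) {
    b <- substr(ch, s + 10, s + 10)
    if (substr(ch, s + 9, s + 9) != b && substr(ch, s + 11, s + 11) != b) {
      start <- s; break
    }
  }
  full <- substr(ch, start, start + 29)
  read <- paste0(substr(full, 1, 10), substr(full, 12, 30))
  aln <- align_reads(data.frame(seq = read), fx$txome$genome, seed = 1)
  a <- aln$alignments
  expect_equal(a$cigar, "10M1D19M")
  expect_equal(a$pos, start)
  m <- aln$mutations
  expect_equal(nrow(m), 1L)
  expect_equal(m$kind, "del")
  expect_equal(m$ref_pos, start + 10L)
})

test_that("substitutions are detected with read and reference bases", {
  fx <- fx_operon()
  ch <- as.character(fx$txome$genome[["chrR"]])
  read <- substr(ch, 4001, 4040)
  orig <- substr(read, 20, 20)
  alt <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(read, 20, 20) <- alt
  aln <- align_reads(data.frame(seq = read), fx$txome$genome, seed = 1)
  expect_equal(aln$alignments$cigar, "40M")
  m <- aln$mutations
  expect_equal(m$kind, "sub")
  expect_equal(m$ref_pos, 4020L)
  expect_equal(m$read_base, alt)
  expect_equal(m$ref_base, orig)
})

test_that("reverse-strand reads align with reference-orientation sequence", {
  fx <- fx_operon()
  ch <- as.character(fx$txome$genome[["chrR"]])
  fwd <- substr(ch, 5001, 5040)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd)))
  aln <- align_reads(data.frame(seq = rc), fx$txome$genome, seed = 1)
  a <- aln$alignments
  expect_equal(a$strand, "-")
  expect_equal(a$pos, 5001L)
  expect_equal(a$seq_ref, fwd)
})

test_that("equal-best multimappers resolve reproducibly under a seed", {
  set.seed(17)
  seg <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
  pad1 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  pad2 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrD = paste0(pad1, seg, pad2, seg,
                                                     pad1)))
  picks <- vapply(1:2, function(i) {
    align_reads(data.frame(seq = seg), genome, seed = 5)$alignments$pos
  }, integer(1))
  expect_equal(picks[1], picks[2])
  a <- align_reads(data.frame(seq = seg), genome, seed = 5)$alignments
  expect_equal(a$n_hits, 2L)
  expect_true(a$pos %in% c(101L, 241L))
})

test_that("unalignable 3' bases are shortened away until the read maps", {
  fx <- fx_operon()
  ch <- as.character(fx$txome$genome[["chrR"]])
  read <- paste0(substr(ch, 2501, 2530), strrep("A", 12))
  aln <- align_reads(data.frame(seq = read), fx$txome$genome, seed = 1)
  a <- aln$alignments
  expect_equal(a$pos, 2501L)
  # shortened down to the genomic 30-mer plus at most a few residual
  # bases the mismatch allowance can absorb
  expect_lte(GenomicAlignments::cigarWidthAlongQuerySpace(a$cigar), 36L)
  expect_gte(GenomicAlignments::cigarWidthAlongQuerySpace(a$cigar), 30L)
  # a read too short to seed is reported unaligned, not an error
  aln2 <- align_reads(data.frame(seq = "ACGTACGTAC"), fx$txome$genome,
                      seed = 1)
  expect_equal(nrow(aln2$alignments), 0L)
  expect_equal(attr(aln2, "n_unaligned"), 1L)
})

test_that("ingest extracts deletion coordinates from the CIGAR", {
  fx <- fx_operon()
  genome <- fx$txome$genome
  ch <- as.character(genome[["chrR"]])
  # record with CIGAR 8M1D12M at POS 101: deletion at reference 109
  seqref <- paste0(substr(ch, 101, 108), substr(ch, 110, 121))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:chrR\tLN:%d", nchar(ch)),
    sprintf("r1\t0\tchrR\t101\t60\t8M1D12M\t*\t0\t0\t%s\t*", seqref),
    sprintf("r2\t0\tchrR\t201\t60\t20M\t*\t0\t0\t%s\t*",
            substr(ch, 201, 220))
  ), sam)
  ing <- ingest_alignments(sam, genome)
  expect_equal(nrow(ing$alignments), 2L)
  m <- ing$mutations
  expect_equal(nrow(m), 1L)
  expect_equal(m$kind, "del")
  expect_equal(m$ref_pos, 109L)
  unlink(sam)
})

test_that("ingest is invariant to record order and skips unmapped records", {
  lib <- fx_operon_lib()
  fx <- fx_operon()
  sam1 <- tempfile(fileext = ".sam"); sam2 <- tempfile(fileext = ".sam")
  write_sam(lib$alignments, fx$txome$genome, sam1)
  lines <- readLines(sam1)
  hdr <- grepl("^@", lines)
  set.seed(4)
  writeLines(c(lines[hdr], sample(lines[!hdr]),
               "unm\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTACGTACGTA\t*"), sam2)
  i1 <- ingest_alignments(sam1, fx$txome$genome)
  i2 <- ingest_alignments(sam2, fx$txome$genome)
  expect_equal(i2$alignments, i1$alignments)
  expect_equal(i2$mutations, i1$mutations)
  expect_equal(attr(i2, "n_unmapped"), 1L)
  unlink(c(sam1, sam2))
})

test_that("truth SAM ingestion recovers planted events exactly", {
  lib <- fx_operon_lib()
  fx <- fx_operon()
  sam <- tempfile(fileext = ".sam")
  write_sam(lib$alignments, fx$txome$genome, sam)
  ing <- ingest_alignments(sam, fx$txome$genome, sample = "S1")
  m0 <- lib$alignments$mutations
  m1 <- ing$mutations
  key <- function(m) sort(paste(m$qname, m$ref_pos, m$kind, m$len,
                                m$ref_base, m$read_base))
  expect_identical(key(m1), key(m0))
  unlink(sam)
})

test_that("aligning simulated reads recovers planted deletions at their sites", {
  # background rates zero; hotspots far apart so no read carries two
  # deletions and every planted deletion is recoverable
  fx <- fx_operon()
  ssu <- ssu_feature()
  xl <- crosslink_spec("chrR", ssu$tx_start + c(494L, 1362L) - 1L,
                       xl_prob = 1, del_prob = 0.3, sub_prob = 0)
  cfg <- library_config(n_fragments = 4000, seed = 55, bg_del_rate = 0,
                        bg_sub_rate = 0, polyA_frac = 0)
  lib <- simulate_library(fx$txome, xl, cfg, sample = "S1")
  col <- preprocess_library(lib, cfg)
  aln <- align_reads(col, fx$txome$genome, seed = 9, sample = "S1")
  truth_tab <- table(lib$events$ref_pos[lib$events$kind == "del"])
  got_tab <- table(aln$mutations$ref_pos[aln$mutations$kind == "del"])
  common <- intersect(names(truth_tab), names(got_tab))
  recovered <- sum(pmin(truth_tab[common], got_tab[common]))
  expect_gte(recovered / sum(truth_tab), 0.99)
})
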