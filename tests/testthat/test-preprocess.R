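mkreads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("F", nchar(seqs))
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = quals, stringsAsFactors = FALSE)
}

test_that("demultiplex assigns by fixed positions and extracts the UMI", {
  specs <- data.frame(sample = c("A", "B"),
                      template = c("NNNTT", "NNNGG"))
  reads <- mkreads(c("ACGTTAGGCCAGTCAGTCAGTC",   # A, UMI ACG
                     "TTTGGAGGCCAGTCAGTCAGTC",   # B, UMI TTT
                     "CCCCCAGGCCAGTCAGTCAGTC",   # matches neither
                     "ACG"))                      # shorter than template
  out <- demultiplex(reads, specs, max_mismatch = 0)
  expect_equal(nrow(out$A), 1L)
  expect_equal(out$A$umi, "ACG")
  expect_equal(out$A$seq, "AGGCCAGTCAGTCAGTC")
  expect_match(out$A$id, "##ACG$")
  expect_equal(nrow(out$B), 1L)
  expect_equal(nrow(out$unassigned), 2L)
  # conservation
  expect_equal(nrow(out$A) + nrow(out$B) + nrow(out$unassigned),
               nrow(reads))
})

test_that("equidistant barcode matches go to the unassigned bin", {
  specs <- data.frame(sample = c("A", "B"),
                      template = c("AAAA", "TTTT"))
  reads <- mkreads("AATTCCCCGGGGCCCCGGGG")
  out <- demultiplex(reads, specs, max_mismatch = 2)
  expect_equal(nrow(out$unassigned), 1L)
})

test_that("demultiplex handles an empty FASTQ", {
  specs <- data.frame(sample = "A", template = "NNNTT")
  out <- demultiplex(mkreads(character(0)), specs)
  expect_equal(nrow(out$A), 0L)
  expect_equal(nrow(out$unassigned), 0L)
})

test_that("simulated barcodes demultiplex exactly to truth counts", {
  fx <- fx_operon()
  cfgA <- library_config(n_fragments = 400, seed = 61,
                         barcode_template = "NNNTAAGC")
  cfgB <- library_config(n_fragments = 300, seed = 62,
                         barcode_template = "NNNGTGGC")
  libA <- simulate_library(fx$txome, fx$xl_sites, cfgA, sample = "A")
  libB <- simulate_library(fx$txome, fx$xl_sites, cfgB, sample = "B")
  libB$reads$id <- paste0("B", libB$reads$id)
  pool <- rbind(libA$reads, libB$reads)
  pool <- pool[sample(nrow(pool)), ]
  out <- demultiplex(pool, data.frame(sample = c("A", "B"),
                                      template = c("NNNTAAGC", "NNNGTGGC")))
  expect_equal(nrow(out$A), nrow(libA$reads))
  expect_equal(nrow(out$B), nrow(libB$reads))
  expect_equal(nrow(out$unassigned), 0L)
})

test_that("adapter trimming follows the minimal-overlap contract", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTACG"
  # full adapter read-through
  r1 <- trim_and_filter(mkreads(paste0(insert, adapter)), adapter)
  expect_equal(r1$seq, insert)
  expect_true(r1$adapter_found)
  # exactly 4 nt of adapter at the 3' end: removed
  r2 <- trim_and_filter(mkreads(paste0(insert, substr(adapter, 1, 4))),
                        adapter)
  expect_equal(r2$seq, insert)
  # only 3 nt of adapter: below min_overlap, kept
  r3 <- trim_and_filter(mkreads(paste0(insert, substr(adapter, 1, 3))),
                        adapter)
  expect_equal(r3$seq, paste0(insert, substr(adapter, 1, 3)))
  expect_false(r3$adapter_found)
})

test_that("trimming matches a brute-force suffix/prefix oracle", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  oracle_trim <- function(s, min_overlap = 4) {
    p <- regexpr(adapter, s, fixed = TRUE)
    if (p > 0) return(substr(s, 1, p - 1))
    for (k in seq(min(nchar(adapter) - 1, nchar(s)), min_overlap)) {
      if (substr(s, nchar(s) - k + 1, nchar(s)) == substr(adapter, 1, k)) {
        return(substr(s, 1, nchar(s) - k))
      }
    }
    s
  }
  set.seed(99)
  seqs <- vapply(1:200, function(i) {
    ins <- paste(sample(c("A", "C", "G", "T"), sample(18:40, 1),
                        replace = TRUE), collapse = "")
    k <- sample(0:nchar(adapter), 1)
    paste0(ins, substr(adapter, 1, k))
  }, character(1))
  got <- trim_and_filter(mkreads(seqs), adapter, min_len = 1,
                         max_uncalled = 100)
  expect_equal(got$seq, vapply(seqs, oracle_trim, character(1),
                               USE.NAMES = FALSE))
})

test_that("quality trimming removes the low-quality 3' tail first", {
  # last 5 bases below Q30 (char '*' = Q9), then 4 adapter bases exposed
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTAC"
  seq <- paste0(insert, substr(adapter, 1, 4), "CCCCC")
  qual <- paste0(strrep("F", nchar(insert) + 4), strrep("*", 5))
  out <- trim_and_filter(mkreads(seq, qual), adapter)
  expect_equal(out$seq, insert)
})

test_that("uncalled-base and length filters apply at their thresholds", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  r_4n <- mkreads("ACGTNNACGTNNACGTACGT")   # 4 N > 3: discarded
  expect_equal(nrow(trim_and_filter(r_4n, adapter)), 0L)
  r_3n <- mkreads("ACGTNNACGTNACGTACGT")    # 3 N: kept
  expect_equal(nrow(trim_and_filter(r_3n, adapter)), 1L)
  expect_equal(nrow(trim_and_filter(mkreads(strrep("C", 17)), adapter)), 1L)
  expect_equal(nrow(trim_and_filter(mkreads(strrep("C", 16)), adapter)), 0L)
})

test_that("trimming never lengthens reads and preserves order", {
  lib <- fx_operon_lib()
  sub <- head(lib$reads, 500)
  out <- trim_and_filter(sub, lib$config$adapter)
  expect_true(all(nchar(out$seq) <= nchar(sub$seq[match(out$id, sub$id)])))
  expect_identical(out$id, sub$id[sub$id %in% out$id])
})

test_that("collapse merges by (sequence, UMI) with first-occurrence rule", {
  r <- data.frame(id = c("a##ACG", "b##ACG", "c##ACG", "d##TTG"),
                  seq = c("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTACGT"),
                  qual = strrep("F", 8), stringsAsFactors = FALSE)
  out <- collapse_reads(r)
  expect_equal(nrow(out), 2L)
  expect_equal(out$mult, c(3L, 1L))
  expect_equal(out$id[1], "1_ACG_x3")
  # idempotence
  again <- collapse_reads(out)
  expect_equal(again$seq, out$seq)
  expect_equal(again$mult, out$mult)
  expect_equal(again$id, out$id)
})

test_that("reads without UMI are rejected with a warning", {
  r <- data.frame(id = c("a##ACG", "b"), seq = c("AAAA", "CCCC"),
                  qual = "FFFF", stringsAsFactors = FALSE)
  expect_warning(out <- collapse_reads(r), "without UMI")
  expect_equal(nrow(out), 1L)
})

test_that("collapsed count equals the truth duplicate-group count exactly", {
  lib <- fx_operon_lib()
  col <- preprocess_library(lib, lib$config)
  expect_equal(nrow(col), max(lib$truth$dup_group))
  # independent hash-set oracle over (post-trim sequence, UMI)
  oracle <- length(unique(paste(lib$truth$insert, lib$truth$umi)))
  expect_equal(nrow(col), oracle)
  # collapsed FASTA round trip
  fa <- tempfile(fileext = ".fa")
  write_collapsed_fasta(col, fa)
  back <- read_collapsed_fasta(fa)
  expect_equal(back$seq, col$seq)
  expect_equal(back$mult, col$mult)
  unlink(fa)
})
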