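## shared fixtures, built once per test run

memo <- local({
  cache <- list()
  function(key, builder) {
    if (is.null(cache[[key]])) cache[[key]] <<- builder()
    cache[[key]]
  }
})

## operon fixture + a mid-sized library with reads
fx_operon <- function() memo("operon", function() operon_fixture(seed = 42))

fx_operon_lib <- function() memo("operon_lib", function() {
  fx <- fx_operon()
  cfg <- library_config(n_fragments = 4000, seed = 101, polyA_frac = 0)
  simulate_library(fx$txome, fx$xl_sites, cfg, sample = "S1")
})

ssu_feature <- function() {
  tr <- fx_operon()$txome$transcripts
  tr[tr$tx_id == "18S-like", ]
}

## small mRNA transcriptome, both strands
fx_mrna <- function() memo("mrna", function() {
  build_transcriptome(n_genes = 12, seed = 7, minus_frac = 0.5)
})

## hand-built two-gene transcriptome on a fixed genome (exact arithmetic)
tiny_txome <- function(chrom_seq, transcripts, exons) {
  genome <- Biostrings::DNAStringSet(chrom_seq)
  tr <- transcripts
  tr$tx_len <- tr$tx_end - tr$tx_start + 1L
  sp <- vapply(split(exons$end - exons$start + 1L, exons$tx_id), sum,
               numeric(1))
  tr$spliced_len <- unname(sp[tr$tx_id])
  if (is.null(tr$utr5)) tr$utr5 <- 0L
  if (is.null(tr$utr3)) tr$utr3 <- 0L
  structure(list(genome = genome, transcripts = tr, exons = exons,
                 utr_table = data.frame(tx_id = tr$tx_id,
                                        utr5_len = tr$utr5,
                                        utr3_len = tr$utr3),
                 seed = NA_integer_),
            class = "crac_transcriptome")
}

## independent brute-force pileup oracle: walk every CIGAR, count
## coverage (M+D), single-nt deletions and substitutions per position
brute_pileup <- function(aln, feature) {
  fstart <- feature$tx_start; fend <- feature$tx_end
  flen <- fend - fstart + 1L
  reads <- integer(flen); dels <- integer(flen); subs <- integer(flen)
  a <- aln$alignments
  for (i in seq_len(nrow(a))) {
    if (a$rname[i] != feature$chrom || a$strand[i] != feature$strand) next
    ops <- regmatches(a$cigar[i], gregexpr("[0-9]+[MIDS]", a$cigar[i]))[[1]]
    p <- a$pos[i]
    for (op in ops) {
      len <- as.integer(sub("[MIDS]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "D")) {
        for (g in p:(p + len - 1L)) {
          if (g >= fstart && g <= fend) reads[g - fstart + 1L] <-
              reads[g - fstart + 1L] + 1L
        }
        if (type == "D" && len == 1L) {
          if (p >= fstart && p <= fend) dels[p - fstart + 1L] <-
              dels[p - fstart + 1L] + 1L
        }
        p <- p + len
      }
    }
  }
  m <- aln$mutations
  for (i in seq_len(nrow(m))) {
    if (m$rname[i] != feature$chrom || m$strand[i] != feature$strand) next
    if (m$kind[i] == "sub" && m$ref_pos[i] >= fstart && m$ref_pos[i] <= fend) {
      subs[m$ref_pos[i] - fstart + 1L] <- subs[m$ref_pos[i] - fstart + 1L] + 1L
    }
  }
  if (feature$strand == "-") {
    reads <- rev(reads); dels <- rev(dels); subs <- rev(subs)
  }
  list(reads = reads, dels = dels, subs = subs)
}

## mirror a fixture: reverse-complement the genome and flip all coordinates,
## annotation and alignments; metagene profiles must be invariant
mirror_cigar <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDS]", cg))[[1]]
    paste(rev(ops), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

mirror_fixture <- function(txome, aln) {
  lens <- setNames(Biostrings::width(txome$genome), names(txome$genome))
  g2 <- Biostrings::reverseComplement(txome$genome)
  names(g2) <- names(txome$genome)
  tr <- txome$transcripts
  L <- lens[tr$chrom]
  tr2 <- tr
  tr2$tx_start <- as.integer(L - tr$tx_end + 1L)
  tr2$tx_end <- as.integer(L - tr$tx_start + 1L)
  tr2$cds_start <- as.integer(L - tr$cds_end + 1L)
  tr2$cds_end <- as.integer(L - tr$cds_start + 1L)
  tr2$strand <- ifelse(tr$strand == "+", "-", "+")
  tr2$pA_site <- ifelse(tr2$strand == "+", tr2$tx_end, tr2$tx_start)
  ex <- txome$exons
  exL <- lens[tr$chrom[match(ex$tx_id, tr$tx_id)]]
  ex2 <- ex
  ex2$start <- as.integer(exL - ex$end + 1L)
  ex2$end <- as.integer(exL - ex$start + 1L)
  tx2 <- txome
  tx2$genome <- g2
  tx2$transcripts <- tr2
  tx2$exons <- ex2

  a <- aln$alignments
  aL <- lens[a$rname]
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(a$cigar)
  a2 <- a
  a2$pos <- as.integer(aL - (a$pos + rw - 1L) + 1L)
  a2$strand <- ifelse(a$strand == "+", "-", "+")
  a2$cigar <- mirror_cigar(a$cigar)
  a2$seq_ref <- ifelse(a$seq_ref == "*", "*",
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAStringSet(
                           ifelse(a$seq_ref == "*", "A", a$seq_ref)))))
  m <- aln$mutations
  mL <- lens[m$rname]
  m2 <- m
  m2$ref_pos <- as.integer(mL - (m$ref_pos + m$len - 1L) + 1L)
  m2$strand <- ifelse(m$strand == "+", "-", "+")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  m2$ref_base <- comp(m$ref_base)
  m2$read_base <- comp(m$read_base)
  list(txome = tx2, aln = new_alignments(a2, m2))
}

## classic pooled-variance two-sample t test, from the textbook formula
textbook_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t), nx + ny - 2)
}

## run the simulate -> preprocess -> collapse path for one sample
preprocess_library <- function(lib, cfg) {
  specs <- data.frame(sample = lib$sample, template = cfg$barcode_template)
  dm <- demultiplex(lib$reads, specs)
  tf <- trim_and_filter(dm[[lib$sample]], cfg$adapter)
  collapse_reads(tf)
}
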