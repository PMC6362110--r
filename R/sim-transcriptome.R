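#' Generate a synthetic transcriptome (genome, annotation, UTR table)
#'
#' Builds a small genome carrying non-overlapping transcripts on one or more
#' chromosomes, optionally including an rRNA-operon-like polycistronic
#' feature with an 18S-like sub-feature, mirroring the structure of the
#' yeast RDN37 pre-rRNA locus. mRNAs have explicit 5'/3' UTRs around a CDS
#' whose length is divisible by 3; a configurable fraction carries a single
#' intron inside the CDS.
#'
#' Coordinates are 1-based closed throughout, matching GFF3/SAM conventions.
#' The polyadenylation (pA) site of a transcript is its last transcribed
#' base (`tx_end` on plus-strand genes, `tx_start` on minus-strand genes).
#'
#' @param n_genes number of mRNAs.
#' @param cds_len integer range (min, max) of CDS lengths in nt; drawn
#'   uniformly then rounded down to a multiple of 3. Default 450--1200.
#' @param utr5_len,utr3_len integer ranges for UTR lengths. Defaults 30--80
#'   and 60--150, footprint-scale yeast-like UTRs.
#' @param intron_frac fraction of mRNAs receiving one intron inside the CDS.
#' @param intron_len intron length range.
#' @param include_rrna_operon if TRUE, a 6.9-kb polycistronic rRNA-like
#'   feature containing an 1800-nt 18S-like sub-feature (at offset 700) is
#'   placed on its own chromosome.
#' @param minus_frac fraction of mRNAs placed on the minus strand.
#' @param spacer intergenic spacer length between genes.
#' @param seed integer seed; the same seed reproduces the transcriptome
#'   byte-for-byte.
#' @return list of class `crac_transcriptome` with elements `genome`
#'   (DNAStringSet), `transcripts` (data.frame: tx_id, chrom, strand,
#'   tx_start, tx_end, cds_start, cds_end, pA_site, rna_class, n_exons,
#'   utr5, utr3, tx_len, spliced_len), `exons` (data.frame: tx_id,
#'   exon_rank, start, end) and `utr_table` (data.frame: tx_id, utr5_len,
#'   utr3_len).
#' @export
build_transcriptome <- function(n_genes = 20,
                                cds_len = c(450, 1200),
                                utr5_len = c(30, 80),
                                utr3_len = c(60, 150),
                                intron_frac = 0,
                                intron_len = c(80, 200),
                                include_rrna_operon = FALSE,
                                minus_frac = 0.4,
                                spacer = 300,
                                seed = 1) {
  stopifnot(cds_len[1] >= 60, spacer >= 50)
  spacer <- as.integer(spacer)
  set.seed(seed)

  tx <- list(); ex <- list(); chrseqs <- list()

  if (n_genes > 0) {
    cds <- (sample_range(cds_len, n_genes) %/% 3L) * 3L
    u5 <- sample_range(utr5_len, n_genes)
    u3 <- sample_range(utr3_len, n_genes)
    has_intron <- runif(n_genes) < intron_frac
    ilen <- ifelse(has_intron, sample_range(intron_len, n_genes), 0L)
    strand <- ifelse(runif(n_genes) < minus_frac, "-", "+")

    glen <- u5 + cds + ilen + u3           # genomic span of each gene
    starts <- spacer + cumsum(c(0L, head(glen + spacer, -1L))) + 1L
    ends <- starts + glen - 1L
    chrom_len <- ends[n_genes] + spacer
    chrseqs[["chrI"]] <- random_dna(chrom_len)

    for (i in seq_len(n_genes)) {
      id <- sprintf("mRNA%03d", i)
      s <- starts[i]; e <- ends[i]
      if (strand[i] == "+") {
        cs <- s + u5[i]; ce <- e - u3[i]
      } else {
        cs <- s + u3[i]; ce <- e - u5[i]
      }
      exons <- data.frame(tx_id = id, exon_rank = 1L, start = s, end = e)
      if (has_intron[i]) {
        # intron placed mid-CDS, never at an exon edge
        mid <- (cs + ce) %/% 2L
        i_start <- mid; i_end <- mid + ilen[i] - 1L
        exons <- data.frame(
          tx_id = id, exon_rank = c(1L, 2L),
          start = c(s, i_end + 1L), end = c(i_start - 1L, e)
        )
      }
      tx[[id]] <- data.frame(
        tx_id = id, chrom = "chrI", strand = strand[i],
        tx_start = s, tx_end = e, cds_start = cs, cds_end = ce,
        pA_site = if (strand[i] == "+") e else s,
        rna_class = "mRNA", n_exons = nrow(exons),
        utr5 = u5[i], utr3 = u3[i],
        stringsAsFactors = FALSE
      )
      ex[[id]] <- exons
    }
  }

  if (include_rrna_operon) {
    op_len <- 6900L; ssu_off <- 700L; ssu_len <- 1800L
    op_start <- 501L
    chrom_len <- op_start + op_len - 1L + 500L
    chr <- random_dna(chrom_len)
    # pin the bases at and left of the hotspot nucleotides so that a
    # deletion there has an unambiguous (leftmost-aligned) coordinate:
    # no hotspot base repeats its left neighbour
    ssu0 <- op_start + ssu_off         # genomic coord of 18S position 1
    patch <- function(x, at, bases) {
      substr(x, at, at + nchar(bases) - 1L) <- bases
      x
    }
    chr <- patch(chr, ssu0 + 493L - 1L, "GT")    # 18S 493-494 (U494-like)
    chr <- patch(chr, ssu0 + 1361L - 1L, "AT")   # 18S 1361-1362
    chr <- patch(chr, ssu0 + 1489L - 1L, "GCTA") # 18S 1489-1492 (C1490-A1492)
    chrseqs[["chrR"]] <- chr
    op_end <- op_start + op_len - 1L
    tx[["RDN37-like"]] <- data.frame(
      tx_id = "RDN37-like", chrom = "chrR", strand = "+",
      tx_start = op_start, tx_end = op_end,
      cds_start = NA_integer_, cds_end = NA_integer_,
      pA_site = op_end, rna_class = "rRNA", n_exons = 1L,
      utr5 = 0L, utr3 = 0L, stringsAsFactors = FALSE
    )
    ex[["RDN37-like"]] <- data.frame(
      tx_id = "RDN37-like", exon_rank = 1L, start = op_start, end = op_end
    )
    ssu_start <- op_start + ssu_off
    tx[["18S-like"]] <- data.frame(
      tx_id = "18S-like", chrom = "chrR", strand = "+",
      tx_start = ssu_start, tx_end = ssu_start + ssu_len - 1L,
      cds_start = NA_integer_, cds_end = NA_integer_,
      pA_site = ssu_start + ssu_len - 1L, rna_class = "rRNA", n_exons = 1L,
      utr5 = 0L, utr3 = 0L, stringsAsFactors = FALSE
    )
    ex[["18S-like"]] <- data.frame(
      tx_id = "18S-like", exon_rank = 1L,
      start = ssu_start, end = ssu_start + ssu_len - 1L
    )
  }

  transcripts <- do.call(rbind, c(tx, list(make.row.names = FALSE)))
  exons <- do.call(rbind, c(ex, list(make.row.names = FALSE)))
  if (is.null(transcripts)) {
    stop("empty transcriptome requested: need n_genes > 0 or the operon")
  }

  genome <- Biostrings::DNAStringSet(unlist(chrseqs))
  names(genome) <- names(chrseqs)

  exons <- exons[order(match(exons$tx_id, transcripts$tx_id), exons$exon_rank), ]
  rownames(exons) <- NULL
  sp_len <- vapply(split(exons$end - exons$start + 1L, exons$tx_id), sum,
                   numeric(1))
  transcripts$tx_len <- transcripts$tx_end - transcripts$tx_start + 1L
  transcripts$spliced_len <- unname(sp_len[transcripts$tx_id])

  utr_table <- data.frame(
    tx_id = transcripts$tx_id,
    utr5_len = transcripts$utr5,
    utr3_len = transcripts$utr3
  )

  structure(
    list(genome = genome, transcripts = transcripts, exons = exons,
         utr_table = utr_table, seed = seed),
    class = "crac_transcriptome"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## sample n values uniformly from an inclusive integer range; safe for
## degenerate ranges (sample() would misread a scalar as 1:x)
sample_range <- function(rng, n) {
  if (rng[1] == rng[2]) rep(as.integer(rng[1]), n) else
    sample(rng[1]:rng[2], n, replace = TRUE)
}

#' The paper-like rRNA operon fixture
#'
#' A transcriptome holding only the rRNA-operon-like feature, with the
#' crosslink hotspot positions used throughout the 18S analyses: the major
#' site at 18S positions 1490-1492 and the two minor sites at 494 and 1362
#' (1-based coordinates within the 18S-like sub-feature).
#'
#' @param seed integer seed.
#' @return list with `txome` (a `crac_transcriptome`) and `xl_sites`
#'   (a data.frame of [crosslink_spec()] rows at the hotspot coordinates).
#' @param del_prob,sub_prob per-crosslink deletion/substitution probabilities.
#' @param xl_prob probability that an overlapping fragment is crosslinked.
#' @export
operon_fixture <- function(seed = 1, xl_prob = 1, del_prob = 0.3,
                           sub_prob = 0.1) {
  txome <- build_transcriptome(n_genes = 0, include_rrna_operon = TRUE,
                               seed = seed)
  ssu <- txome$transcripts[txome$transcripts$tx_id == "18S-like", ]
  hot <- c(494L, 1362L, 1490L, 1491L, 1492L)
  xl <- crosslink_spec(
    chrom = "chrR",
    pos = ssu$tx_start + hot - 1L,
    xl_prob = xl_prob, del_prob = del_prob, sub_prob = sub_prob
  )
  list(txome = txome, xl_sites = xl, hotspots_18S = hot)
}

#' Declare planted crosslink sites
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based genomic position(s) of the crosslinked nucleotide.
#' @param xl_prob probability that a fragment overlapping `pos` is
#'   crosslinked there.
#' @param del_prob probability that a crosslinked fragment carries a 1-nt
#'   deletion at `pos`.
#' @param sub_prob probability of a substitution at `pos` instead.
#' @return data.frame of crosslink specifications.
#' @export
crosslink_spec <- function(chrom, pos, xl_prob = 1, del_prob = 0.3,
                           sub_prob = 0.1) {
  stopifnot(all(xl_prob >= 0 & xl_prob <= 1),
            all(del_prob >= 0 & del_prob <= 1),
            all(sub_prob >= 0 & sub_prob <= 1),
            all(del_prob + sub_prob <= 1))
  data.frame(chrom = chrom, pos = as.integer(pos),
             xl_prob = xl_prob, del_prob = del_prob, sub_prob = sub_prob)
}

#' Export a transcriptome as genome FASTA + GFF3 + UTR table
#'
#' @param txome a `crac_transcriptome`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the written paths.
#' @export
write_transcriptome <- function(txome, dir, prefix = "txome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  utr <- file.path(dir, paste0(prefix, "_utrs.tsv"))
  write_fasta(txome$genome, fa)
  export_gff3(txome, gff)
  write.table(txome$utr_table, utr, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(fasta = fa, gff = gff, utr = utr)
}

export_gff3 <- function(txome, path) {
  tr <- txome$transcripts
  gr_tx <- GenomicRanges::GRanges(
    seqnames = tr$chrom,
    ranges = IRanges::IRanges(tr$tx_start, tr$tx_end),
    strand = tr$strand,
    type = ifelse(tr$rna_class == "mRNA", "mRNA", "transcript"),
    ID = tr$tx_id,
    rna_class = tr$rna_class
  )
  exm <- merge(txome$exons, tr[, c("tx_id", "chrom", "strand")], by = "tx_id")
  gr_ex <- GenomicRanges::GRanges(
    seqnames = exm$chrom,
    ranges = IRanges::IRanges(exm$start, exm$end),
    strand = exm$strand,
    type = "exon",
    ID = paste0(exm$tx_id, ".exon", exm$exon_rank),
    Parent = exm$tx_id
  )
  cds <- tr[!is.na(tr$cds_start), , drop = FALSE]
  gr <- c(gr_tx, gr_ex)
  if (nrow(cds) > 0) {
    gr_cds <- GenomicRanges::GRanges(
      seqnames = cds$chrom,
      ranges = IRanges::IRanges(cds$cds_start, cds$cds_end),
      strand = cds$strand,
      type = "CDS",
      phase = 0L,
      ID = paste0(cds$tx_id, ".cds"),
      Parent = cds$tx_id
    )
    gr <- c(gr, gr_cds)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a transcriptome back from FASTA + GFF3 (+ UTR table)
#'
#' Round-trip reader for the files written by [write_transcriptome()]; also
#' accepts any GFF3 with mRNA/transcript, exon and CDS features.
#'
#' @param fasta genome FASTA path.
#' @param gff GFF3 annotation path.
#' @param utr optional UTR table TSV path.
#' @return a `crac_transcriptome`.
#' @export
read_transcriptome <- function(fasta, gff, utr = NULL) {
  genome <- read_fasta(fasta)
  g <- rtracklayer::import(gff, format = "gff3")
  is_tx <- g$type %in% c("mRNA", "transcript")
  txg <- g[is_tx]
  exg <- g[g$type == "exon"]
  cdg <- g[g$type == "CDS"]
  rc <- if (!is.null(txg$rna_class)) as.character(txg$rna_class) else
    ifelse(as.character(txg$type) == "mRNA", "mRNA", "other")
  parent_of <- function(x) {
    p <- x$Parent
    vapply(p, function(v) as.character(v)[1], character(1))
  }
  cds_by <- split(seq_along(cdg), parent_of(cdg))
  tr <- data.frame(
    tx_id = as.character(txg$ID),
    chrom = as.character(GenomicRanges::seqnames(txg)),
    strand = as.character(GenomicRanges::strand(txg)),
    tx_start = GenomicRanges::start(txg),
    tx_end = GenomicRanges::end(txg),
    stringsAsFactors = FALSE
  )
  tr$cds_start <- NA_integer_; tr$cds_end <- NA_integer_
  for (i in seq_len(nrow(tr))) {
    idx <- cds_by[[tr$tx_id[i]]]
    if (!is.null(idx)) {
      tr$cds_start[i] <- min(GenomicRanges::start(cdg[idx]))
      tr$cds_end[i] <- max(GenomicRanges::end(cdg[idx]))
    }
  }
  tr$pA_site <- ifelse(tr$strand == "+", tr$tx_end, tr$tx_start)
  tr$rna_class <- rc
  ex <- data.frame(
    tx_id = parent_of(exg),
    start = GenomicRanges::start(exg),
    end = GenomicRanges::end(exg),
    stringsAsFactors = FALSE
  )
  ex <- ex[order(match(ex$tx_id, tr$tx_id), ex$start), ]
  ex$exon_rank <- unlist(lapply(split(ex$tx_id, ex$tx_id)[unique(ex$tx_id)],
                                seq_along), use.names = FALSE)
  # restore 5'->3' exon rank on minus strand
  for (id in tr$tx_id[tr$strand == "-"]) {
    sel <- ex$tx_id == id
    ex$exon_rank[sel] <- rev(ex$exon_rank[sel])
  }
  tr$n_exons <- as.integer(table(ex$tx_id)[tr$tx_id])
  sp_len <- vapply(split(ex$end - ex$start + 1L, ex$tx_id), sum, numeric(1))
  tr$tx_len <- tr$tx_end - tr$tx_start + 1L
  tr$spliced_len <- unname(sp_len[tr$tx_id])
  tr$utr5 <- ifelse(tr$strand == "+", tr$cds_start - tr$tx_start,
                    tr$tx_end - tr$cds_end)
  tr$utr3 <- ifelse(tr$strand == "+", tr$tx_end - tr$cds_end,
                    tr$cds_start - tr$tx_start)
  utr_table <- if (!is.null(utr)) read.delim(utr) else
    data.frame(tx_id = tr$tx_id, utr5_len = tr$utr5, utr3_len = tr$utr3)
  ex <- ex[, c("tx_id", "exon_rank", "start", "end")]
  rownames(ex) <- NULL; rownames(tr) <- NULL
  structure(list(genome = genome, transcripts = tr, exons = ex,
                 utr_table = utr_table, seed = NA_integer_),
            class = "crac_transcriptome")
}
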