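#' @importFrom stats median rgeom runif rnorm rlnorm rbinom setNames t.test cor dnorm quantile
#' @importFrom utils read.delim write.table head tail
NULL

#' Read a FASTQ file into a plain read table
#'
#' Reads are held in memory as a data frame with columns `id`, `seq`, `qual`;
#' all downstream preprocessing operates on this table. Parsing is delegated
#' to \pkg{Biostrings}.
#'
#' @param path FASTQ file (Phred+33, uncompressed or gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write a read table as FASTQ (Phred+33)
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::PhredQuality(Biostrings::BStringSet(reads$qual))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#' @param path FASTA file.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a DNAStringSet (or named character vector) as FASTA
#' @param x sequences.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## reverse complement on character vectors
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

## genome accessors: genome is a named DNAStringSet; keep character copies
## cached so substr-heavy code does not re-decode the XString each call
genome_chars <- function(genome) {
  ch <- attr(genome, "crackle_chars")
  if (is.null(ch)) {
    ch <- setNames(as.character(genome), names(genome))
  }
  ch
}

genome_seq <- function(genome, chrom, start, end) {
  ch <- genome_chars(genome)[[chrom]]
  substr(ch, start, end)
}

chrom_lengths <- function(genome) setNames(Biostrings::width(genome), names(genome))

#' Write alignments as SAM
#'
#' Emits a valid SAM file (1-based POS, FLAG 0/16, MD and NH tags) from the
#' package's in-memory alignment table. Sequences are stored in reference
#' orientation as the SAM specification requires.
#'
#' @param aln a `crac_alignments` object (see [ingest_alignments()]).
#' @param genome named DNAStringSet (for the header and MD tags).
#' @param path output SAM file.
#' @export
write_sam <- function(aln, genome, path) {
  a <- aln$alignments
  lens <- chrom_lengths(genome)
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(lens), unname(lens))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(a) > 0) {
    md <- md_tags(aln, genome)
    seqs <- a$seq_ref
    flag <- ifelse(a$strand == "-", 16L, 0L)
    mapq <- ifelse(a$n_hits > 1L, 0L, 60L)
    recs <- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNH:i:%d\tMD:Z:%s",
      a$qname, flag, a$rname, a$pos, mapq, a$cigar, seqs, a$n_hits, md
    )
    writeLines(recs, con)
  }
  invisible(path)
}

## MD tag per alignment from the mutations table (reference-space walk)
md_tags <- function(aln, genome) {
  a <- aln$alignments
  mut <- aln$mutations
  md <- character(nrow(a))
  refw <- cigar_ref_width(a$cigar)
  mut <- mut[mut$kind != "ins", , drop = FALSE]
  byq <- split(seq_len(nrow(mut)), factor(mut$qname, levels = a$qname))
  for (i in seq_len(nrow(a))) {
    idx <- byq[[i]]
    if (length(idx) == 0) {
      md[i] <- as.character(refw[i])
      next
    }
    m <- mut[idx, , drop = FALSE]
    m <- m[order(m$ref_pos), , drop = FALSE]
    cur <- a$pos[i]
    parts <- character(0)
    for (j in seq_len(nrow(m))) {
      gap <- m$ref_pos[j] - cur
      if (m$kind[j] == "sub") {
        parts <- c(parts, as.character(gap), m$ref_base[j])
        cur <- m$ref_pos[j] + 1L
      } else { # deletion (possibly multi-nt)
        parts <- c(parts, as.character(gap), paste0("^", m$ref_base[j]))
        cur <- m$ref_pos[j] + m$len[j]
      }
    }
    parts <- c(parts, as.character(a$pos[i] + refw[i] - cur))
    md[i] <- paste(parts, collapse = "")
  }
  md
}

## CIGAR widths (vectorized, via GenomicAlignments)
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

cigar_query_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
}
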