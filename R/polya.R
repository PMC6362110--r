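#' Detect candidate oligo(A) tails and strip them
#'
#' Only reads whose 3' adapter was found (so the true 3' end of the cDNA
#' is known) are eligible. A candidate tail is a maximal terminal run of
#' A of length at least `min_tail`. Trailing As are removed from every
#' eligible read -- candidate or not -- before (re)alignment: a terminal A
#' cannot be attributed to tail or template from the read alone, so
#' stripping all of them gives tailed and untailed reads the same mapped
#' 3'-end convention (the last non-A base), which keeps the pA-site
#' oligo(A) fraction unbiased. Classification as templated or
#' non-templated happens against the genome once alignments of the
#' stripped reads are available (see [classify_tails()]).
#'
#' @param reads data.frame with `id`, `seq` and an `adapter_found` logical
#'   column (from [trim_and_filter()]).
#' @param min_tail minimum terminal A-run length for a candidate call.
#' @param min_len stripped reads shorter than this are dropped (they
#'   cannot be realigned); the count is reported.
#' @return list: `stripped` (all eligible reads, trailing As removed),
#'   `candidates` (data.frame id, tail_len), `n_dropped_short`.
#' @export
detect_and_strip_tails <- function(reads, min_tail = 4, min_len = 17) {
  stopifnot(!is.null(reads$adapter_found))
  r <- reads[reads$adapter_found, , drop = FALSE]
  tail_run <- nchar(r$seq) - nchar(sub("A*$", "", r$seq))
  is_cand <- tail_run >= min_tail
  stripped <- r
  stripped$seq <- sub("A*$", "", r$seq)
  if (!is.null(stripped$qual)) {
    stripped$qual <- substr(stripped$qual, 1L, nchar(stripped$seq))
  }
  short <- nchar(stripped$seq) < min_len
  n_dropped <- sum(short)
  candidates <- data.frame(id = r$id[is_cand & !short],
                           tail_len = tail_run[is_cand & !short],
                           stringsAsFactors = FALSE)
  stripped <- stripped[!short, , drop = FALSE]
  rownames(stripped) <- NULL
  list(stripped = stripped, candidates = candidates,
       n_dropped_short = n_dropped)
}

## 3' end (genomic coordinate of the last transcribed base) per alignment
aligned_three_prime <- function(aln) {
  a <- aln$alignments
  rw <- cigar_ref_width(a$cigar)
  data.frame(qname = a$qname, rname = a$rname, strand = a$strand,
             end3 = ifelse(a$strand == "+", a$pos + rw - 1L, a$pos),
             stringsAsFactors = FALSE)
}

#' Classify candidate tails as templated or non-templated
#'
#' A candidate tail is non-templated iff the genomic bases immediately 3'
#' of the stripped alignment cannot explain the run: i.e. the next
#' `tail_len` genomic bases (read-strand orientation) are not all A. If at
#' least one tail base is non-templated the tail is called, matching the
#' notion of a non-encoded oligo(A) addition.
#'
#' @param candidates data.frame from [detect_and_strip_tails()].
#' @param aln `crac_alignments` of the stripped reads (qnames must match
#'   candidate ids).
#' @param genome named DNAStringSet.
#' @param txome optional transcriptome; when given, the signed distance of
#'   the mapped 3' end to the nearest annotated pA site on the same
#'   chromosome/strand is reported (positive = downstream of the pA).
#' @return data.frame of tail calls: id, tail_len, non_templated, rname,
#'   end3, strand, dist_pA (NA without annotation).
#' @export
classify_tails <- function(candidates, aln, genome, txome = NULL) {
  ends <- aligned_three_prime(aln)
  m <- merge(candidates, ends, by.x = "id", by.y = "qname")
  if (nrow(m) == 0) {
    return(data.frame(id = character(0), tail_len = integer(0),
                      non_templated = logical(0), rname = character(0),
                      end3 = integer(0), strand = character(0),
                      dist_pA = integer(0)))
  }
  chars <- genome_chars(genome)
  lens <- chrom_lengths(genome)
  cont <- character(nrow(m))
  plus <- m$strand == "+"
  for (cc in unique(m$rname)) {
    sel <- m$rname == cc
    p <- sel & plus
    if (any(p)) {
      cont[p] <- substring(chars[[cc]], m$end3[p] + 1L,
                           pmin(m$end3[p] + m$tail_len[p], lens[[cc]]))
    }
    q <- sel & !plus
    if (any(q)) {
      cont[q] <- revcomp(substring(chars[[cc]],
                                   pmax(m$end3[q] - m$tail_len[q], 1L),
                                   m$end3[q] - 1L))
    }
  }
  all_a <- cont == strrep("A", m$tail_len) & nchar(cont) == m$tail_len
  m$non_templated <- !all_a
  m$dist_pA <- NA_integer_
  if (!is.null(txome)) {
    m$dist_pA <- distance_to_pA(m, txome)
  }
  m[, c("id", "tail_len", "non_templated", "rname", "end3", "strand",
        "dist_pA")]
}

## signed distance (transcript orientation) to nearest pA on same
## chromosome and strand; NA when none exists
distance_to_pA <- function(df, txome) {
  tr <- txome$transcripts
  out <- rep(NA_integer_, nrow(df))
  for (cc in unique(df$rname)) {
    for (str in c("+", "-")) {
      sel <- df$rname == cc & df$strand == str
      pa <- tr$pA_site[tr$chrom == cc & tr$strand == str]
      if (!any(sel) || length(pa) == 0) next
      d <- outer(df$end3[sel], pa, `-`)
      if (str == "-") d <- -d
      pick <- apply(d, 1, function(z) z[which.min(abs(z))])
      out[sel] <- as.integer(pick)
    }
  }
  out
}

#' Fraction of oligo-adenylated reads at pA sites
#'
#' Among adapter-containing reads whose (stripped) 3' end maps within
#' `window` nt of an annotated pA site, the percentage carrying a
#' non-templated oligo(A) tail: reads at the pA site in oligo-adenylated
#' reads divided by reads at the pA site in all adapter-containing reads.
#'
#' @param tail_calls data.frame from [classify_tails()].
#' @param aln `crac_alignments` of all adapter-containing (stripped)
#'   reads.
#' @param txome transcriptome with pA annotation.
#' @param window half-width around the pA site (0 = the exact pA
#'   nucleotide).
#' @return list: `percent` (oligo(A) percentage), `n_pA_reads`
#'   (denominator), `n_tailed` (numerator), `flag` ("no_pA_reads" when
#'   the denominator is zero, percent then NA).
#' @export
pa_fraction <- function(tail_calls, aln, txome, window = 0) {
  ends <- aligned_three_prime(aln)
  ends$dist_pA <- distance_to_pA(data.frame(rname = ends$rname,
                                            strand = ends$strand,
                                            end3 = ends$end3), txome)
  at_pa <- !is.na(ends$dist_pA) & abs(ends$dist_pA) <= window
  denom <- sum(at_pa)
  tailed_ids <- tail_calls$id[tail_calls$non_templated]
  num <- sum(at_pa & ends$qname %in% tailed_ids)
  if (denom == 0) {
    return(list(percent = NA_real_, n_pA_reads = 0L, n_tailed = num,
                flag = "no_pA_reads"))
  }
  list(percent = 100 * num / denom, n_pA_reads = denom, n_tailed = num,
       flag = "")
}

#' Fraction of oligo(A) calls mapping far from any pA site
#'
#' The internal (within-transcript) oligo(A) level: among all
#' non-templated tail calls, the fraction whose 3' end lies more than
#' `min_distance` nt from every annotated pA site. In wild-type libraries
#' this should sit near the detection false-positive rate.
#'
#' @param tail_calls data.frame from [classify_tails()].
#' @param txome transcriptome.
#' @param min_distance distance threshold, nt.
#' @return list: `fraction`, `n_calls`, `flag` ("no_calls" when empty,
#'   fraction then 0).
#' @export
internal_background <- function(tail_calls, txome, min_distance = 50) {
  calls <- tail_calls[tail_calls$non_templated, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(list(fraction = 0, n_calls = 0L, flag = "no_calls"))
  }
  d <- calls$dist_pA
  if (all(is.na(d))) d <- distance_to_pA(calls, txome)
  list(fraction = mean(is.na(d) | abs(d) > min_distance),
       n_calls = nrow(calls), flag = "")
}
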