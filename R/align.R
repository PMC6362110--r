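## ---- alignment container -------------------------------------------------

empty_alignment_df <- function() {
  data.frame(qname = character(0), rname = character(0), pos = integer(0),
              strand = character(0), cigar = character(0), mult = integer(0),
              umi = character(0), sample = character(0), n_hits = integer(0),
              seq_ref = character(0), stringsAsFactors = FALSE)
}

empty_mutation_df <- function() {
  data.frame(qname = character(0), rname = character(0), ref_pos = integer(0),
              strand = character(0), kind = character(0), len = integer(0),
              read_base = character(0), ref_base = character(0),
              stringsAsFactors = FALSE)
}

#' Construct a crac_alignments object
#'
#' The package's central alignment container: a table of mapped reads
#' (1-based leftmost position, strand, CIGAR, collapse multiplicity, UMI,
#' equal-best hit count) plus a table of per-read mutation events
#' (substitutions, insertions, deletions with their reference coordinate).
#'
#' @param alignments data.frame with columns qname, rname, pos, strand,
#'   cigar, mult, umi, sample, n_hits, seq_ref.
#' @param mutations data.frame with columns qname, rname, ref_pos, strand,
#'   kind ("sub"/"del"/"ins"), len, read_base, ref_base.
#' @return object of class `crac_alignments`.
#' @export
new_alignments <- function(alignments, mutations) {
  structure(list(alignments = alignments, mutations = mutations),
            class = "crac_alignments")
}

#' @export
print.crac_alignments <- function(x, ...) {
  cat(sprintf("crac_alignments: %d alignments, %d mutation events\n",
              nrow(x$alignments), nrow(x$mutations)))
  invisible(x)
}

## ---- aligner -------------------------------------------------------------

#' Build an exact k-mer index over a genome (both strands)
#'
#' @param genome named DNAStringSet.
#' @param k seed length.
#' @return opaque index used by [align_reads()].
#' @export
genome_index <- function(genome, k = 12) {
  lens <- chrom_lengths(genome)
  spacer <- strrep("N", 150)
  chars <- genome_chars(genome)
  concat <- paste(chars, collapse = spacer)
  offs <- cumsum(c(0L, head(lens + 150L, -1L)))  # 0-based chrom offsets
  nco <- nchar(concat)
  starts <- seq_len(nco - k + 1L)
  kmers <- substring(concat, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  idx <- split(starts[keep], kmers[keep])
  structure(list(index = list2env(idx, hash = TRUE), concat = concat,
                 k = k, chrom = names(lens), offs = offs, lens = lens),
            class = "crac_genome_index")
}

## map concat coordinate -> (chrom, pos); NA when spanning a spacer
concat_to_chrom <- function(gi, p, width) {
  ci <- findInterval(p, gi$offs + 1L)
  pos <- as.integer(p - gi$offs[ci])
  ok <- pos >= 1L & (pos + width - 1L) <= gi$lens[ci]
  list(chrom = gi$chrom[ci], pos = pos, ok = ok)
}

#' Align reads by seeded extension with micro-deletion tolerance
#'
#' A deliberately small aligner for short CRAC reads: exact k-mer seeds,
#' ungapped extension allowing up to `max_sub` substitutions, plus at most
#' one single-nucleotide reference deletion (the crosslink signature). If a
#' read fails to align it is shortened from the 3' end by `shorten_step`
#' and retried until it would drop below `min_len`. Equal-best loci are
#' resolved uniformly at random under `seed` and their count is recorded
#' as `n_hits`. Scoring prefers fewest mutations, then the longest aligned
#' read, then the random choice.
#'
#' @param reads data.frame of collapsed reads (columns `seq`, and
#'   optionally `id`/`umi`/`mult`), or a `crac_collapsed` object.
#' @param genome named DNAStringSet, or a prebuilt [genome_index()].
#' @param k seed length.
#' @param max_sub maximum substitutions.
#' @param max_del maximum single-nt deletions (0 or 1).
#' @param min_len shortest read length attempted.
#' @param shorten_step 3' trim step on alignment failure.
#' @param multimap only "random" is implemented.
#' @param seed RNG seed for multimapper resolution.
#' @param sample sample label stored on the alignments.
#' @return a `crac_alignments`; unaligned read count in
#'   `attr(, "n_unaligned")`.
#' @export
align_reads <- function(reads, genome, k = 12, max_sub = 2, max_del = 1,
                        min_len = 17, shorten_step = 1,
                        multimap = "random", seed = 1, sample = "S1") {
  stopifnot(multimap == "random")
  gi <- if (inherits(genome, "crac_genome_index")) genome else
    genome_index(genome, k)
  k <- gi$k
  set.seed(seed)

  if (is.data.frame(reads)) {
    seqs <- reads$seq
    ids <- if (!is.null(reads$id)) reads$id else sprintf("read%06d",
                                                         seq_along(seqs))
    umis <- if (!is.null(reads$umi)) reads$umi else ""
    mults <- if (!is.null(reads$mult)) reads$mult else 1L
  } else stop("reads must be a data.frame")

  n <- length(seqs)
  if (length(umis) == 1L) umis <- rep(umis, n)
  if (length(mults) == 1L) mults <- rep(mults, n)
  rcs <- revcomp(seqs)

  # preallocated result columns (data.frame built once at the end)
  r_qname <- character(n); r_rname <- character(n); r_pos <- integer(n)
  r_strand <- character(n); r_cigar <- character(n); r_nhits <- integer(n)
  r_seq <- character(n); hit_ok <- logical(n)
  muts <- vector("list", n)
  n_unaligned <- 0L

  for (i in seq_len(n)) {
    s <- seqs[i]; rc <- rcs[i]
    hit <- NULL
    while (nchar(s) >= max(min_len, k)) {
      hit <- align_one(s, rc, gi, k, max_sub, max_del)
      if (!is.null(hit)) break
      s <- substr(s, 1L, nchar(s) - shorten_step)
      rc <- substr(rc, shorten_step + 1L, nchar(rc))
    }
    if (is.null(hit)) { n_unaligned <- n_unaligned + 1L; next }
    nh <- length(hit$best)
    pick <- hit$best[[if (nh > 1L) sample.int(nh, 1L) else 1L]]
    loc <- concat_to_chrom(gi, pick$p, pick$ref_w)
    if (!loc$ok) { n_unaligned <- n_unaligned + 1L; next }
    hit_ok[i] <- TRUE
    r_qname[i] <- ids[i]; r_rname[i] <- loc$chrom; r_pos[i] <- loc$pos
    r_strand[i] <- pick$strand; r_cigar[i] <- pick$cigar
    r_nhits[i] <- nh
    r_seq[i] <- if (pick$strand == "-") substr(rcs[i], nchar(rcs[i]) -
                                                 nchar(s) + 1L, nchar(rcs[i]))
                else s
    mm <- pick$mutations
    if (!is.null(mm) && length(mm$ref_pos) > 0) {
      mm$ref_pos <- mm$ref_pos - (pick$p - loc$pos)
      mm$qname <- ids[i]; mm$rname <- loc$chrom; mm$strand <- pick$strand
      muts[[i]] <- mm
    }
  }

  aln <- if (any(hit_ok)) {
    data.frame(qname = r_qname[hit_ok], rname = r_rname[hit_ok],
               pos = r_pos[hit_ok], strand = r_strand[hit_ok],
               cigar = r_cigar[hit_ok], mult = mults[hit_ok],
               umi = umis[hit_ok], sample = sample, n_hits = r_nhits[hit_ok],
               seq_ref = r_seq[hit_ok], stringsAsFactors = FALSE)
  } else empty_alignment_df()
  keep <- !vapply(muts, is.null, logical(1))
  mut <- if (any(keep)) {
    ml <- muts[keep]
    data.frame(
      qname = rep(vapply(ml, function(m) m$qname, character(1)),
                  vapply(ml, function(m) length(m$ref_pos), integer(1))),
      rname = rep(vapply(ml, function(m) m$rname, character(1)),
                  vapply(ml, function(m) length(m$ref_pos), integer(1))),
      ref_pos = unlist(lapply(ml, function(m) m$ref_pos)),
      strand = rep(vapply(ml, function(m) m$strand, character(1)),
                   vapply(ml, function(m) length(m$ref_pos), integer(1))),
      kind = unlist(lapply(ml, function(m) m$kind)),
      len = unlist(lapply(ml, function(m) m$len)),
      read_base = unlist(lapply(ml, function(m) m$read_base)),
      ref_base = unlist(lapply(ml, function(m) m$ref_base)),
      stringsAsFactors = FALSE
    )
  } else empty_mutation_df()
  res <- new_alignments(aln, mut)
  attr(res, "n_unaligned") <- n_unaligned
  res
}

## score one read (both strands); returns the list of equal-best candidates
align_one <- function(s, rc, gi, k, max_sub, max_del) {
  L <- nchar(s)
  cands <- list()
  keys <- character(0)
  for (strand in c("+", "-")) {
    q <- if (strand == "-") rc else s
    ps <- integer(0)
    for (o in c(0L, k, 2L * k)) {
      if (o + k > L) break
      hits <- gi$index[[substr(q, o + 1L, o + k)]]
      if (!is.null(hits)) ps <- c(ps, hits - o, if (max_del > 0) hits - o - 1L)
      if (length(ps) > 0 && o >= k) break
    }
    ps <- unique(ps[ps >= 1L])
    for (p in ps) {
      sc <- score_candidate(q, p, gi$concat, max_sub, max_del)
      if (!is.null(sc)) {
        key <- paste0(strand, p, ":", sc$cigar)
        if (!(key %in% keys)) {
          sc$strand <- strand
          cands[[length(cands) + 1L]] <- sc
          keys <- c(keys, key)
        }
      }
    }
  }
  if (length(cands) == 0) return(NULL)
  nmut <- vapply(cands, function(x) x$nmut, integer(1))
  cands <- cands[nmut == min(nmut)]
  # tie-break: longest aligned (reference) span; a deletion explanation
  # spans one base more than an equal-score substitution explanation
  refw <- vapply(cands, function(x) x$ref_w, integer(1))
  list(best = cands[refw == max(refw)])
}

## evaluate read q against concat genome at start p: ungapped or 1-deletion
score_candidate <- function(q, p, concat, max_sub, max_del) {
  L <- nchar(q)
  x <- utf8ToInt(q)
  g1 <- substr(concat, p, p + L - 1L)
  if (nchar(g1) < L) return(NULL)
  y1 <- utf8ToInt(g1)
  m1 <- x != y1
  ns1 <- sum(m1)
  best <- NULL
  if (ns1 <= max_sub) {
    best <- list(p = p, cigar = paste0(L, "M"), nmut = ns1, ref_w = L,
                 mutations = mismatch_events(x, y1, p, 0L))
  }
  if (max_del > 0 && (is.null(best) || ns1 > 0L)) {
    g2 <- substr(concat, p + 1L, p + L)
    if (nchar(g2) == L) {
      y2 <- utf8ToInt(g2)
      m2 <- x != y2
      A <- c(0L, cumsum(m1))              # A[d] = mismatches in read[1..d-1]
      B <- rev(c(0L, cumsum(rev(m2))))    # B[d] = mismatches in read[d..L]
      tot <- A[1:L] + B[1:L]              # deletion before read pos d
      tot_d <- tot[2:L]
      dmin <- 1L + which.min(tot_d)       # leftmost minimal (SAM convention)
      nsub <- tot[dmin]
      if (nsub <= max_sub && (is.null(best) || nsub + 1L < best$nmut)) {
        del_pos <- p + dmin - 1L
        y_del <- c(y1[seq_len(dmin - 1L)], y2[dmin:L])
        ev <- mismatch_events(x, y_del, p, dmin)
        ev$ref_pos <- c(ev$ref_pos, del_pos)
        ev$kind <- c(ev$kind, "del")
        ev$len <- c(ev$len, 1L)
        ev$read_base <- c(ev$read_base, "")
        ev$ref_base <- c(ev$ref_base, substr(concat, del_pos, del_pos))
        best <- list(p = p, cigar = paste0(dmin - 1L, "M1D", L - dmin + 1L,
                                           "M"),
                     nmut = nsub + 1L, ref_w = L + 1L, mutations = ev)
      }
    }
  }
  best
}

## substitution events (as plain vectors) from an elementwise comparison;
## read position j maps to reference p+j-1, +1 from the deletion onwards
mismatch_events <- function(x, y, p, del_shift_at) {
  mm <- which(x != y)
  if (length(mm) == 0) {
    return(list(ref_pos = integer(0), kind = character(0), len = integer(0),
                read_base = character(0), ref_base = character(0)))
  }
  shift <- if (del_shift_at > 0L) as.integer(mm >= del_shift_at) else 0L
  list(ref_pos = p + mm - 1L + shift, kind = rep("sub", length(mm)),
       len = rep(1L, length(mm)),
       read_base = intToUtf8(x[mm], multiple = TRUE),
       ref_base = intToUtf8(y[mm], multiple = TRUE))
}

## ---- ingest --------------------------------------------------------------

#' Ingest alignments from SAM/BAM and extract mutation events
#'
#' Reads a SAM or BAM file (via Rsamtools/GenomicAlignments), skips
#' unmapped records, and extracts per-read mutation events: deletions and
#' insertions from the CIGAR, substitutions by base-wise comparison of the
#' reference-space read sequence against the genome. Records whose CIGAR
#' and sequence lengths disagree are rejected with a message. The result is
#' sorted canonically (reference, position, name), so ingestion is
#' invariant to record order.
#'
#' UMI and collapse multiplicity are recovered from read names following
#' the collapsed-FASTA dialect `serial_UMI_xN` when present.
#'
#' @param path SAM or BAM file.
#' @param genome named DNAStringSet (for substitution calling).
#' @param sample sample label.
#' @return a `crac_alignments`; skipped-record counts in attributes
#'   `n_unmapped` and `n_rejected`.
#' @export
ingest_alignments <- function(path, genome, sample = "S1") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq")
  )
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_all <- length(b$qname)
  unmapped <- bitwAnd(b$flag, 4L) > 0L
  keep <- !unmapped
  qw <- rep(NA_integer_, n_all)
  qw[keep] <- GenomicAlignments::cigarWidthAlongQuerySpace(b$cigar[keep])
  bad <- keep & qw != Biostrings::width(b$seq)
  if (any(bad, na.rm = TRUE)) {
    message(sum(bad, na.rm = TRUE), " records rejected (CIGAR/seq mismatch)")
  }
  keep <- keep & !bad
  df <- data.frame(
    qname = b$qname[keep],
    rname = as.character(b$rname[keep]),
    pos = b$pos[keep],
    strand = as.character(b$strand[keep]),
    cigar = b$cigar[keep],
    stringsAsFactors = FALSE
  )
  seqs <- as.character(b$seq[keep])

  # collapsed-header dialect: {serial}_{umi}_x{multiplicity}
  mt <- regmatches(df$qname,
                   regexec("_([ACGTN]+)_x([0-9]+)$", df$qname))
  df$umi <- vapply(mt, function(m) if (length(m) == 3) m[2] else "",
                   character(1))
  df$mult <- vapply(mt, function(m) if (length(m) == 3) as.integer(m[3]) else 1L,
                    integer(1))
  df$sample <- sample
  df$n_hits <- 1L
  df$seq_ref <- seqs

  ord <- order(df$rname, df$pos, df$qname, df$cigar)
  df <- df[ord, , drop = FALSE]
  seqs <- seqs[ord]
  rownames(df) <- NULL

  mut <- extract_mutations(df, seqs, genome)
  res <- new_alignments(
    df[, c("qname", "rname", "pos", "strand", "cigar", "mult", "umi",
           "sample", "n_hits", "seq_ref")],
    mut
  )
  attr(res, "n_unmapped") <- sum(unmapped)
  attr(res, "n_rejected") <- sum(bad, na.rm = TRUE)
  res
}

## CIGAR + sequence -> mutation events, vectorized where it counts
extract_mutations <- function(df, seqs, genome) {
  n <- nrow(df)
  if (n == 0) return(empty_mutation_df())
  chars <- genome_chars(genome)

  cig <- df$cigar
  # deletions: reference-space ranges of D ops
  dr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = "D", pos = df$pos)
  nd <- S4Vectors::elementNROWS(dr)
  del_i <- rep.int(seq_len(n), nd)
  drf <- unlist(dr)
  del <- if (length(del_i) > 0) {
    dstart <- IRanges::start(drf); dwidth <- IRanges::width(drf)
    refb <- substring(chars[df$rname[del_i]], dstart, dstart + dwidth - 1L)
    data.frame(qname = df$qname[del_i], rname = df$rname[del_i],
               ref_pos = dstart, strand = df$strand[del_i], kind = "del",
               len = dwidth, read_base = "", ref_base = refb,
               stringsAsFactors = FALSE)
  } else empty_mutation_df()

  # insertions: query-space ranges of I ops, anchored at preceding ref base
  ir_ref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = "I", pos = df$pos)
  ir_q <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "I")
  ni <- S4Vectors::elementNROWS(ir_ref)
  ins_i <- rep.int(seq_len(n), ni)
  ins <- if (length(ins_i) > 0) {
    irf <- unlist(ir_ref); iqf <- unlist(ir_q)
    rb <- substring(seqs[ins_i], IRanges::start(iqf), IRanges::end(iqf))
    data.frame(qname = df$qname[ins_i], rname = df$rname[ins_i],
               ref_pos = IRanges::start(irf) - 1L, strand = df$strand[ins_i],
               kind = "ins", len = IRanges::width(iqf), read_base = rb,
               ref_base = "", stringsAsFactors = FALSE)
  } else empty_mutation_df()

  # substitutions: lay the read into reference space, compare to genome
  lay <- as.character(GenomicAlignments::sequenceLayer(
    Biostrings::DNAStringSet(seqs), cig, from = "query", to = "reference"))
  refw <- nchar(lay)
  gref <- substring(chars[df$rname], df$pos, df$pos + refw - 1L)
  subs <- sub_events(df, lay, gref)

  out <- rbind(del, ins, subs)
  out <- out[order(out$rname, out$ref_pos, out$qname), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sub_events <- function(df, lay, gref) {
  n <- nrow(df)
  res <- vector("list", n)
  differs <- lay != gref
  for (i in which(differs)) {
    x <- utf8ToInt(lay[i]); y <- utf8ToInt(gref[i])
    mm <- which(x != y & x != utf8ToInt("-") & x != utf8ToInt("N"))
    if (length(mm) == 0) next
    res[[i]] <- data.frame(
      qname = df$qname[i], rname = df$rname[i],
      ref_pos = df$pos[i] + mm - 1L, strand = df$strand[i], kind = "sub",
      len = 1L, read_base = intToUtf8(x[mm], multiple = TRUE),
      ref_base = intToUtf8(y[mm], multiple = TRUE),
      stringsAsFactors = FALSE
    )
  }
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) return(empty_mutation_df())
  do.call(rbind, c(res[keep], list(make.row.names = FALSE)))
}
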