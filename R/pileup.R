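#' Per-nucleotide read/substitution/deletion pileup over a feature
#'
#' For one annotated feature, counts at every nucleotide: the number of
#' alignments covering the position (M and D CIGAR operations both count as
#' coverage, so the deleted base is "covered" by its read and deletion
#' fractions are bounded by 1), the number of substitution events, and the
#' number of single-nucleotide deletion events. Deletions of length >= 2
#' are tallied per deleted base in a side channel (`dels_multi`) and
#' excluded from the headline `dels` array, which is the micro-deletion
#' crosslink statistic. Antisense alignments are excluded.
#'
#' Arrays are reported in the feature's 5' to 3' orientation; position 1 is
#' the feature's first transcribed base.
#'
#' @param aln a `crac_alignments`.
#' @param feature list or one-row data.frame with `chrom` (or `rname`),
#'   `start`, `end`, `strand` and optionally `tx_id`/`id`.
#' @param meta optional list of sample/condition/replicate labels.
#' @return object of class `crac_track` with integer arrays `reads`,
#'   `subs`, `dels`, `dels_multi`.
#' @export
pileup_feature <- function(aln, feature, meta = list()) {
  ft <- as.list(feature)
  chrom <- if (!is.null(ft$chrom)) ft$chrom else ft$rname
  fstart <- as.integer(if (!is.null(ft$start)) ft$start else ft$tx_start)
  fend <- as.integer(if (!is.null(ft$end)) ft$end else ft$tx_end)
  fstrand <- as.character(ft$strand)
  fid <- if (!is.null(ft$tx_id)) ft$tx_id else
    if (!is.null(ft$id)) ft$id else "feature"
  flen <- fend - fstart + 1L
  stopifnot(flen >= 1L)

  a <- aln$alignments
  sel <- a$rname == chrom & a$strand == fstrand
  a <- a[sel, , drop = FALSE]

  reads <- integer(flen)
  if (nrow(a) > 0) {
    rw <- cigar_ref_width(a$cigar)
    ir <- IRanges::IRanges(a$pos, a$pos + rw - 1L)
    ir <- IRanges::restrict(ir, start = fstart, end = fend)
    ir <- ir[IRanges::width(ir) > 0]
    if (length(ir) > 0) {
      cov <- IRanges::coverage(IRanges::shift(ir, -(fstart - 1L)),
                               width = flen)
      reads <- as.integer(cov)
    }
  }

  m <- aln$mutations
  m <- m[m$rname == chrom & m$strand == fstrand, , drop = FALSE]
  count_at <- function(pos, weight = NULL) {
    keep <- pos >= fstart & pos <= fend
    tabulate(pos[keep] - fstart + 1L, nbins = flen)
  }
  subs <- count_at(m$ref_pos[m$kind == "sub"])
  dels <- count_at(m$ref_pos[m$kind == "del" & m$len == 1L])
  multi <- m[m$kind == "del" & m$len > 1L, , drop = FALSE]
  dels_multi <- integer(flen)
  if (nrow(multi) > 0) {
    per_base <- unlist(Map(function(p, l) p:(p + l - 1L),
                           multi$ref_pos, multi$len))
    dels_multi <- count_at(per_base)
  }

  if (fstrand == "-") {
    reads <- rev(reads); subs <- rev(subs); dels <- rev(dels)
    dels_multi <- rev(dels_multi)
  }

  structure(
    list(feature_id = fid, chrom = chrom, start = fstart, end = fend,
         strand = fstrand, length = flen,
         reads = reads, subs = subs, dels = dels, dels_multi = dels_multi,
         meta = meta, normalized = FALSE),
    class = "crac_track"
  )
}

#' @export
print.crac_track <- function(x, ...) {
  cat(sprintf("crac_track %s (%s:%d-%d%s, %d nt)%s\n", x$feature_id,
              x$chrom, x$start, x$end, x$strand, x$length,
              if (x$normalized) " [normalized]" else ""))
  cat(sprintf("  reads %d, subs %d, dels %d (multi-nt del bases %d)\n",
              sum(x$reads), sum(x$subs), sum(x$dels), sum(x$dels_multi)))
  invisible(x)
}

#' Sum pileup tracks from library size fractions
#'
#' Samples processed as separate size fractions are combined by elementwise
#' summation of the raw counts before normalization.
#'
#' @param tracks list of `crac_track`s over the same feature.
#' @return combined `crac_track`.
#' @export
combine_fractions <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  out <- tracks[[1]]
  stopifnot(!out$normalized)
  for (t in tracks[-1]) {
    if (t$length != out$length || t$feature_id != out$feature_id) {
      stop("cannot combine tracks of different features/lengths")
    }
    stopifnot(!t$normalized)
    out$reads <- out$reads + t$reads
    out$subs <- out$subs + t$subs
    out$dels <- out$dels + t$dels
    out$dels_multi <- out$dels_multi + t$dels_multi
  }
  out
}

#' Normalize a pileup track to unit sums
#'
#' Each of the reads/subs/dels arrays is divided by its own total so that
#' the sum of all values is 1, making samples of different depth
#' comparable. All-zero arrays stay zero and are flagged. Raw counts are
#' retained alongside (site calling uses the per-position deletion fraction
#' of coverage, which needs them).
#'
#' @param track a raw `crac_track`.
#' @return the track with `norm_reads`, `norm_subs`, `norm_dels` added and
#'   `normalized = TRUE`; `zero_arrays` lists arrays that had no signal.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "crac_track"))
  if (sum(track$reads) == 0 && sum(track$subs) == 0 && sum(track$dels) == 0) {
    stop("nothing to normalize: all arrays are zero")
  }
  norm1 <- function(v) if (sum(v) > 0) v / sum(v) else as.numeric(v)
  track$norm_reads <- norm1(track$reads)
  track$norm_subs <- norm1(track$subs)
  track$norm_dels <- norm1(track$dels)
  track$zero_arrays <- c("reads", "subs", "dels")[
    c(sum(track$reads) == 0, sum(track$subs) == 0, sum(track$dels) == 0)]
  track$normalized <- TRUE
  track
}

#' Elementwise min/mean/max across replicate normalized tracks
#'
#' @param tracks list of normalized `crac_track`s over the same feature.
#' @param what which array to summarize ("reads", "subs" or "dels").
#' @return data.frame with position (1-based), min, mean, max.
#' @export
replicate_envelope <- function(tracks, what = c("dels", "reads", "subs")) {
  what <- match.arg(what)
  stopifnot(all(vapply(tracks, function(t) isTRUE(t$normalized), logical(1))))
  m <- do.call(cbind, lapply(tracks, function(t) t[[paste0("norm_", what)]]))
  data.frame(position = seq_len(nrow(m)),
             min = apply(m, 1, min), mean = rowMeans(m),
             max = apply(m, 1, max))
}

#' Write a pileup track as TSV
#'
#' Columns: 1-based position within the feature, raw reads/subs/dels and,
#' when the track is normalized, the unit-sum columns.
#'
#' @param track a `crac_track`.
#' @param path output file.
#' @export
write_track_tsv <- function(track, path) {
  df <- data.frame(position = seq_len(track$length),
                   reads = track$reads, subs = track$subs, dels = track$dels,
                   dels_multi = track$dels_multi)
  if (isTRUE(track$normalized)) {
    df$norm_reads <- track$norm_reads
    df$norm_subs <- track$norm_subs
    df$norm_dels <- track$norm_dels
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
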