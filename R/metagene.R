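## ---- hittables -----------------------------------------------------------

#' Count reads per feature and per RNA class (hittable)
#'
#' A read counts toward the feature containing its leftmost aligned base
#' on the matching strand; when features are nested (an rRNA sub-feature
#' inside the operon) the smallest containing feature wins. Reads landing
#' in no feature go to the "unannotated" bucket. Counts are produced from
#' collapsed data (one per unique molecule) or raw data (weighted by the
#' collapse multiplicity).
#'
#' @param aln a `crac_alignments`.
#' @param txome a `crac_transcriptome` (or its `transcripts` data.frame).
#' @param mode "collapsed" (weight 1) or "raw" (weight = multiplicity).
#' @return list of class `crac_hittable`: `features` (tx_id, rna_class,
#'   count), `classes` (rna_class, count), `total` (library total),
#'   `unannotated`.
#' @export
make_hittable <- function(aln, txome, mode = c("collapsed", "raw")) {
  mode <- match.arg(mode)
  tr <- if (inherits(txome, "crac_transcriptome")) txome$transcripts else txome
  a <- aln$alignments
  w <- if (mode == "raw") a$mult else rep(1L, nrow(a))

  counts <- setNames(numeric(nrow(tr)), tr$tx_id)
  unann <- 0
  if (nrow(a) > 0) {
    pts <- GenomicRanges::GRanges(a$rname, IRanges::IRanges(a$pos, a$pos),
                                  strand = a$strand)
    fts <- GenomicRanges::GRanges(tr$chrom,
                                  IRanges::IRanges(tr$tx_start, tr$tx_end),
                                  strand = tr$strand)
    ov <- GenomicRanges::findOverlaps(pts, fts)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh) > 0) {
      # smallest containing feature wins
      wdt <- tr$tx_end[sh] - tr$tx_start[sh]
      ord <- order(qh, wdt)
      qh <- qh[ord]; sh <- sh[ord]
      first <- !duplicated(qh)
      qh <- qh[first]; sh <- sh[first]
      add <- rowsum(w[qh], tr$tx_id[sh])
      counts[rownames(add)] <- counts[rownames(add)] + add[, 1]
    }
    unann <- sum(w) - sum(counts)
  }
  features <- data.frame(tx_id = tr$tx_id, rna_class = tr$rna_class,
                         count = unname(counts), stringsAsFactors = FALSE)
  cls <- rowsum(features$count, features$rna_class)
  classes <- data.frame(rna_class = rownames(cls), count = cls[, 1],
                        stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  structure(list(features = features, classes = classes,
                 total = sum(w), unannotated = unann, mode = mode),
            class = "crac_hittable")
}

#' Per-class fold enrichment of a sample over a control hittable
#'
#' fold(class) = (sample class reads / sample total) /
#' (control class reads / control total). Classes absent from the control
#' get an infinite fold and a flag.
#'
#' @param sample,control `crac_hittable`s.
#' @return data.frame with rna_class, sample_frac, control_frac, fold,
#'   flag.
#' @export
class_enrichment <- function(sample, control) {
  stopifnot(sample$total > 0, control$total > 0)
  cls <- union(sample$classes$rna_class, control$classes$rna_class)
  sf <- setNames(rep(0, length(cls)), cls)
  cf <- sf
  sf[sample$classes$rna_class] <- sample$classes$count / sample$total
  cf[control$classes$rna_class] <- control$classes$count / control$total
  fold <- ifelse(cf > 0, sf / cf, ifelse(sf > 0, Inf, NA_real_))
  data.frame(rna_class = cls, sample_frac = unname(sf),
             control_frac = unname(cf), fold = unname(fold),
             flag = ifelse(cf == 0 & sf > 0, "zero_control", ""),
             stringsAsFactors = FALSE)
}

## ---- genome-wide signal tracks -------------------------------------------

#' Build per-strand genome signal tracks (reads or deletions)
#'
#' In "reads" mode every reference position covered by an alignment (M or
#' D operation) is incremented; in "deletions" mode only positions of
#' single-nucleotide deletion events are counted. Plus- and minus-strand
#' tracks are kept separately and a non-strand-specific view is their sum,
#' mirroring the bedgraph-to-merged-wig track construction used for
#' metagene input.
#'
#' @param aln a `crac_alignments`.
#' @param genome named DNAStringSet (defines chromosome lengths).
#' @param count "reads" or "deletions".
#' @param weight "collapsed" (1 per alignment) or "raw" (multiplicity).
#' @return list of class `crac_signal` with `plus`, `minus`, `merged`:
#'   each a named list of numeric vectors per chromosome.
#' @export
build_tracks <- function(aln, genome, count = c("reads", "deletions"),
                         weight = c("collapsed", "raw")) {
  count <- match.arg(count)
  weight <- match.arg(weight)
  lens <- chrom_lengths(genome)
  a <- aln$alignments
  w <- if (weight == "raw") a$mult else rep(1L, max(nrow(a), 0L))

  zero <- lapply(lens, function(L) numeric(L))
  plus <- zero; minus <- zero

  if (count == "reads" && nrow(a) > 0) {
    rw <- cigar_ref_width(a$cigar)
    for (str in c("+", "-")) {
      sel <- a$strand == str
      for (cc in unique(a$rname[sel])) {
        s2 <- sel & a$rname == cc
        ir <- IRanges::IRanges(a$pos[s2],
                               pmin(a$pos[s2] + rw[s2] - 1L, lens[[cc]]))
        cov <- IRanges::coverage(ir, weight = as.numeric(w[s2]),
                                 width = lens[[cc]])
        v <- as.numeric(cov)
        if (str == "+") plus[[cc]] <- plus[[cc]] + v else
          minus[[cc]] <- minus[[cc]] + v
      }
    }
  } else if (count == "deletions") {
    m <- aln$mutations
    m <- m[m$kind == "del" & m$len == 1L, , drop = FALSE]
    if (nrow(m) > 0) {
      wm <- if (weight == "raw") {
        a$mult[match(m$qname, a$qname)]
      } else rep(1L, nrow(m))
      for (str in c("+", "-")) {
        sel <- m$strand == str
        for (cc in unique(m$rname[sel])) {
          s2 <- sel & m$rname == cc
          v <- numeric(lens[[cc]])
          tab <- rowsum(as.numeric(wm[s2]), m$ref_pos[s2])
          v[as.integer(rownames(tab))] <- tab[, 1]
          if (str == "+") plus[[cc]] <- plus[[cc]] + v else
            minus[[cc]] <- minus[[cc]] + v
        }
      }
    }
  }
  merged <- Map(`+`, plus, minus)
  structure(list(plus = plus, minus = minus, merged = merged,
                 count = count),
            class = "crac_signal")
}

#' Export a signal track as bedGraph
#'
#' Standard 4-column bedGraph (0-based half-open intervals); zero runs are
#' omitted. One file per requested strand view.
#'
#' @param signal a `crac_signal`.
#' @param path output file.
#' @param view "plus", "minus" or "merged".
#' @export
export_bedgraph <- function(signal, path, view = c("merged", "plus", "minus")) {
  view <- match.arg(view)
  vecs <- signal[[view]]
  chroms <- character(0); starts <- integer(0); ends <- integer(0)
  scores <- numeric(0)
  for (cc in names(vecs)) {
    r <- S4Vectors::Rle(vecs[[cc]])
    v <- S4Vectors::runValue(r)
    keep <- v != 0
    if (!any(keep)) next
    st <- cumsum(c(1L, S4Vectors::runLength(r)))
    s0 <- st[-length(st)][keep]
    chroms <- c(chroms, rep(cc, sum(keep)))
    starts <- c(starts, s0)
    ends <- c(ends, s0 + S4Vectors::runLength(r)[keep] - 1L)
    scores <- c(scores, v[keep])
  }
  gr <- GenomicRanges::GRanges(
    factor(chroms, levels = names(vecs)),
    IRanges::IRanges(starts, ends), score = scores,
    seqlengths = vapply(vecs, length, integer(1)))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

## ---- metagene matrices ---------------------------------------------------

new_metagene <- function(values, anchor, bin, segments, offsets = NULL) {
  structure(list(values = values, anchor = anchor, bin = bin,
                 segments = segments, offsets = offsets),
            class = "crac_metagene")
}

#' @export
print.crac_metagene <- function(x, ...) {
  cat(sprintf("crac_metagene: %d genes x %d bins (anchor %s, bin %d nt)\n",
              nrow(x$values), ncol(x$values), x$anchor, x$bin))
  invisible(x)
}

## anchor coordinate per gene (genomic, 1-based); "position 0" of the row
anchor_coord <- function(tr, anchor) {
  plus <- tr$strand == "+"
  switch(anchor,
    start = ifelse(plus, tr$cds_start, tr$cds_end),
    stop = ifelse(plus, tr$cds_end - 2L, tr$cds_start + 2L),
    TSS = ifelse(plus, tr$tx_start, tr$tx_end),
    pA = ifelse(plus, tr$tx_end, tr$tx_start),
    stop("unknown anchor")
  )
}

#' Reference-point metagene matrix
#'
#' One row per gene: the merged (non-strand-specific) signal in a window
#' around an anchor (start codon, first base of the stop codon, TSS or pA
#' site), strand-aware so that "upstream" is 5' of the anchor on the
#' coding strand. Bin j covers offsets `[-upstream + (j-1)*bin,
#' -upstream + j*bin)` relative to the anchor. Positions outside the
#' chromosome are missing values (excluded from aggregation, not
#' zero-filled).
#'
#' @param signal a `crac_signal` (its merged view is used).
#' @param txome transcriptome (genes with CDS where the anchor needs one).
#' @param anchor "start", "stop", "TSS" or "pA".
#' @param upstream,downstream window, nt; multiples of `bin`.
#' @param bin bin size (1 or 10 nt typically).
#' @param genes optional character vector restricting/ordering the rows.
#' @return a `crac_metagene`.
#' @export
reference_point_matrix <- function(signal, txome, anchor = "stop",
                                   upstream = 100, downstream = 100,
                                   bin = 1, genes = NULL) {
  stopifnot(upstream %% bin == 0, downstream %% bin == 0)
  tr <- txome$transcripts
  if (!is.null(genes)) tr <- tr[match(genes, tr$tx_id), , drop = FALSE]
  if (anchor %in% c("start", "stop")) tr <- tr[!is.na(tr$cds_start), ,
                                               drop = FALSE]
  anc <- anchor_coord(tr, anchor)
  nb <- (upstream + downstream) %/% bin
  vals <- matrix(NA_real_, nrow = nrow(tr), ncol = nb,
                 dimnames = list(tr$tx_id, NULL))
  for (i in seq_len(nrow(tr))) {
    v <- signal$merged[[tr$chrom[i]]]
    L <- length(v)
    if (tr$strand[i] == "+") {
      gpos <- (anc[i] - upstream):(anc[i] + downstream - 1L)
    } else {
      gpos <- (anc[i] + upstream):(anc[i] - downstream + 1L)
    }
    row <- rep(NA_real_, length(gpos))
    ok <- gpos >= 1L & gpos <= L
    row[ok] <- v[gpos[ok]]
    if (bin == 1) {
      vals[i, ] <- row
    } else {
      g <- rep(seq_len(nb), each = bin)
      vals[i, ] <- as.numeric(tapply(row, g, function(z) {
        if (all(is.na(z))) NA_real_ else sum(z, na.rm = TRUE)
      }))
    }
  }
  new_metagene(vals, anchor, bin,
               segments = c(up = upstream %/% bin, u5 = 0L, body = 0L,
                            u3 = 0L, down = downstream %/% bin),
               offsets = seq(-upstream, downstream - bin, by = bin))
}

## fractional-boundary rebinning of a numeric vector into nb equal bins
scale_into_bins <- function(v, nb) {
  L <- length(v)
  cs <- c(0, cumsum(v))
  q <- seq(0, L, length.out = nb + 1)
  interp <- function(x) {
    f <- floor(x)
    r <- x - f
    cs[f + 1] + if (f < L) r * v[f + 1] else 0
  }
  ends <- vapply(q, interp, numeric(1))
  diff(ends)
}

#' Scaled-region metagene matrix (120 bins)
#'
#' mRNAs are aligned on their coding region and scaled between start codon
#' + `u5` nt and stop codon - `u3` nt: each row consists of `b/bin` bins
#' upstream of the start codon, `u5/bin` unscaled 5' bins, `body_bins`
#' scaled body bins (linear coordinate interpolation with fractional bin
#' edges), `u3/bin` unscaled 3' bins ending at the stop codon, and `a/bin`
#' bins downstream. With the default parameters (b=100, a=250, u5=250,
#' u3=100, 50 body bins, 10-nt bins) every row has
#' 10+25+50+10+25 = 120 bins.
#'
#' Genes whose CDS is not longer than `u5 + u3` cannot be scaled; they are
#' excluded and reported via `attr(, "excluded")`.
#'
#' @param signal a `crac_signal`.
#' @param txome transcriptome.
#' @param b,a upstream/downstream flank, nt.
#' @param u5,u3 unscaled 5'/3' region lengths, nt.
#' @param body_bins number of scaled body bins.
#' @param bin bin size, nt.
#' @param genes optional gene subset.
#' @return a `crac_metagene` with 120 columns under the defaults.
#' @export
scaled_region_matrix <- function(signal, txome, b = 100, a = 250, u5 = 250,
                                 u3 = 100, body_bins = 50, bin = 10,
                                 genes = NULL) {
  stopifnot(b %% bin == 0, a %% bin == 0, u5 %% bin == 0, u3 %% bin == 0)
  tr <- txome$transcripts
  tr <- tr[!is.na(tr$cds_start), , drop = FALSE]
  if (!is.null(genes)) tr <- tr[tr$tx_id %in% genes, , drop = FALSE]
  cds_len <- tr$cds_end - tr$cds_start + 1L
  excluded <- tr$tx_id[cds_len <= u5 + u3]
  tr <- tr[cds_len > u5 + u3, , drop = FALSE]
  if (nrow(tr) == 0) stop("all genes excluded: no CDS longer than u5 + u3")

  nb <- (b + u5) %/% bin + body_bins + (u3 + a) %/% bin
  vals <- matrix(NA_real_, nrow = nrow(tr), ncol = nb,
                 dimnames = list(tr$tx_id, NULL))
  for (i in seq_len(nrow(tr))) {
    v <- signal$merged[[tr$chrom[i]]]
    L <- length(v)
    plus <- tr$strand[i] == "+"
    if (plus) {
      gpos <- (tr$cds_start[i] - b):(tr$cds_end[i] + a)
    } else {
      gpos <- (tr$cds_end[i] + b):(tr$cds_start[i] - a)
    }
    row <- rep(0, length(gpos))
    ok <- gpos >= 1L & gpos <= L
    row[ok] <- v[gpos[ok]]
    na_mask <- !ok
    # segment boundaries along the oriented row
    n_flank5 <- b; n_u5 <- u5
    cds_n <- tr$cds_end[i] - tr$cds_start[i] + 1L
    seg_u5 <- row[(n_flank5 + 1):(n_flank5 + u5)]
    seg_body <- row[(n_flank5 + u5 + 1):(n_flank5 + cds_n - u3)]
    seg_u3 <- row[(n_flank5 + cds_n - u3 + 1):(n_flank5 + cds_n)]
    seg_up <- row[1:n_flank5]
    seg_down <- row[(n_flank5 + cds_n + 1):(n_flank5 + cds_n + a)]
    bin_sums <- function(z) as.numeric(rowsum(z, rep(seq_len(length(z) %/% bin),
                                                     each = bin)))
    vals[i, ] <- c(bin_sums(seg_up), bin_sums(seg_u5),
                   scale_into_bins(seg_body, body_bins),
                   bin_sums(seg_u3), bin_sums(seg_down))
    if (any(na_mask)) {
      # flanks beyond the chromosome: mark affected flank bins missing
      up_na <- na_mask[1:n_flank5]
      dn_na <- na_mask[(n_flank5 + cds_n + 1):(n_flank5 + cds_n + a)]
      if (any(up_na)) {
        bad <- unique(ceiling(which(up_na) / bin))
        vals[i, bad] <- NA_real_
      }
      if (any(dn_na)) {
        bad <- unique((b + u5) %/% bin + body_bins + u3 %/% bin +
                        ceiling(which(dn_na) / bin))
        vals[i, bad] <- NA_real_
      }
    }
  }
  out <- new_metagene(vals, "scaled-region", bin,
                      segments = c(up = b %/% bin, u5 = u5 %/% bin,
                                   body = body_bins, u3 = u3 %/% bin,
                                   down = a %/% bin))
  attr(out, "excluded") <- excluded
  out
}

## ---- normalization and aggregation ---------------------------------------

#' Normalize metagene matrices and aggregate to per-sample profiles
#'
#' Implements the two normalization contracts used for scaled metagene
#' plots. For each data set, every gene's row is divided by that gene's
#' total signal over the matrix, rows are summed into one profile, then:
#' \describe{
#'   \item{wt_ratio}{each profile is multiplied by the ratio of the data
#'     set's total read signal (over the shared gene set) to the wild-type
#'     data set's total, and all profiles are divided by the wild-type
#'     area so the wild-type area under the curve is exactly 1;}
#'   \item{auc1}{each profile's own area under the curve is set to 1.}
#' }
#' Genes with zero total in a data set are dropped from that data set (and
#' reported); missing bins are excluded from sums.
#'
#' @param mats named list of `crac_metagene`s over the same gene set and
#'   bin structure, one per data set.
#' @param wt name of the wild-type data set in `mats`.
#' @param mode "wt_ratio" or "auc1".
#' @return named list of numeric profiles (class `crac_profiles`), with
#'   the bin structure in `attr(, "segments")` and per-data-set dropped
#'   genes in `attr(, "dropped")`.
#' @export
normalize_and_aggregate <- function(mats, wt, mode = c("wt_ratio", "auc1")) {
  mode <- match.arg(mode)
  stopifnot(wt %in% names(mats))
  seg <- mats[[1]]$segments
  nb <- ncol(mats[[1]]$values)
  stopifnot(all(vapply(mats, function(m) ncol(m$values) == nb, logical(1))))

  dropped <- list()
  totals <- numeric(length(mats)); names(totals) <- names(mats)
  profiles <- list()
  for (nm in names(mats)) {
    v <- mats[[nm]]$values
    gt <- rowSums(v, na.rm = TRUE)
    drop <- gt == 0
    dropped[[nm]] <- rownames(v)[drop]
    v <- v[!drop, , drop = FALSE]
    gt <- gt[!drop]
    totals[nm] <- sum(gt)
    profiles[[nm]] <- colSums(v / gt, na.rm = TRUE)
  }

  if (mode == "wt_ratio") {
    ratio <- totals / totals[[wt]]
    profiles <- Map(function(p, r) p * r, profiles, as.list(ratio))
    wt_area <- sum(profiles[[wt]])
    profiles <- lapply(profiles, function(p) p / wt_area)
  } else {
    profiles <- lapply(profiles, function(p) p / sum(p))
  }
  structure(profiles, class = "crac_profiles", segments = seg,
            bin = mats[[1]]$bin, dropped = dropped)
}

#' Median profile across replicate data sets
#'
#' Aggregate profiles of the same strain are summarized bin-wise by the
#' median ("plots represent medians of normalized, scaled data").
#'
#' @param profiles list of numeric profiles (same length).
#' @return numeric median profile.
#' @export
aggregate_profiles <- function(profiles) {
  m <- do.call(rbind, profiles)
  apply(m, 2, median)
}

#' Rolling-average smoothing of a profile
#'
#' Centered rolling mean of odd `window`; edges use shrinking windows
#' (the simple mean of the available points).
#'
#' @param profile numeric vector.
#' @param window odd window width (default 9, the 9-nt rolling average
#'   used for 1-nt deletion metagenes).
#' @return smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(profile, window = 9) {
  stopifnot(window %% 2 == 1)
  n <- length(profile)
  if (window > n) stop("window longer than profile")
  h <- (window - 1) %/% 2
  cs <- c(0, cumsum(profile))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Six-bin region sums around the start and stop codons
#'
#' From a 10-nt-binned scaled-region profile, sums the read density over
#' three diagnostic windows, each exactly 6 bins: after the start codon
#' (first 60 nt of the CDS), before the stop codon (-90 to -30 nt) and
#' after the stop codon (+50 to +110 nt).
#'
#' @param profile numeric profile from [normalize_and_aggregate()] (or any
#'   vector with the same structure).
#' @param segments bin structure `c(up, u5, body, u3, down)` in bins; taken
#'   from the profile attribute when present.
#' @param bin bin size, must be 10.
#' @return named numeric vector: after_start, before_stop, after_stop.
#' @export
region_sums <- function(profile, segments = attr(profile, "segments"),
                        bin = attr(profile, "bin")) {
  if (is.null(bin)) bin <- 10
  stopifnot(bin == 10, !is.null(segments))
  p <- as.numeric(profile)
  up <- segments[["up"]]; u5 <- segments[["u5"]]
  body <- segments[["body"]]; u3 <- segments[["u3"]]
  down <- segments[["down"]]
  if (u5 < 6 || u3 < 10 || down < 11) {
    stop("profile lacks the span required for the 6-bin windows")
  }
  start_bin <- up            # last bin before the start codon
  stop_bin <- up + u5 + body + u3   # last bin before the stop-codon end
  after_start <- sum(p[(start_bin + 1):(start_bin + 6)])
  before_stop <- sum(p[(stop_bin - 8):(stop_bin - 3)])   # [-90,-30)
  after_stop <- sum(p[(stop_bin + 6):(stop_bin + 11)])   # [+50,+110)
  c(after_start = after_start, before_stop = before_stop,
    after_stop = after_stop)
}

## ---- top-bound gene selection --------------------------------------------

#' Select reproducibly top-bound transcripts
#'
#' Genes are ranked within each replicate by binding density in hits per
#' million per kilobase; "reproducible" membership means appearing in the
#' top `top_n` of every replicate. The intersection is then filtered to
#' transcripts of at least `min_tx_len` nt.
#'
#' @param hittables list of `crac_hittable`s (>= 2 replicates).
#' @param txome transcriptome (for transcript lengths).
#' @param top_n per-replicate rank cutoff.
#' @param min_tx_len minimum transcript length, nt.
#' @return character vector of selected tx_ids (density-ordered by the
#'   first replicate).
#' @export
select_top_bound <- function(hittables, txome, top_n = 300,
                             min_tx_len = 500) {
  stopifnot(length(hittables) >= 2)
  tr <- if (inherits(txome, "crac_transcriptome")) txome$transcripts else txome
  lens <- setNames(tr$tx_len, tr$tx_id)
  tops <- lapply(hittables, function(h) {
    f <- h$features
    dens <- f$count / (lens[f$tx_id] / 1000) / (h$total / 1e6)
    ord <- order(-dens, f$tx_id)
    n_eff <- min(top_n, sum(f$count > 0))
    if (n_eff < top_n) {
      warning("fewer than top_n bound genes in a replicate; using all ",
              n_eff)
    }
    f$tx_id[ord][seq_len(n_eff)]
  })
  sel <- Reduce(intersect, tops)
  sel <- sel[lens[sel] >= min_tx_len]
  sel[order(match(sel, tops[[1]]))]
}
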