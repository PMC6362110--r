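#' Library simulation configuration
#'
#' Bundles the parameters of one simulated CRAC sequencing library. Defaults
#' describe a footprint-scale library: triangular fragment lengths
#' (20, 35, 60) nt after RNase digestion, 100-cycle reads, an 8-nt in-line
#' barcode whose first three positions are random nucleotides (the UMI),
#' geometric PCR duplication with mean multiplicity 3, and low uniform
#' background error rates.
#'
#' @param n_fragments number of independent cDNA fragments (duplicate
#'   groups) to generate.
#' @param fragment_len (min, mode, max) of the triangular fragment-length
#'   distribution, nt.
#' @param read_len sequencing read length (cycles).
#' @param barcode_template 5' in-line barcode; `N` marks random (UMI)
#'   positions.
#' @param adapter 3' sequencing adapter appended after the insert.
#' @param pcr_dup_p geometric parameter: multiplicity ~ 1 + Geom(p), mean
#'   1/p. `pcr_dup_p = 1/3` gives mean multiplicity 3.
#' @param bg_del_rate,bg_sub_rate per-base background single-nt deletion /
#'   substitution probabilities (reverse transcription / PCR / sequencing
#'   noise).
#' @param polyA_frac fraction of pA-spanning fragments receiving a
#'   non-templated oligo(A) tail.
#' @param tail_len (min, max) tail length, uniform, nt.
#' @param occupancy positional occupancy profile for fragment centers:
#'   `"uniform"` or `"hel2like"` (start-proximal depletion, strong
#'   stop-flanking windows, a 30-nt valley over the stop codon).
#' @param seed integer seed for this library's RNG stream.
#' @return list of class `crac_libconfig`.
#' @export
library_config <- function(n_fragments = 10000,
                           fragment_len = c(20, 35, 60),
                           read_len = 100,
                           barcode_template = "NNNTAAGC",
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           pcr_dup_p = 1 / 3,
                           bg_del_rate = 0.005,
                           bg_sub_rate = 0.005,
                           polyA_frac = 0.6,
                           tail_len = c(5, 15),
                           occupancy = c("uniform", "hel2like"),
                           seed = 1) {
  occupancy <- match.arg(occupancy)
  stopifnot(
    n_fragments >= 0,
    length(fragment_len) == 3, all(diff(fragment_len) >= 0),
    read_len >= nchar(barcode_template) + 17,
    pcr_dup_p > 0, pcr_dup_p <= 1,
    bg_del_rate >= 0, bg_del_rate <= 1,
    bg_sub_rate >= 0, bg_sub_rate <= 1,
    polyA_frac >= 0, polyA_frac <= 1,
    length(tail_len) == 2, tail_len[1] <= tail_len[2]
  )
  if (read_len < nchar(barcode_template) + fragment_len[3] + tail_len[2]) {
    warning("read_len may truncate the longest tailed fragments")
  }
  structure(
    list(n_fragments = as.integer(n_fragments), fragment_len = fragment_len,
         read_len = as.integer(read_len),
         barcode_template = barcode_template, adapter = adapter,
         pcr_dup_p = pcr_dup_p, bg_del_rate = bg_del_rate,
         bg_sub_rate = bg_sub_rate, polyA_frac = polyA_frac,
         tail_len = as.integer(tail_len), occupancy = occupancy,
         seed = as.integer(seed)),
    class = "crac_libconfig"
  )
}

rtriangular <- function(n, a, m, b) {
  u <- runif(n)
  fm <- (m - a) / (b - a)
  x <- ifelse(u < fm,
              a + sqrt(u * (b - a) * (m - a)),
              b - sqrt((1 - u) * (b - a) * (b - m)))
  pmax(a, pmin(b, as.integer(round(x))))
}

## occupancy weight of fragment-center positions along the spliced transcript
occupancy_weights <- function(kind, tx, L) {
  w <- rep(1, L)
  if (kind == "hel2like" && !is.na(tx$cds_start)) {
    # spliced coordinates of start/stop codon (single-exon assumption for
    # occupancy shaping; introns shift by their length upstream of the stop)
    if (tx$strand == "+") {
      s0 <- tx$cds_start - tx$tx_start + 1L
      st <- tx$cds_end - tx$tx_start + 1L - 2L
    } else {
      s0 <- tx$tx_end - tx$cds_end + 1L
      st <- tx$tx_end - tx$cds_start + 1L - 2L
    }
    clip <- function(i) i[i >= 1 & i <= L]
    w[clip(s0:(s0 + 149L))] <- 0.1
    w[clip((st - 90L):(st - 30L))] <- 4
    w[clip((st + 50L):(st + 110L))] <- 4
    w[clip((st - 15L):(st + 15L))] <- 0
  }
  w
}

#' Simulate one CRAC library with ground truth
#'
#' Draws fragments from the transcriptome under the configured occupancy
#' profile, plants crosslink-induced single-nucleotide deletions and
#' substitutions at the specified sites, adds uniform background errors,
#' appends non-templated oligo(A) tails to a fraction of pA-spanning
#' fragments, wraps each fragment into a read (in-line barcode with random
#' nucleotides + insert + tail + 3' adapter, truncated to the read length,
#' constant Q37) and duplicates reads geometrically to emulate PCR.
#'
#' The returned truth table and truth alignments are the test oracle for
#' every downstream stage: truth CIGARs encode the planted deletions
#' exactly, and the events table lists every planted mutation with its
#' genomic coordinate.
#'
#' Fragments never span exon junctions (spliced alignment is out of scope);
#' for multi-exon transcripts a fragment is clamped into the exon containing
#' its sampled center.
#'
#' @param txome a `crac_transcriptome`.
#' @param xl_sites data.frame from [crosslink_spec()], or NULL for a
#'   background-only (untagged-control-like) library.
#' @param config a `crac_libconfig`.
#' @param sample sample label recorded in the truth and alignments.
#' @param tx_weights named per-transcript sampling weights (default: equal
#'   over transcripts; sub-features, i.e. transcripts nested inside another
#'   annotated transcript, are skipped as sampling units).
#' @param emit_reads if FALSE, skip sequence assembly: the truth table and
#'   truth alignments are still complete (duplicate groups then equal
#'   fragments by construction), which is sufficient for pileup-level
#'   analyses and much faster for large replicate sweeps.
#' @return list of class `crac_library`: `reads` (data.frame id/seq/qual or
#'   NULL), `truth` (per-fragment table), `events` (planted mutations),
#'   `alignments` (a `crac_alignments` of the truth alignments), `config`,
#'   `sample`.
#' @export
simulate_library <- function(txome, xl_sites = NULL, config = library_config(),
                             sample = "S1", tx_weights = NULL,
                             emit_reads = TRUE) {
  set.seed(config$seed)
  tr <- txome$transcripts
  ex <- txome$exons

  # sampling units: drop transcripts fully nested in another on same chrom
  nested <- vapply(seq_len(nrow(tr)), function(i) {
    any(tr$chrom == tr$chrom[i] & tr$tx_start <= tr$tx_start[i] &
          tr$tx_end >= tr$tx_end[i] & tr$tx_id != tr$tx_id[i])
  }, logical(1))
  units <- tr[!nested, , drop = FALSE]

  n <- config$n_fragments
  if (n == 0) {
    return(empty_library(config, sample))
  }

  if (!is.null(xl_sites) && nrow(xl_sites) > 0) {
    inside <- vapply(seq_len(nrow(xl_sites)), function(i) {
      any(tr$chrom == xl_sites$chrom[i] & tr$tx_start <= xl_sites$pos[i] &
            tr$tx_end >= xl_sites$pos[i])
    }, logical(1))
    if (!all(inside)) stop("crosslink site outside every transcript")
  }
  chars <- genome_chars(txome$genome)
  if (emit_reads && any(vapply(chars, grepl, logical(1),
                               pattern = config$adapter, fixed = TRUE))) {
    warning("adapter sequence occurs in the genome: trimming is ambiguous")
  }

  w_tx <- if (is.null(tx_weights)) {
    setNames(rep(1, nrow(units)), units$tx_id)
  } else tx_weights[units$tx_id]
  ti <- sample.int(nrow(units), n, replace = TRUE, prob = w_tx)

  flen <- rtriangular(n, config$fragment_len[1], config$fragment_len[2],
                      config$fragment_len[3])

  # per-transcript center sampling under the occupancy profile
  L <- units$spliced_len
  centers <- integer(n)
  for (u in unique(ti)) {
    sel <- which(ti == u)
    w <- occupancy_weights(config$occupancy, units[u, ], L[u])
    if (sum(w) == 0) w[] <- 1
    centers[sel] <- sample.int(L[u], length(sel), replace = TRUE, prob = w)
  }
  flen <- pmin(flen, L[ti])
  sp_start <- pmax(1L, pmin(centers - (flen - 1L) %/% 2L, L[ti] - flen + 1L))
  sp_end <- sp_start + flen - 1L

  # clamp multi-exon fragments into the exon containing the center
  exu <- ex[ex$tx_id %in% units$tx_id, , drop = FALSE]
  exw <- exu$end - exu$start + 1L
  sp_off <- unlist(lapply(split(exw, factor(exu$tx_id, levels = units$tx_id)),
                          function(v) cumsum(c(0L, head(v, -1L)))),
                   use.names = FALSE)
  exu$sp_start <- sp_off + 1L
  exu$sp_end <- sp_off + exw
  multi <- units$tx_id[units$n_exons > 1L]
  if (length(multi) > 0) {
    for (id in multi) {
      sel <- which(units$tx_id[ti] == id)
      if (length(sel) == 0) next
      exs <- exu[exu$tx_id == id, , drop = FALSE]
      ei <- findInterval(centers[sel], exs$sp_start)
      s2 <- pmax(sp_start[sel], exs$sp_start[ei])
      e2 <- pmin(sp_end[sel], exs$sp_end[ei])
      sp_start[sel] <- s2; sp_end[sel] <- e2
    }
    flen <- sp_end - sp_start + 1L
  }

  # spliced -> genomic (fragment lies inside one exon)
  tx_of <- units[ti, ]
  # locate containing exon per fragment
  exon_idx <- integer(n)
  exu_by_tx <- split(seq_len(nrow(exu)), exu$tx_id)
  for (id in unique(tx_of$tx_id)) {
    sel <- which(tx_of$tx_id == id)
    exs <- exu[exu_by_tx[[id]], , drop = FALSE]
    exon_idx[sel] <- exu_by_tx[[id]][findInterval(sp_start[sel], exs$sp_start)]
  }
  local <- sp_start - exu$sp_start[exon_idx] + 1L
  plus <- tx_of$strand == "+"
  gstart <- ifelse(plus,
                   exu$start[exon_idx] + local - 1L,
                   exu$end[exon_idx] - (local + flen - 1L) + 1L)
  gend <- gstart + flen - 1L

  pa_span <- sp_end == L[ti]
  tail_len <- integer(n)
  cand <- which(pa_span)
  if (length(cand) > 0 && config$polyA_frac > 0) {
    tailed <- cand[runif(length(cand)) < config$polyA_frac]
    tail_len[tailed] <- sample_range(config$tail_len, length(tailed))
  }

  # ----- mutation events ------------------------------------------------
  ev <- plant_events(txome, xl_sites, config, tx_of, gstart, gend, flen, plus)

  # ----- multiplicities, UMIs, barcodes ---------------------------------
  mult <- 1L + rgeom(n, config$pcr_dup_p)
  tpl <- strsplit(config$barcode_template, "")[[1]]
  n_umi <- sum(tpl == "N")
  umi_mat <- matrix(sample(c("A", "C", "G", "T"), n * n_umi, replace = TRUE),
                    nrow = n)
  umi <- if (n_umi > 0) do.call(paste0, as.data.frame(umi_mat)) else
    rep("", n)

  frag_id <- sprintf("frag%06d", seq_len(n))

  # ----- truth CIGARs (reference orientation) ---------------------------
  cigar <- paste0(flen, "M")
  del_ev <- ev[ev$kind == "del", , drop = FALSE]
  if (nrow(del_ev) > 0) {
    o <- order(del_ev$frag, del_ev$ref_pos)
    del_ev <- del_ev[o, , drop = FALSE]
    ndel_per <- tabulate(del_ev$frag, nbins = n)
    one <- which(ndel_per == 1L)
    if (length(one) > 0) {
      off1 <- del_ev$ref_pos[match(one, del_ev$frag)] - gstart[one] + 1L
      cigar[one] <- sprintf("%dM1D%dM", off1 - 1L, flen[one] - off1)
    }
    multi <- which(ndel_per > 1L)
    if (length(multi) > 0) {
      by_frag <- split(del_ev$ref_pos, del_ev$frag)
      for (f in as.character(multi)) {
        i <- as.integer(f)
        offs <- by_frag[[f]] - gstart[i] + 1L     # already sorted
        seg <- diff(c(0L, offs)) - 1L
        parts <- paste0(seg, "M1D", collapse = "")
        last <- flen[i] - offs[length(offs)]
        cigar[i] <- gsub("(^|D)0M", "\\1", paste0(parts, last, "M"))
      }
    }
  }

  n_del <- tabulate(del_ev$frag, nbins = n)
  sub_ev <- ev[ev$kind == "sub", , drop = FALSE]
  n_sub <- tabulate(sub_ev$frag, nbins = n)

  qname <- sprintf("%s_%s_x%d", frag_id, umi, mult)
  aln_df <- data.frame(
    qname = qname, rname = tx_of$chrom, pos = gstart,
    strand = tx_of$strand, cigar = cigar, mult = mult, umi = umi,
    sample = sample, n_hits = 1L, seq_ref = "*",
    stringsAsFactors = FALSE
  )
  # mutation table read_base follows SAM convention (reference orientation)
  mut_df <- if (nrow(ev) > 0) {
    mut_rb <- ifelse(tx_of$strand[ev$frag] == "-" & ev$kind == "sub",
                     chartr("ACGT", "TGCA", ev$read_base), ev$read_base)
    data.frame(
      qname = qname[ev$frag], rname = tx_of$chrom[ev$frag],
      ref_pos = ev$ref_pos, strand = tx_of$strand[ev$frag],
      kind = ev$kind, len = 1L,
      read_base = mut_rb, ref_base = ev$ref_base,
      stringsAsFactors = FALSE
    )
  } else empty_mutation_df()

  truth <- data.frame(
    frag_id = frag_id, qname = qname, sample = sample,
    tx_id = tx_of$tx_id, chrom = tx_of$chrom,
    gstart = gstart, gend = gend, strand = tx_of$strand,
    sp_start = sp_start, frag_len = flen, center_sp = centers,
    umi = umi, mult = mult, tail_len = tail_len,
    n_del = n_del, n_sub = n_sub,
    pa_span = pa_span,
    stringsAsFactors = FALSE
  )

  reads <- NULL
  if (emit_reads) {
    asm <- assemble_reads(chars, config, tx_of, gstart, gend, flen, plus,
                          ev, tail_len, umi, tpl, frag_id, mult)
    reads <- asm$reads
    aln_df$seq_ref <- asm$seq_ref
    truth$insert_len <- nchar(asm$insert)
    truth$insert <- asm$insert_trunc
    truth$dup_group <- match(paste0(asm$insert_trunc, "#", umi),
                             unique(paste0(asm$insert_trunc, "#", umi)))
  } else {
    truth$insert_len <- flen - n_del + tail_len
    truth$dup_group <- seq_len(n)
  }

  structure(
    list(reads = reads, truth = truth,
         events = data.frame(frag_id = frag_id[ev$frag], qname = qname[ev$frag],
                             rname = tx_of$chrom[ev$frag], ref_pos = ev$ref_pos,
                             kind = ev$kind, read_off = ev$read_off,
                             read_base = ev$read_base, ref_base = ev$ref_base,
                             stringsAsFactors = FALSE),
         alignments = new_alignments(aln_df, mut_df),
         config = config, sample = sample),
    class = "crac_library"
  )
}

## plant crosslink and background events; returns data.frame
## frag, ref_pos (genomic), kind, read_off (fragment 5'->3'), read/ref bases
plant_events <- function(txome, xl_sites, config, tx_of, gstart, gend, flen,
                         plus) {
  n <- length(gstart)
  chars <- genome_chars(txome$genome)
  frag <- integer(0); pos <- integer(0); kind <- character(0)

  if (!is.null(xl_sites) && nrow(xl_sites) > 0) {
    fr <- GenomicRanges::GRanges(tx_of$chrom, IRanges::IRanges(gstart, gend))
    si <- GenomicRanges::GRanges(xl_sites$chrom,
                                 IRanges::IRanges(xl_sites$pos, xl_sites$pos))
    ov <- GenomicRanges::findOverlaps(fr, si)
    qi <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
    if (length(qi) > 0) {
      crossed <- runif(length(qi)) < xl_sites$xl_prob[sj]
      u <- runif(length(qi))
      k <- ifelse(u < xl_sites$del_prob[sj], "del",
                  ifelse(u < xl_sites$del_prob[sj] + xl_sites$sub_prob[sj],
                         "sub", "none"))
      keep <- crossed & k != "none"
      frag <- c(frag, qi[keep])
      pos <- c(pos, xl_sites$pos[sj[keep]])
      kind <- c(kind, k[keep])
    }
  }

  for (bg in c("del", "sub")) {
    rate <- if (bg == "del") config$bg_del_rate else config$bg_sub_rate
    if (rate > 0) {
      cnt <- rbinom(n, flen, rate)
      idx <- rep.int(seq_len(n), cnt)
      if (length(idx) > 0) {
        off <- 1L + as.integer(floor(runif(length(idx)) * flen[idx]))
        gp <- ifelse(plus[idx], gstart[idx] + off - 1L, gend[idx] - off + 1L)
        frag <- c(frag, idx); pos <- c(pos, gp)
        kind <- c(kind, rep(bg, length(idx)))
      }
    }
  }

  if (length(frag) == 0) {
    return(data.frame(frag = integer(0), ref_pos = integer(0),
                      kind = character(0), read_off = integer(0),
                      read_base = character(0), ref_base = character(0)))
  }

  base_at <- function(p, f) {
    out <- character(length(p))
    for (cc in unique(tx_of$chrom[f])) {
      sel <- tx_of$chrom[f] == cc
      out[sel] <- substring(chars[[cc]], p[sel], p[sel])
    }
    out
  }

  # normalize deletions to the leftmost base of their homopolymer run
  # (the SAM convention the aligner follows), and drop deletions whose
  # run reaches a fragment boundary: there the deletion is unobservable
  # (the alignment merely shortens)
  di <- which(kind == "del")
  if (length(di) > 0) {
    for (iter in seq_len(12L)) {
      b0 <- base_at(pos[di], frag[di]); bl <- base_at(pos[di] - 1L, frag[di])
      can <- pos[di] - 1L >= gstart[frag[di]] & bl == b0
      if (!any(can)) break
      pos[di[can]] <- pos[di[can]] - 1L
    }
    # right extent of the run
    j <- pos[di]
    b0 <- base_at(pos[di], frag[di])
    for (iter in seq_len(12L)) {
      can <- j + 1L <= gend[frag[di]] & base_at(j + 1L, frag[di]) == b0
      if (!any(can)) break
      j[can] <- j[can] + 1L
    }
    drop <- pos[di] == gstart[frag[di]] | j == gend[frag[di]]
    if (any(drop)) {
      rm_i <- di[drop]
      frag <- frag[-rm_i]; pos <- pos[-rm_i]; kind <- kind[-rm_i]
    }
  }

  # deduplicate per (fragment, position); deletions win over substitutions
  ord <- order(frag, pos, kind)  # "del" < "sub"
  frag <- frag[ord]; pos <- pos[ord]; kind <- kind[ord]
  dup <- duplicated(paste(frag, pos))
  frag <- frag[!dup]; pos <- pos[!dup]; kind <- kind[!dup]

  read_off <- ifelse(plus[frag], pos - gstart[frag] + 1L,
                     gend[frag] - pos + 1L)
  if (length(frag) == 0) {
    return(data.frame(frag = integer(0), ref_pos = integer(0),
                      kind = character(0), read_off = integer(0),
                      read_base = character(0), ref_base = character(0)))
  }
  ref_base <- substring(chars[[tx_of$chrom[1]]], pos, pos)
  if (length(unique(tx_of$chrom)) > 1) {
    for (cc in unique(tx_of$chrom[frag])) {
      sel <- tx_of$chrom[frag] == cc
      ref_base[sel] <- substring(chars[[cc]], pos[sel], pos[sel])
    }
  }
  # template base in read orientation; substituted base differs from it
  tmpl <- ifelse(plus[frag], ref_base,
                 chartr("ACGT", "TGCA", ref_base))
  read_base <- tmpl
  is_sub <- kind == "sub"
  if (any(is_sub)) {
    alt <- c("A", "C", "G", "T")
    pick <- vapply(tmpl[is_sub], function(b) {
      sample(setdiff(alt, b), 1L)
    }, character(1))
    read_base[is_sub] <- pick
  }
  read_base[kind == "del"] <- ""
  data.frame(frag = frag, ref_pos = pos, kind = kind, read_off = read_off,
             read_base = read_base, ref_base = ref_base,
             stringsAsFactors = FALSE)
}

## build read sequences; returns reads df (duplicates expanded), the
## reference-orientation insert sequences and truncated inserts for
## duplicate-group identity
assemble_reads <- function(chars, config, tx_of, gstart, gend, flen, plus,
                           ev, tail_len, umi, tpl, frag_id, mult) {
  n <- length(gstart)
  gseq <- character(n)
  for (cc in unique(tx_of$chrom)) {
    sel <- tx_of$chrom == cc
    gseq[sel] <- substring(chars[[cc]], gstart[sel], gend[sel])
  }
  rseq <- gseq
  neg <- !plus
  if (any(neg)) rseq[neg] <- revcomp(gseq[neg])

  # apply events in read orientation (few fragments carry any)
  if (nrow(ev) > 0) {
    by_frag <- split(ev, ev$frag)
    for (f in names(by_frag)) {
      i <- as.integer(f)
      e <- by_frag[[f]]
      x <- rseq[i]
      subs <- e[e$kind == "sub", , drop = FALSE]
      for (j in seq_len(nrow(subs))) {
        substr(x, subs$read_off[j], subs$read_off[j]) <- subs$read_base[j]
      }
      dels <- sort(e$read_off[e$kind == "del"])
      if (length(dels) > 0) {
        keep_start <- c(1L, dels + 1L)
        keep_end <- c(dels - 1L, nchar(x))
        x <- paste(substring(x, keep_start, keep_end), collapse = "")
      }
      rseq[i] <- x
    }
  }

  insert <- paste0(rseq, strrep("A", tail_len))
  max_insert <- config$read_len - nchar(config$barcode_template)
  insert_trunc <- substr(insert, 1L, max_insert)

  # barcodes: fill N positions from the UMI
  cols <- vector("list", length(tpl))
  k <- 0L
  for (j in seq_along(tpl)) {
    if (tpl[j] == "N") {
      k <- k + 1L
      cols[[j]] <- substring(umi, k, k)
    } else cols[[j]] <- rep(tpl[j], n)
  }
  barcode <- do.call(paste0, cols)

  full <- substr(paste0(barcode, insert, config$adapter), 1L, config$read_len)
  qual <- strrep("F", nchar(full))  # constant Q37

  idx <- rep.int(seq_len(n), mult)
  copy <- sequence(mult)
  reads <- data.frame(
    id = sprintf("%s/%d", frag_id[idx], copy),
    seq = full[idx], qual = qual[idx],
    stringsAsFactors = FALSE
  )
  seq_ref <- rseq
  if (any(neg)) seq_ref[neg] <- revcomp(rseq[neg])
  list(reads = reads, seq_ref = seq_ref, insert = insert,
       insert_trunc = insert_trunc)
}

empty_library <- function(config, sample) {
  structure(
    list(
      reads = data.frame(id = character(0), seq = character(0),
                         qual = character(0)),
      truth = data.frame(),
      events = data.frame(frag_id = character(0), qname = character(0),
                          rname = character(0), ref_pos = integer(0),
                          kind = character(0), read_off = integer(0),
                          read_base = character(0), ref_base = character(0)),
      alignments = new_alignments(empty_alignment_df(), empty_mutation_df()),
      config = config, sample = sample
    ),
    class = "crac_library"
  )
}

#' Simulate an untagged-control library
#'
#' Same generative model with crosslinking disabled (background errors
#' only) and 5-fold fewer fragments, emulating the lower RNA recovery of
#' libraries from strains without the affinity tag.
#'
#' @inheritParams simulate_library
#' @export
simulate_control <- function(txome, config = library_config(),
                             sample = "untagged", tx_weights = NULL,
                             emit_reads = TRUE) {
  config$n_fragments <- as.integer(max(0, config$n_fragments %/% 5L))
  simulate_library(txome, xl_sites = NULL, config = config, sample = sample,
                   tx_weights = tx_weights, emit_reads = emit_reads)
}
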