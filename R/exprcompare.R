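#' Build the mature-transcript quantitation database
#'
#' Mature mRNA sequences for abundance comparison: 5' UTR + exons with
#' introns excised + 3' UTR, plus an arbitrary run of 10 adenines at the
#' 3' end to mimic the poly(A) tail. When the annotation's transcript
#' bounds already include the UTRs (as the simulator's do), the spliced
#' exon sequence is used directly; a UTR table can instead extend
#' CDS-only annotations.
#'
#' @param txome a `crac_transcriptome`.
#' @param utr_table optional data.frame (tx_id, utr5_len, utr3_len) used
#'   to extend transcripts whose bounds equal their CDS.
#' @param classes RNA classes to include (default mRNA).
#' @return named DNAStringSet; every record ends in the 10 appended As.
#' @export
build_mature_db <- function(txome, utr_table = NULL, classes = "mRNA") {
  tr <- txome$transcripts[txome$transcripts$rna_class %in% classes, ,
                          drop = FALSE]
  chars <- genome_chars(txome$genome)
  seqs <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    id <- tr$tx_id[i]
    exs <- txome$exons[txome$exons$tx_id == id, , drop = FALSE]
    exs <- exs[order(exs$start), , drop = FALSE]
    s <- exs$start; e <- exs$end
    if (!is.null(utr_table) && tr$tx_start[i] == tr$cds_start[i] &&
        tr$tx_end[i] == tr$cds_end[i]) {
      u <- utr_table[utr_table$tx_id == id, , drop = FALSE]
      if (nrow(u) == 1) {
        if (tr$strand[i] == "+") {
          s[1] <- s[1] - u$utr5_len
          e[length(e)] <- e[length(e)] + u$utr3_len
        } else {
          s[1] <- s[1] - u$utr3_len
          e[length(e)] <- e[length(e)] + u$utr5_len
        }
        if (s[1] < 1) {
          warning("UTR extension beyond chromosome start for ", id)
          s[1] <- 1L
        }
      }
    }
    parts <- substring(chars[[tr$chrom[i]]], s, e)
    spliced <- paste(parts, collapse = "")
    if (tr$strand[i] == "-") spliced <- revcomp(spliced)
    seqs[i] <- paste0(spliced, strrep("A", 10))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tr$tx_id
  out
}

#' Normalize per-transcript coverage to 1 kb per million
#'
#' value = coverage x (1000 / length) x (1e6 / library total). Coverage is
#' the mean per-base read depth over the mature transcript (including the
#' 10-A extension) or any per-transcript count on a consistent scale.
#'
#' @param coverage named numeric vector (one dataset).
#' @param lengths named effective transcript lengths, nt.
#' @param library_size library total; defaults to `sum(coverage)`.
#' @return named numeric vector of normalized values.
#' @export
normalize_abundance <- function(coverage, lengths, library_size = NULL) {
  lengths <- lengths[names(coverage)]
  if (any(lengths <= 0)) stop("zero-length transcript")
  if (is.null(library_size)) library_size <- sum(coverage)
  stopifnot(library_size > 0)
  coverage * (1000 / lengths) * (1e6 / library_size)
}

#' Summarize replicate datasets into per-type medians and log2 medians
#'
#' Datasets of the same experiment type (RNASeq, RiboSeq, CRAC) are
#' summarized by the per-gene median of normalized values; the median is
#' log2-transformed to reduce the effect of outliers. Genes whose median
#' is zero in any requested type are dropped from the log2 table (and
#' reported), rather than pseudo-counted.
#'
#' @param norm_mat genes x datasets matrix of normalized values.
#' @param types character vector: experiment type of each column.
#' @return list: `medians` (genes x types), `log2_medians` (zero-median
#'   genes removed), `dropped` (their ids).
#' @export
summarize_experiments <- function(norm_mat, types) {
  stopifnot(ncol(norm_mat) == length(types))
  ut <- unique(types)
  med <- vapply(ut, function(tp) {
    apply(norm_mat[, types == tp, drop = FALSE], 1, median)
  }, numeric(nrow(norm_mat)))
  colnames(med) <- ut
  zero <- apply(med == 0, 1, any)
  list(medians = med,
       log2_medians = log2(med[!zero, , drop = FALSE]),
       dropped = rownames(med)[zero])
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via [stats::cor()].
#' Constant input is undefined and returns NA with a warning.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return rho (scalar).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Quintile analysis of translation versus binding
#'
#' Genes are split into five equal-size groups by their CRAC value (ties
#' broken by stable input order) and the RiboSeq-to-RNASeq ratio (the
#' translation-efficiency proxy) is summarized per quintile with box
#' statistics: median, quartiles, whiskers extending 1.5 times the
#' interquartile range from the quartiles, and outliers beyond them.
#' Genes with zero RNASeq are dropped from the ratios and reported.
#'
#' @param crac,ribo,rna named numeric vectors over the same gene set.
#' @return list: `assignment` (gene, quintile), `summary` (per-quintile
#'   n, median, q25, q75, whisker_lo, whisker_hi, n_outliers), `ratios`
#'   (list of per-quintile ratio vectors), `dropped`.
#' @export
quintile_ratios <- function(crac, ribo, rna) {
  stopifnot(length(crac) == length(ribo), length(crac) == length(rna))
  n <- length(crac)
  ord <- order(crac)                      # stable for ties
  qsizes <- diff(floor(seq(0, n, length.out = 6)))
  quint <- integer(n)
  quint[ord] <- rep(seq_len(5), times = qsizes)

  genes <- if (!is.null(names(crac))) names(crac) else as.character(seq_len(n))
  zero_rna <- rna == 0
  dropped <- genes[zero_rna]

  ratios <- lapply(seq_len(5), function(qi) {
    sel <- quint == qi & !zero_rna
    ribo[sel] / rna[sel]
  })
  summ <- do.call(rbind, lapply(seq_len(5), function(qi) {
    v <- ratios[[qi]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo_lim <- q[1] - 1.5 * iqr
    hi_lim <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_lim & v <= hi_lim]
    data.frame(quintile = qi, n = length(v), median = q[2],
               q25 = q[1], q75 = q[3],
               whisker_lo = if (length(inside)) min(inside) else NA_real_,
               whisker_hi = if (length(inside)) max(inside) else NA_real_,
               n_outliers = sum(v < lo_lim | v > hi_lim))
  }))
  list(assignment = data.frame(gene = genes, quintile = quint,
                               stringsAsFactors = FALSE),
       summary = summ, ratios = ratios, dropped = dropped)
}

#' Simulate matched RNASeq / RiboSeq / CRAC abundance tables
#'
#' RNASeq abundances are lognormal; RiboSeq = RNASeq x TE with lognormal
#' translation efficiency; CRAC follows RiboSeq (binding tracks
#' translation) or RNASeq (the null, binding blind to TE) under
#' multiplicative lognormal noise. Generation parameters are recorded as
#' attributes.
#'
#' @param n_genes number of genes (>= 50).
#' @param sdlog_rna lognormal sd of RNASeq abundance.
#' @param sdlog_te lognormal sd of translation efficiency.
#' @param noise_sd lognormal sd of CRAC measurement noise (0 = noiseless).
#' @param crac_follows "ribo" (planted monotone CRAC~TE relation) or
#'   "rna" (null).
#' @param seed integer seed.
#' @return data.frame gene, rna, ribo, crac, te; parameters in
#'   `attr(, "params")`.
#' @export
simulate_expression <- function(n_genes = 1000, sdlog_rna = 1,
                                sdlog_te = 0.5, noise_sd = 0.3,
                                crac_follows = c("ribo", "rna"), seed = 1) {
  stopifnot(n_genes >= 50)
  crac_follows <- match.arg(crac_follows)
  set.seed(seed)
  rna <- rlnorm(n_genes, meanlog = 4, sdlog = sdlog_rna)
  te <- rlnorm(n_genes, meanlog = 0, sdlog = sdlog_te)
  ribo <- rna * te
  base <- if (crac_follows == "ribo") ribo else rna
  crac <- base * rlnorm(n_genes, meanlog = 0, sdlog = noise_sd)
  out <- data.frame(gene = sprintf("g%04d", seq_len(n_genes)),
                    rna = rna, ribo = ribo, crac = crac, te = te,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(n_genes = n_genes, sdlog_rna = sdlog_rna,
                              sdlog_te = sdlog_te, noise_sd = noise_sd,
                              crac_follows = crac_follows, seed = seed)
  out
}
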