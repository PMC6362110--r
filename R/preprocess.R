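#' Demultiplex reads by 5' in-line barcodes
#'
#' Each barcode template is a string over A/C/G/T/N read as a 5' prefix;
#' `N` marks the random nucleotides (the UMI). A read is assigned to the
#' unique sample whose fixed template positions match its prefix with at
#' most `max_mismatch` mismatches; ties and reads shorter than the
#' template go to the unassigned bin. The barcode is removed and the UMI
#' is appended to the read identifier as `id##UMI`.
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param specs data.frame with columns `sample` and `template`.
#' @param max_mismatch allowed mismatches at fixed barcode positions.
#' @return named list of per-sample read data.frames (with `umi` column)
#'   plus an `unassigned` element; every input read lands in exactly one
#'   bin.
#' @export
demultiplex <- function(reads, specs, max_mismatch = 0) {
  stopifnot(all(c("sample", "template") %in% names(specs)))
  n <- nrow(reads)
  ns <- nrow(specs)
  mm <- matrix(Inf, nrow = n, ncol = ns)
  if (n > 0) {
    for (j in seq_len(ns)) {
      tpl <- strsplit(specs$template[j], "")[[1]]
      fixed <- which(tpl != "N")
      long_enough <- nchar(reads$seq) >= length(tpl)
      d <- integer(n)
      for (p in fixed) {
        d <- d + as.integer(substr(reads$seq, p, p) != tpl[p])
      }
      mm[long_enough, j] <- d[long_enough]
    }
  }
  best <- apply(mm, 1, function(r) {
    m <- min(r)
    if (!is.finite(m) || m > max_mismatch) return(0L)
    hits <- which(r == m)
    if (length(hits) > 1L) 0L else hits  # tie -> unassigned
  })
  if (n == 0) best <- integer(0)

  out <- list()
  for (j in seq_len(ns)) {
    sel <- which(best == j)
    tpl <- strsplit(specs$template[j], "")[[1]]
    npos <- which(tpl == "N")
    r <- reads[sel, , drop = FALSE]
    umi <- if (length(npos) > 0 && length(sel) > 0) {
      cols <- lapply(npos, function(p) substr(r$seq, p, p))
      do.call(paste0, cols)
    } else rep("", length(sel))
    if (nrow(r) > 0) {
      r$seq <- substr(r$seq, length(tpl) + 1L, nchar(r$seq))
      r$qual <- substr(r$qual, length(tpl) + 1L, nchar(r$qual))
      r$id <- paste0(r$id, "##", umi)
    }
    r$umi <- umi
    rownames(r) <- NULL
    out[[specs$sample[j]]] <- r
  }
  una <- reads[best == 0L, , drop = FALSE]
  rownames(una) <- NULL
  out$unassigned <- una
  out
}

#' Trim adapters, quality-trim and filter reads
#'
#' Mirrors the behaviour of a standard adapter trimmer run with a minimum
#' adapter overlap of 4, a 3' quality cutoff of 30, at most 3 uncalled
#' bases and a minimum length of 17:
#' \enumerate{
#'   \item 3' bases with Phred quality below `phred_cut` are trimmed;
#'   \item the first full internal occurrence of the adapter, or a read
#'     suffix exactly matching an adapter prefix of at least `min_overlap`
#'     bases, is removed;
#'   \item reads with more than `max_uncalled` N bases or shorter than
#'     `min_len` are discarded.
#' }
#' Output order preserves input order.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (and optional extra
#'   columns, preserved).
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_overlap minimal exact suffix/prefix overlap.
#' @param phred_cut 3' quality cutoff (Phred).
#' @param max_uncalled maximum number of N bases.
#' @param min_len minimum read length after trimming.
#' @return filtered data.frame; logical column `adapter_found` records
#'   whether the 3' adapter was detected (needed for poly(A) analysis).
#' @export
trim_and_filter <- function(reads, adapter, min_overlap = 4, phred_cut = 30,
                            max_uncalled = 3, min_len = 17) {
  stopifnot(nchar(adapter) > 0)
  r <- reads
  if (nrow(r) == 0) {
    r$adapter_found <- logical(0)
    return(r)
  }

  # 1. 3' quality trimming: drop the maximal low-quality suffix
  ascii <- rawToChar(as.raw(33:126), multiple = TRUE)
  low <- ascii[seq_len(phred_cut)]          # qualities 0..phred_cut-1
  mask <- chartr(paste(ascii, collapse = ""),
                 paste(c(rep("0", phred_cut),
                         rep("1", length(ascii) - phred_cut)), collapse = ""),
                 r$qual)
  run <- attr(regexpr("0+$", mask), "match.length")
  run[run < 0] <- 0L
  keep_len <- nchar(r$seq) - run
  r$seq <- substr(r$seq, 1L, keep_len)
  r$qual <- substr(r$qual, 1L, keep_len)

  # 2. adapter removal: full internal occurrence first, then 3' overlap
  pos <- regexpr(adapter, r$seq, fixed = TRUE)
  found <- pos > 0L
  cut_at <- ifelse(found, pos - 1L, nchar(r$seq))
  rest <- !found
  if (any(rest)) {
    kmax <- min(nchar(adapter) - 1L, max(nchar(r$seq[rest]), 0L))
    for (kk in seq(from = kmax, by = -1L,
                   length.out = max(0L, kmax - min_overlap + 1L))) {
      pre <- substr(adapter, 1L, kk)
      cand <- rest & !found & nchar(r$seq) >= kk &
        substr(r$seq, nchar(r$seq) - kk + 1L, nchar(r$seq)) == pre
      if (any(cand)) {
        cut_at[cand] <- nchar(r$seq[cand]) - kk
        found[cand] <- TRUE
      }
    }
  }
  r$seq <- substr(r$seq, 1L, cut_at)
  r$qual <- substr(r$qual, 1L, cut_at)
  r$adapter_found <- found

  # 3. filters
  n_uncalled <- nchar(r$seq) - nchar(gsub("N", "", r$seq, fixed = TRUE))
  ok <- n_uncalled <= max_uncalled & nchar(r$seq) >= min_len
  r <- r[ok, , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Collapse PCR duplicates using sequence + UMI identity
#'
#' Reads sharing both their (trimmed) sequence and the random nucleotides
#' from the in-line barcode are PCR copies of one cDNA molecule; they are
#' collapsed to a single record whose representative is the first
#' occurrence in file order, with the multiplicity recorded. Reads
#' without a UMI are rejected with a warning. Collapsing is idempotent.
#'
#' @param reads data.frame with `seq` and either a `umi` column or
#'   identifiers carrying `##UMI` (as produced by [demultiplex()]).
#' @return data.frame of class `crac_collapsed`: `serial`, `umi`, `seq`,
#'   `mult`, and `id` following the dialect `serial_UMI_xMULT`.
#' @export
collapse_reads <- function(reads) {
  r <- reads
  if (is.null(r$umi)) {
    m <- regmatches(r$id, regexec("##([ACGTN]*)$", r$id))
    r$umi <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
                    character(1))
  }
  # already-collapsed input: expand multiplicities into the key
  prior_mult <- if (!is.null(r$mult)) r$mult else rep(1L, nrow(r))
  missing_umi <- is.na(r$umi) | r$umi == ""
  if (any(missing_umi)) {
    warning(sum(missing_umi), " reads without UMI rejected")
    r <- r[!missing_umi, , drop = FALSE]
    prior_mult <- prior_mult[!missing_umi]
  }
  if (nrow(r) == 0) {
    out <- data.frame(serial = integer(0), umi = character(0),
                      seq = character(0), mult = integer(0),
                      id = character(0), stringsAsFactors = FALSE)
    class(out) <- c("crac_collapsed", "data.frame")
    return(out)
  }
  key <- paste0(r$seq, "#", r$umi)
  first <- !duplicated(key)
  uk <- key[first]
  mult <- as.integer(rowsum(prior_mult, factor(key, levels = uk))[, 1])
  out <- data.frame(
    serial = seq_along(uk),
    umi = r$umi[first],
    seq = r$seq[first],
    mult = mult,
    stringsAsFactors = FALSE
  )
  out$id <- sprintf("%d_%s_x%d", out$serial, out$umi, out$mult)
  class(out) <- c("crac_collapsed", "data.frame")
  out
}

#' Write collapsed reads as FASTA
#'
#' Header dialect: `>{serial}_{umi}_x{multiplicity}`.
#'
#' @param collapsed a `crac_collapsed` table.
#' @param path output FASTA.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  x <- setNames(collapsed$seq, collapsed$id)
  write_fasta(x, path)
}

#' Read a collapsed FASTA back
#'
#' @param path FASTA with `serial_UMI_xMULT` headers.
#' @return a `crac_collapsed` data.frame.
#' @export
read_collapsed_fasta <- function(path) {
  x <- read_fasta(path)
  m <- regmatches(names(x), regexec("^(.+)_([ACGTN]+)_x([0-9]+)$", names(x)))
  out <- data.frame(
    serial = seq_along(x),
    umi = vapply(m, function(v) v[3], character(1)),
    seq = as.character(x),
    mult = as.integer(vapply(m, function(v) v[4], character(1))),
    id = names(x),
    stringsAsFactors = FALSE
  )
  class(out) <- c("crac_collapsed", "data.frame")
  out
}
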