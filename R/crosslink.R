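#' Call crosslink sites from a micro-deletion track
#'
#' Crosslinked nucleotides show up as positions where a large fraction of
#' covering reads carry a single-nucleotide deletion, far above the
#' background deletion density of the feature. A position is kept when
#' both hold:
#' \itemize{
#'   \item its deletion fraction of coverage, `dels[i]/reads[i]`, is at
#'     least `min_fraction` (background RT/PCR/sequencing deletions sit at
#'     a few per mille; crosslink sites reach tens of percent), and
#'   \item its share of the normalized deletion array is at least
#'     `min_fold_over_median` times the feature's average deletion
#'     density over covered positions (1/n_covered for a unit-sum array).
#' }
#' The average is used as the background reference because the median
#' deletion share is degenerate at moderate coverage: most covered
#' positions carry zero deletions, so the median is 0 and a median-based
#' fold threshold filters nothing.
#' Kept positions closer than `merge_within` nt are merged into one site;
#' sites are ranked by their total normalized deletion share over the
#' site span (ties broken by leftmost position), so a multi-nucleotide
#' site like the major 18S site outranks single-nucleotide minor sites.
#' Both criteria are ratios, so calls are invariant under rescaling of
#' the raw counts.
#'
#' @param track a normalized `crac_track` (see [normalize_track()]).
#' @param min_fraction minimum per-position deletion fraction of coverage.
#' @param min_fold_over_median minimum fold over the median normalized
#'   deletion share of covered positions.
#' @param merge_within merge kept positions within this many nt.
#' @return data.frame with feature, start, end (1-based within the
#'   feature), peak_pos, peak_fraction (normalized deletion share at the
#'   peak), site_fraction (summed share over the span),
#'   peak_del_fraction (deletion fraction of coverage at the peak) and
#'   rank; zero rows when nothing qualifies.
#' @export
call_sites <- function(track, min_fraction = 0.02, min_fold_over_median = 10,
                       merge_within = 3) {
  stopifnot(inherits(track, "crac_track"), isTRUE(track$normalized))
  empty <- data.frame(feature = character(0), start = integer(0),
                      end = integer(0), peak_pos = integer(0),
                      peak_fraction = numeric(0), site_fraction = numeric(0),
                      peak_del_fraction = numeric(0), rank = integer(0))
  if ("dels" %in% track$zero_arrays) return(empty)

  rel <- track$norm_dels
  covered <- track$reads > 0
  if (!any(covered)) return(empty)
  covfrac <- ifelse(covered, track$dels / pmax(track$reads, 1L), 0)
  ref_level <- mean(rel[covered])
  keep <- which(covfrac >= min_fraction &
                  rel >= min_fold_over_median * ref_level &
                  track$dels > 0)
  if (length(keep) == 0) return(empty)

  grp <- cumsum(c(1L, as.integer(diff(keep) > merge_within)))
  sites <- do.call(rbind, lapply(split(keep, grp), function(p) {
    pk <- p[which.max(rel[p])]
    data.frame(feature = track$feature_id, start = min(p), end = max(p),
               peak_pos = pk, peak_fraction = rel[pk],
               site_fraction = sum(rel[min(p):max(p)]),
               peak_del_fraction = covfrac[pk])
  }))
  ord <- order(-sites$site_fraction, sites$start)
  sites <- sites[ord, , drop = FALSE]
  sites$rank <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  sites
}

#' Compare site-level deletion fractions between conditions
#'
#' For each called site, sums the normalized deletion share over the site
#' span in every replicate, then compares each condition against the
#' reference with a classic (equal-variance, two-tailed) two-sample
#' Student's t test. The fold change is median(reference)/median(test); a
#' test condition with zero median is reported as an infinite fold and
#' flagged. With fewer than two replicates on either side the fold is
#' still reported but the p-value is absent and flagged.
#'
#' @param tracks_by_condition named list; each element a list of
#'   normalized replicate `crac_track`s of one condition.
#' @param sites site table from [call_sites()].
#' @param reference_condition name of the reference (wild-type) condition.
#' @param welch if TRUE use Welch's unequal-variance t test instead of the
#'   classic Student's t.
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] across all (site, condition) tests; default
#'   "none".
#' @return data.frame with one row per site x non-reference condition:
#'   feature, start, end, condition, fold, p, significant (p < 0.05),
#'   flag; per-replicate site values in `attr(, "values")`.
#' @export
compare_conditions <- function(tracks_by_condition, sites,
                               reference_condition, welch = FALSE,
                               p_adjust = "none") {
  stopifnot(reference_condition %in% names(tracks_by_condition))
  site_value <- function(track, s) sum(track$norm_dels[s$start:s$end])

  vals <- list()
  for (cond in names(tracks_by_condition)) {
    for (r in seq_along(tracks_by_condition[[cond]])) {
      tr <- tracks_by_condition[[cond]][[r]]
      stopifnot(isTRUE(tr$normalized))
      for (i in seq_len(nrow(sites))) {
        s <- sites[i, ]
        vals[[length(vals) + 1L]] <- data.frame(
          feature = s$feature, start = s$start, end = s$end,
          condition = cond, replicate = r,
          value = site_value(tr, s), stringsAsFactors = FALSE
        )
      }
    }
  }
  vals <- do.call(rbind, vals)

  res <- list()
  other <- setdiff(names(tracks_by_condition), reference_condition)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    here <- vals$start == s$start & vals$end == s$end &
      vals$feature == s$feature
    ref_v <- vals$value[here & vals$condition == reference_condition]
    for (cond in other) {
      test_v <- vals$value[here & vals$condition == cond]
      flag <- ""
      fold <- if (median(test_v) > 0) median(ref_v) / median(test_v) else {
        flag <- "zero_test_median"
        Inf
      }
      p <- NA_real_
      if (length(ref_v) >= 2 && length(test_v) >= 2) {
        if (isTRUE(all.equal(ref_v, test_v)) ||
            (stats::sd(ref_v) == 0 && stats::sd(test_v) == 0)) {
          p <- if (mean(ref_v) == mean(test_v)) 1 else 0
        } else {
          p <- t.test(test_v, ref_v, var.equal = !welch)$p.value
        }
      } else {
        flag <- paste0(flag, if (nzchar(flag)) ";" else "", "too_few_replicates")
      }
      res[[length(res) + 1L]] <- data.frame(
        feature = s$feature, start = s$start, end = s$end,
        condition = cond, fold = fold, p = p, flag = flag,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  if (p_adjust != "none") out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- !is.na(out$p) & out$p < 0.05
  rownames(out) <- NULL
  attr(out, "values") <- vals
  out
}
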