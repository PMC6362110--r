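#' Simulate a polysome gradient A260 trace
#'
#' A flat dead-volume segment followed by Gaussian peaks of given areas
#' plus optional Gaussian noise (clipped at zero). Peak truth areas and
#' the true signal start are recorded for use as test oracles.
#'
#' @param peaks data.frame with `center`, `width` (Gaussian sd, in
#'   samples) and `area`; centers must be ordered and lie after the dead
#'   volume.
#' @param n trace length in samples.
#' @param dead_volume number of leading flat samples.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return data.frame (position, a260) of class `crac_gradient`; truth in
#'   `attr(, "truth")`.
#' @export
simulate_polysome_profile <- function(peaks, n = 600, dead_volume = 50,
                                      noise_sd = 0, seed = 1) {
  if (nrow(peaks) > 1) stopifnot(!is.unsorted(peaks$center))
  set.seed(seed)
  x <- seq_len(n)
  v <- numeric(n)
  for (i in seq_len(nrow(peaks))) {
    v <- v + peaks$area[i] * dnorm(x, peaks$center[i], peaks$width[i])
  }
  v[seq_len(dead_volume)] <- 0
  if (noise_sd > 0) v <- pmax(v + rnorm(n, 0, noise_sd), 0)
  out <- data.frame(position = x, a260 = v)
  class(out) <- c("crac_gradient", "data.frame")
  attr(out, "truth") <- list(start = dead_volume + 1L, peaks = peaks,
                             dead_volume = dead_volume, noise_sd = noise_sd)
  out
}

#' Align a gradient trace to its start and normalize the area to 1
#'
#' The leading dead-volume segment is removed: the start is the first
#' sample exceeding baseline + k x noise, where baseline and noise are
#' the mean and sd of the first `baseline_frac` of the trace. The
#' remaining trace is normalized so its values sum to 1.
#'
#' @param profile data.frame (position, a260) or numeric vector.
#' @param k noise multiplier for start detection.
#' @param baseline_frac fraction of the trace used for the baseline
#'   estimate.
#' @return normalized `crac_gradient`; detected start index in
#'   `attr(, "start")`.
#' @export
align_and_normalize <- function(profile, k = 5, baseline_frac = 0.05) {
  v <- if (is.data.frame(profile)) profile$a260 else as.numeric(profile)
  stopifnot(length(v) > 0)
  nb <- max(2L, floor(length(v) * baseline_frac))
  base <- mean(v[seq_len(nb)])
  noise <- stats::sd(v[seq_len(nb)])
  thr <- base + k * noise
  start <- which(v > thr)[1]
  if (is.na(start)) stop("no start detected: trace is flat")
  out <- v[start:length(v)]
  out <- out / sum(out)
  res <- data.frame(position = seq_along(out), a260 = out)
  class(res) <- c("crac_gradient", "data.frame")
  attr(res, "start") <- start
  res
}

#' Sliding-window median smoothing of a gradient trace
#'
#' Centered running median of odd `window` (default 5 samples); edges use
#' symmetrically shrinking windows (so the window stays centered and odd,
#' and monotone traces pass unchanged). Single-sample spikes are removed.
#'
#' @param profile `crac_gradient` or numeric vector.
#' @param window odd window width.
#' @return smoothed object of the same shape.
#' @export
median_smooth <- function(profile, window = 5) {
  if (window %% 2 != 1) stop("window must be odd")
  v <- if (is.data.frame(profile)) profile$a260 else as.numeric(profile)
  n <- length(v)
  if (window > n) stop("window longer than trace")
  sm <- as.numeric(stats::runmed(v, window, endrule = "keep"))
  h <- (window - 1) %/% 2
  for (i in seq_len(min(h, n))) {
    hi <- i - 1L                      # symmetric shrunk half-window
    sm[i] <- median(v[(i - hi):(i + hi)])
    j <- n - i + 1L
    sm[j] <- median(v[(j - hi):(j + hi)])
  }
  if (is.data.frame(profile)) {
    profile$a260 <- sm
    profile
  } else sm
}

#' Quantify gradient peaks as sums over annotated boundaries
#'
#' @param profile `crac_gradient` or numeric vector (typically aligned,
#'   normalized and smoothed).
#' @param boundaries data.frame with `name`, `start`, `end` (sample
#'   indices, inclusive); intervals must not overlap and must lie within
#'   the trace.
#' @return named numeric vector of per-peak sums.
#' @export
peak_quantify <- function(profile, boundaries) {
  v <- if (is.data.frame(profile)) profile$a260 else as.numeric(profile)
  b <- boundaries[order(boundaries$start), , drop = FALSE]
  stopifnot(all(b$start <= b$end))
  if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
    stop("overlapping peak boundaries")
  }
  if (any(b$start < 1) || any(b$end > length(v))) {
    stop("boundaries outside the trace")
  }
  setNames(vapply(seq_len(nrow(b)), function(i) {
    sum(v[b$start[i]:b$end[i]])
  }, numeric(1)), b$name)
}

#' Read / write two-column gradient trace TSVs
#'
#' @param path TSV with columns position, a260.
#' @export
read_gradient_tsv <- function(path) {
  df <- read.delim(path)
  names(df)[1:2] <- c("position", "a260")
  class(df) <- c("crac_gradient", "data.frame")
  df
}

#' @rdname read_gradient_tsv
#' @param profile gradient data.frame to write.
#' @export
write_gradient_tsv <- function(profile, path) {
  write.table(as.data.frame(profile)[, c("position", "a260")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
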