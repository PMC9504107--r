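#' Segment a joint-angle series into fixed overlapping windows
#'
#' Fixed-length windows of `window_ms` milliseconds with fractional overlap
#' between neighbors (default 50%, i.e. stride of half a window); the
#' trailing partial window is dropped. For `N` samples and a `w`-sample
#' window the count is `floor((N - w) / (w * (1 - overlap))) + 1`.
#'
#' @param series a `"joint_angles"` data frame (or any data frame with a `t`
#'   column and numeric channels).
#' @param window_ms window length in milliseconds (default 1000).
#' @param overlap fractional overlap in `[0, 1)` between adjacent windows
#'   (default 0.5).
#' @param rate sampling rate in Hz; default inferred from `t`.
#' @return list of windows, each a numeric matrix (samples x channels) with
#'   attributes `t0` (start time) and `rate`.
#' @export
segment_windows <- function(series, window_ms = 1000, overlap = 0.5, rate = NULL) {
  chans <- angle_channels(series)
  x <- as.matrix(series[, chans, drop = FALSE])
  N <- nrow(x)
  if (is.null(rate)) {
    if (N < 2L) pk_stop("posturekit_too_short", "cannot infer the rate from one sample")
    rate <- 1 / stats::median(diff(series$t))
  }
  w <- round(rate * window_ms / 1000)
  if (w < 2L) pk_stop("posturekit_too_short", "window shorter than two samples")
  if (N < w)
    pk_stop("posturekit_too_short",
            sprintf("series of %d samples is shorter than one %d-sample window", N, w))
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  starts <- seq.int(1L, N - w + 1L, by = stride)
  lapply(starts, function(s) {
    win <- x[s:(s + w - 1L), , drop = FALSE]
    attr(win, "t0") <- series$t[s]
    attr(win, "rate") <- rate
    win
  })
}

#' Names of the 23 per-channel window features
#'
#' @return character vector of length 23.
#' @export
feature_names <- function() {
  c("mean", "med", "std", "mad", "quantile1", "quantile2", "iqr",
    "skewness", "kurtosis", "var", "entropy", "spectral_entropy",
    "maxfreq", "maxval", "maxratio", "peak", "height", "position",
    paste0("spwf", 1:5))
}

#' Extract the 23-feature vector from one window
#'
#' Twelve time-domain features (mean, median, standard deviation, median
#' absolute deviation, 25th and 75th percentiles, interquartile range,
#' skewness, excess kurtosis, variance, Shannon entropy of a 16-bin
#' histogram, spectral entropy of the normalized one-sided power spectrum),
#' six frequency/autoregressive scalars (dominant frequency, its power, its
#' share of total power, the main peak of the order-4 Yule-Walker AR
#' spectrum, and the height and frequency of its second peak) and the power
#' in five adjacent equal-width bands spanning 0-10 Hz.
#'
#' Degenerate (constant) windows return 0 for skewness, kurtosis, both
#' entropies and every spectral quantity, so no feature is ever `NaN`.
#'
#' @param window numeric vector, or a matrix from [segment_windows()]
#'   (features are computed per column and concatenated with
#'   `channel_feature` names).
#' @param rate sampling rate in Hz (taken from the window attribute when
#'   present).
#' @param ar_order autoregression order (default 4).
#' @param n_bands number of spectral power bands (default 5).
#' @param band_top upper edge of the banded range, Hz (default 10).
#' @return named numeric vector, 23 values per channel.
#' @export
extract_features <- function(window, rate = NULL, ar_order = 4,
                             n_bands = 5, band_top = 10) {
  if (is.null(rate)) rate <- attr(window, "rate")
  if (is.null(rate)) pk_stop("posturekit_malformed_trace", "a sampling rate is required")
  if (is.matrix(window)) {
    chans <- colnames(window) %||% paste0("ch", seq_len(ncol(window)))
    out <- lapply(seq_len(ncol(window)), function(j)
      extract_features(window[, j], rate, ar_order, n_bands, band_top))
    v <- unlist(out, use.names = FALSE)
    names(v) <- as.vector(t(outer(chans, feature_names(), paste, sep = "_")))
    return(v)
  }
  x <- as.numeric(window)
  n <- length(x)
  if (n < 2L) pk_stop("posturekit_too_short", "window must hold at least two samples")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m <- mean(x)
  dev <- x - m
  m2 <- mean(dev^2)
  feats <- c(
    mean = m, med = qs[2], std = stats::sd(x),
    mad = stats::median(abs(x - qs[2])),
    quantile1 = qs[1], quantile2 = qs[3], iqr = qs[3] - qs[1],
    skewness = if (m2 > 0) mean(dev^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(dev^4) / m2^2 - 3 else 0,
    var = stats::var(x),
    entropy = hist_entropy(x),
    spectral_entropy = 0
  )
  spec <- c(maxfreq = 0, maxval = 0, maxratio = 0, peak = 0, height = 0, position = 0,
            stats::setNames(numeric(n_bands), paste0("spwf", seq_len(n_bands))))
  if (m2 > 0) {
    P <- one_sided_power(dev)
    freqs <- seq_along(P) * rate / n
    tot <- sum(P)
    p <- P / tot
    pk <- which.max(P)
    feats["spectral_entropy"] <- -sum(ifelse(p > 0, p * log(p), 0))
    spec["maxfreq"] <- freqs[pk]
    spec["maxval"] <- P[pk]
    spec["maxratio"] <- P[pk] / tot
    spec[c("peak", "height", "position")] <- ar_peaks(x, rate, ar_order)
    edges <- seq(0, band_top, length.out = n_bands + 1)
    for (b in seq_len(n_bands))
      spec[paste0("spwf", b)] <- sum(P[freqs > edges[b] & freqs <= edges[b + 1]])
  }
  c(feats, spec)
}

# Shannon entropy (natural log) of a 16-bin histogram over the window range.
hist_entropy <- function(x, bins = 16) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(0)
  counts <- tabulate(pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins)), bins)
  p <- counts / length(x)
  -sum(ifelse(p > 0, p * log(p), 0))
}

# One-sided power spectrum of a (de-meaned) window, DC excluded.
one_sided_power <- function(x) {
  n <- length(x)
  Mod(stats::fft(x))[2:(n %/% 2 + 1)]^2
}

# Main-peak value plus second-peak height and frequency of the order-p
# Yule-Walker AR power spectrum evaluated on a 257-point grid up to Nyquist.
ar_peaks <- function(x, rate, p = 4) {
  fit <- tryCatch(stats::ar.yw(x, aic = FALSE, order.max = p, demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || fit$var.pred <= 0) return(c(0, 0, 0))
  f <- seq(0, rate / 2, length.out = 257)
  a <- fit$ar
  denom <- abs(1 - sapply(f, function(fi)
    sum(a * exp(-2i * pi * fi * seq_along(a) / rate))))^2
  psd <- fit$var.pred / pmax(denom, 1e-300)
  # local maxima (interior points, plus the boundary grid points)
  d <- diff(psd)
  locmax <- c(d[1] < 0, d[-length(d)] > 0 & d[-1] < 0, d[length(d)] > 0)
  idx <- which(locmax)
  if (!length(idx)) idx <- which.max(psd)
  ord <- idx[order(psd[idx], decreasing = TRUE)]
  peak <- psd[ord[1]]
  if (length(ord) >= 2L) c(peak, psd[ord[2]], f[ord[2]]) else c(peak, 0, 0)
}

#' Build a labeled feature table from per-task joint-angle series
#'
#' Windows every series of every task ([segment_windows()]), extracts the
#' 23 features per channel ([extract_features()]) and stacks the windows
#' into one table with the integer task label (1 = reciting words,
#' 2 = reading comprehension, 3 = browsing, 4 = listening to music) in the
#' first column.
#'
#' @param series_by_class list of length <= 4 indexed by task label; each
#'   element one `"joint_angles"` series or a list of them.
#' @param labels integer labels matching `series_by_class` (default
#'   `seq_along(series_by_class)`).
#' @param window_ms,overlap windowing parameters, see [segment_windows()].
#' @param ... passed to [extract_features()].
#' @return a data frame: `label` (factor) then `23 * channels` feature
#'   columns, one row per window.
#' @export
build_dataset <- function(series_by_class, labels = seq_along(series_by_class),
                          window_ms = 1000, overlap = 0.5, ...) {
  if (!length(series_by_class))
    pk_stop("posturekit_empty_class", "no classes supplied")
  if (any(!labels %in% 1:4))
    pk_stop("posturekit_empty_class", "task labels must lie in 1..4")
  rows <- list()
  for (ci in seq_along(series_by_class)) {
    group <- series_by_class[[ci]]
    if (is.data.frame(group)) group <- list(group)
    if (!length(group))
      pk_stop("posturekit_empty_class",
              sprintf("class %d has no series", labels[ci]))
    feats <- list()
    for (s in group) {
      wins <- segment_windows(s, window_ms = window_ms, overlap = overlap)
      feats <- c(feats, lapply(wins, extract_features, ...))
    }
    block <- do.call(rbind, feats)
    rows[[ci]] <- data.frame(label = rep(labels[ci], nrow(block)), block,
                             check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = sort(unique(labels)))
  rownames(out) <- NULL
  out
}
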