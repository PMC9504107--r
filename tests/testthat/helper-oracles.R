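# Independent oracles, deliberately coded via different routes than the
# package: 3x3 rotation matrices for the quaternion algebra, and formula-level
# reimplementations of the window features.

# quaternion (scalar first) -> rotation matrix
oracle_quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, byrow = TRUE)
}

# rotation matrix -> quaternion (Shepperd-style, canonical sign)
oracle_mat_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q <- q / sqrt(sum(q^2))
  nz <- which(abs(q) > 0)[1]
  if (q[nz] < 0) q <- -q
  q
}

oracle_rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
oracle_ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
oracle_rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)

random_quat <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  nz <- which(abs(q) > 0)[1]
  if (q[nz] < 0) q <- -q
  quat(q)
}

# -- feature oracle: formula-level reimplementation of the 23 features -------

oracle_features <- function(x, rate, ar_order = 4, n_bands = 5, band_top = 10) {
  n <- length(x)
  med <- stats::median(x)
  q1 <- stats::quantile(x, 0.25, names = FALSE)
  q3 <- stats::quantile(x, 0.75, names = FALSE)
  const <- stats::var(x) == 0
  # histogram entropy via cut()
  hent <- if (const) 0 else {
    br <- seq(min(x), max(x), length.out = 17)
    p <- as.numeric(table(cut(x, br, include.lowest = TRUE))) / n
    -sum(p[p > 0] * log(p[p > 0]))
  }
  out <- c(
    mean = mean(x), med = med, std = stats::sd(x),
    mad = stats::mad(x, constant = 1),
    quantile1 = q1, quantile2 = q3, iqr = stats::IQR(x),
    skewness = if (const) 0 else e1071::skewness(x, type = 1),
    kurtosis = if (const) 0 else e1071::kurtosis(x, type = 1),
    var = stats::var(x)
  )
  spec <- stats::setNames(numeric(13 + n_bands - 5),
                          c("entropy", "spectral_entropy", "maxfreq", "maxval",
                            "maxratio", "peak", "height", "position",
                            paste0("spwf", seq_len(n_bands))))
  spec["entropy"] <- hent
  if (!const) {
    xc <- x - mean(x)
    kmax <- n %/% 2
    P <- vapply(seq_len(kmax), function(k) {
      ph <- -2 * pi * k * (0:(n - 1)) / n
      sum(xc * cos(ph))^2 + sum(xc * sin(ph))^2
    }, 1)
    freqs <- seq_len(kmax) * rate / n
    p <- P / sum(P)
    spec["spectral_entropy"] <- -sum(p[p > 0] * log(p[p > 0]))
    spec["maxfreq"] <- freqs[which.max(P)]
    spec["maxval"] <- max(P)
    spec["maxratio"] <- max(P) / sum(P)
    # Yule-Walker by hand: solve the autocorrelation system
    r <- stats::acf(x, lag.max = ar_order, plot = FALSE, demean = TRUE,
                    type = "covariance")$acf[, 1, 1]
    # ar.yw uses denominator n for the autocovariances
    Rm <- stats::toeplitz(r[1:ar_order])
    a <- solve(Rm, r[2:(ar_order + 1)])
    vp <- (r[1] - sum(a * r[2:(ar_order + 1)])) * n / (n - ar_order - 1)
    f <- seq(0, rate / 2, length.out = 257)
    psd <- vp / pmax(vapply(f, function(fi)
      Mod(1 - sum(a * exp(-2i * pi * fi * seq_len(ar_order) / rate)))^2, 1), 1e-300)
    d <- diff(psd)
    locmax <- c(d[1] < 0, d[-length(d)] > 0 & d[-1] < 0, d[length(d)] > 0)
    idx <- which(locmax)
    if (!length(idx)) idx <- which.max(psd)
    ord <- idx[order(psd[idx], decreasing = TRUE)]
    spec["peak"] <- psd[ord[1]]
    if (length(ord) >= 2) {
      spec["height"] <- psd[ord[2]]
      spec["position"] <- f[ord[2]]
    }
    edges <- seq(0, band_top, length.out = n_bands + 1)
    for (b in seq_len(n_bands))
      spec[paste0("spwf", b)] <- sum(P[freqs > edges[b] & freqs <= edges[b + 1]])
  }
  c(out, spec)
}
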