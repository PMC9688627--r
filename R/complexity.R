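# Six nonlinear complexity features, implemented from first principles.
# All entropies use base-2 logarithms; normalized variants lie in [0,1].

.xlog2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p)) + 0     # + 0 normalises IEEE negative zero
}

#' Feature hyperparameters
#'
#' Defaults follow common practice for short EEG windows: permutation /
#' SVD embeddings of order 3 with delay 1, sample entropy with m = 2 and
#' r = 0.2 x SD of the window (Chebyshev distance), Higuchi kmax = 10,
#' Welch PSD for spectral entropy, DFA box sizes log-spaced between 4
#' and n/4.
#'
#' @param permOrder,permDelay permutation-entropy embedding order/delay.
#' @param sampOrder sample-entropy template length m.
#' @param sampRFactor tolerance r as a multiple of the window SD.
#' @param svdOrder,svdDelay SVD-entropy embedding order/delay.
#' @param higuchiKmax maximal segment scale for Higuchi's method.
#' @return a list of class `FeatureParams`.
#' @export
featureParams <- function(permOrder = 3, permDelay = 1,
                          sampOrder = 2, sampRFactor = 0.2,
                          svdOrder = 3, svdDelay = 1,
                          higuchiKmax = 10) {
  stopifnot(permOrder >= 2, sampOrder >= 1, svdOrder >= 2,
            higuchiKmax >= 2, sampRFactor > 0, permDelay >= 1,
            svdDelay >= 1)
  structure(list(permOrder = permOrder, permDelay = permDelay,
                 sampOrder = sampOrder, sampRFactor = sampRFactor,
                 svdOrder = svdOrder, svdDelay = svdDelay,
                 higuchiKmax = higuchiKmax),
            class = "FeatureParams")
}

#' Canonical feature names, in the conventional combination order
#' @return character vector of the six feature names.
#' @export
featureNames <- function() {
  c("PermEnt", "SampEnt", "SVDEnt", "DFA", "SpectEnt", "Higuchi")
}

.embed <- function(x, order, delay) {
  n <- length(x) - (order - 1) * delay
  E <- matrix(0, n, order)
  for (j in seq_len(order)) E[, j] <- x[seq_len(n) + (j - 1) * delay]
  E
}

#' Permutation entropy
#'
#' Shannon entropy (base 2) of the distribution of ordinal patterns of
#' `m` consecutive (delay-spaced) values. Ties are broken by order of
#' appearance: of two equal values the earlier one ranks lower. Patterns
#' are identified by their Lehmer code.
#'
#' @param x numeric vector, length >= m * tau + 1.
#' @param m embedding order (>= 2).
#' @param tau embedding delay.
#' @param normalized divide by log2(m!) so the result lies in [0,1].
#' @return entropy in bits (or normalized, unitless).
#' @examples
#' permEntropy(c(4, 7, 9, 10, 6, 11, 3), m = 2, normalized = FALSE)
#' @export
permEntropy <- function(x, m = 3, tau = 1, normalized = TRUE) {
  n <- length(x)
  if (n < m * tau + 1) stop("signal too short for permutation entropy")
  E <- .embed(x, m, tau)
  # Lehmer code: l_j = #{k > j : v_k < v_j}; ties keep appearance order
  code <- rep(0, nrow(E))
  w <- rev(cumprod(c(1, seq_len(m - 1))))     # (m-1)!, ..., 1!, 0!
  for (j in seq_len(m - 1)) {
    lj <- rep(0, nrow(E))
    for (k in (j + 1):m) lj <- lj + (E[, k] < E[, j])
    code <- code + lj * w[j]
  }
  p <- tabulate(code + 1L, nbins = factorial(m)) / nrow(E)
  H <- .xlog2(p)
  if (normalized) H / log2(factorial(m)) else H
}

#' Sample entropy
#'
#' -ln(A/B) where B is the number of template pairs of length `m` within
#' Chebyshev distance `r` and A the number also matching at length
#' m + 1; self-matches are excluded. Returns NaN (with a warning) when
#' A or B is zero, where the statistic is undefined.
#'
#' @param x numeric vector, length >= m + 2.
#' @param m template length.
#' @param r tolerance (same units as `x`); defaults to 0.2 x SD(x).
#'   A constant signal (SD = 0) is a degenerate input and raises an
#'   error.
#' @return sample entropy (natural log), or NaN if undefined.
#' @export
sampleEntropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) < m + 2) stop("signal too short for sample entropy")
  if (!is.finite(r) || r <= 0)
    stop("degenerate input: tolerance r must be positive ",
         "(constant signal has SD = 0)")
  cnt <- .sampenCounts(as.numeric(x), as.integer(m), as.numeric(r))
  if (cnt[1] == 0 || cnt[2] == 0) {
    warning("sample entropy undefined (no matching template pairs)")
    return(NaN)
  }
  -log(cnt[2] / cnt[1])
}

#' Welch power spectral density
#'
#' Hann-windowed segments of length min(256, n) with 50% overlap, each
#' mean-detrended; one-sided PSD.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nperseg segment length.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welchPSD <- function(x, fs, nperseg = min(256L, length(x))) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1) / (nperseg - 1))
  nf <- nperseg %/% 2L + 1L
  acc <- rep(0, nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * sum(win^2))
  # double the interior bins for a one-sided spectrum
  if (nf > 2) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd)
}

#' Spectral entropy
#'
#' Shannon entropy (base 2) of the Welch power spectral density
#' normalized to a probability distribution; divided by log2 of the
#' number of frequency bins when `normalized`.
#'
#' @param x numeric vector (not all zero).
#' @param fs sampling rate (Hz).
#' @param normalized normalize to [0, 1].
#' @return spectral entropy.
#' @export
spectralEntropy <- function(x, fs, normalized = TRUE) {
  if (all(x == 0)) stop("all-zero signal has no spectrum")
  w <- welchPSD(x, fs)
  p <- w$psd / sum(w$psd)
  H <- .xlog2(p)
  if (normalized) H / log2(length(p)) else H
}

#' Singular-value-decomposition entropy
#'
#' Entropy (base 2) of the singular values of the delay-embedding
#' matrix, normalized to sum to one; divided by log2(order) when
#' `normalized`.
#'
#' @param x numeric vector, length >= order * delay.
#' @param order embedding dimension.
#' @param delay embedding delay.
#' @param normalized normalize to [0, 1].
#' @return SVD entropy.
#' @export
svdEntropy <- function(x, order = 3, delay = 1, normalized = TRUE) {
  if (length(x) < order * delay) stop("signal too short for SVD entropy")
  E <- .embed(x, order, delay)
  s <- svd(E, nu = 0, nv = 0)$d
  p <- s / sum(s)
  H <- .xlog2(p)
  if (normalized) H / log2(order) else H
}

#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-removed signal, splits the profile into
#' non-overlapping boxes of size n, removes a linear trend per box, and
#' returns the slope of log RMS fluctuation versus log box size.
#' White noise gives alpha ~ 0.5, Brownian motion ~ 1.5.
#'
#' @param x numeric vector, length >= 64.
#' @param windowSizes integer box sizes; default log-spaced from 4 to
#'   length(x)/4 (10 sizes).
#' @return the scaling exponent alpha.
#' @export
dfaExponent <- function(x, windowSizes = NULL) {
  n <- length(x)
  if (n < 64) stop("signal too short for DFA (need >= 64 samples)")
  if (is.null(windowSizes))
    windowSizes <- unique(round(exp(seq(log(4), log(n / 4),
                                        length.out = 10))))
  y <- cumsum(x - mean(x))
  Fn <- vapply(windowSizes, function(s) {
    nb <- n %/% s
    Y <- matrix(y[seq_len(nb * s)], nrow = s)
    t <- seq_len(s)
    tc <- t - mean(t)
    # per-box linear detrend in closed form
    beta <- colSums(Y * tc) / sum(tc^2)
    alpha <- colMeans(Y)
    res <- Y - outer(tc, beta) -
      matrix(alpha, s, nb, byrow = TRUE)
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- Fn > 0
  lx <- log(windowSizes[ok])
  ly <- log(Fn[ok])
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Higuchi fractal dimension
#'
#' Builds Higuchi's reconstructed curve lengths L(k) for k = 1..kmax
#' (averaged over offsets, standard normalisation) and returns the
#' negative slope of log L(k) versus log k. Smooth curves give ~ 1,
#' white noise ~ 2.
#'
#' @param x numeric vector, length >= 2 * kmax.
#' @param kmax maximal scale.
#' @return fractal dimension estimate.
#' @export
higuchiFD <- function(x, kmax = 10) {
  if (length(x) < 2 * kmax) stop("signal too short for Higuchi FD")
  L <- .higuchiLk(as.numeric(x), as.integer(kmax))
  lx <- log(seq_len(kmax))
  ly <- log(L)
  -sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

.channelFeatures1 <- function(x, params) {
  c(PermEnt = permEntropy(x, params$permOrder, params$permDelay),
    SampEnt = sampleEntropy(x, params$sampOrder,
                            params$sampRFactor * sd(x)),
    SVDEnt = svdEntropy(x, params$svdOrder, params$svdDelay),
    DFA = dfaExponent(x),
    SpectEnt = spectralEntropy(x, fs = 200),
    Higuchi = higuchiFD(x, params$higuchiKmax))
}

#' Extract the six nonlinear features from a window vector
#'
#' Each feature is computed per electrode row, then arithmetically
#' averaged across the selected electrodes; the class label is
#' propagated.
#'
#' @param window a window vector from [vectorize()] (list with `x`, `y`).
#' @param electrodes electrodes to use (default: all rows of the
#'   window); matched case-insensitively.
#' @param params a [featureParams()] list.
#' @return list with `values` (named numeric of length 6, in
#'   [featureNames()] order) and `y`.
#' @export
extractFeatures <- function(window, electrodes = NULL,
                            params = featureParams()) {
  x <- window$x
  if (is.null(electrodes)) {
    sel <- seq_len(nrow(x))
  } else {
    sel <- match(toupper(canonicalizeLabels(electrodes)),
                 toupper(rownames(x)))
    if (anyNA(sel))
      stop("electrode(s) not present in window: ",
           paste(electrodes[is.na(sel)], collapse = ", "))
  }
  vals <- vapply(sel, function(i) {
    tryCatch(.channelFeatures1(x[i, ], params),
             error = function(e)
               stop("channel ", rownames(x)[i], ": ",
                    conditionMessage(e), call. = FALSE))
  }, numeric(6))
  list(values = rowMeans(vals), y = window$y)
}

#' Per-channel features for a whole cohort
#'
#' Runs the preprocessing chain (filter, crop at `span` seconds after
#' the trigger, resample to 200 Hz, window into 1 s vectors) and
#' computes the six features for every channel of every window. The
#' result is the single table all selection stages operate on: averaging
#' subsets of its channels reproduces region- or montage-level feature
#' vectors without recomputation.
#'
#' @param cohort list of [EEGRecording-class] objects.
#' @param span seconds after the trigger to use.
#' @param params a [featureParams()] list.
#' @param filter apply [filterChain()] first (default TRUE).
#' @return data.frame with columns `subject`, `window`, `channel`, `y`
#'   and one column per feature.
#' @export
channelFeatures <- function(cohort, span, params = featureParams(),
                            filter = TRUE) {
  rows <- lapply(cohort, function(rec) {
    if (filter) rec <- filterChain(rec)
    rec <- cropAndResample(rec, span)
    wins <- vectorize(rec)
    do.call(rbind, lapply(wins, function(w) {
      f <- vapply(seq_len(nrow(w$x)), function(i)
        .channelFeatures1(w$x[i, ], params), numeric(6))
      df <- as.data.frame(t(f))
      df$subject <- w$subject
      df$window <- w$window
      df$channel <- rownames(w$x)
      df$y <- w$y
      df
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subject", "window", "channel", "y", featureNames())]
}

#' Average per-channel features over an electrode set
#'
#' @param chanFeat output of [channelFeatures()].
#' @param electrodes electrodes to average over (case-insensitive);
#'   default all channels in the table.
#' @param features which features to keep (default all six).
#' @return data.frame with `subject`, `window`, `y` and one column per
#'   feature (electrode-averaged).
#' @export
featureVectors <- function(chanFeat, electrodes = NULL,
                           features = featureNames()) {
  if (!is.null(electrodes)) {
    keep <- toupper(chanFeat$channel) %in%
      toupper(canonicalizeLabels(electrodes))
    missing <- setdiff(toupper(canonicalizeLabels(electrodes)),
                       unique(toupper(chanFeat$channel)))
    if (length(missing))
      stop("electrode(s) absent from feature table: ",
           paste(missing, collapse = ", "))
    chanFeat <- chanFeat[keep, , drop = FALSE]
  }
  agg <- aggregate(chanFeat[, features, drop = FALSE],
                   by = list(subject = chanFeat$subject,
                             window = chanFeat$window,
                             y = chanFeat$y),
                   FUN = mean)
  agg <- agg[order(agg$subject, agg$window), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("subject", "window", "y", features)]
}

#' Write a long-format feature table CSV
#'
#' One row per (subject, window, feature): columns `subject_id`,
#' `window_index`, `feature`, `value`, `y`.
#'
#' @param featVec output of [featureVectors()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(featVec, path) {
  feats <- intersect(featureNames(), names(featVec))
  long <- do.call(rbind, lapply(feats, function(f)
    data.frame(subject_id = featVec$subject,
               window_index = featVec$window,
               feature = f, value = featVec[[f]], y = featVec$y,
               stringsAsFactors = FALSE)))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
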