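# Independent brute-force oracles for the complexity estimators and the
# AUC. Deliberately literal (explicit loops, reference primitives), so
# they share no code path with the package implementations.

oraclePermEnt <- function(x, m = 3, tau = 1, normalized = TRUE) {
  n <- length(x) - (m - 1) * tau
  pats <- character(n)
  for (i in seq_len(n)) {
    v <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(v), collapse = "-")  # stable: ties by position
  }
  p <- table(pats) / n
  H <- -sum(p * log2(p))
  if (normalized) H / log2(factorial(m)) else H
}

oracleSampEn <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  N <- n - m
  A <- 0; B <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        dm1 <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (dm1 <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

oracleSVDEnt <- function(x, order = 3, delay = 1, normalized = TRUE) {
  n <- length(x) - (order - 1) * delay
  H <- matrix(NA_real_, n, order)
  for (i in seq_len(n)) for (j in seq_len(order))
    H[i, j] <- x[i + (j - 1) * delay]
  s <- svd(H)$d
  p <- s / sum(s)
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  if (normalized) ent / log2(order) else ent
}

oracleHiguchi <- function(x, kmax = 10) {
  n <- length(x)
  L <- numeric(kmax)
  for (k in 1:kmax) {
    Lmk <- numeric(k)
    for (m in 1:k) {
      nm <- floor((n - m) / k)
      s <- 0
      for (i in 1:nm) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lmk[m] <- s * (n - 1) / (nm * k) / k
    }
    L[k] <- mean(Lmk)
  }
  fit <- lm(log(L) ~ log(1:kmax))
  -unname(coef(fit)[2])
}

oracleDFA <- function(x, windowSizes = NULL) {
  n <- length(x)
  if (is.null(windowSizes))
    windowSizes <- unique(round(exp(seq(log(4), log(n / 4),
                                        length.out = 10))))
  y <- cumsum(x - mean(x))
  Fn <- numeric(length(windowSizes))
  for (si in seq_along(windowSizes)) {
    s <- windowSizes[si]
    nb <- floor(n / s)
    res2 <- numeric(0)
    for (b in 1:nb) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      t <- 1:s
      fit <- lm(seg ~ t)
      res2 <- c(res2, residuals(fit)^2)
    }
    Fn[si] <- sqrt(mean(res2))
  }
  unname(coef(lm(log(Fn) ~ log(windowSizes)))[2])
}

# Welch PSD entropy computed with an independent, literal segment loop
oracleSpectEnt <- function(x, fs, normalized = TRUE) {
  n <- length(x)
  nseg <- min(256, n)
  win <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1)) / (nseg - 1)))
  starts <- seq(1, n - nseg + 1, by = floor(nseg / 2))
  nf <- floor(nseg / 2) + 1
  psd <- rep(0, nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- seg - mean(seg)
    ft <- fft(seg * win)
    psd <- psd + (Mod(ft[1:nf]))^2
  }
  psd <- psd / (length(starts) * fs * sum(win^2))
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  p <- psd / sum(psd)
  p <- p[p > 0]
  H <- -sum(p * log2(p))
  if (normalized) H / log2(nf) else H
}

oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (a in pos) for (b in neg)
    conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(pos) * length(neg))
}
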