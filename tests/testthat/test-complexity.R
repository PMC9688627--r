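# The six nonlinear estimators: brute-force oracle agreement, analytic
# limits, and the electrode-averaging contract.

test_that("every estimator matches its brute-force oracle on random signals", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(40:120, 1)
    x <- rnorm(n)
    expect_equal(permEntropy(x, 3, 1), oraclePermEnt(x, 3, 1),
                 tolerance = 1e-12)
    expect_equal(svdEntropy(x, 3, 1), oracleSVDEnt(x, 3, 1),
                 tolerance = 1e-10)
    expect_equal(higuchiFD(x, 8), oracleHiguchi(x, 8),
                 tolerance = 1e-10)
    r <- 0.2 * sd(x)
    expect_identical(sampleEntropy(x, 2, r), oracleSampEn(x, 2, r))
  }
  for (i in 1:10) {
    x <- rnorm(300)
    expect_equal(dfaExponent(x), oracleDFA(x), tolerance = 1e-10)
    expect_equal(spectralEntropy(x, 200), oracleSpectEnt(x, 200),
                 tolerance = 1e-10)
  }
})

test_that("permutation entropy: monotone sequence, hand count, uniform limit", {
  expect_equal(permEntropy(1:100, 3), 0)
  expect_equal(permEntropy(seq(5, 1, length.out = 30), 4), 0)
  # (4,7,9,10,6,11,3): 4 ascending and 2 descending pairs of 6
  expect_equal(permEntropy(c(4, 7, 9, 10, 6, 11, 3), m = 2,
                           normalized = FALSE),
               -(4 / 6) * log2(4 / 6) - (2 / 6) * log2(2 / 6),
               tolerance = 1e-12)
  set.seed(7)
  expect_equal(permEntropy(runif(100000), 3), 1, tolerance = 0.01)
})

test_that("permutation entropy breaks ties by order of appearance", {
  # constant signal: a single ordinal pattern, entropy 0
  expect_equal(permEntropy(rep(1, 50), 3), 0)
  expect_error(permEntropy(c(1, 2), m = 3), "too short")
})

test_that("sample entropy limits and degenerate inputs", {
  expect_error(sampleEntropy(rep(2, 100)), "degenerate")
  # perfectly predictable alternation: A == B, entropy 0
  alt <- rep(c(0, 1), 50)
  expect_equal(sampleEntropy(alt, 2, 0.2 * sd(alt)), 0)
  expect_error(sampleEntropy(c(1, 2, 3), m = 2), "too short")
  # no matches at all -> undefined, flagged (not silently 0)
  expect_warning(v <- sampleEntropy(c(1, 10, 100, 1000, 1e4, 1e5),
                                    m = 2, r = 1e-6), "undefined")
  expect_true(is.nan(v))
})

test_that("spectral entropy: sine and white-noise limits", {
  t <- (0:9999) / 200
  expect_lt(spectralEntropy(sin(2 * pi * 10 * t), 200), 0.2)
  set.seed(8)
  expect_equal(spectralEntropy(rnorm(100000), 200), 1, tolerance = 0.02)
  # an equal-power second tone adds exactly one bit of spectral
  # uncertainty (both tones on Welch bin centres: k * 200 / 256)
  one <- sin(2 * pi * 25 * t)
  two <- one + sin(2 * pi * 50 * t)
  expect_equal(spectralEntropy(two, 200, normalized = FALSE) -
                 spectralEntropy(one, 200, normalized = FALSE), 1,
               tolerance = 0.1)
  expect_error(spectralEntropy(rep(0, 100), 200), "all-zero")
})

test_that("SVD entropy: constant and isotropic limits", {
  expect_equal(svdEntropy(rep(3, 100)), 0, tolerance = 1e-10)
  set.seed(9)
  expect_gte(svdEntropy(rnorm(10000), 3, 1), 0.95)
  expect_error(svdEntropy(c(1, 2), order = 3), "too short")
})

test_that("DFA recovers theoretical exponents", {
  set.seed(10)
  expect_equal(mean(replicate(5, dfaExponent(rnorm(10000)))), 0.5,
               tolerance = 0.05)
  expect_equal(mean(replicate(5, dfaExponent(cumsum(rnorm(10000))))),
               1.5, tolerance = 0.1)
  expect_gte(dfaExponent(seq(0, 1, length.out = 1000)), 1.8)
  expect_error(dfaExponent(rnorm(50)), "too short")
})

test_that("Higuchi FD: smooth-curve and white-noise limits", {
  expect_equal(higuchiFD(seq(0, 5, length.out = 1000)), 1,
               tolerance = 0.02)
  set.seed(11)
  expect_equal(mean(replicate(5, higuchiFD(rnorm(10000)))), 2,
               tolerance = 0.1)
  expect_error(higuchiFD(rnorm(10), kmax = 10), "too short")
})

test_that("normalized entropies stay in [0,1] and finite at n = 200", {
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(200)
    v <- c(permEntropy(x), svdEntropy(x), spectralEntropy(x, 200))
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0 & v <= 1))
    expect_true(is.finite(dfaExponent(x)))
    expect_true(is.finite(higuchiFD(x)))
    expect_true(is.finite(sampleEntropy(x)))
  }
})

test_that("spectral entropy falls and DFA rises monotonically in beta", {
  set.seed(13)
  betas <- seq(0, 2, by = 0.25)
  se <- dfa <- numeric(length(betas))
  for (i in seq_along(betas)) {
    se[i] <- mean(replicate(8, spectralEntropy(onefNoise(2000, betas[i],
                                                         200), 200)))
    dfa[i] <- mean(replicate(8, dfaExponent(onefNoise(2000, betas[i],
                                                      200))))
  }
  expect_equal(cor(betas, se, method = "spearman"), -1)
  expect_equal(cor(betas, dfa, method = "spearman"), 1)
})

test_that("extractFeatures averages per-electrode features", {
  set.seed(14)
  x <- rnorm(200)
  w1 <- list(x = rbind(A = x, B = x, C = x), y = 1L)
  single <- extractFeatures(list(x = rbind(A = x), y = 1L))
  multi <- extractFeatures(w1)
  expect_equal(multi$values, single$values, tolerance = 1e-12)
  expect_identical(multi$y, 1L)

  x2 <- rnorm(200)
  wAB <- list(x = rbind(A = x, B = x2), y = 0L)
  wBA <- list(x = rbind(B = x2, A = x), y = 0L)
  expect_equal(extractFeatures(wAB)$values, extractFeatures(wBA)$values,
               tolerance = 1e-12)
  fa <- extractFeatures(wAB, electrodes = "A")$values
  fb <- extractFeatures(wAB, electrodes = "B")$values
  expect_equal(extractFeatures(wAB)$values, (fa + fb) / 2,
               tolerance = 1e-12)
  expect_error(extractFeatures(wAB, electrodes = "Z"), "not present")
})

test_that("per-channel feature errors carry channel context", {
  w <- list(x = rbind(GOOD = rnorm(200), FLATISH = rep(1, 200)), y = 1L)
  expect_error(extractFeatures(w), "FLATISH")
})

test_that("feature table writer emits long format", {
  fv <- data.frame(subject = c("a", "a"), window = 1:2, y = 1L,
                   PermEnt = c(0.5, 0.6), SampEnt = c(1, 2))
  f <- tempfile(fileext = ".csv")
  writeFeatureTable(fv, f)
  long <- read.csv(f)
  expect_setequal(names(long),
                  c("subject_id", "window_index", "feature", "value",
                    "y"))
  expect_equal(nrow(long), 4)
  expect_setequal(unique(long$feature), c("PermEnt", "SampEnt"))
})
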