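# Preprocessing chain: reading, filtering, referencing, cropping,
# resampling and windowing contracts.

.rec <- function(m, fs = 500, trig = 1L, id = "t", label = 1L) {
  EEGRecording(m, fs = fs,
               events = data.frame(sample = trig, label = "EC_start",
                                   stringsAsFactors = FALSE),
               subjectId = id, label = label)
}

test_that("read -> write -> read is idempotent on names and events", {
  spec <- cohortSpec(nCtl = 1, nDep = 1, duration = 17,
                     channels = c("FC2", "AFz", "F2"), seed = 2)
  r <- generateCohort(spec)[[1]]
  f1 <- tempfile(fileext = ".edf"); f2 <- tempfile(fileext = ".edf")
  writeEDF(r, f1)
  a <- readRecording(f1)
  writeEDF(a, f2)
  b <- readRecording(f2)
  expect_identical(channelNames(a), channelNames(b))
  expect_identical(eegEvents(a), eegEvents(b))
  expect_identical(classLabel(a), classLabel(b))
})

test_that("channel labels are canonicalized, duplicates rejected", {
  expect_identical(canonicalizeLabels(c("afz", "FP2", "cpz", "Status")),
                   c("AFz", "Fp2", "CPz", "Status"))
  m <- matrix(rnorm(1000), 2, 500, dimnames = list(c("afz", "o1"), NULL))
  f <- tempfile(fileext = ".edf")
  writeEDF(.rec(m), f)
  expect_identical(channelNames(readRecording(f)), c("AFz", "O1"))

  m2 <- matrix(rnorm(1000), 2, 500,
               dimnames = list(c("AFz", "afz"), NULL))
  f2 <- tempfile(fileext = ".edf")
  writeEDF(.rec(m2), f2)
  expect_error(readRecording(f2), "duplicate")
})

test_that("FIF and missing files raise clear errors", {
  expect_error(readRecording(tempfile(), "EDF"), "not found")
  f <- tempfile(fileext = ".fif"); file.create(f)
  expect_error(readRecording(f, "FIF"), "unsupported format")
})

test_that("filter chain notches 50 Hz by >= 20 dB", {
  t <- (0:9999) / 500
  m <- rbind(Cz = sin(2 * pi * 50 * t), Pz = sin(2 * pi * 10 * t))
  out <- eegData(filterChain(.rec(m)))
  bin50 <- 50 * 10000 / 500 + 1
  before <- abs(fft(m["Cz", ]))[bin50]
  after <- abs(fft(out["Cz", ] - out["Pz", ]))[bin50] # undo avg ref
  expect_gte(20 * log10(before / (after / 2)), 20)
})

test_that("filter chain removes DC and enforces the average reference", {
  set.seed(3)
  n <- 30000                       # 60 s: several 0.1 Hz periods
  m <- rbind(Cz = rnorm(n) + 100, Pz = rnorm(n) - 40,
             Oz = rnorm(n))
  out <- eegData(filterChain(.rec(m)))
  # channel mean at each sample is zero after average referencing
  expect_lt(max(abs(colMeans(out))), 1e-9)
  # DC offsets removed (ignore filter edge transients)
  core <- 10000:20000
  expect_lt(abs(mean(out["Cz", core] - out["Oz", core])), 1)
  expect_identical(dim(out), dim(m))
})

test_that("low sampling rates are refused", {
  m <- matrix(rnorm(400), 2, 200, dimnames = list(c("Cz", "Pz"), NULL))
  expect_error(filterChain(.rec(m, fs = 200)), "240")
})

test_that("crop and resample produce exactly span x 200 samples", {
  spec <- cohortSpec(nCtl = 1, nDep = 1, duration = 17,
                     channels = c("FC2", "Cz"), seed = 7)
  r <- generateCohort(spec)[[1]]
  c15 <- cropAndResample(r, 15)
  expect_identical(ncol(eegData(c15)), 3000L)
  expect_identical(samplingRate(c15), 200)
  expect_identical(eegEvents(c15)$sample, 1L)
  c1 <- cropAndResample(r, 1)
  expect_identical(ncol(eegData(c1)), 200L)
})

test_that("insufficient post-trigger data raises a subject-named error", {
  m <- matrix(rnorm(2000), 2, 1000,
              dimnames = list(c("Cz", "Pz"), NULL))
  r <- .rec(m, trig = 1000L, id = "sub77")
  expect_error(cropAndResample(r, 1), "sub77")
  expect_error(cropAndResample(.rec(m, trig = 1L, id = "sub88"), 3),
               "sub88")
})

test_that("FFT resampling preserves band-limited content", {
  t <- (0:4999) / 500
  x <- sin(2 * pi * 20 * t)
  y <- resampleFFT(x, 2000)               # 500 -> 200 Hz
  t2 <- (0:1999) / 200
  expect_lt(max(abs(y - sin(2 * pi * 20 * t2))), 1e-6)
  expect_length(resampleFFT(rnorm(501), 200), 200)
})

test_that("vectorize yields unit-norm, label-carrying 200-sample windows", {
  spec <- cohortSpec(nCtl = 1, nDep = 1, duration = 17,
                     channels = c("FC2", "AFz", "F2"), seed = 8)
  r <- cropAndResample(generateCohort(spec)[[2]], 15)
  w <- vectorize(r)
  expect_length(w, 15)
  norms <- unlist(lapply(w, function(v) apply(v$x, 1, function(z)
    sqrt(sum(z^2)))))
  expect_equal(unname(norms), rep(1, length(norms)), tolerance = 1e-9)
  expect_true(all(vapply(w, `[[`, integer(1), "y") == 0L))
  expect_identical(ncol(w[[1]]$x), 200L)

  # trailing remainder below 200 samples is dropped
  m <- matrix(rnorm(2 * 3100), 2, 3100,
              dimnames = list(c("FC2", "Cz"), NULL))
  expect_length(vectorize(.rec(m, fs = 200)), 15)
})

test_that("vectorize enforces resampling, channel presence and non-flat rows", {
  m <- matrix(rnorm(2 * 400), 2, 400,
              dimnames = list(c("FC2", "Cz"), NULL))
  expect_error(vectorize(.rec(m, fs = 500)), "200 Hz")
  r <- .rec(m, fs = 200)
  expect_error(vectorize(r, "Pz"), "not in recording")
  m2 <- m; m2[2, ] <- 0
  expect_error(vectorize(.rec(m2, fs = 200)), "flat")
})

test_that("integer spans give exactly floor(span) windows", {
  spec <- cohortSpec(nCtl = 1, nDep = 1, duration = 17,
                     channels = c("FC2", "Cz"), seed = 9)
  r <- generateCohort(spec)[[1]]
  for (s in c(1, 4, 9))
    expect_length(vectorize(cropAndResample(r, s)), s)
})
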