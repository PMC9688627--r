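# Synthetic resting-state EEG cohorts with class-dependent complexity.
#
# Channels are 1/f^beta coloured noise (spectral shaping of white
# Gaussian noise) plus a 10 Hz alpha oscillation, a shared low-rank
# background common to all channels of a subject (a crude stand-in for
# volume conduction) and white sensor noise. Class effects (a different
# spectral exponent and alpha amplitude) are injected only on the
# discriminative channels of DEP subjects, so the region-selection stage
# has a recoverable ground truth.

# SD (uV) of the per-channel coloured background and the weight of the
# shared across-channel component.
.SYNTH_BG_SD <- 10
.SYNTH_SHARED_W <- 0.3

#' 1/f^beta coloured noise by spectral shaping
#'
#' White Gaussian noise is transformed to the frequency domain, its
#' amplitude spectrum multiplied by f^(-beta/2) (DC removed), and
#' transformed back; the result is standardised to unit SD.
#'
#' @param n number of samples.
#' @param beta spectral exponent (>= 0); 0 gives white noise, 2 a random
#'   walk-like spectrum. The DFA exponent of the result is approximately
#'   (beta + 1) / 2.
#' @param fs sampling rate (Hz), only used to anchor the frequency axis.
#' @return numeric vector of length `n`, mean 0, SD 1.
#' @examples
#' x <- onefNoise(1000, beta = 1)
#' @export
onefNoise <- function(n, beta, fs = 500) {
  w <- rnorm(n)
  if (beta == 0) return(as.numeric(scale(w)))
  W <- fft(w)
  k <- seq_len(n) - 1L
  f <- fs * pmin(k, n - k) / n      # two-sided symmetric frequencies
  g <- rep(0, n)
  g[f > 0] <- f[f > 0]^(-beta / 2)
  x <- Re(fft(W * g, inverse = TRUE)) / n
  as.numeric(scale(x))
}

.synthChannel <- function(n, beta, alphaAmp, fs, shared) {
  x <- .SYNTH_BG_SD * onefNoise(n, beta, fs)
  t <- (seq_len(n) - 1) / fs
  x <- x + alphaAmp * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
  x + .SYNTH_SHARED_W * .SYNTH_BG_SD * shared
}

.synthRecording <- function(spec, subjectId, label) {
  n <- as.integer(round((spec@leadIn + spec@duration) * spec@fs))
  shared <- onefNoise(n, spec@betaCtl, spec@fs)
  dep <- identical(label, 0L)
  dat <- matrix(0, length(spec@channels), n,
                dimnames = list(spec@channels, NULL))
  for (ch in spec@channels) {
    eff <- dep && ch %in% spec@discriminativeChannels
    beta <- if (eff) spec@betaDep else spec@betaCtl
    amp <- if (eff) spec@alphaAmpDep else spec@alphaAmpCtl
    dat[ch, ] <- .synthChannel(n, beta, amp, spec@fs, shared)
  }
  if (spec@noiseSd > 0)
    dat <- dat + matrix(rnorm(length(dat), sd = spec@noiseSd), nrow(dat))
  trig <- as.integer(round(spec@leadIn * spec@fs)) + 1L
  EEGRecording(dat, fs = spec@fs,
               events = data.frame(sample = trig, label = "EC_start",
                                   stringsAsFactors = FALSE),
               subjectId = subjectId, label = label)
}

#' Generate a synthetic cohort
#'
#' Produces `nCtl + nDep` labelled [EEGRecording-class] objects, each
#' with an eyes-closed trigger event ("EC_start") after `leadIn` seconds
#' and `duration` seconds of signal after it. Identical spec + seed gives
#' byte-identical cohorts.
#'
#' @param spec a [CohortSpec-class] (see [cohortSpec()]).
#' @return named list of `EEGRecording`s, controls first (label 1), then
#'   depressive subjects (label 0).
#' @examples
#' spec <- cohortSpec(nCtl = 1, nDep = 1, duration = 17,
#'                    channels = c("FC2", "AFz", "F2"), seed = 7)
#' cohort <- generateCohort(spec)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  ctl <- lapply(seq_len(spec@nCtl), function(i)
    .synthRecording(spec, sprintf("ctl%02d", i), 1L))
  dep <- lapply(seq_len(spec@nDep), function(i)
    .synthRecording(spec, sprintf("dep%02d", i), 0L))
  cohort <- c(ctl, dep)
  names(cohort) <- vapply(cohort, subjectId, character(1))
  cohort
}

#' Inject stereotyped blink artifacts (robustness testing only)
#'
#' Adds smooth, large, low-frequency transients to frontal channels
#' (labels starting Fp/AF/F). Not part of cohort generation: synthetic
#' cohorts are artifact-free by construction and artifact removal is a
#' pass-through hook in this package.
#'
#' @param recording an [EEGRecording-class].
#' @param rate blinks per second (default 0.25).
#' @param amplitude peak amplitude in uV (default 80).
#' @param seed integer seed.
#' @return the recording with blinks added.
#' @export
injectBlinks <- function(recording, rate = 0.25, amplitude = 80,
                         seed = 1L) {
  set.seed(seed)
  dat <- eegData(recording)
  fs <- samplingRate(recording)
  n <- ncol(dat)
  frontal <- grep("^(FP|AF|F)[0-9Zz]", toupper(rownames(dat)))
  nBlink <- max(1L, as.integer(round(rate * n / fs)))
  width <- as.integer(round(0.2 * fs))
  kernel <- amplitude * exp(-((seq_len(width) - width / 2)^2) /
                              (2 * (width / 6)^2))
  at <- sort(sample.int(n - width, nBlink))
  for (a in at)
    dat[frontal, a:(a + width - 1L)] <-
      dat[frontal, a:(a + width - 1L)] +
      matrix(kernel, length(frontal), width, byrow = TRUE)
  initialize(recording, data = dat)
}

#' Write a cohort as EDF(+) files
#'
#' One file per subject, deterministically named `<subjectId>.edf`.
#'
#' @param cohort list of [EEGRecording-class] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths.
#' @seealso [writeEDF()]
#' @export
writeCohortEDF <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort, function(r) {
    p <- file.path(dir, paste0(subjectId(r), ".edf"))
    writeEDF(r, p)
    p
  }, character(1))
  invisible(paths)
}
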