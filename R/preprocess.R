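# Preprocessing chain: band-pass 0.1-120 Hz, 50 Hz notch, 90 Hz
# low-pass (all zero-phase), average reference, crop after the
# eyes-closed trigger, FFT resampling to 200 Hz, and L2-normalised
# 200-sample window vectors.

.filtRow <- function(b, a, x) as.numeric(signal::filtfilt(b, a, x))

# RBJ biquad notch at f0 with quality factor Q
.notchCoef <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Filter and re-reference a recording
#'
#' Applies, in order: an optional artifact-removal hook (pass-through by
#' default; artifact subspace reconstruction can be plugged in here), a
#' 0.1 Hz high-pass and 120 Hz low-pass (4th-order Butterworth,
#' forward-backward so zero-phase), a 50 Hz notch (biquad, Q = 30), a
#' 90 Hz low-pass (4th-order Butterworth), and common average
#' referencing. Channel and sample counts are preserved.
#'
#' @param recording an [EEGRecording-class]; `fs` must exceed 240 Hz so
#'   the 120 Hz band edge exists.
#' @param artifactHook optional `function(recording) -> recording`
#'   applied before filtering (default identity).
#' @return the filtered, average-referenced recording.
#' @export
filterChain <- function(recording, artifactHook = NULL) {
  fs <- samplingRate(recording)
  if (fs <= 240)
    stop("sampling rate ", fs,
         " Hz too low: the 0.1-120 Hz passband needs fs > 240 Hz")
  if (!is.null(artifactHook)) recording <- artifactHook(recording)
  dat <- eegData(recording)
  nyq <- fs / 2
  hp <- signal::butter(4, 0.1 / nyq, type = "high")
  lp120 <- signal::butter(4, 120 / nyq, type = "low")
  nt <- .notchCoef(50, fs, Q = 30)
  lp90 <- signal::butter(4, 90 / nyq, type = "low")
  for (i in seq_len(nrow(dat))) {
    x <- dat[i, ]
    x <- .filtRow(hp$b, hp$a, x)
    x <- .filtRow(lp120$b, lp120$a, x)
    x <- .filtRow(nt$b, nt$a, x)
    x <- .filtRow(lp90$b, lp90$a, x)
    dat[i, ] <- x
  }
  # common average reference: channel mean at every sample becomes 0
  dat <- sweep(dat, 2, colMeans(dat))
  initialize(recording, data = dat)
}

#' Fourier-domain resampling to an arbitrary length
#'
#' Truncates (or zero-pads) the spectrum and inverse-transforms, i.e.
#' ideal band-limited resampling under a periodic-extension assumption.
#'
#' @param x numeric vector.
#' @param nNew target length.
#' @return numeric vector of length `nNew`.
#' @export
resampleFFT <- function(x, nNew) {
  n <- length(x)
  nNew <- as.integer(nNew)
  if (nNew == n) return(x)
  X <- fft(x)
  Y <- complex(nNew)
  m <- min(n, nNew)
  hpos <- (m - 1L) %/% 2L             # strictly positive, non-Nyquist
  Y[1] <- X[1]
  if (hpos >= 1) {
    Y[2:(hpos + 1)] <- X[2:(hpos + 1)]
    Y[(nNew - hpos + 1):nNew] <- X[(n - hpos + 1):n]
  }
  if (m %% 2L == 0L) {
    ny <- m %/% 2L + 1L
    if (nNew < n) {
      Y[ny] <- X[ny] + X[n - m %/% 2L + 1L]   # fold aliased Nyquist pair
    } else {
      Y[ny] <- X[ny] / 2
      Y[nNew - m %/% 2L + 1L] <- X[ny] / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

.triggerSample <- function(recording, trigger = "EC_start") {
  ev <- eegEvents(recording)
  if (nrow(ev) == 0)
    stop("recording '", subjectId(recording), "' has no events")
  hit <- which(ev$label == trigger)
  if (length(hit) == 0) hit <- 1L
  ev$sample[hit[1]]
}

#' Crop after the eyes-closed trigger and resample
#'
#' Takes exactly `span` seconds starting at the trigger event and
#' resamples them to `targetFs` (default 200 Hz), yielding
#' `span * targetFs` samples per channel.
#'
#' @param recording an [EEGRecording-class].
#' @param span seconds to keep after the trigger.
#' @param targetFs target sampling rate (Hz).
#' @param trigger event label marking the eyes-closed start (falls back
#'   to the first event if the label is absent).
#' @return a cropped, resampled recording whose trigger is at sample 1.
#' @export
cropAndResample <- function(recording, span, targetFs = 200,
                            trigger = "EC_start") {
  fs <- samplingRate(recording)
  trig <- .triggerSample(recording, trigger)
  nNeed <- as.integer(round(span * fs))
  nAvail <- nSamples(recording) - trig + 1L
  if (nAvail < nNeed)
    stop("subject '", subjectId(recording), "': only ",
         round(nAvail / fs, 3), " s available after the trigger, need ",
         span, " s")
  dat <- eegData(recording)[, trig:(trig + nNeed - 1L), drop = FALSE]
  nOut <- as.integer(round(span * targetFs))
  out <- t(apply(dat, 1, resampleFFT, nNew = nOut))
  rownames(out) <- rownames(dat)
  initialize(recording, data = out, fs = as.numeric(targetFs),
             events = data.frame(sample = 1L, label = trigger,
                                 stringsAsFactors = FALSE))
}

#' Split a recording into L2-normalised 1 s window vectors
#'
#' Consecutive non-overlapping 200-sample windows, restricted to
#' `selectedChannels`; each channel row of each window is scaled to unit
#' L2 norm; a trailing remainder shorter than 200 samples is dropped.
#'
#' @param recording an [EEGRecording-class] resampled to 200 Hz.
#' @param selectedChannels channels to keep (default all); matched
#'   case-insensitively.
#' @return list of window vectors; each element is a list with `x`
#'   (channels x 200 matrix, unit-norm rows), `y` (class label),
#'   `subject` and `window` (1-based index).
#' @export
vectorize <- function(recording, selectedChannels = NULL) {
  if (abs(samplingRate(recording) - 200) > 1e-9)
    stop("vectorize expects a 200 Hz recording; resample first")
  dat <- eegData(recording)
  if (is.null(selectedChannels)) {
    sel <- seq_len(nrow(dat))
  } else {
    sel <- match(toupper(canonicalizeLabels(selectedChannels)),
                 toupper(rownames(dat)))
    if (anyNA(sel))
      stop("channel(s) not in recording: ",
           paste(selectedChannels[is.na(sel)], collapse = ", "))
  }
  dat <- dat[sel, , drop = FALSE]
  nWin <- ncol(dat) %/% 200L
  y <- classLabel(recording)
  lapply(seq_len(nWin), function(k) {
    w <- dat[, ((k - 1L) * 200L + 1L):(k * 200L), drop = FALSE]
    nrm <- sqrt(rowSums(w^2))
    if (any(nrm == 0))
      stop("flat (zero-norm) channel ",
           paste(rownames(w)[nrm == 0], collapse = ", "),
           " in window ", k, " of subject '", subjectId(recording), "'")
    list(x = w / nrm, y = y, subject = subjectId(recording), window = k)
  })
}
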