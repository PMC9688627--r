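#' EEGRecording: a labelled multichannel EEG recording
#'
#' Container for one subject's multichannel EEG: a channels x samples
#' voltage matrix (microvolts) with 10-20 channel names as rownames, a
#' sampling rate, an event table, a subject identifier and a class label
#' (0 = depressive, 1 = control, NA = unknown).
#'
#' Sample indices in the event table are 1-based (first sample = 1);
#' windows taken from a recording are closed intervals of whole samples.
#'
#' @slot data numeric matrix, channels x samples, rownames are channel
#'   labels in canonical 10-20 form.
#' @slot fs sampling rate in Hz.
#' @slot events data.frame with columns `sample` (integer, 1-based index
#'   into the columns of `data`) and `label` (character).
#' @slot subjectId character scalar.
#' @slot label integer scalar: 0 (DEP), 1 (CTL) or NA (unknown).
#'
#' @seealso [generateCohort()], [readRecording()], [filterChain()]
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    events = "data.frame",
    subjectId = "character",
    label = "integer"
  ),
  prototype(
    data = matrix(numeric(0), 0, 0),
    fs = 500,
    events = data.frame(sample = integer(0), label = character(0),
                        stringsAsFactors = FALSE),
    subjectId = NA_character_,
    label = NA_integer_
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "data must be a numeric matrix")
  if (is.null(rownames(d)) && nrow(d) > 0)
    msg <- c(msg, "data must have channel names as rownames")
  if (!is.null(rownames(d)) && anyDuplicated(rownames(d)))
    msg <- c(msg, "duplicate channel labels")
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  ev <- object@events
  if (!all(c("sample", "label") %in% names(ev)))
    msg <- c(msg, "events must have columns 'sample' and 'label'")
  else if (nrow(ev) > 0 &&
           (any(ev$sample < 1) || any(ev$sample > ncol(d))))
    msg <- c(msg, "event sample indices out of data bounds")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0 (DEP), 1 (CTL) or NA")
  if (length(msg)) msg else TRUE
})

#' @describeIn EEGRecording compact display
#' @param object an `EEGRecording`
#' @export
setMethod("show", "EEGRecording", function(object) {
  cls <- if (is.na(object@label)) "unknown" else
    if (object@label == 1L) "CTL" else "DEP"
  cat(sprintf("EEGRecording '%s' [%s]\n", object@subjectId, cls))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  if (nrow(object@data) > 0) {
    ch <- rownames(object@data)
    shown <- paste(head(ch, 8), collapse = ", ")
    if (length(ch) > 8) shown <- paste0(shown, ", ...")
    cat("  channels:", shown, "\n")
  }
  if (nrow(object@events) > 0)
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s@%d", object@events$label,
                              object@events$sample), collapse = ", ")))
  invisible(NULL)
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix with channel rownames.
#' @param fs sampling rate (Hz).
#' @param events data.frame with `sample` (1-based) and `label` columns.
#' @param subjectId subject identifier.
#' @param label class label: 0 (DEP), 1 (CTL) or NA.
#' @return an [EEGRecording-class] object.
#' @examples
#' x <- matrix(rnorm(400), 2, 200, dimnames = list(c("AFz", "F2"), NULL))
#' EEGRecording(x, fs = 200, subjectId = "s01", label = 1L)
#' @export
EEGRecording <- function(data, fs,
                         events = data.frame(sample = integer(0),
                                             label = character(0),
                                             stringsAsFactors = FALSE),
                         subjectId = NA_character_,
                         label = NA_integer_) {
  new("EEGRecording", data = data, fs = as.numeric(fs), events = events,
      subjectId = as.character(subjectId), label = as.integer(label))
}

#' CohortSpec: parameters of a synthetic resting-state EEG cohort
#'
#' Describes the synthetic study conditions: group sizes, montage,
#' sampling rate, eyes-closed duration after the trigger, class-specific
#' 1/f spectral exponents and alpha (10 Hz) amplitudes, the electrode
#' subset carrying the class effect, sensor noise and seed.
#'
#' @slot nCtl,nDep number of control / depressive subjects (>= 1).
#' @slot channels character vector of 10-20 electrode labels.
#' @slot fs sampling rate (Hz, default 500).
#' @slot duration eyes-closed seconds after the trigger (default 180,
#'   must be >= 17 so the full span sweep is supported).
#' @slot betaCtl,betaDep spectral exponents of the 1/f^beta background
#'   (unitless, >= 0); betaDep applies only on the discriminative
#'   channels of DEP subjects.
#' @slot alphaAmpCtl,alphaAmpDep amplitude of the 10 Hz alpha
#'   oscillation (microvolts) for the same channel groups.
#' @slot discriminativeChannels electrodes carrying the class effect
#'   (default FC2, AFz, F2); must be a subset of `channels`.
#' @slot noiseSd white sensor-noise SD (microvolts).
#' @slot leadIn seconds of recording before the eyes-closed trigger.
#' @slot seed integer seed; identical spec + seed gives byte-identical
#'   cohorts.
#' @export
setClass("CohortSpec",
  representation(
    nCtl = "integer", nDep = "integer",
    channels = "character",
    fs = "numeric", duration = "numeric",
    betaCtl = "numeric", betaDep = "numeric",
    alphaAmpCtl = "numeric", alphaAmpDep = "numeric",
    discriminativeChannels = "character",
    noiseSd = "numeric", leadIn = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nCtl < 1L || object@nDep < 1L)
    msg <- c(msg, "nCtl and nDep must be >= 1")
  if (length(object@channels) < 1) msg <- c(msg, "empty montage")
  unknown <- setdiff(object@channels, standardElectrodes())
  if (length(unknown))
    msg <- c(msg, paste("unknown electrode name(s):",
                        paste(unknown, collapse = ", ")))
  if (object@duration < 17)
    msg <- c(msg, "duration must be >= 17 s (the span sweep needs 17 s)")
  n <- object@duration * object@fs
  if (abs(n - round(n)) > 1e-9)
    msg <- c(msg, "duration * fs must be an integer sample count")
  if (!all(object@discriminativeChannels %in% object@channels))
    msg <- c(msg, "discriminativeChannels must be a subset of channels")
  if (object@betaCtl < 0 || object@betaDep < 0)
    msg <- c(msg, "beta exponents must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@leadIn < 0) msg <- c(msg, "leadIn must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortSpec compact display
#' @param object a `CohortSpec`
#' @export
setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d CTL + %d DEP, %d channels @ %g Hz, %g s EC\n",
              object@nCtl, object@nDep, length(object@channels),
              object@fs, object@duration))
  cat(sprintf("  beta CTL/DEP: %.2f/%.2f  alpha amp CTL/DEP: %.1f/%.1f uV\n",
              object@betaCtl, object@betaDep,
              object@alphaAmpCtl, object@alphaAmpDep))
  cat(sprintf("  effect channels: %s  (seed %d)\n",
              paste(object@discriminativeChannels, collapse = ", "),
              object@seed))
  invisible(NULL)
})

#' Construct a CohortSpec
#'
#' Defaults emulate the study conditions: ~50 subjects, a >= 32 channel
#' 10-20 montage at 500 Hz, 3 min of eyes-closed signal after a trigger,
#' and class effects confined to FC2, AFz and F2.
#'
#' @param nCtl,nDep group sizes.
#' @param channels montage labels (default [defaultMontage()]).
#' @param fs sampling rate in Hz.
#' @param duration eyes-closed seconds after the trigger (>= 17).
#' @param betaCtl,betaDep 1/f spectral exponents (background / DEP effect).
#' @param alphaAmpCtl,alphaAmpDep 10 Hz oscillation amplitudes (uV).
#' @param discriminativeChannels electrodes where the class effect is
#'   injected; the default (FC2, AFz, F2) is restricted to the montage
#'   when not given explicitly.
#' @param noiseSd white sensor-noise SD (uV).
#' @param leadIn pre-trigger seconds.
#' @param seed integer seed.
#' @return a validated [CohortSpec-class].
#' @examples
#' cohortSpec(nCtl = 2, nDep = 2, duration = 17,
#'            channels = c("FC2", "AFz", "F2", "Cz"))
#' @export
cohortSpec <- function(nCtl = 24, nDep = 26,
                       channels = defaultMontage(),
                       fs = 500, duration = 180,
                       betaCtl = 1.0, betaDep = 1.5,
                       alphaAmpCtl = 4, alphaAmpDep = 6,
                       discriminativeChannels = c("FC2", "AFz", "F2"),
                       noiseSd = 2, leadIn = 2,
                       seed = 1L) {
  if (missing(discriminativeChannels))
    discriminativeChannels <- intersect(discriminativeChannels,
                                        channels)
  new("CohortSpec",
      nCtl = as.integer(nCtl), nDep = as.integer(nDep),
      channels = as.character(channels),
      fs = as.numeric(fs), duration = as.numeric(duration),
      betaCtl = as.numeric(betaCtl), betaDep = as.numeric(betaDep),
      alphaAmpCtl = as.numeric(alphaAmpCtl),
      alphaAmpDep = as.numeric(alphaAmpDep),
      discriminativeChannels = as.character(discriminativeChannels),
      noiseSd = as.numeric(noiseSd), leadIn = as.numeric(leadIn),
      seed = as.integer(seed))
}
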