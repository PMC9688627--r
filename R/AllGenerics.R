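#' @name accessors
#' @title Accessors for EEGRecording objects
#' @description Read the channel names, sampling rate, voltage matrix,
#'   event table, subject identifier or class label of an
#'   [EEGRecording-class].
#' @param x an `EEGRecording`
#' @return `channelNames`: character vector; `samplingRate`: Hz;
#'   `eegData`: channels x samples matrix; `eegEvents`: data.frame;
#'   `subjectId`: character; `classLabel`: integer (0 DEP / 1 CTL / NA).
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) rownames(x@data))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("eegEvents", function(x) standardGeneric("eegEvents"))
#' @rdname accessors
#' @export
setMethod("eegEvents", "EEGRecording", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setMethod("classLabel", "EEGRecording", function(x) x@label)

#' Number of samples in a recording
#' @param x an `EEGRecording`
#' @return integer sample count per channel
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname nSamples
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))
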