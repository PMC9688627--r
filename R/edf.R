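# Minimal EDF(+) I/O: 16-bit EDF with one annotation signal carrying the
# recording's events as EDF+ text annotation lists (TALs). The whole
# recording is stored as a single data record, which keeps the
# round-trip exact for arbitrary durations.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEGRecording to an EDF(+) file
#'
#' Signals are scaled to the full 16-bit digital range per channel
#' (physical units uV); events are stored on an "EDF Annotations" signal
#' with onsets in seconds relative to file start. The subject id and
#' class label travel in the patient-identification header field so a
#' round trip through [readRecording()] recovers them.
#'
#' @param recording an [EEGRecording-class] with at least one sample.
#' @param path output file path.
#' @return invisibly, `path`.
#' @examples
#' x <- matrix(sin(seq(0, 8 * pi, length.out = 500)), 1, 500,
#'             dimnames = list("Cz", NULL))
#' r <- EEGRecording(x, fs = 500, subjectId = "s1", label = 1L)
#' f <- tempfile(fileext = ".edf")
#' writeEDF(r, f)
#' @export
writeEDF <- function(recording, path) {
  dat <- eegData(recording)
  if (nrow(dat) == 0 || ncol(dat) == 0) stop("empty recording")
  fs <- samplingRate(recording)
  n <- ncol(dat)
  nsig <- nrow(dat)

  # per-channel symmetric physical range; 4 significant digits so the
  # header's 8-char ascii fields hold the exact value used for scaling
  pmaxs <- signif(pmin(pmax(apply(dat, 1, function(x) max(abs(x))) *
                              1.001, 0.01), 32000), 4)
  # same affine map the reader applies: [-pmax, pmax] -> [-32768, 32767]
  dig <- matrix(0L, nsig, n)
  for (i in seq_len(nsig))
    dig[i, ] <- as.integer(round((dat[i, ] + pmaxs[i]) /
                                   (2 * pmaxs[i]) * 65535 - 32768))

  # annotations: timestamp TAL + one TAL per event
  ev <- eegEvents(recording)
  tal <- "+0\x14\x14"
  if (nrow(ev) > 0)
    tal <- paste0(tal, paste0("+", sprintf("%.7g", (ev$sample - 1) / fs),
                              "\x14", ev$label, "\x14", collapse = ""))
  annBytes <- c(utf8ToInt(tal), rep(0L, 2 * ceiling(nchar(tal) / 2) +
                                      2 - nchar(tal)))
  annSamples <- length(annBytes) / 2

  ns <- nsig + 1L                      # + annotation signal
  lab <- if (is.na(classLabel(recording))) "X" else classLabel(recording)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8),
    .edfPad(sprintf("subject=%s label=%s", subjectId(recording), lab), 80),
    .edfPad("Startdate 01-JAN-2026 synthetic", 80),
    .edfPad("01.01.26", 8), .edfPad("00.00.00", 8),
    .edfPad(256 * (ns + 1), 8),
    .edfPad("EDF+C", 44),
    .edfPad(1, 8),
    .edfPad(sprintf("%.7g", n / fs), 8),
    .edfPad(ns, 4),
    paste0(vapply(c(rownames(dat), "EDF Annotations"),
                  .edfPad, character(1), width = 16), collapse = ""),
    paste0(vapply(rep("", ns), .edfPad, character(1), width = 80),
           collapse = ""),
    paste0(vapply(c(rep("uV", nsig), ""), .edfPad, character(1),
                  width = 8), collapse = ""),
    paste0(vapply(c(sprintf("%.7g", -pmaxs), "-1"), .edfPad,
                  character(1), width = 8), collapse = ""),
    paste0(vapply(c(sprintf("%.7g", pmaxs), "1"), .edfPad,
                  character(1), width = 8), collapse = ""),
    paste0(vapply(c(rep("-32768", nsig), "-32768"), .edfPad,
                  character(1), width = 8), collapse = ""),
    paste0(vapply(c(rep("32767", nsig), "32767"), .edfPad,
                  character(1), width = 8), collapse = ""),
    paste0(vapply(rep("", ns), .edfPad, character(1), width = 80),
           collapse = ""),
    paste0(vapply(c(rep(n, nsig), annSamples), .edfPad, character(1),
                  width = 8), collapse = ""),
    paste0(vapply(rep("", ns), .edfPad, character(1), width = 32),
           collapse = "")
  )
  writeBin(charToRaw(hdr), con)
  for (i in seq_len(nsig))
    writeBin(dig[i, ], con, size = 2, endian = "little")
  writeBin(as.raw(annBytes), con)
  invisible(path)
}

.readAscii <- function(con, nchars) {
  raw <- readBin(con, "raw", nchars)
  trimws(rawToChar(raw))
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .readAscii(con, 8)                             # version
  patient <- .readAscii(con, 80)
  .readAscii(con, 80); .readAscii(con, 8); .readAscii(con, 8)
  .readAscii(con, 8); .readAscii(con, 44)
  nrec <- as.integer(.readAscii(con, 8))
  recDur <- as.numeric(.readAscii(con, 8))
  ns <- as.integer(.readAscii(con, 4))
  labels <- vapply(seq_len(ns), function(i) .readAscii(con, 16),
                   character(1))
  for (i in seq_len(ns)) .readAscii(con, 80)     # transducer
  for (i in seq_len(ns)) .readAscii(con, 8)      # physical dimension
  physMin <- vapply(seq_len(ns), function(i)
    as.numeric(.readAscii(con, 8)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i)
    as.numeric(.readAscii(con, 8)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i)
    as.numeric(.readAscii(con, 8)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i)
    as.numeric(.readAscii(con, 8)), numeric(1))
  for (i in seq_len(ns)) .readAscii(con, 80)     # prefiltering
  sampPerRec <- vapply(seq_len(ns), function(i)
    as.integer(.readAscii(con, 8)), integer(1))
  for (i in seq_len(ns)) .readAscii(con, 32)     # reserved

  isAnn <- labels == "EDF Annotations"
  sigs <- vector("list", ns)
  for (i in seq_len(ns)) sigs[[i]] <- vector("list", nrec)
  annRaw <- raw(0)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) {
        annRaw <- c(annRaw, readBin(con, "raw", 2 * sampPerRec[i]))
      } else {
        sigs[[i]][[r]] <- readBin(con, "integer", sampPerRec[i],
                                  size = 2, endian = "little")
      }
    }
  }
  keep <- which(!isAnn)
  n <- sum(sampPerRec[keep[1]] * nrec)
  dat <- matrix(0, length(keep), n)
  for (j in seq_along(keep)) {
    i <- keep[j]
    d <- unlist(sigs[[i]])
    dat[j, ] <- physMin[i] + (d - digMin[i]) *
      (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
  }
  chn <- canonicalizeLabels(labels[keep])
  if (anyDuplicated(toupper(chn)))
    stop("duplicate channel label(s) after canonicalization: ",
         paste(unique(chn[duplicated(toupper(chn))]), collapse = ", "))
  rownames(dat) <- chn

  fs <- round(sampPerRec[keep[1]] / recDur, 6)
  # parse TALs: +onset[\x15dur]\x14label\x14 ... terminated by NUL
  txt <- rawToChar(annRaw[annRaw != as.raw(0)])
  events <- data.frame(sample = integer(0), label = character(0),
                       stringsAsFactors = FALSE)
  if (nzchar(txt)) {
    tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
    for (tal in tals) {
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(parts) < 2) next                # bare timestamp TAL
      onset <- as.numeric(strsplit(parts[1], "\x15")[[1]][1])
      for (lb in parts[-1]) {
        if (!nzchar(lb)) next
        events <- rbind(events, data.frame(
          sample = as.integer(round(onset * fs)) + 1L, label = lb,
          stringsAsFactors = FALSE))
      }
    }
  }
  sid <- sub(".*subject=(\\S+).*", "\\1", patient)
  lab <- sub(".*label=(\\S+).*", "\\1", patient)
  lab <- if (lab %in% c("0", "1")) as.integer(lab) else NA_integer_
  EEGRecording(dat, fs = fs, events = events, subjectId = sid,
               label = lab)
}

#' Read an EEG recording from disk
#'
#' Channel names are canonicalized to 10-20 nomenclature (see
#' [canonicalizeLabels()]) and events are extracted from EDF+
#' annotations. Only the EDF(+) format is supported; FIF is recognised
#' but not implemented.
#'
#' @param path file path.
#' @param format "EDF" (default) or "FIF".
#' @return an [EEGRecording-class].
#' @export
readRecording <- function(path, format = c("EDF", "FIF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "FIF")
    stop("unsupported format 'FIF': no FIF parser is available; ",
         "convert to EDF(+)")
  .readEDF(path)
}
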