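# Desikan-region -> 10-20 electrode association table and montage helpers.

.montageCache <- new.env(parent = emptyenv())

#' Standard 10-20 / 10-10 electrode labels
#'
#' Canonical scalp electrode names used to validate montages and to
#' canonicalize labels read from files.
#'
#' @return character vector of canonical labels.
#' @export
standardElectrodes <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F9", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "F10",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "TP8", "TP10",
    "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "Iz",
    "A1", "A2")
}

#' Canonicalize 10-20 electrode labels
#'
#' Case-insensitive matching against [standardElectrodes()]; labels with a
#' canonical counterpart are rewritten to it (e.g. "afz" -> "AFz",
#' "CPZ" -> "CPz"); labels without one (auxiliary channels, the
#' nonstandard N1/N2 of the region table) are returned trimmed but
#' otherwise verbatim.
#'
#' @param labels character vector.
#' @return character vector of the same length.
#' @examples
#' canonicalizeLabels(c("afz", "FP2", "Status"))
#' @export
canonicalizeLabels <- function(labels) {
  std <- standardElectrodes()
  labels <- trimws(labels)
  idx <- match(toupper(labels), toupper(std))
  out <- labels
  out[!is.na(idx)] <- std[idx[!is.na(idx)]]
  out
}

#' Default synthetic montage
#'
#' All electrodes of the shipped Desikan association table that carry
#' standard 10-20/10-10 names (the nonstandard N1, N2 and the far-lateral
#' F9/F10 of the printed table are excluded from synthetic montages), 52
#' channels in total.
#'
#' @return character vector of electrode labels.
#' @export
defaultMontage <- function() {
  all <- unique(unlist(desikanRegionMap()))
  all <- canonicalizeLabels(all)
  setdiff(intersect(all, standardElectrodes()), c("F9", "F10"))
}

#' Desikan region -> electrode association table
#'
#' The exploratory-baseline mapping of 26 Desikan cortical regions to
#' overlying 10-20 electrode groups (Giacometti mapping), shipped as a
#' CSV resource and stored exactly as printed (including the nonstandard
#' labels N1, N2, F9, F10).
#'
#' @return named list: region name -> ordered character vector of
#'   electrode labels.
#' @seealso [electrodesFor()], [validateMontage()], [regionScoreTable()]
#' @examples
#' desikanRegionMap()[["Caudal anterior-cingulate"]]
#' @export
desikanRegionMap <- function() {
  if (is.null(.montageCache$map)) {
    tab <- regionScoreTable()
    .montageCache$map <- setNames(strsplit(tab$electrodes, " ",
                                           fixed = TRUE), tab$region)
  }
  .montageCache$map
}

#' The shipped region table with its printed cross-validation scores
#'
#' @return data.frame with columns `region`, `electrodes`
#'   (space-separated, as printed), `score_mean`, `score_sd`.
#' @export
regionScoreTable <- function() {
  if (is.null(.montageCache$tab)) {
    path <- system.file("extdata", "desikan_region_electrodes.csv",
                        package = "restingEEG", mustWork = TRUE)
    .montageCache$tab <- read.csv(path, stringsAsFactors = FALSE)
  }
  .montageCache$tab
}

#' Electrodes associated with a Desikan region
#'
#' @param region region name exactly as in the shipped table.
#' @return character vector of electrode labels, as printed.
#' @examples
#' electrodesFor("Caudal anterior-cingulate")
#' @export
electrodesFor <- function(region) {
  map <- desikanRegionMap()
  if (!region %in% names(map))
    stop("unknown region '", region, "'; valid regions: ",
         paste(names(map), collapse = "; "))
  map[[region]]
}

#' Check a recording's montage against the region table
#'
#' For every region, reports which of its electrodes are missing from the
#' montage (case-insensitive matching) and whether the region is fully
#' covered ("usable").
#'
#' @param x an [EEGRecording-class] or a character vector of channel
#'   labels.
#' @param map region map (default the shipped table).
#' @return data.frame with columns `region`, `n_electrodes`, `missing`
#'   (comma-separated, "" if none) and `usable` (logical).
#' @examples
#' validateMontage(c("FC2", "AFz", "F2"))
#' @export
validateMontage <- function(x, map = desikanRegionMap()) {
  channels <- if (is(x, "EEGRecording")) channelNames(x) else
    as.character(x)
  have <- toupper(channels)
  rows <- lapply(names(map), function(rg) {
    el <- map[[rg]]
    miss <- el[!toupper(el) %in% have]
    data.frame(region = rg, n_electrodes = length(el),
               missing = paste(miss, collapse = ","),
               usable = length(miss) == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
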