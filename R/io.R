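## File interchange: BrainVision triplet (.vhdr/.vmrk/.eeg) for continuous
## recordings, CSV for event tables, inertial traces and result maps.

#' Write / read event tables as CSV
#'
#' Columns: `onset_s`, `type`, `condition`, `subcondition`, `source`.
#'
#' @param events an [eventTable()].
#' @param path CSV path.
#' @return `readEventsCsv` returns an event table; `writeEventsCsv` its
#'   path, invisibly.
#' @export
writeEventsCsv <- function(events, path) {
  out <- data.frame(onset_s = events$onset, type = events$type,
                    condition = events$condition,
                    subcondition = events$subcondition,
                    source = events$source)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsCsv
#' @export
readEventsCsv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  eventTable(onset = tab$onset_s, type = tab$type,
             condition = tab$condition, subcondition = tab$subcondition,
             source = tab$source)
}

#' Write / read an inertial trace as CSV
#'
#' Columns: `t`, `ax`, `ay`, `az` (seconds / g).
#'
#' @param trace an [ImuTrace].
#' @param path CSV path.
#' @param fs sampling rate used when reading (inferred from `t` if
#'   omitted).
#' @export
writeImuCsv <- function(trace, path) {
  n <- nrow(trace@acc)
  out <- data.frame(t = (seq_len(n) - 1) / trace@fs,
                    ax = trace@acc[, 1], ay = trace@acc[, 2],
                    az = trace@acc[, 3])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeImuCsv
#' @export
readImuCsv <- function(path, fs = NULL) {
  tab <- read.csv(path)
  if (is.null(fs)) fs <- 1 / median(diff(tab$t))
  new("ImuTrace", acc = cbind(tab$ax, tab$ay, tab$az), fs = fs,
      label = "paddle", participant = "", condition = "")
}

#' Write a recording as a BrainVision triplet
#'
#' Produces `<base>.vhdr` (text header), `<base>.vmrk` (markers from the
#' recording's annotations) and `<base>.eeg` (multiplexed IEEE float-32
#' binary, microvolts).  Channel roles are encoded in the channel names
#' (`EEG ...`, `NOISE ...`, `EMG ...`).
#'
#' @param rec a [Recording].
#' @param base path without extension.
#' @return `base`, invisibly.
#' @export
writeBrainVision <- function(rec, base) {
  stopifnot(is(rec, "Recording"))
  bn <- basename(base)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", bn), sprintf("MarkerFile=%s.vmrk", bn),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec@data)),
    sprintf("SamplingInterval=%.10g", 1e6 / rec@fs),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec@data)),
            rec@channels$name))
  writeLines(hdr, paste0(base, ".vhdr"))
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]", "Codepage=UTF-8",
          sprintf("DataFile=%s.eeg", bn),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(rec@annotations)) {
    a <- rec@annotations
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,%d,0",
                        seq_len(nrow(a)) + 1, a$label,
                        round(a$onset * rec@fs) + 1,
                        pmax(1, round(a$duration * rec@fs))))
  }
  writeLines(mk, paste0(base, ".vmrk"))
  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec@data), con, size = 4)  # multiplexed: column-major
  invisible(base)
}

## Parse key=value pairs within one INI-style section of a header file.
bvSection <- function(lines, section) {
  hdr <- grep(sprintf("^\\[%s\\]", section), lines)
  if (!length(hdr)) scStop("malformed header: missing [%s] section (line %d)",
                           section, length(lines))
  rest <- lines[(hdr[1] + 1):length(lines)]
  stop <- grep("^\\[", rest)
  if (length(stop)) rest <- rest[seq_len(stop[1] - 1)]
  rest <- rest[grepl("=", rest) & !grepl("^;", rest)]
  kv <- regmatches(rest, regexpr("=", rest), invert = TRUE)
  setNames(vapply(kv, `[`, character(1), 2),
           vapply(kv, `[`, character(1), 1))
}

#' Read a BrainVision recording
#'
#' Minimal reader for the triplet written by [writeBrainVision()]
#' (multiplexed IEEE float-32).  Channel roles are recovered from the
#' channel-name prefixes and a standard spherical montage is attached to
#' the scalp/noise layers.
#'
#' @param vhdr path to the `.vhdr` header.
#' @return a [Recording].
#' @export
readBrainVision <- function(vhdr) {
  if (!file.exists(vhdr)) scStop("header not found: %s", vhdr)
  lines <- readLines(vhdr, warn = FALSE)
  common <- bvSection(lines, "Common Infos")
  binInfo <- bvSection(lines, "Binary Infos")
  if (!identical(unname(binInfo[["BinaryFormat"]]), "IEEE_FLOAT_32"))
    scStop("unsupported BinaryFormat (only IEEE_FLOAT_32)")
  nCh <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])
  chan <- bvSection(lines, "Channel Infos")
  names_ <- vapply(strsplit(unname(chan), ","), `[`, character(1), 1)
  eegPath <- file.path(dirname(vhdr), common[["DataFile"]])
  if (!file.exists(eegPath)) scStop("data file missing: %s", eegPath)
  sz <- file.info(eegPath)$size
  con <- file(eegPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = sz / 4, size = 4)
  nS <- length(vals) %/% nCh
  data <- matrix(vals[seq_len(nCh * nS)], nCh, nS)
  role <- rep("scalp", nCh)
  role[grepl("^NOISE", names_)] <- "noise"
  role[grepl("^EMG", names_)] <- "muscle"
  nScalp <- sum(role == "scalp")
  montage <- sphericalMontage(nScalp)
  positions <- matrix(NA_real_, nCh, 3)
  positions[role == "scalp", ] <- montage
  if (sum(role == "noise") == nScalp) positions[role == "noise", ] <- montage
  ann <- data.frame(onset = numeric(0), duration = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)
  vmrkPath <- file.path(dirname(vhdr), common[["MarkerFile"]] %||% "")
  if (!is.na(vmrkPath) && nzchar(vmrkPath) && file.exists(vmrkPath)) {
    ml <- readLines(vmrkPath, warn = FALSE)
    mk <- grep("^Mk[0-9]+=", ml, value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
    stim <- parts[vapply(parts, `[`, character(1), 1) == "Stimulus"]
    if (length(stim))
      ann <- data.frame(
        onset = (as.numeric(vapply(stim, `[`, character(1), 3)) - 1) / fs,
        duration = as.numeric(vapply(stim, `[`, character(1), 4)) / fs,
        label = vapply(stim, `[`, character(1), 2),
        stringsAsFactors = FALSE)
  }
  new("Recording", data = data, fs = fs,
      channels = data.frame(name = names_, role = role,
                            stringsAsFactors = FALSE),
      positions = positions, annotations = ann, interpolated = integer(0),
      participant = "", condition = "")
}

#' Write a time-frequency map (or mask) as CSV
#'
#' Long format: `freq`, `time`, `value`.
#'
#' @param m freqs x times matrix.
#' @param freqs,times axis values.
#' @param path CSV path.
#' @export
writeMapCsv <- function(m, freqs, times, path) {
  out <- data.frame(freq = rep(freqs, times = length(times)),
                    time = rep(times, each = length(freqs)),
                    value = as.vector(m))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
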