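# Plain-text file formats: CSV sample matrices with a YAML metadata sidecar
# and a BIDS-like events TSV (columns onset, duration, trial_type; seconds;
# period decimal separator).

sidecar_paths <- function(stem) {
  stem <- sub("\\.csv$", "", stem)
  list(meta = paste0(stem, ".meta.yaml"), events = paste0(stem, ".events.tsv"))
}

write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_events_tsv <- function(path) {
  if (!file.exists(path)) return(events_frame())
  ev <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "trial_type") %in% names(ev)))
    stop(sprintf("events file %s needs columns onset, duration, trial_type", path),
         call. = FALSE)
  ev
}

#' Write an EEG recording to CSV with sidecar metadata and events
#'
#' Writes `<stem>.csv` (time x channels, header = channel labels),
#' `<stem>.meta.yaml` (sampling rate, channel names) and
#' `<stem>.events.tsv`.
#'
#' @param rec An [eeg_recording()].
#' @param stem Output path stem (with or without `.csv`).
#' @return The data CSV path, invisibly.
#' @export
write_eeg_csv <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- sub("\\.csv$", "", stem)
  side <- sidecar_paths(stem)
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$channel_names
  write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  yaml::write_yaml(list(fs = rec$fs, channel_names = as.list(rec$channel_names)),
                   side$meta)
  write_events_tsv(rec$events, side$events)
  invisible(paste0(stem, ".csv"))
}

#' Read an EEG recording from CSV + sidecars
#'
#' @param path Path to the data CSV (or its stem). Expects
#'   `<stem>.meta.yaml` and `<stem>.events.tsv` beside it; the events file
#'   is optional.
#' @return An [eeg_recording()]. The channel count of the CSV must match
#'   the metadata, and event onsets must be strictly increasing.
#' @export
read_eeg_csv <- function(path) {
  stem <- sub("\\.csv$", "", path)
  side <- sidecar_paths(stem)
  if (!file.exists(side$meta))
    stop(sprintf("metadata sidecar %s not found", side$meta), call. = FALSE)
  meta <- yaml::read_yaml(side$meta)
  df <- read.csv(paste0(stem, ".csv"), check.names = FALSE)
  chans <- unlist(meta$channel_names)
  if (ncol(df) != length(chans))
    stop(sprintf("CSV has %d channel column(s) but metadata declares %d",
                 ncol(df), length(chans)), call. = FALSE)
  eeg_recording(t(as.matrix(df)), fs = meta$fs, channel_names = chans,
                events = read_events_tsv(side$events))
}

#' Write an fNIRS recording to paired CSVs with sidecar metadata and events
#'
#' Writes `<stem>.hbo.csv` and `<stem>.hbr.csv` (time x channels),
#' `<stem>.meta.yaml` and `<stem>.events.tsv`.
#'
#' @param rec An [fnirs_recording()].
#' @param stem Output path stem.
#' @return The HBO CSV path, invisibly.
#' @export
write_fnirs_csv <- function(rec, stem) {
  stopifnot(inherits(rec, "fnirs_recording"))
  stem <- sub("\\.(hbo\\.)?csv$", "", stem)
  for (sp in c("hbo", "hbr")) {
    df <- as.data.frame(t(rec[[sp]]))
    names(df) <- rec$channel_names
    write.csv(df, sprintf("%s.%s.csv", stem, sp), row.names = FALSE)
  }
  yaml::write_yaml(list(fs = rec$fs, channel_names = as.list(rec$channel_names)),
                   paste0(stem, ".meta.yaml"))
  write_events_tsv(rec$events, paste0(stem, ".events.tsv"))
  invisible(paste0(stem, ".hbo.csv"))
}

#' Read an fNIRS recording from paired CSVs
#'
#' Both the HBO and the HBR file are required: the total-hemoglobin
#' identity HBT = HBO + HBR cannot be maintained from one species alone.
#'
#' @param stem Path stem as used by [write_fnirs_csv()].
#' @return An [fnirs_recording()].
#' @export
read_fnirs_csv <- function(stem) {
  stem <- sub("\\.(hbo\\.)?csv$", "", stem)
  pb <- sprintf("%s.hbo.csv", stem); pr <- sprintf("%s.hbr.csv", stem)
  if (!file.exists(pb)) stop(sprintf("HBO file %s not found", pb), call. = FALSE)
  if (!file.exists(pr))
    stop(sprintf("HBR file %s not found: both species are required (HBT = HBO + HBR)", pr),
         call. = FALSE)
  meta_path <- paste0(stem, ".meta.yaml")
  if (!file.exists(meta_path))
    stop(sprintf("metadata sidecar %s not found", meta_path), call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  chans <- unlist(meta$channel_names)
  rd <- function(p) {
    df <- read.csv(p, check.names = FALSE)
    if (ncol(df) != length(chans))
      stop(sprintf("%s has %d channel column(s) but metadata declares %d",
                   p, ncol(df), length(chans)), call. = FALSE)
    t(as.matrix(df))
  }
  fnirs_recording(rd(pb), rd(pr), fs = meta$fs, channel_names = chans,
                  events = read_events_tsv(paste0(stem, ".events.tsv")))
}

#' Read a per-subject feature table from CSV
#'
#' Schema by column name (any order, any case): subject_id (optional), AGE,
#' ERD, HBO, BBS.
#'
#' @param path CSV path.
#' @param enforce_bbs Passed to [feature_table()].
#' @return A [feature_table()].
#' @export
read_features <- function(path, enforce_bbs = TRUE) {
  feature_table(read.csv(path, stringsAsFactors = FALSE),
                enforce_bbs = enforce_bbs)
}

#' Write a feature table to CSV
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
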