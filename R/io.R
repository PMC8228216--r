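## Plain-text readers and writers: track CSV, morphology CSV, FASTA.
## All formats are UTF-8; coordinates in micrometres, time as integer frame
## indices (the frame rate travels separately, default 50 Hz).

TRACK_COLUMNS <- c("male_id", "island", "year", "track_id", "frame",
                   "x_um", "y_um", "elongation")

#' Write a track set to CSV
#'
#' One row per tracked point, columns `male_id`, `island`, `year`,
#' `track_id`, `frame`, `x_um`, `y_um`, `elongation`.
#'
#' @param tracks list of [sperm_track()]s.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(male_id = tr$male_id, island = tr$island, year = tr$year,
               track_id = tr$track_id, frame = tr$frame,
               x_um = tr$x, y_um = tr$y, elongation = tr$elongation,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a track CSV
#'
#' Validates the schema, rejects duplicate `(track_id, frame)` pairs and
#' non-monotone frame indices, and returns one [sperm_track()] per track in
#' first-appearance order.
#'
#' @param path a CSV written by [write_tracks_csv()] (header required).
#' @return List of `sperm_track`s.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stopf("track file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRACK_COLUMNS, names(df))
  if (length(miss)) stopf("track CSV '%s' missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  key <- paste(df$track_id, df$frame)
  if (anyDuplicated(key))
    stopf("duplicate (track_id, frame) pair: %s", key[duplicated(key)][1L])
  ord <- unique(df$track_id)
  lapply(ord, function(tid) {
    sub <- df[df$track_id == tid, ]
    if (any(diff(sub$frame) <= 0))
      stopf("track '%s': frame indices not strictly increasing", tid)
    sperm_track(tid, sub$male_id[1L], sub$island[1L],
                as.character(sub$year[1L]), frame = sub$frame,
                x = sub$x_um, y = sub$y_um, elongation = sub$elongation[1L])
  })
}

MORPH_COLUMNS <- c("male_id", "island", "year", "cell_id", "head_um",
                   "midpiece_um", "tail_um")

#' Write a morphology cell table to CSV
#'
#' @param cells data frame with the morphology schema (`male_id`, `island`,
#'   `year`, `cell_id`, `head_um`, `midpiece_um`, `tail_um`, optional
#'   `measurer`).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_morphology_csv <- function(cells, path) {
  miss <- setdiff(MORPH_COLUMNS, names(cells))
  if (length(miss)) stopf("morphology table missing column(s): %s",
                          paste(miss, collapse = ", "))
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read a morphology CSV
#'
#' Validates the schema and rejects non-positive lengths, reporting the
#' offending row.
#'
#' @param path CSV with the morphology schema.
#' @return Data frame of cells.
#' @export
read_morphology <- function(path) {
  if (!file.exists(path)) stopf("morphology file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(MORPH_COLUMNS, names(df))
  if (length(miss)) stopf("morphology CSV '%s' missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  for (nm in c("head_um", "midpiece_um", "tail_um")) {
    bad <- which(!is.finite(df[[nm]]) | df[[nm]] <= 0)
    if (length(bad))
      stopf("morphology CSV '%s': column '%s' non-positive at row %d",
            path, nm, bad[1L])
  }
  df$year <- as.character(df$year)
  df
}

#' Write aligned sequences to FASTA
#'
#' @param sequences named character vector (one record per individual, id
#'   typically `<individual>_<island>`).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences))) stopf("sequences must be named")
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(sequences), ""), identity))
  names(bin) <- names(sequences)
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' Read aligned sequences from FASTA
#'
#' @param path FASTA file; record ids must be unique.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  bin <- ape::read.FASTA(path)
  if (length(bin) == 0L) stopf("FASTA '%s' contains no sequences", path)
  if (anyDuplicated(names(bin)))
    stopf("FASTA '%s' has duplicate id(s): %s", path,
          names(bin)[duplicated(names(bin))][1L])
  vapply(as.character(bin), function(s) toupper(paste(s, collapse = "")), "")
}
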