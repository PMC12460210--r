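# Plain-text interchange: columnar EEG with a JSON sidecar, tidy CSV tables
# for connectivity, node metrics and behavior.

#' Write an EEG recording as columnar text plus JSON sidecar
#'
#' The samples x channels matrix goes to `<prefix>.tsv` (tab-separated, with
#' a header of channel labels) and the metadata (sampling rate, labels,
#' subject/session/trial) to `<prefix>.json`.
#'
#' @param rec An [eeg_recording()].
#' @param prefix Path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_eeg_columnar <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  utils::write.table(t(rec$data), tsv, sep = "\t", row.names = FALSE,
                     col.names = rec$channel_labels, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         subject = rec$subject, session = rec$session, trial = rec$trial),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(data = tsv, sidecar = js))
}

#' Read an EEG recording written by [write_eeg_columnar()]
#'
#' @param prefix Path prefix (without extension).
#' @return An [eeg_recording()].
#' @export
read_eeg_columnar <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t",
                                   header = TRUE, check.names = FALSE))
  eeg_recording(t(x), fs = as.numeric(meta$fs),
                channel_labels = meta$channel_labels,
                subject = meta$subject, session = meta$session,
                trial = if (is.null(meta$trial)) NA_integer_ else
                  as.integer(meta$trial))
}

#' Write connectivity matrices as a tidy long CSV
#'
#' @param mats List of `"conn_matrix"` objects.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_conn_long <- function(mats, path) {
  utils::write.csv(conn_to_long(mats), path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy long connectivity CSV back into matrices
#'
#' @param path CSV written by [write_conn_long()].
#' @param channel_labels Node ordering for the rebuilt matrices; defaults to
#'   [eeg_montage_16()] when all nodes belong to it, else sorted labels.
#' @return Named list of `"conn_matrix"` objects (subject/session/band).
#' @export
read_conn_long <- function(path, channel_labels = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  nodes <- unique(c(d$node_i, d$node_j))
  if (is.null(channel_labels)) {
    channel_labels <- if (all(nodes %in% eeg_montage_16()))
      intersect(eeg_montage_16(), nodes) else sort(nodes)
  }
  keys <- paste(d$subject, d$session, d$band, sep = "/")
  lapply(split(d, keys), function(g) {
    n <- length(channel_labels)
    m <- matrix(0, n, n)
    i <- match(g$node_i, channel_labels)
    j <- match(g$node_j, channel_labels)
    m[cbind(i, j)] <- g$value
    m[cbind(j, i)] <- g$value
    conn_matrix(m, g$band[1], channel_labels, n_windows = NA_integer_,
                subject = as.character(g$subject[1]),
                session = as.character(g$session[1]))
  })
}
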