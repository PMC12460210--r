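# EEG containers, zero-phase filtering, sliding windows, and band-wise
# PLV / ciPLV connectivity estimation from windowed cross-spectra.

#' Construct an EEG recording
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz (512 for study-faithful runs).
#' @param channel_labels Ordered channel labels; defaults to the 16-channel
#'   montage of [eeg_montage_16()] when `data` has 16 rows.
#' @param subject,session,trial Identifiers carried through the pipeline.
#' @return Object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject = NA_character_, session = NA_character_,
                          trial = NA_integer_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 16L) eeg_montage_16() else
      paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must match nrow(data)", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject = subject, session = session, trial = trial),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz",
      if (!is.na(x$subject)) paste0("  [", x$subject, "/", x$session,
                                    "/trial ", x$trial, "]"), "\n", sep = "")
  invisible(x)
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies, per channel, an eighth-order Butterworth band-pass (0.5-100 Hz by
#' default) followed by a fourth-order Butterworth band-stop notch around
#' 50 Hz, both run forward-backward (`signal::filtfilt`) so that no phase
#' distortion is introduced ahead of phase-synchronization estimation.
#'
#' @param rec An [eeg_recording()].
#' @param band Band-pass edges in Hz.
#' @param band_order Band-pass filter order (even; 8 = order-4 prototype).
#' @param notch Notch center frequency in Hz; `NULL` disables the notch.
#' @param notch_width Full stop-band width in Hz around `notch`.
#' @param notch_order Notch filter order (even).
#' @return The filtered recording (length preserved).
#' @export
preprocess_eeg <- function(rec, band = c(0.5, 100), band_order = 8,
                           notch = 50, notch_width = 4, notch_order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (band[2] >= nyq) {
    stop("sampling rate too low for a ", band[2], " Hz band edge (Nyquist ",
         nyq, " Hz)", call. = FALSE)
  }
  bp <- signal::butter(band_order / 2, band / nyq, type = "pass")
  x <- rec$data
  for (i in seq_len(nrow(x))) x[i, ] <- signal::filtfilt(bp, x[i, ])
  if (!is.null(notch) && notch < nyq) {
    bs <- signal::butter(notch_order / 2,
                         c(notch - notch_width / 2, notch + notch_width / 2) / nyq,
                         type = "stop")
    for (i in seq_len(nrow(x))) x[i, ] <- signal::filtfilt(bs, x[i, ])
  }
  rec$data <- x
  rec
}

#' Number of full sliding windows in a recording
#'
#' `floor((T - window_length) / stride) + 1` for duration `T`; ragged tails
#' are dropped.
#'
#' @param duration Recording duration in seconds.
#' @param window_length,stride Window length and stride in seconds.
#' @return Integer window count (0 when `duration < window_length`).
#' @export
#' @examples
#' n_sliding_windows(240, 4, 2)  # 119
n_sliding_windows <- function(duration, window_length = 4, stride = 2) {
  if (window_length <= 0 || stride <= 0) {
    stop("window_length and stride must be positive", call. = FALSE)
  }
  if (duration < window_length) return(0L)
  as.integer(floor((duration - window_length) / stride) + 1)
}

#' Cut a recording into sliding windows
#'
#' @param rec An [eeg_recording()] (or a list of them, whose windows are
#'   pooled in order — e.g. the trials of one session).
#' @param window_length Window length in seconds (default 4).
#' @param stride Stride between window onsets in seconds (default 2).
#' @return Object of class `"window_set"`: list of channels x samples
#'   matrices plus `fs`, `channel_labels`, `window_length`, `stride`, and a
#'   `provenance` data frame (subject, session, trial per window).
#' @export
sliding_windows <- function(rec, window_length = 4, stride = 2) {
  if (inherits(rec, "eeg_recording")) rec <- list(rec)
  stopifnot(all(vapply(rec, inherits, TRUE, "eeg_recording")))
  fs <- rec[[1]]$fs
  labels <- rec[[1]]$channel_labels
  wl <- round(window_length * fs)
  st <- round(stride * fs)
  if (wl <= 0 || st <= 0) {
    stop("window_length and stride must be positive", call. = FALSE)
  }
  windows <- list()
  prov <- list()
  for (r in rec) {
    if (!identical(r$fs, fs) || !identical(r$channel_labels, labels)) {
      stop("all recordings must share fs and channel labels", call. = FALSE)
    }
    n <- ncol(r$data)
    if (n < wl) {
      stop("recording shorter than one window (", n / fs, " s < ",
           window_length, " s)", call. = FALSE)
    }
    nw <- floor((n - wl) / st) + 1
    for (k in seq_len(nw)) {
      off <- (k - 1) * st
      windows[[length(windows) + 1L]] <- r$data[, (off + 1):(off + wl),
                                                drop = FALSE]
      prov[[length(prov) + 1L]] <- data.frame(subject = r$subject,
                                              session = r$session,
                                              trial = r$trial)
    }
  }
  structure(list(windows = windows, fs = fs, channel_labels = labels,
                 window_length = window_length, stride = stride,
                 provenance = do.call(rbind, prov)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> ", length(x$windows), " windows of ", x$window_length,
      " s (stride ", x$stride, " s) @ ", x$fs, " Hz, ",
      length(x$channel_labels), " channels\n", sep = "")
  invisible(x)
}

# Per-window Hann-tapered FFT of all channels; returns a list of
# (n_bins x n_channels) complex matrices restricted to the requested bins.
window_spectra <- function(ws, bin_idx) {
  n <- ncol(ws$windows[[1]])
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  lapply(ws$windows, function(w) {
    X <- stats::mvfft(t(w) * taper)
    X[bin_idx, , drop = FALSE]
  })
}

# Shared driver: average over windows of the unit-normalized cross-spectrum,
# per frequency bin; returns complex n_ch x n_ch x n_bins array E.
normalized_cross_expectation <- function(ws, band) {
  band <- resolve_band(band)
  n <- ncol(ws$windows[[1]])
  if (length(ws$windows) < 2L) {
    stop("need at least 2 windows for a cross-window expectation",
         call. = FALSE)
  }
  freqs <- (seq_len(n) - 1) * ws$fs / n
  if (band[2] >= ws$fs / 2) {
    stop("band upper edge must lie below Nyquist", call. = FALSE)
  }
  bin_idx <- which(freqs >= band[1] & freqs <= band[2] & freqs > 0)
  if (!length(bin_idx)) {
    stop("no frequency bins fall inside the band [", band[1], ", ", band[2],
         "] Hz at this window length", call. = FALSE)
  }
  nc <- length(ws$channel_labels)
  specs <- window_spectra(ws, bin_idx)
  acc <- array(0 + 0i, dim = c(nc, nc, length(bin_idx)))
  for (X in specs) {
    for (b in seq_along(bin_idx)) {
      v <- X[b, ]
      S <- outer(v, Conj(v))
      a <- abs(S)
      a[a == 0] <- 1           # zero-power bins contribute 0, not NaN
      acc[, , b] <- acc[, , b] + S / a
    }
  }
  list(E = acc / length(specs), bins = bin_idx,
       freqs = freqs[bin_idx])
}

#' Construct a connectivity matrix object
#'
#' Container for one symmetric node-by-node connectivity matrix with its
#' band, provenance and window count. Usually produced by [ciplv()] or
#' [plv()]; exported so matrices from other sources can enter the pipeline.
#'
#' @param values Symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\] for phase-locking measures.
#' @param band Band name or numeric `c(lo, hi)` (stored as a label).
#' @param channel_labels Node labels, one per row.
#' @param n_windows Number of windows the estimate was averaged over.
#' @param subject,session Identifiers.
#' @param measure Estimator name (default `"ciplv"`).
#' @return Object of class `"conn_matrix"`.
#' @export
conn_matrix <- function(values, band, channel_labels, n_windows,
                        subject = NA_character_, session = NA_character_,
                        measure = "ciplv") {
  dimnames(values) <- list(channel_labels, channel_labels)
  structure(list(values = values, band = band_label(band),
                 channel_labels = channel_labels, n_windows = n_windows,
                 subject = subject, session = session, measure = measure),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat("<conn_matrix> ", x$measure, ", band ", x$band, ", ",
      nrow(x$values), " nodes, ", x$n_windows, " windows",
      if (!is.na(x$subject)) paste0("  [", x$subject, "/", x$session, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Corrected imaginary phase-locking value (ciPLV) connectivity
#'
#' For every channel pair and frequency bin in `band`, averages the
#' unit-normalized cross-spectrum `S_xy / |S_xy|` over windows and forms
#' \deqn{\mathrm{ciPLV} = \frac{|E[\Im(S_{xy}/|S_{xy}|)]|}
#'                             {\sqrt{1 - |E[\Re(S_{xy}/|S_{xy}|)]|^2}}}
#' then averages ciPLV across the bins of the band. The correction discards
#' the real (zero-lag) part of the mean phase difference, so synchrony that is
#' instantaneous — the signature of volume conduction and source leakage —
#' scores 0, while a consistent non-zero phase lag scores up to 1.
#'
#' Bins where `|E[Re]| = 1` (phase differences identically zero, so the
#' imaginary part is identically 0) are set to 0; the number of such bins is
#' attached as attribute `"degenerate_bins"` on the value matrix.
#'
#' @param ws A [sliding_windows()] window set (>= 2 windows).
#' @param band Band name (`"theta"`, `"alpha"`, `"beta"`, `"gamma"`) or
#'   numeric `c(lo, hi)` in Hz, inside (0, fs/2).
#' @param subject,session Identifiers stored on the result.
#' @return A `"conn_matrix"`: symmetric matrix in \[0, 1\] with zero diagonal.
#' @seealso [plv()] for the uncorrected phase-locking value.
#' @export
ciplv <- function(ws, band, subject = NA_character_,
                  session = NA_character_) {
  stopifnot(inherits(ws, "window_set"))
  ex <- normalized_cross_expectation(ws, band)
  Ere <- Re(ex$E)
  Eim <- Im(ex$E)
  num <- abs(Eim)
  re_mag <- pmin(abs(Ere), 1)
  den <- sqrt(1 - re_mag^2)
  vals <- array(0, dim = dim(num))
  ok <- den > 1e-9
  vals[ok] <- num[ok] / den[ok]
  ut <- upper.tri(vals[, , 1])
  degenerate <- sum(apply(!ok, 3, function(m) sum(m[ut])))
  m <- apply(vals, c(1, 2), mean)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m <- pmin(m, 1)
  attr(m, "degenerate_bins") <- degenerate
  conn_matrix(m, band, ws$channel_labels, length(ws$windows),
              subject, session, measure = "ciplv")
}

#' Classical phase-locking value (PLV) connectivity
#'
#' `PLV = |E[S_xy / |S_xy|]|` per frequency bin, averaged across the band's
#' bins. Unlike [ciplv()], PLV retains the real part of the mean phase
#' difference, so zero-lag (volume-conducted) synchrony scores near 1.
#'
#' @inheritParams ciplv
#' @return A `"conn_matrix"` with `measure = "plv"`.
#' @export
plv <- function(ws, band, subject = NA_character_, session = NA_character_) {
  stopifnot(inherits(ws, "window_set"))
  ex <- normalized_cross_expectation(ws, band)
  vals <- sqrt(Re(ex$E)^2 + Im(ex$E)^2)
  m <- apply(vals, c(1, 2), mean)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  conn_matrix(pmin(m, 1), band, ws$channel_labels, length(ws$windows),
              subject, session, measure = "plv")
}

#' Average connectivity matrices element-wise
#'
#' @param mats List of `"conn_matrix"` objects sharing band, measure and
#'   channel labels (e.g. the per-trial matrices of one session).
#' @return One `"conn_matrix"`, the element-wise arithmetic mean, with
#'   `n_windows` summed.
#' @export
average_conn <- function(mats) {
  stopifnot(length(mats) >= 1L, all(vapply(mats, inherits, TRUE, "conn_matrix")))
  bands <- unique(vapply(mats, `[[`, "", "band"))
  if (length(bands) != 1L) {
    stop("cannot average matrices of mixed bands: ",
         paste(bands, collapse = ", "), call. = FALSE)
  }
  vals <- Reduce(`+`, lapply(mats, function(m) unclass(m$values))) /
    length(mats)
  conn_matrix(vals, bands, mats[[1]]$channel_labels,
              sum(vapply(mats, `[[`, 0, "n_windows")),
              mats[[1]]$subject, mats[[1]]$session, mats[[1]]$measure)
}

#' Average connectivity matrices by subject, session and band
#'
#' Groups a flat list of `"conn_matrix"` objects by (subject, session, band)
#' and element-wise averages each group, yielding one matrix per subject and
#' session per band.
#'
#' @param mats List of `"conn_matrix"` objects.
#' @return Named list of `"conn_matrix"` (names `subject/session/band`).
#' @export
average_sessions <- function(mats) {
  stopifnot(all(vapply(mats, inherits, TRUE, "conn_matrix")))
  keys <- vapply(mats, function(m)
    paste(m$subject, m$session, m$band, sep = "/"), "")
  out <- lapply(split(mats, keys), average_conn)
  out[order(names(out))]
}

#' Flatten connectivity matrices to a tidy long table
#'
#' @param mats List of `"conn_matrix"` objects (or a single one).
#' @return Data frame with columns `subject`, `session`, `band`, `node_i`,
#'   `node_j`, `value` — one row per unique undirected pair (i < j).
#' @export
conn_to_long <- function(mats) {
  if (inherits(mats, "conn_matrix")) mats <- list(mats)
  rows <- lapply(mats, function(m) {
    up <- upper_pairs(nrow(m$values))
    data.frame(subject = m$subject, session = m$session, band = m$band,
               node_i = m$channel_labels[up[, 1]],
               node_j = m$channel_labels[up[, 2]],
               value = m$values[up])
  })
  do.call(rbind, rows)
}

#' Nearest-neighbour surface Laplacian re-reference (approximation)
#'
#' Hjorth-style spatial high-pass: each channel minus the mean of its
#' neighbours under a fixed adjacency map for the 16-channel montage. This is
#' a coarse, montage-geometry-free approximation of a true spline surface
#' Laplacian and is off by default in the pipeline; it is provided for
#' sensitivity analyses only.
#'
#' @param rec An [eeg_recording()] with the [eeg_montage_16()] labels.
#' @return The re-referenced recording.
#' @export
surface_laplacian_nn <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nb <- list(
    AF3 = c("AF4", "FC3", "FCz"), AF4 = c("AF3", "FCz", "FC4"),
    FC3 = c("AF3", "FCz", "C3"), FCz = c("AF3", "AF4", "FC3", "FC4", "Cz"),
    FC4 = c("AF4", "FCz", "C4"), C3 = c("FC3", "T7", "Cz", "CP3"),
    Cz = c("FCz", "C3", "C4", "CPz"), C4 = c("FC4", "Cz", "T8", "CP4"),
    T7 = c("C3", "CP3"), T8 = c("C4", "CP4"),
    CP3 = c("C3", "T7", "CPz", "Pz"), CPz = c("Cz", "CP3", "CP4", "Pz"),
    CP4 = c("C4", "T8", "CPz", "Pz"), Pz = c("CP3", "CPz", "CP4", "O1", "O2"),
    O1 = c("Pz", "O2"), O2 = c("Pz", "O1"))
  if (!all(rec$channel_labels %in% names(nb))) {
    stop("nearest-neighbour Laplacian is defined only for the standard ",
         "16-channel montage", call. = FALSE)
  }
  x <- rec$data
  out <- x
  for (ch in rec$channel_labels) {
    out[ch, ] <- x[ch, ] - colMeans(x[nb[[ch]], , drop = FALSE])
  }
  rec$data <- out
  rec
}
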