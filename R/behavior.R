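# Behavioral task: sum-of-sines tracks, clipped-Pearson tracking score,
# session aggregation and bimanual PCA.

#' Evaluate a sum-of-sines track profile
#'
#' Computes the horizontal track coordinate
#' \deqn{g(y, t) = \sum_i A_i \sin(f_i (y + t/6) + \phi_i)}
#' where the phases `phi_deg` are given in degrees and converted to radians.
#' This is the deterministic kernel behind [generate_track()]; it is exported
#' so tests and callers can evaluate arbitrary component sets.
#'
#' @param A,f,phi_deg Numeric vectors of equal length: amplitudes, frequencies
#'   and phases (degrees) of the sine components.
#' @param t Time points in seconds.
#' @param y Vertical coordinate (scalar, normalized screen units); default 0
#'   evaluates the track at the cursor row.
#' @return Numeric vector of track x-coordinates, one per element of `t`.
#' @export
#' @examples
#' eval_track(A = 1, f = 0, phi_deg = 90, t = seq(0, 1, by = 0.02))
eval_track <- function(A, f, phi_deg, t, y = 0) {
  stopifnot(length(A) == length(f), length(f) == length(phi_deg))
  g <- numeric(length(t))
  phi <- phi_deg * pi / 180
  for (i in seq_along(A)) {
    g <- g + A[i] * sin(f[i] * (y + t / 6) + phi[i])
  }
  g
}

#' Generate a pseudorandom tracking-task track
#'
#' Draws 20 sine components with amplitudes `A ~ U(1, 10)`, phases
#' `phi ~ U(-180, 180)` degrees, and frequencies uniform on a
#' difficulty-dependent range: `U(0.01, 0.5)` (easy), `U(0.01, 0.75)`
#' (moderate), or `U(0.01, 1)` (hard). The track is sampled at `fs` Hz
#' (50 Hz, the display refresh rate, by default).
#'
#' @param difficulty One of `"easy"`, `"moderate"`, `"hard"`.
#' @param duration Track duration in seconds (> 0).
#' @param seed Integer seed; equal seeds yield identical tracks.
#' @param fs Sampling rate in Hz.
#' @param y Vertical coordinate at which the profile is evaluated.
#' @param n_components Number of sine components (20 by default).
#' @return An object of class `"track_trace"`: list with `t`, `g`, the
#'   component parameters `A`, `f`, `phi_deg`, and `fs`, `difficulty`, `y`.
#' @export
#' @examples
#' tr <- generate_track("hard", duration = 10, seed = 1)
#' range(tr$g)
generate_track <- function(difficulty = c("easy", "moderate", "hard"),
                           duration, seed = NULL, fs = 50, y = 0,
                           n_components = 20L) {
  difficulty <- match.arg(difficulty)
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  f_max <- switch(difficulty, easy = 0.5, moderate = 0.75, hard = 1)
  par <- with_seed(seed, {
    list(A = stats::runif(n_components, 1, 10),
         f = stats::runif(n_components, 0.01, f_max),
         phi_deg = stats::runif(n_components, -180, 180))
  })
  t <- seq(0, duration, by = 1 / fs)
  structure(
    list(t = t, g = eval_track(par$A, par$f, par$phi_deg, t, y = y),
         A = par$A, f = par$f, phi_deg = par$phi_deg,
         fs = fs, difficulty = difficulty, y = y),
    class = "track_trace")
}

#' @export
print.track_trace <- function(x, ...) {
  cat("<track_trace> ", x$difficulty, " difficulty, ",
      length(x$t), " samples @ ", x$fs, " Hz, ",
      length(x$A), " sine components\n", sep = "")
  invisible(x)
}

#' Clipped-Pearson tracking performance score
#'
#' Pearson correlation between cursor and track positions, clipped below at
#' zero, so the score lies in \[0, 1\]: 1 means perfect linear tracking,
#' 0 means no (or negative) linear relationship. The score is invariant to
#' positive affine transforms of either trace.
#'
#' @param cursor,track Numeric vectors of equal length (n >= 3), each with
#'   non-zero variance.
#' @return Scalar score in \[0, 1\].
#' @export
#' @examples
#' performance_r(1:10, 1:10)        # 1
#' performance_r(1:10, 10:1)        # 0 (negative correlation clipped)
performance_r <- function(cursor, track) {
  if (length(cursor) != length(track)) {
    stop("cursor and track must have equal length", call. = FALSE)
  }
  if (length(cursor) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(cursor) == 0 || stats::sd(track) == 0) {
    stop("correlation undefined: zero-variance input", call. = FALSE)
  }
  max(stats::cor(cursor, track), 0)
}

#' Average per-trial hand scores within sessions
#'
#' Collapses trial-level scores to one mean per subject x session x hand,
#' irrespective of task condition. Every subject x session x hand cell must
#' contain at least one trial.
#'
#' @param trials Data frame with columns `subject`, `session`, `hand`, `r`
#'   (and optionally `trial`).
#' @return Data frame with columns `subject`, `session`, `hand`, `r`
#'   (the trial mean), one row per cell.
#' @export
session_scores <- function(trials) {
  needed <- c("subject", "session", "hand", "r")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- stats::aggregate(r ~ subject + session + hand, data = trials,
                          FUN = mean)
  full <- expand.grid(subject = unique(trials$subject),
                      session = unique(trials$session),
                      hand = unique(trials$hand),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$session, d$hand, sep = "/")
  absent <- setdiff(key(full), key(out))
  if (length(absent)) {
    stop("no trials for cell(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out[order(out$subject, out$session, out$hand), , drop = FALSE]
}

#' Reduce left- and right-hand scores to one bimanual performance score
#'
#' First principal component of the standardized (left, right) session-mean
#' matrix, pooling all subject x session rows. The component sign is fixed so
#' that the score correlates positively with the mean of the two hands; the
#' explained-variance fraction of the first component is reported.
#'
#' @param scores Data frame with columns `subject`, `session`, `left`,
#'   `right` (session-mean hand scores), at least 3 rows.
#' @return List of class `"bimanual_pca"`: `scores` (data frame with
#'   `subject`, `session`, `pc1`), `explained_variance`, `loadings`,
#'   `center`, `scale`.
#' @export
bimanual_pca <- function(scores) {
  needed <- c("subject", "session", "left", "right")
  if (!all(needed %in% names(scores))) {
    stop("scores must have columns subject, session, left, right",
         call. = FALSE)
  }
  if (nrow(scores) < 3L) stop("need at least 3 rows for PCA", call. = FALSE)
  x <- as.matrix(scores[, c("left", "right")])
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("degenerate PCA: a hand score column is constant", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  pc1 <- pc$x[, 1]
  # sign convention: positive association with the mean of the two hands
  if (stats::cor(pc1, rowMeans(x)) < 0) {
    pc1 <- -pc1
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  ev <- pc$sdev[1]^2 / sum(pc$sdev^2)
  structure(
    list(scores = data.frame(subject = scores$subject,
                             session = scores$session, pc1 = pc1,
                             row.names = NULL),
         explained_variance = ev,
         loadings = pc$rotation[, 1],
         center = pc$center, scale = pc$scale),
    class = "bimanual_pca")
}

#' @export
print.bimanual_pca <- function(x, ...) {
  cat("<bimanual_pca> ", nrow(x$scores), " observations; PC1 explains ",
      sprintf("%.1f%%", 100 * x$explained_variance), " of variance\n",
      sep = "")
  invisible(x)
}
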