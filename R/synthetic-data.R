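# Seeded synthetic generators: band-limited phase-coupled EEG, paired
# pre/post connectivity cohorts, and simulated tracking behavior. These
# provide the ground truth against which every analysis stage is validated.

#' Specify a phase coupling between two channels
#'
#' @param pair Character vector of two channel labels (order matters: the
#'   second channel carries the phase-shifted copy).
#' @param band Band name (`theta`, `alpha`, `beta`, `gamma`) or numeric
#'   `c(lo, hi)` in Hz.
#' @param phase_lag Phase lag in radians, in (-pi, pi]. A lag of 0 produces
#'   pure zero-lag synchrony (high PLV, ciPLV near 0 — the volume-conduction
#'   trap the corrected estimator exists to reject).
#' @param strength Coupling coefficient in \[0, 1\]; 0 leaves the pair
#'   independent, 1 makes the pair's band component fully shared.
#' @return List of class `"coupling_spec"`.
#' @export
coupling_spec <- function(pair, band, phase_lag, strength) {
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop("pair must be two distinct channel labels", call. = FALSE)
  }
  resolve_band(band)
  if (phase_lag <= -pi || phase_lag > pi) {
    stop("phase_lag must lie in (-pi, pi]", call. = FALSE)
  }
  if (strength < 0 || strength > 1) {
    stop("strength must lie in [0, 1]", call. = FALSE)
  }
  structure(list(pair = pair, band = band, phase_lag = phase_lag,
                 strength = strength), class = "coupling_spec")
}

# Unit-variance band-limited Gaussian carrier: white noise band-pass
# filtered (zero-phase) to the requested band.
bandlimited_noise <- function(n, fs, band) {
  band <- resolve_band(band)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

# 1/f-shaped background noise, unit variance.
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))                 # avoid dividing DC by 0
  f <- pmin(f, n - f + 1)                   # mirror for negative freqs
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Rotate every spectral component of x by `lag` radians (analytic-signal
# rotation); for a narrow-band signal this delays its phase by `lag`.
phase_rotate <- function(x, lag) {
  Re(analytic_signal(x) * exp(-1i * lag))
}

#' Generate multichannel EEG with controlled narrow-band phase coupling
#'
#' Each channel is independent 1/f-shaped background noise of amplitude
#' `noise_sd`. For every [coupling_spec()], a unit-variance band-limited
#' Gaussian carrier is added to the first channel of the pair, and the
#' second channel receives a mixture
#' `strength * rotated_carrier + sqrt(1 - strength^2) * independent_carrier`,
#' where the rotated copy is the carrier with every spectral component
#' shifted by `phase_lag` radians. Expected ciPLV for the pair therefore
#' grows monotonically with `strength` (at fixed non-zero lag) and reaches 1
#' at `strength = 1`, `noise_sd = 0`.
#'
#' @param spec_list List of [coupling_spec()] objects (possibly empty).
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz; must exceed twice the highest requested
#'   band edge.
#' @param duration Duration in seconds; must cover at least one analysis
#'   window (`min_duration`).
#' @param noise_sd Amplitude of the per-channel background noise.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param channel_labels Channel labels; defaults to [eeg_montage_16()] for
#'   16 channels.
#' @param min_duration Minimum admissible duration in seconds (one analysis
#'   window; 4 by default).
#' @param subject,session,trial Identifiers stored on the recording.
#' @return An [eeg_recording()].
#' @export
gen_coupled_eeg <- function(spec_list = list(), n_channels = 16, fs = 512,
                            duration = 60, noise_sd = 1, seed = NULL,
                            channel_labels = NULL, min_duration = 4,
                            subject = NA_character_, session = NA_character_,
                            trial = NA_integer_) {
  if (inherits(spec_list, "coupling_spec")) spec_list <- list(spec_list)
  stopifnot(all(vapply(spec_list, inherits, TRUE, "coupling_spec")))
  if (duration < min_duration) {
    stop("duration (", duration, " s) shorter than one analysis window (",
         min_duration, " s)", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (n_channels == 16L) eeg_montage_16() else
      paste0("ch", seq_len(n_channels))
  }
  for (sp in spec_list) {
    upper <- resolve_band(sp$band)[2]
    if (fs <= 2 * upper) {
      stop("fs must exceed twice the band's upper edge (", upper, " Hz)",
           call. = FALSE)
    }
    if (!all(sp$pair %in% channel_labels)) {
      stop("coupling pair refers to unknown channel label(s): ",
           paste(setdiff(sp$pair, channel_labels), collapse = ", "),
           call. = FALSE)
    }
  }
  n <- round(duration * fs)
  with_seed(seed, {
    x <- matrix(0, n_channels, n, dimnames = list(channel_labels, NULL))
    if (noise_sd > 0) {
      for (i in seq_len(n_channels)) x[i, ] <- noise_sd * pink_noise(n)
    }
    for (sp in spec_list) {
      if (sp$strength == 0) next
      i <- match(sp$pair[1], channel_labels)
      j <- match(sp$pair[2], channel_labels)
      carrier <- bandlimited_noise(n, fs, sp$band)
      indep <- bandlimited_noise(n, fs, sp$band)
      x[i, ] <- x[i, ] + carrier
      x[j, ] <- x[j, ] + sp$strength * phase_rotate(carrier, sp$phase_lag) +
        sqrt(1 - sp$strength^2) * indep
    }
    eeg_recording(x, fs, channel_labels, subject, session, trial)
  })
}

#' Specify a paired two-session synthetic cohort
#'
#' Defines the generative model for a pre/post cohort of connectivity
#' matrices (or raw recordings). With `effect_size = 0` the two sessions are
#' exchangeable draws from one distribution (the null configuration for
#' family-wise-error simulation); with `effect_size != 0`, exactly the edges
#' in `effect_edges` change in expectation by `effect_size` (post minus pre,
#' in ciPLV units).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effect_edges Edges carrying the session effect: a list of
#'   2-element character vectors of channel labels (or `NULL` for none).
#' @param effect_size Additive post-minus-pre change in expected edge weight
#'   (ciPLV units); negative values model the training-related connectivity
#'   decreases typical of adaptation studies.
#' @param noise_sd Within-subject standard deviation of edge weights
#'   (ciPLV units; default 0.05).
#' @param seed Integer seed.
#' @param mode `"matrix"` draws connectivity matrices directly (fast; used
#'   for permutation-test simulation), `"eeg"` synthesises raw recordings via
#'   [gen_coupled_eeg()] for full-pipeline runs.
#' @param channel_labels Channel labels (default 16-channel montage).
#' @param band Band label attached to generated matrices.
#' @param behavior_link Slope linking a per-observation latent to the
#'   behavioral score; 0 (default) leaves behavior independent of
#'   connectivity. When non-zero, the same latent also displaces every edge
#'   incident to the `link_nodes` by `latent_scale * latent`, planting a
#'   monotone node-metric/performance association.
#' @param link_nodes Channel labels of the nodes carrying the planted
#'   behavior association (ignored when `behavior_link = 0`).
#' @param latent_scale Edge-weight displacement per latent unit (ciPLV
#'   units) when `behavior_link` is non-zero.
#' @param session_shift Additive post-minus-pre change in expected behavior
#'   score (training effect; default 0.16, a realistic improvement for this
#'   task).
#' @param behavior_noise SD of trial-level behavior noise.
#' @param n_trials Trials per session per hand for behavior generation.
#' @param eeg_duration,fs Recording length (s) and sampling rate for
#'   `mode = "eeg"`.
#' @param base_strength Baseline coupling strength on `effect_edges` in
#'   `mode = "eeg"`.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 20, effect_edges = NULL,
                        effect_size = 0, noise_sd = 0.05, seed = NULL,
                        mode = c("matrix", "eeg"), channel_labels = NULL,
                        band = "theta", behavior_link = 0,
                        link_nodes = NULL,
                        latent_scale = 0.08, session_shift = 0.16,
                        behavior_noise = 0.05, n_trials = 4,
                        eeg_duration = 20, fs = 512, base_strength = 0.5) {
  mode <- match.arg(mode)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (is.null(channel_labels)) channel_labels <- eeg_montage_16()
  if (!is.null(effect_edges)) {
    if (is.matrix(effect_edges)) {
      effect_edges <- split(effect_edges, row(effect_edges))
    }
    for (e in effect_edges) {
      if (length(e) != 2L || !all(e %in% channel_labels)) {
        stop("effect edge refers to unknown channel label(s): ",
             paste(setdiff(e, channel_labels), collapse = ", "),
             call. = FALSE)
      }
    }
  }
  if (!is.null(link_nodes) && !all(link_nodes %in% channel_labels)) {
    stop("link_nodes contains unknown channel label(s): ",
         paste(setdiff(link_nodes, channel_labels), collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, effect_edges = effect_edges,
                 effect_size = effect_size, noise_sd = noise_sd, seed = seed,
                 mode = mode, channel_labels = channel_labels, band = band,
                 behavior_link = behavior_link, link_nodes = link_nodes,
                 latent_scale = latent_scale,
                 session_shift = session_shift,
                 behavior_noise = behavior_noise, n_trials = n_trials,
                 eeg_duration = eeg_duration, fs = fs,
                 base_strength = base_strength),
            class = "cohort_spec")
}

#' Generate a paired pre/post synthetic cohort
#'
#' In `"matrix"` mode, each subject x session connectivity matrix is drawn as
#' `clip01(mu_e + effect + latent displacement + N(0, noise_sd))` per unique
#' edge, with fixed per-cohort baseline means `mu_e ~ U(0.25, 0.55)`; the
#' session effect `effect_size` is added to the post-session expectation of
#' exactly the `effect_edges`. In `"eeg"` mode, raw recordings are
#' synthesised with coupling strengths on `effect_edges` shifted between
#' sessions. Trial-level left/right behavior scores are generated alongside,
#' optionally linked to the connectivity latent (see [cohort_spec()]).
#'
#' @param spec A [cohort_spec()].
#' @return List of class `"cohort"` with elements `pre` and `post` (lists of
#'   [eeg_recording()] lists or `"conn_matrix"` objects, one per subject),
#'   `behavior` (trial-level data frame: subject, session, trial, hand, r),
#'   `latent` (subject x session data frame), and `spec`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    nsub <- spec$n_subjects
    subjects <- sprintf("S%02d", seq_len(nsub))
    nch <- length(spec$channel_labels)
    up <- upper_pairs(nch)
    ne <- nrow(up)
    eff_idx <- integer(0)
    if (!is.null(spec$effect_edges)) {
      eff_idx <- vapply(spec$effect_edges, function(e) {
        i <- sort(match(e, spec$channel_labels))
        which(up[, 1] == i[1] & up[, 2] == i[2])
      }, 0L)
    }
    # per-observation latent shared by connectivity and behavior
    latent <- expand.grid(subject = subjects, session = c("pre", "post"),
                          stringsAsFactors = FALSE)
    latent$u <- stats::rnorm(nrow(latent))
    get_u <- function(s, sess)
      latent$u[latent$subject == s & latent$session == sess]

    pre <- vector("list", nsub)
    post <- vector("list", nsub)
    names(pre) <- names(post) <- subjects
    link_idx <- integer(0)
    if (!is.null(spec$link_nodes) && spec$behavior_link != 0) {
      link_ch <- match(spec$link_nodes, spec$channel_labels)
      link_idx <- which(up[, 1] %in% link_ch | up[, 2] %in% link_ch)
    }
    if (spec$mode == "matrix") {
      mu <- stats::runif(ne, 0.25, 0.55)
      draw <- function(s, sess) {
        w <- mu + stats::rnorm(ne, 0, spec$noise_sd)
        if (length(eff_idx) && sess == "post") {
          w[eff_idx] <- w[eff_idx] + spec$effect_size
        }
        if (length(link_idx)) {
          w[link_idx] <- w[link_idx] + spec$latent_scale * get_u(s, sess)
          # keep displaced edges strictly positive so the graph stays
          # connected (a requirement of percolation thresholding)
          w[link_idx] <- pmax(w[link_idx], 0.02)
        }
        w <- clip01(w)
        m <- matrix(0, nch, nch)
        m[cbind(up[, 1], up[, 2])] <- w
        m <- m + t(m)
        conn_matrix(m, spec$band, spec$channel_labels, n_windows = NA_integer_,
                    subject = s, session = sess)
      }
      for (k in seq_len(nsub)) {
        pre[[k]] <- draw(subjects[k], "pre")
        post[[k]] <- draw(subjects[k], "post")
      }
    } else {
      draw <- function(s, sess) {
        strengths <- clip01(spec$base_strength +
          (if (sess == "post") spec$effect_size else 0) +
          (if (spec$behavior_link != 0)
             spec$latent_scale * get_u(s, sess) else 0))
        specs <- lapply(seq_along(spec$effect_edges), function(i) {
          coupling_spec(spec$effect_edges[[i]], spec$band,
                        phase_lag = pi / 2, strength = strengths)
        })
        gen_coupled_eeg(specs, n_channels = nch, fs = spec$fs,
                        duration = spec$eeg_duration,
                        noise_sd = spec$noise_sd,
                        seed = NULL, channel_labels = spec$channel_labels,
                        subject = s, session = sess, trial = 1L)
      }
      for (k in seq_len(nsub)) {
        pre[[k]] <- draw(subjects[k], "pre")
        post[[k]] <- draw(subjects[k], "post")
      }
    }

    behavior <- expand.grid(subject = subjects, session = c("pre", "post"),
                            trial = seq_len(spec$n_trials),
                            hand = c("left", "right"),
                            stringsAsFactors = FALSE)
    base <- 0.55
    behavior$r <- clip01(
      base + ifelse(behavior$session == "post", spec$session_shift, 0) +
        spec$behavior_link *
          mapply(get_u, behavior$subject, behavior$session) +
        stats::rnorm(nrow(behavior), 0, spec$behavior_noise))
    structure(list(pre = pre, post = post, behavior = behavior,
                   latent = latent, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", x$spec$n_subjects, " subjects, 2 sessions, mode '",
      x$spec$mode, "', band ", x$spec$band, ", effect ",
      x$spec$effect_size, " on ", length(x$spec$effect_edges),
      " edge(s)\n", sep = "")
  invisible(x)
}

#' Simulate a cursor trace following a track
#'
#' The simulated participant reproduces the track delayed by `lag` seconds
#' plus white noise: `lag = 0, noise_sd = 0` reproduces the track exactly
#' (performance score 1); increasing noise drives the score toward 0.
#'
#' @param track A [generate_track()] object, or a numeric track trace (in
#'   which case `fs` must be supplied).
#' @param lag Non-negative response lag in seconds.
#' @param noise_sd SD of additive white noise (track units).
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz when `track` is a bare numeric vector.
#' @return Numeric cursor trace of the same length as the track.
#' @export
gen_tracker <- function(track, lag = 0, noise_sd = 0, seed = NULL, fs = 50) {
  if (inherits(track, "track_trace")) {
    g <- track$g
    fs <- track$fs
  } else {
    g <- as.numeric(track)
  }
  if (lag < 0) stop("lag must be non-negative", call. = FALSE)
  shift <- round(lag * fs)
  if (shift >= length(g)) stop("lag exceeds track duration", call. = FALSE)
  cursor <- if (shift > 0) c(rep(g[1], shift), g[seq_len(length(g) - shift)])
            else g
  with_seed(seed, cursor + stats::rnorm(length(cursor), 0, noise_sd))
}
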