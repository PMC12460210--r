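test_that("preprocessing attenuates the notch band and passes the passband", {
  fs <- 512
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  core <- 1000:4000  # avoid filter edge transients
  rec50 <- eeg_recording(matrix(sin(2 * pi * 50 * t), 1), fs, "a")
  out50 <- preprocess_eeg(rec50)
  expect_lt(sd(out50$data[1, core]) / sd(rec50$data[1, core]), 0.05)

  rec10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "a")
  out10 <- preprocess_eeg(rec10)
  expect_equal(sd(out10$data[1, core]) / sd(rec10$data[1, core]), 1,
               tolerance = 0.05)

  recdc <- eeg_recording(matrix(1, 1, length(t)), fs, "a")
  outdc <- preprocess_eeg(recdc)
  expect_lt(max(abs(outdc$data[1, core])), 0.1)

  expect_equal(ncol(out10$data), length(t))  # length preserved
  expect_error(preprocess_eeg(eeg_recording(matrix(rnorm(100), 1), 150, "a")),
               "sampling rate too low")
})

test_that("window counts follow the stride arithmetic", {
  fs <- 512
  expect_equal(n_sliding_windows(60, 4, 2), 29)
  expect_equal(n_sliding_windows(240, 4, 2), 119)
  expect_equal(n_sliding_windows(4, 4, 2), 1)
  rec <- eeg_recording(matrix(rnorm(2 * 60 * fs), 2), fs, c("a", "b"))
  expect_length(sliding_windows(rec, 4, 2)$windows, 29)
  rec1 <- eeg_recording(matrix(rnorm(2 * 4 * fs), 2), fs, c("a", "b"))
  expect_length(sliding_windows(rec1, 4, 2)$windows, 1)
  expect_error(sliding_windows(rec, 4, 0), "positive")
  expect_error(sliding_windows(rec1, 8, 2), "shorter than one window")

  # brute-force enumeration of admissible offsets agrees with the formula
  set.seed(5)
  for (k in 1:25) {
    T_ <- runif(1, 5, 100)
    wl <- runif(1, 1, 5)
    st <- runif(1, 0.5, 3)
    brute <- sum((seq(0, T_, by = st) + wl) <= T_ + 1e-9)
    expect_equal(n_sliding_windows(T_, wl, st), brute)
  }
})

test_that("ciPLV hits its analytic anchors and PLV keeps zero-lag synchrony", {
  # zero-lag identical signals: ciPLV exactly 0 (degenerate real part)
  rec <- sinusoid_recording(10, 104)
  ws <- sliding_windows(rec)
  m0 <- ciplv(ws, "alpha")
  expect_equal(m0$values["a", "b"], 0, tolerance = 1e-6)

  # constant 90-degree lag at 10 Hz: ciPLV 1 at the 10 Hz bin
  rec90 <- sinusoid_recording(10, 104, phase2 = pi / 2)
  ws90 <- sliding_windows(rec90)
  expect_equal(ciplv(ws90, c(10, 10))$values["a", "b"], 1, tolerance = 1e-6)
  # ... and PLV is 1 in both cases
  expect_equal(plv(ws, c(10, 10))$values["a", "b"], 1, tolerance = 1e-6)
  expect_equal(plv(ws90, c(10, 10))$values["a", "b"], 1, tolerance = 1e-6)

  expect_error(ciplv(ws, c(300, 400)), "Nyquist")
  expect_error(ciplv(sliding_windows(sinusoid_recording(10, 4)), "alpha"),
               "2 windows")
})

test_that("ciPLV output is symmetric, bounded, and amplitude invariant", {
  for (s in 1:3) {
    rec <- gen_coupled_eeg(list(coupling_spec(c("C3", "C4"), "alpha",
                                              pi / 3, 0.6)),
                           duration = 20, noise_sd = 1, seed = s)
    ws <- sliding_windows(rec)
    m <- ciplv(ws, "alpha")$values
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))

    # scaling a channel by a positive constant changes nothing
    rec2 <- rec
    rec2$data["C3", ] <- 7.3 * rec2$data["C3", ]
    m2 <- ciplv(sliding_windows(rec2), "alpha")$values
    expect_equal(m, m2, tolerance = 1e-12)
  }
})

test_that("independent channels stay below a window-shuffled null", {
  set.seed(99)
  fs <- 256
  rec <- eeg_recording(matrix(rnorm(2 * 204 * fs), 2), fs, c("a", "b"))
  ws <- sliding_windows(rec, 4, 2)  # 101 windows
  obs <- ciplv(ws, "alpha")$values["a", "b"]
  # null: re-pair channel b's windows at random, destroying any alignment
  null <- replicate(40, {
    perm <- sample(length(ws$windows))
    ws2 <- ws
    for (k in seq_along(ws$windows)) {
      ws2$windows[[k]][2, ] <- ws$windows[[perm[k]]][2, ]
    }
    ciplv(ws2, "alpha")$values["a", "b"]
  })
  expect_lt(obs, quantile(null, 0.95) + 0.05)
})

test_that("session averaging is the element-wise mean with band checking", {
  w1 <- random_weight_matrix(4, 1)
  w2 <- random_weight_matrix(4, 2)
  labels <- letters[1:4]
  cm <- function(w, band = "alpha", subject = "S1", session = "pre") {
    conn_matrix(w, band, labels, n_windows = 1, subject = subject,
                session = session)
  }
  a <- cm(w1); b <- cm(w2)
  expect_equal(average_conn(list(a))$values, a$values)          # identity
  expect_equal(average_conn(list(a, a))$values, a$values)       # idempotent
  expect_equal(unclass(average_conn(list(a, b))$values)[2, 3],
               (w1[2, 3] + w2[2, 3]) / 2)
  # averaging entries 0 and 1 gives 0.5
  z <- cm(matrix(0, 4, 4)); o <- cm(1 - diag(4))
  expect_true(all(average_conn(list(z, o))$values[upper.tri(w1)] == 0.5))
  expect_error(average_conn(list(a, cm(w2, band = "beta"))), "mixed bands")

  grouped <- average_sessions(list(cm(w1), cm(w2),
                                   cm(w2, session = "post")))
  expect_length(grouped, 2)
  expect_equal(grouped[["S1/pre/alpha"]]$values,
               average_conn(list(cm(w1), cm(w2)))$values)
})

test_that("connectivity matrices survive the long-CSV round trip", {
  ch <- gen_cohort(cohort_spec(n_subjects = 3, seed = 21))
  mats <- c(ch$pre, ch$post)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_conn_long(mats, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 6 * choose(16, 2))  # 120 unique edges per matrix
  back <- read_conn_long(path)
  key <- paste(mats[[1]]$subject, mats[[1]]$session, mats[[1]]$band,
               sep = "/")
  expect_equal(back[[key]]$values, unclass(mats[[1]]$values),
               ignore_attr = TRUE, tolerance = 1e-12)
})
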