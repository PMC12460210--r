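test_that("partial Spearman reduces to Spearman and respects monotonicity", {
  set.seed(1)
  x <- rnorm(30)
  y <- 0.6 * x + rnorm(30)
  plain <- partial_spearman(x, y)
  expect_equal(plain$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(plain$p, cor.test(x, y, method = "spearman",
                                 exact = FALSE)$p.value, tolerance = 1e-6)
  # monotone transform invariance (of x and of y)
  expect_equal(partial_spearman(exp(x), y)$rho, plain$rho)
  expect_equal(partial_spearman(x, y^3 + 10 * y)$rho, plain$rho)
  # y = x^3 is monotone: rho exactly 1
  expect_equal(partial_spearman(x, x^3)$rho, 1)
  expect_true(plain$ci_lo <= plain$rho && plain$rho <= plain$ci_hi)
})

test_that("controls absorb confounded variation", {
  # y driven purely by the session dummy: partial rho ~ 0 across seeds
  rhos <- vapply(1:100, function(s) {
    set.seed(s)
    session <- rep(c("pre", "post"), each = 15)
    x <- rnorm(30) + 2 * (session == "post")
    y <- 3 * (session == "post") + rnorm(30, sd = 0.1)
    partial_spearman(x, y, controls = data.frame(session = session))$rho
  }, 0)
  expect_lt(abs(mean(rhos)), 0.06)

  session <- rep(c("pre", "post"), each = 4)
  expect_error(
    partial_spearman(rnorm(8), rnorm(8),
                     controls = data.frame(a = session, b = session)),
    "collinear")
})

test_that("Bonferroni flags use alpha / m", {
  expect_true(bonferroni(0.002, alpha = 0.05, m = 16))
  expect_false(bonferroni(0.004, alpha = 0.05, m = 16))
  expect_identical(bonferroni(c(0.03, 0.06), alpha = 0.05, m = 1),
                   c(TRUE, FALSE))  # m = 1 reduces to p < alpha
  expect_error(bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("VIF matches its closed form", {
  set.seed(3)
  # orthogonal columns: VIF 1
  # orthonormal columns, also orthogonal to the intercept (mean zero)
  x <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200))))[, 2:4]
  expect_equal(unname(vif(x)), rep(1, 3), tolerance = 1e-10)
  # two columns at correlation r: VIF = 1 / (1 - r^2) = 5.263 at r = 0.9
  r <- 0.9
  n <- 2e5
  a <- rnorm(n)
  b <- r * a + sqrt(1 - r^2) * rnorm(n)
  v <- vif(cbind(a, b))
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 0.05)
  # duplicated column: infinite with a note
  expect_message(vd <- vif(cbind(a = a[1:50], b = rnorm(50), c = a[1:50])),
                 "collinear")
  expect_true(all(is.infinite(vd[c("a", "c")])))
  expect_error(vif(matrix(rnorm(10), 10, 1)), "2 features")
})

test_that("PCR recovers exact and null relationships", {
  set.seed(11)
  n <- 40
  x <- matrix(rnorm(n * 3), n)
  colnames(x) <- c("n1", "n2", "n3")
  pc1 <- prcomp(scale(x))$x[, 1]
  # exact linear relationship: R^2 = 1, residuals 0
  y <- 2 * pc1 + 1
  fit <- pcr_fit(x, y)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(max(abs(residuals(fit)))), 0, tolerance = 1e-10)
  expect_equal(abs(unname(coef(fit)["slope"])), 2, tolerance = 1e-10)

  # independent outcome: slope magnitude and R^2 near zero over seeds
  # (the sign convention makes the fitted slope non-negative, so the
  # relevant null behaviour is |slope| small, not signed slope ~ 0)
  stats0 <- t(vapply(1:60, function(s) {
    set.seed(100 + s)
    xx <- matrix(rnorm(n * 3), n)
    yy <- rnorm(n)
    f <- pcr_fit(xx, yy)
    c(f$coefficients["slope"], f$r2)
  }, c(0, 0)))
  expect_lt(mean(abs(stats0[, 1])), 0.15)
  expect_lt(mean(stats0[, 2]), 0.1)

  expect_error(pcr_fit(cbind(a = rep(1, 10)), rnorm(10)), "zero-variance")
})

test_that("PCR slope recovery stays within two standard errors", {
  covered <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 40
    x <- matrix(rnorm(n * 4), n)
    pc1 <- prcomp(scale(x))$x[, 1]
    y <- 0.5 * pc1 + rnorm(n, sd = 0.4)
    f <- pcr_fit(x, y)
    se <- summary(f)$slope_se
    abs(abs(unname(coef(f)["slope"])) - 0.5) <= 2 * se
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("prediction respects training standardization and controls", {
  set.seed(21)
  n <- 30
  x <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  ctrl <- data.frame(session = rep(c("pre", "post"), each = n / 2),
                     subject = rep(sprintf("S%02d", 1:(n / 2)), 2))
  y <- rowMeans(x) + 0.3 * (ctrl$session == "post") + rnorm(n, sd = 0.1)
  fit <- pcr_fit(x, y, controls = ctrl)
  # in-sample partial predictions equal the fitted values
  expect_equal(predict(fit, x, newcontrols = ctrl), unname(fitted(fit)),
               tolerance = 1e-10)
  expect_error(predict(fit, x), "supply newcontrols")
  resp <- predict(fit, x, newcontrols = ctrl, type = "response")
  expect_equal(cor(resp, y) > 0.8, TRUE)
})

test_that("LOOCV is leakage-free, optimistic-bounded, and exact when noiseless", {
  set.seed(31)
  n <- 24
  # noiseless one-factor metrics: every column a multiple of the same
  # latent, so the refit PCA chain is identical across folds and the
  # linear relationship is exactly recoverable
  u <- rnorm(n)
  x <- outer(u, c(1, 0.9, 1.1))
  y <- 1.5 * u + 0.2
  cv <- loocv_pcr(x, y)
  expect_equal(cv$r2, 1, tolerance = 1e-6)
  expect_lt(cv$rmse, 1e-6)

  # pure-noise outcomes: cross-validated R^2 <= 0 in expectation
  null_r2 <- vapply(1:40, function(s) {
    set.seed(200 + s)
    loocv_pcr(matrix(rnorm(n * 3), n), rnorm(n))$r2
  }, 0)
  expect_lt(mean(null_r2), 0)

  # optimism: held-out RMSE is at least the in-sample RMSE (on average,
  # and almost always pointwise)
  worse <- vapply(1:40, function(s) {
    set.seed(300 + s)
    xx <- matrix(rnorm(n * 3), n)
    yy <- prcomp(scale(xx))$x[, 1] + rnorm(n)
    f <- pcr_fit(xx, yy)
    c(loocv_pcr(xx, yy)$rmse, sqrt(mean(residuals(f)^2)))
  }, c(0, 0))
  expect_gte(mean(worse[1, ] >= worse[2, ]), 0.95)
  expect_gt(mean(worse[1, ] - worse[2, ]), 0)

  # no leakage: per-fold standardization statistics differ fold to fold
  centers <- vapply(seq_len(n), function(i) colMeans(x[-i, ])[1], 0)
  expect_gt(length(unique(centers)), 1)

  expect_error(loocv_pcr(x[1:4, ], y[1:4]), "at least 5")
})

test_that("the screening chain selects planted nodes in most replicates", {
  planted <- c("CPz", "Pz", "O1", "O2")
  hits <- vapply(1:12, function(s) {
    spec <- cohort_spec(n_subjects = 20, noise_sd = 0.01,
                        link_nodes = planted, behavior_link = 0.1,
                        latent_scale = 0.2, behavior_noise = 0.002,
                        seed = s)
    ch <- gen_cohort(spec)
    tab <- node_metric_table(c(ch$pre, ch$post))
    beh <- aggregate(r ~ subject + session, data = ch$behavior, mean)
    names(beh)[3] <- "pc1"
    scr <- screen_nodes(tab, beh)
    all(planted %in% scr$node[scr$significant])
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("rescreening mode reports per-fold selections", {
  set.seed(51)
  n <- 20
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 * x[, "a"] + rnorm(n, sd = 0.05)
  cv <- suppressWarnings(loocv_pcr(x, y, rescreen = TRUE, alpha = 0.2))
  sel <- unlist(cv$selected)
  expect_gt(sum(sel == "a"), 0.9 * length(cv$selected[!vapply(cv$selected,
                                                              is.null, TRUE)]))
})
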