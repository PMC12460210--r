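# Linking node metrics to behavior: partial Spearman screening with
# Bonferroni correction, collinearity diagnostics, principal-component
# regression (classed S3 model), and leave-one-out cross-validation.

control_matrix <- function(controls, n) {
  if (is.null(controls)) return(NULL)
  controls <- as.data.frame(controls)
  if (nrow(controls) != n) {
    stop("controls must have one row per observation", call. = FALSE)
  }
  controls[] <- lapply(controls, function(col) {
    if (is.character(col)) factor(col) else col
  })
  mm <- stats::model.matrix(~ ., data = controls)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    drop <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    if (all(drop %in% colnames(mm)[-1])) {
      stop("controls are collinear after dummy coding: ",
           paste(drop, collapse = ", "), call. = FALSE)
    }
  }
  mm
}

residualize <- function(v, mm) {
  if (is.null(mm)) return(v - mean(v))
  stats::lm.fit(mm, v)$residuals
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y`, residualizes both ranks on the dummy-coded
#' control variables (e.g. session and participant), and correlates the rank
#' residuals. The p-value uses the t approximation with degrees of freedom
#' reduced by the number of control columns; the 95% CI is Fisher-z based
#' with the same reduction. With no controls this reduces to the ordinary
#' Spearman correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param controls Optional data frame of control variables (factors or
#'   numeric), one row per observation.
#' @return One-row data frame: `rho`, `p`, `ci_lo`, `ci_hi`, `df`,
#'   `n_controls`.
#' @export
partial_spearman <- function(x, y, controls = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  mm <- control_matrix(controls, n)
  q <- if (is.null(mm)) 0L else ncol(mm) - 1L
  df <- n - 2L - q
  if (df < 1L) {
    stop("not enough residual degrees of freedom after controls",
         call. = FALSE)
  }
  rx <- residualize(rank(x), mm)
  ry <- residualize(rank(y), mm)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero-variance rank residuals: correlation undefined",
         call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  z <- atanh(max(min(rho, 1 - 1e-12), -1 + 1e-12))
  se <- 1 / sqrt(max(n - 3 - q, 1))
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  data.frame(rho = rho, p = p, ci_lo = ci[1], ci_hi = ci[2], df = df,
             n_controls = q)
}

#' Bonferroni significance flags
#'
#' Flags test i significant iff `p[i] < alpha / m`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param alpha Family-wise significance level.
#' @param m Number of tests in the family (defaults to `length(p)`).
#' @return Logical vector of flags.
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p < alpha / m
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing feature j on the remaining
#' features (with intercept). Perfectly collinear features are reported as
#' `Inf` with a message.
#'
#' @param x Numeric matrix or data frame of features (>= 2 columns,
#'   more rows than columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 features", call. = FALSE)
  if (nrow(x) <= p) stop("need more observations than features", call. = FALSE)
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(x) %||% paste0("x", seq_len(p))
  if (any(is.infinite(out))) {
    message("perfectly collinear feature(s): ",
            paste(names(out)[is.infinite(out)], collapse = ", "))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen nodes by partial Spearman correlation with behavior
#'
#' Runs [partial_spearman()] of each node's metric against the behavioral
#' score (controlling for session and participant) and applies a Bonferroni
#' correction over the family of nodes.
#'
#' @param metrics Data frame with columns `subject`, `session`, `node` and a
#'   metric column (`closeness` by default).
#' @param behavior Data frame with columns `subject`, `session`, and a score
#'   column (`pc1` by default).
#' @param alpha Family-wise level for the Bonferroni flags.
#' @param metric,score Names of the metric and score columns.
#' @return Data frame, one row per node: `node`, `rho`, `p`, `ci_lo`,
#'   `ci_hi`, `significant`.
#' @export
screen_nodes <- function(metrics, behavior, alpha = 0.05,
                         metric = "closeness", score = "pc1") {
  merged <- merge(metrics, behavior, by = c("subject", "session"))
  if (!nrow(merged)) stop("no overlapping observations", call. = FALSE)
  nodes <- sort(unique(merged$node))
  rows <- lapply(nodes, function(nd) {
    d <- merged[merged$node == nd, ]
    ps <- partial_spearman(d[[metric]], d[[score]],
                           controls = d[, c("session", "subject")])
    cbind(node = nd, ps[, c("rho", "p", "ci_lo", "ci_hi")])
  })
  out <- do.call(rbind, rows)
  out$significant <- bonferroni(out$p, alpha = alpha, m = length(nodes))
  rownames(out) <- NULL
  out
}

#' Principal-component regression of behavior on node metrics
#'
#' Standardizes the selected metric columns, takes their first principal
#' component (sign fixed to correlate positively with the outcome),
#' residualizes both the component and the outcome on the dummy-coded
#' controls, and fits the partial OLS line `y' = b0 * x' + b1`.
#'
#' @param x Numeric matrix or data frame of selected node metrics (one
#'   column per node).
#' @param y Numeric outcome (bimanual performance score).
#' @param controls Optional data frame of control variables (session,
#'   participant).
#' @return Object of class `"pcr_model"` with components `loadings`,
#'   `center`, `scale`, `explained_variance`, `coefficients`
#'   (`slope`, `intercept`), `r2`, `fitted`, `residuals`, `x_partial`,
#'   `y_partial`, and the control-model fits used for prediction.
#' @seealso [loocv_pcr()] for out-of-sample evaluation; the usual
#'   `print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods
#'   apply.
#' @export
pcr_fit <- function(x, y, controls = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("y must match nrow(x)", call. = FALSE)
  if (ncol(x) < 1L) stop("need at least one selected node", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance feature column(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
  }
  xs <- scale(x, center = ctr, scale = scl)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  if (pc$sdev[1] < 1e-12) {
    stop("degenerate PCA: zero-variance principal component", call. = FALSE)
  }
  load1 <- pc$rotation[, 1]
  pc1 <- drop(xs %*% load1)
  if (stats::cor(pc1, y) < 0) {
    load1 <- -load1
    pc1 <- -pc1
  }
  ev <- pc$sdev[1]^2 / sum(pc$sdev^2)

  ctrl_df <- if (is.null(controls)) NULL else {
    cd <- as.data.frame(controls)
    cd[] <- lapply(cd, function(col) if (is.character(col)) factor(col)
                   else col)
    cd
  }
  if (is.null(ctrl_df)) {
    fit_x <- stats::lm(pc1 ~ 1)
    fit_y <- stats::lm(y ~ 1)
  } else {
    fit_x <- stats::lm(pc1 ~ ., data = ctrl_df)
    fit_y <- stats::lm(y ~ ., data = ctrl_df)
  }
  xp <- stats::residuals(fit_x)
  yp <- stats::residuals(fit_y)
  if (stats::sd(xp) < 1e-12) {
    stop("principal component has no variance left after controls",
         call. = FALSE)
  }
  ols <- stats::lm(yp ~ xp)
  b <- stats::coef(ols)
  r2 <- 1 - sum(stats::residuals(ols)^2) / sum((yp - mean(yp))^2)
  structure(list(loadings = load1, center = ctr, scale = scl,
                 explained_variance = ev,
                 coefficients = c(slope = unname(b["xp"]),
                                  intercept = unname(b["(Intercept)"])),
                 r2 = r2, ols = ols, fit_x = fit_x, fit_y = fit_y,
                 controls = ctrl_df,
                 x_partial = xp, y_partial = yp,
                 fitted = stats::fitted(ols),
                 residuals = stats::residuals(ols),
                 nodes = colnames(x), n = n,
                 call = match.call()),
            class = "pcr_model")
}

#' @export
print.pcr_model <- function(x, ...) {
  cat("Principal-component regression (", length(x$nodes), " node(s), n = ",
      x$n, ")\n", sep = "")
  cat("  PC1 explains ", sprintf("%.1f%%", 100 * x$explained_variance),
      " of node-metric variance\n", sep = "")
  cat(sprintf("  y' = %.4f x' + %.4g   (R^2 = %.3f)\n",
              x$coefficients["slope"], x$coefficients["intercept"], x$r2))
  invisible(x)
}

#' @export
summary.pcr_model <- function(object, ...) {
  s <- summary(object$ols)
  out <- list(model = object, ols_summary = s,
              slope_se = s$coefficients["xp", "Std. Error"],
              slope_p = s$coefficients["xp", "Pr(>|t|)"],
              fstat = s$fstatistic)
  class(out) <- "summary.pcr_model"
  out
}

#' @export
print.summary.pcr_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  slope SE = %.4f, p = %.4g", x$slope_se, x$slope_p))
  if (!is.null(x$fstat)) {
    cat(sprintf(", F(%d, %d) = %.3f", x$fstat[2], x$fstat[3], x$fstat[1]))
  }
  cat("\n  loadings:\n")
  print(round(x$model$loadings, 3))
  invisible(x)
}

#' @export
coef.pcr_model <- function(object, ...) object$coefficients

#' @export
residuals.pcr_model <- function(object, ...) object$residuals

#' @export
fitted.pcr_model <- function(object, ...) object$fitted

#' Predict from a principal-component regression
#'
#' Projects new metric rows onto the training-set standardization and
#' loadings, residualizes on the control model fits from training, and
#' applies the partial OLS line.
#'
#' @param object A `"pcr_model"`.
#' @param newx New metric matrix (same columns as at fit time).
#' @param newcontrols Control rows matching `newx` (required when the model
#'   was fit with controls).
#' @param type `"partial"` (default) returns predictions of the
#'   control-residualized outcome `y'`; `"response"` adds back the control
#'   model's contribution to predict `y` itself.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pcr_model <- function(object, newx, newcontrols = NULL,
                              type = c("partial", "response"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  xs <- scale(newx, center = object$center, scale = object$scale)
  pc1 <- drop(xs %*% object$loadings)
  if (is.null(object$controls)) {
    xp <- pc1 - stats::coef(object$fit_x)[1]
    y_ctrl <- rep(stats::coef(object$fit_y)[1], length(pc1))
  } else {
    if (is.null(newcontrols)) {
      stop("model was fit with controls; supply newcontrols", call. = FALSE)
    }
    nc <- as.data.frame(newcontrols)
    nc[] <- lapply(nc, function(col) if (is.character(col)) factor(col)
                   else col)
    xp <- pc1 - stats::predict(object$fit_x, newdata = nc)
    y_ctrl <- stats::predict(object$fit_y, newdata = nc)
  }
  yp_hat <- object$coefficients["slope"] * xp + object$coefficients["intercept"]
  if (type == "partial") unname(yp_hat) else unname(yp_hat + y_ctrl)
}

#' Partial-regression plot of a PCR model
#'
#' @param x A `"pcr_model"`.
#' @param ... Passed to `plot()`.
#' @export
plot.pcr_model <- function(x, ...) {
  graphics::plot(x$x_partial, x$y_partial,
                 xlab = "node-metric PC1 (control-residualized)",
                 ylab = "performance (control-residualized)", ...)
  graphics::abline(x$coefficients["intercept"], x$coefficients["slope"],
                   col = "steelblue", lwd = 2)
  invisible(x)
}

#' Leave-one-out cross-validation of the PCR chain
#'
#' Each observation is held out in turn; standardization, PCA,
#' control-residualization and the OLS line are all refit on the remaining
#' observations (no leakage), and the held-out control-residualized outcome
#' is predicted. Optionally the node-screening step is also re-run inside
#' each fold (`rescreen = TRUE`), recording the nodes selected per fold.
#'
#' @param x Metric matrix: the externally selected node columns (default
#'   mode) or all candidate node columns (`rescreen = TRUE`).
#' @param y Outcome vector.
#' @param controls Optional control data frame (session, participant).
#' @param rescreen Re-run partial-Spearman + Bonferroni selection inside
#'   each fold.
#' @param alpha Screening level when `rescreen = TRUE`.
#' @return List of class `"loocv_pcr"`: `r2` (1 - SSE/SST over held-out
#'   predictions), `rmse`, `obs`, `pred`, `selected` (per-fold node lists
#'   when rescreening), `excluded` (folds dropped as degenerate).
#' @export
loocv_pcr <- function(x, y, controls = NULL, rescreen = FALSE,
                      alpha = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5L) stop("need at least 5 observations for LOOCV", call. = FALSE)
  obs <- pred <- rep(NA_real_, n)
  selected <- vector("list", n)
  excluded <- integer(0)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    ctr <- if (is.null(controls)) NULL else controls[-i, , drop = FALSE]
    cols <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
    use <- seq_len(ncol(x))
    if (rescreen) {
      ps <- vapply(seq_len(ncol(x)), function(j) {
        partial_spearman(xtr[, j], ytr, controls = ctr)$p
      }, 0)
      flags <- bonferroni(ps, alpha = alpha, m = ncol(x))
      if (!any(flags)) {
        excluded <- c(excluded, i)
        next
      }
      use <- which(flags)
    }
    selected[[i]] <- cols[use]
    fit <- tryCatch(pcr_fit(xtr[, use, drop = FALSE], ytr, controls = ctr),
                    error = function(e) NULL)
    if (is.null(fit)) {
      excluded <- c(excluded, i)
      next
    }
    pred[i] <- predict(fit, x[i, use, drop = FALSE],
                       newcontrols = if (is.null(controls)) NULL else
                         controls[i, , drop = FALSE],
                       type = "partial")
    # held-out truth on the same partial scale: residual w.r.t. the fold's
    # control model
    if (is.null(fit$controls)) {
      obs[i] <- y[i] - stats::coef(fit$fit_y)[1]
    } else {
      nc <- as.data.frame(controls[i, , drop = FALSE])
      nc[] <- lapply(nc, function(col) if (is.character(col)) factor(col)
                     else col)
      obs[i] <- y[i] - stats::predict(fit$fit_y, newdata = nc)
    }
  }
  if (length(excluded)) {
    warning("fold(s) excluded (no selection or degenerate fit): ",
            paste(excluded, collapse = ", "))
  }
  keep <- !is.na(pred)
  sse <- sum((obs[keep] - pred[keep])^2)
  sst <- sum((obs[keep] - mean(obs[keep]))^2)
  structure(list(r2 = 1 - sse / sst,
                 rmse = sqrt(mean((obs[keep] - pred[keep])^2)),
                 obs = obs, pred = pred,
                 selected = selected, excluded = excluded),
            class = "loocv_pcr")
}

#' @export
print.loocv_pcr <- function(x, ...) {
  cat(sprintf("<loocv_pcr> cross-validated R^2 = %.3f, RMSE = %.4f (%d folds%s)\n",
              x$r2, x$rmse, sum(!is.na(x$pred)),
              if (length(x$excluded))
                paste0(", ", length(x$excluded), " excluded") else ""))
  invisible(x)
}
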