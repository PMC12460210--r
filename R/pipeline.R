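# End-to-end orchestration: synthetic cohort -> behavior scores ->
# connectivity -> graph metrics -> NBS -> PCR, from a single seeded config,
# with tidy CSV artifacts and a JSON run manifest.

#' Build a pipeline run configuration
#'
#' All stage seeds are derived deterministically from `seed`, so identical
#' configurations produce byte-identical artifacts.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for artifacts and the manifest.
#' @param mode `"synthetic"` generates a cohort via [gen_cohort()];
#'   `"files"` loads a connectivity long CSV and behavior CSV from `paths`.
#' @param cohort A [cohort_spec()] (its `seed` is overridden by the derived
#'   stage seed) for synthetic mode.
#' @param paths Named list with `connectivity` and `behavior` CSV paths for
#'   file mode.
#' @param window,stride Sliding-window parameters (seconds) for raw-EEG
#'   cohorts.
#' @param bands Character vector of band names to analyse.
#' @param percolation Apply percolation thresholding before closeness.
#' @param nbs List of NBS settings: `T`, `k`, `alpha`, `tail`.
#' @param stats List of stats settings: `alpha` (screening level),
#'   `rescreen` (LOOCV mode).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("netlearn-run-"),
                       mode = c("synthetic", "files"),
                       cohort = cohort_spec(), paths = list(),
                       window = 4, stride = 2, bands = NULL,
                       percolation = TRUE,
                       nbs = list(T = 2.75, k = 1000, alpha = 0.05,
                                  tail = "decrease"),
                       stats = list(alpha = 0.05, rescreen = FALSE)) {
  mode <- match.arg(mode)
  cfg <- list(seed = seed, out_dir = out_dir, mode = mode, cohort = cohort,
              paths = paths, window = window, stride = stride,
              bands = bands, percolation = percolation, nbs = nbs,
              stats = stats)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the `cohort` block
#' is passed to [cohort_spec()].
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_spec, y$cohort)
  do.call(run_config, y)
}

stage_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 1000L + offset

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (synthetic or file-based),
#' behavior scoring (session means + bimanual PCA), connectivity estimation
#' (ciPLV for raw-EEG cohorts; pass-through for matrix cohorts),
#' graph metrics (percolation + closeness), NBS edge-wise testing, and the
#' partial-Spearman / PCR / LOOCV stats chain. Every stage writes a tidy CSV
#' under `cfg$out_dir`, and a JSON manifest records the configuration hash,
#' derived seeds, per-stage row counts and headline results.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("netlearn")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed, stages = list())
  run_stage <- function(name, fun) {
    log_line(con, "stage ", name, " ...")
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- res$info
    res$value
  }

  # -- stage 1: cohort -------------------------------------------------
  cohort <- run_stage("cohort", function() {
    if (cfg$mode == "synthetic") {
      spec <- cfg$cohort
      spec$seed <- stage_seed(cfg, 1L)
      ch <- gen_cohort(spec)
      list(value = ch,
           info = list(mode = "synthetic", n_subjects = spec$n_subjects,
                       cohort_mode = spec$mode, seed = spec$seed))
    } else {
      mats <- read_conn_long(cfg$paths$connectivity)
      behavior <- utils::read.csv(cfg$paths$behavior,
                                  stringsAsFactors = FALSE)
      list(value = list(matrices = mats, behavior = behavior),
           info = list(mode = "files", n_matrices = length(mats),
                       behavior_rows = nrow(behavior)))
    }
  })

  # -- stage 2: behavior ------------------------------------------------
  bim <- run_stage("behavior", function() {
    trials <- cohort$behavior
    sess <- session_scores(trials)
    wide <- stats::reshape(sess, idvar = c("subject", "session"),
                           timevar = "hand", direction = "wide")
    names(wide) <- sub("^r\\.", "", names(wide))
    bp <- bimanual_pca(wide)
    utils::write.csv(trials, file.path(cfg$out_dir, "behavior_trials.csv"),
                     row.names = FALSE)
    utils::write.csv(bp$scores, file.path(cfg$out_dir, "behavior_pc1.csv"),
                     row.names = FALSE)
    list(value = bp,
         info = list(trials = nrow(trials), observations = nrow(bp$scores),
                     explained_variance = bp$explained_variance))
  })

  # -- stage 3: connectivity --------------------------------------------
  session_mats <- run_stage("connectivity", function() {
    if (cfg$mode == "files") {
      mats <- cohort$matrices
    } else if (cfg$cohort$mode == "matrix") {
      mats <- c(cohort$pre, cohort$post)
    } else {
      bands <- cfg$bands %||% cfg$cohort$band
      mats <- list()
      for (side in c("pre", "post")) {
        for (rec in cohort[[side]]) {
          filtered <- preprocess_eeg(rec)
          ws <- sliding_windows(filtered, cfg$window, cfg$stride)
          for (b in bands) {
            mats[[length(mats) + 1L]] <-
              ciplv(ws, b, subject = rec$subject, session = rec$session)
          }
        }
      }
      mats <- average_sessions(mats)
    }
    write_conn_long(mats, file.path(cfg$out_dir, "connectivity_long.csv"))
    list(value = mats,
         info = list(matrices = length(mats),
                     edges_per_matrix = choose(nrow(conn_values(mats[[1]])), 2)))
  })

  # -- stage 4: graph metrics -------------------------------------------
  metrics <- run_stage("graph_metrics", function() {
    tab <- node_metric_table(session_mats, threshold = cfg$percolation)
    utils::write.csv(tab, file.path(cfg$out_dir, "node_metrics.csv"),
                     row.names = FALSE)
    list(value = tab, info = list(rows = nrow(tab),
                                  thresholded = cfg$percolation))
  })

  # -- stage 5: NBS ------------------------------------------------------
  nbs_res <- run_stage("nbs", function() {
    bands <- unique(vapply(session_mats, function(m) m$band, ""))
    results <- list()
    comp_rows <- list()
    for (b in bands) {
      in_band <- Filter(function(m) m$band == b, session_mats)
      key <- vapply(in_band, function(m) m$session, "")
      pre <- in_band[key == "pre"]
      post <- in_band[key == "post"]
      sid <- function(m) m$subject
      pre <- pre[order(vapply(pre, sid, ""))]
      post <- post[order(vapply(post, sid, ""))]
      names(pre) <- vapply(pre, sid, "")
      names(post) <- vapply(post, sid, "")
      res <- nbs_test(pre, post, T = cfg$nbs$T, k = cfg$nbs$k,
                      alpha = cfg$nbs$alpha, tail = cfg$nbs$tail,
                      seed = stage_seed(cfg, 5L))
      results[[b]] <- res
      comp <- nbs_components(res, significant_only = FALSE)
      if (nrow(comp)) comp_rows[[b]] <- cbind(band = b, comp)
    }
    comp_all <- if (length(comp_rows)) do.call(rbind, comp_rows) else
      data.frame(band = character(), component = integer(),
                 node_i = character(), node_j = character(), t = numeric(),
                 extent = integer(), p_value = numeric())
    utils::write.csv(comp_all, file.path(cfg$out_dir, "nbs_components.csv"),
                     row.names = FALSE)
    list(value = results,
         info = list(bands = as.list(bands),
                     components = sum(vapply(results, function(r)
                       length(r$extents), 0L)),
                     significant = sum(vapply(results, function(r)
                       sum(r$significant), 0L))))
  })

  # -- stage 6: stats ----------------------------------------------------
  stats_res <- run_stage("stats", function() {
    bands <- unique(metrics$band)
    screens <- list()
    models <- list()
    info <- list(bands = as.list(bands))
    for (b in bands) {
      mb <- metrics[metrics$band == b, ]
      screen <- screen_nodes(mb, bim$scores, alpha = cfg$stats$alpha)
      screens[[b]] <- cbind(band = b, screen)
      sel <- screen$node[screen$significant]
      binfo <- list(selected = length(sel), selected_nodes = as.list(sel))
      if (length(sel)) {
        merged <- merge(mb[mb$node %in% sel,
                           c("subject", "session", "node", "closeness")],
                        bim$scores, by = c("subject", "session"))
        wide <- stats::reshape(merged,
                               idvar = c("subject", "session", "pc1"),
                               timevar = "node", direction = "wide")
        feat_cols <- grep("^closeness\\.", names(wide))
        x <- as.matrix(wide[, feat_cols, drop = FALSE])
        colnames(x) <- sub("^closeness\\.", "", names(wide)[feat_cols])
        ctrl <- wide[, c("session", "subject")]
        model <- pcr_fit(x, wide$pc1, controls = ctrl)
        cv <- loocv_pcr(x, wide$pc1, controls = ctrl,
                        rescreen = isTRUE(cfg$stats$rescreen),
                        alpha = cfg$stats$alpha)
        models[[b]] <- list(model = model, cv = cv)
        binfo$vif <- as.list(if (ncol(x) >= 2) vif(x) else
          stats::setNames(1, colnames(x)))
        binfo$r2 <- model$r2
        binfo$loocv_r2 <- cv$r2
        binfo$loocv_rmse <- cv$rmse
        jsonlite::write_json(
          list(band = b, nodes = colnames(x),
               loadings = as.list(model$loadings),
               explained_variance = model$explained_variance,
               slope = model$coefficients[["slope"]],
               intercept = model$coefficients[["intercept"]],
               r2 = model$r2, loocv_r2 = cv$r2, loocv_rmse = cv$rmse),
          file.path(cfg$out_dir, paste0("pcr_model_", b, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
      info[[b]] <- binfo
    }
    screen_all <- do.call(rbind, screens)
    utils::write.csv(screen_all, file.path(cfg$out_dir, "node_screening.csv"),
                     row.names = FALSE)
    info$screened <- nrow(screen_all)
    list(value = list(screen = screen_all, models = models), info = info)
  })

  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  cfg_path <- file.path(cfg$out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$completed_stages <- names(manifest$stages)
  sel_all <- unlist(lapply(manifest$stages$stats[
    setdiff(names(manifest$stages$stats), c("bands", "screened"))],
    function(b) b$selected_nodes))
  manifest$summary <- list(
    nbs_significant = manifest$stages$nbs$significant,
    selected_nodes = as.list(sel_all %||% character(0)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(con, "completed ", length(manifest$stages), " stages")
  invisible(manifest)
}
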