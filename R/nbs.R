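# Network-based statistic: paired edge-wise t statistics, supra-threshold
# component extraction, and family-wise error control by within-subject
# sign-flip permutation of the maximal component extent.

# Stacks (lists of conn_matrix or plain matrices, one per subject) to an
# n_subjects x n_edges matrix of upper-triangle weights.
stack_to_edges <- function(stack) {
  mats <- lapply(stack, conn_values)
  n <- nrow(mats[[1]])
  up <- upper_pairs(n)
  t(vapply(mats, function(m) m[up], numeric(nrow(up))))
}

stack_labels <- function(stack) conn_labels(stack[[1]])

check_stacks <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2L) {
    stop("pre and post stacks must have equal length >= 2", call. = FALSE)
  }
  pre_ids <- names(pre)
  post_ids <- names(post)
  if (!is.null(pre_ids) && !is.null(post_ids) &&
      !identical(pre_ids, post_ids)) {
    stop("subject sets/order differ between stacks: ",
         paste(setdiff(union(pre_ids, post_ids),
                       intersect(pre_ids, post_ids)), collapse = ", "),
         call. = FALSE)
  }
}

# Paired t statistics for an n_subjects x n_edges difference matrix.
# Zero-variance edges get statistic 0 (and are counted).
paired_t_edges <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 1e-12] <- 0   # numerically constant differences are degenerate
  tt <- numeric(ncol(D))
  ok <- v > 0
  tt[ok] <- m[ok] / sqrt(v[ok] / n)
  attr(tt, "zero_variance") <- sum(!ok)
  tt
}

#' Paired edge-wise t statistics between sessions
#'
#' For each unique undirected edge, the paired t statistic of the
#' post-minus-pre weight differences across subjects. Edges whose
#' differences have zero variance are assigned statistic 0 (with a message),
#' since the t statistic is unbounded or undefined there.
#'
#' @param pre,post Lists of `"conn_matrix"` objects (or plain matrices), one
#'   per subject, in identical subject order.
#' @return Symmetric matrix of t statistics (zero diagonal) with channel
#'   labels as dimnames.
#' @export
edge_stats <- function(pre, post) {
  check_stacks(pre, post)
  D <- stack_to_edges(post) - stack_to_edges(pre)
  tt <- paired_t_edges(D)
  if (attr(tt, "zero_variance") > 0) {
    message(attr(tt, "zero_variance"),
            " edge(s) had zero-variance differences; statistic set to 0")
  }
  labels <- stack_labels(pre)
  n <- length(labels)
  up <- upper_pairs(n)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[cbind(up[, 1], up[, 2])] <- tt
  m + t(m)
}

# Edge columns (indices into the upper-triangle ordering) exceeding the
# threshold in the configured direction.
supra_edges <- function(tt, T, tail) {
  switch(tail,
         increase = which(tt >= T),
         decrease = which(tt <= -T),
         both = which(abs(tt) >= T))
}

# Connected components of an edge subset; returns list of integer edge-index
# vectors, largest first.
edge_components <- function(edge_idx, up) {
  if (!length(edge_idx)) return(list())
  el <- up[edge_idx, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(as.character(el[, 1]),
                                         as.character(el[, 2])),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[as.character(el[, 1])]
  comps <- split(edge_idx, comp_of_edge)
  comps[order(-vapply(comps, length, 0L))]
}

max_component_extent <- function(edge_idx, up) {
  if (length(edge_idx) <= 1L) return(length(edge_idx))
  max(vapply(edge_components(edge_idx, up), length, 0L))
}

#' Network-based statistic between paired sessions
#'
#' Identifies connected subnetworks of edges whose paired t statistic
#' exceeds the component-forming threshold `T` in the configured direction,
#' and assigns each component a family-wise-error-corrected p-value by
#' comparing its extent (edge count) against the permutation distribution of
#' the maximal supra-threshold component extent under within-subject
#' pre/post sign flips.
#'
#' When the full sign-flip space is affordable (`2^n <= k`) it is enumerated
#' exactly; otherwise `k` random flips are drawn and the observed labeling
#' is included in the reference, `p = (1 + #\{null >= observed\}) / (k + 1)`,
#' so p-values are never 0.
#'
#' @param pre,post Per-subject stacks as in [edge_stats()].
#' @param T Component-forming t threshold (> 0); default 2.75.
#' @param k Number of permutations (>= 100); default 100000.
#' @param alpha Significance level; components with `p < alpha` are flagged.
#' @param tail `"decrease"` (post < pre; default, the direction of
#'   training-related connectivity reductions), `"increase"`, or `"both"`
#'   (threshold on |t|).
#' @param seed Integer seed for the permutation draw.
#' @return Object of class `"nbs_result"`: `t_matrix`, `components` (list of
#'   data frames with `node_i`, `node_j`, `t`), `extents`, `p_values`,
#'   `significant`, `null_max_extents`, `exact` (TRUE when enumerated), and
#'   the configuration.
#' @export
nbs_test <- function(pre, post, T = 2.75, k = 100000, alpha = 0.05,
                     tail = c("decrease", "increase", "both"), seed = NULL) {
  tail <- match.arg(tail)
  if (T <= 0) stop("T must be positive", call. = FALSE)
  if (k < 100) stop("k must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  check_stacks(pre, post)
  labels <- stack_labels(pre)
  nch <- length(labels)
  up <- upper_pairs(nch)
  D <- stack_to_edges(post) - stack_to_edges(pre)
  n <- nrow(D)
  if (n < 5) {
    warning("only ", n, " subjects: at most 2^", n,
            " distinct sign flips exist; p-value resolution is limited")
  }
  if (1 / (k + 1) > alpha) {
    warning("k = ", k, " cannot resolve p-values below alpha = ", alpha)
  }

  tt <- paired_t_edges(D)
  if (attr(tt, "zero_variance") > 0) {
    message(attr(tt, "zero_variance"),
            " edge(s) had zero-variance differences; statistic set to 0")
  }
  obs_idx <- supra_edges(tt, T, tail)
  comps <- edge_components(obs_idx, up)
  extents <- vapply(comps, length, 0L)

  exact <- 2^n <= k
  css <- colSums(D^2)
  perm_max <- function(S) {
    # S: flips x subjects sign matrix
    M <- (S %*% D) / n
    V <- sweep(-n * M^2, 2, css, `+`) / (n - 1)
    V[V < 1e-12] <- 0
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    apply(Tm, 1, function(row) max_component_extent(supra_edges(row, T, tail),
                                                    up))
  }
  if (exact) {
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_max <- perm_max(grid)
    p_fun <- function(e) mean(null_max >= e)
  } else {
    null_max <- with_seed(seed, {
      out <- numeric(k)
      chunk <- 2000L
      done <- 0L
      while (done < k) {
        nb <- min(chunk, k - done)
        S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
        out[(done + 1):(done + nb)] <- perm_max(S)
        done <- done + nb
      }
      out
    })
    p_fun <- function(e) (1 + sum(null_max >= e)) / (k + 1)
  }
  p_values <- vapply(extents, p_fun, 0)

  comp_tables <- lapply(comps, function(ix) {
    data.frame(node_i = labels[up[ix, 1]], node_j = labels[up[ix, 2]],
               t = tt[ix], row.names = NULL)
  })
  tmat <- matrix(0, nch, nch, dimnames = list(labels, labels))
  tmat[cbind(up[, 1], up[, 2])] <- tt
  tmat <- tmat + t(tmat)
  structure(list(t_matrix = tmat, components = comp_tables,
                 extents = extents, p_values = p_values,
                 significant = p_values < alpha,
                 null_max_extents = null_max, exact = exact,
                 T = T, k = k, alpha = alpha, tail = tail, seed = seed,
                 n_subjects = n),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("<nbs_result> ", x$n_subjects, " subjects, tail '", x$tail,
      "', T = ", x$T, ", ",
      if (x$exact) paste0("exact (", length(x$null_max_extents), " flips)")
      else paste0("k = ", x$k, " permutations"), "\n", sep = "")
  if (!length(x$extents)) {
    cat("  no supra-threshold components\n")
  } else {
    for (i in seq_along(x$extents)) {
      cat(sprintf("  component %d: %d edge(s), p = %.4g%s\n", i,
                  x$extents[i], x$p_values[i],
                  if (x$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

#' Tidy table of NBS component edges
#'
#' @param x An `"nbs_result"`.
#' @param significant_only Keep only components with `p < alpha`.
#' @return Data frame with `component`, `node_i`, `node_j`, `t`, `extent`,
#'   `p_value` (zero rows when nothing passes).
#' @export
nbs_components <- function(x, significant_only = TRUE) {
  stopifnot(inherits(x, "nbs_result"))
  keep <- if (significant_only) which(x$significant) else
    seq_along(x$components)
  if (!length(keep)) {
    return(data.frame(component = integer(), node_i = character(),
                      node_j = character(), t = numeric(),
                      extent = integer(), p_value = numeric()))
  }
  out <- do.call(rbind, lapply(keep, function(i) {
    d <- x$components[[i]]
    d$component <- i
    d$extent <- x$extents[i]
    d$p_value <- x$p_values[i]
    d
  }))
  rownames(out) <- NULL
  out[, c("component", "node_i", "node_j", "t", "extent", "p_value")]
}
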