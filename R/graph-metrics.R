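# Percolation thresholding of weighted connectivity graphs and weighted
# closeness centrality on reciprocal-weight shortest paths.

conn_values <- function(m) {
  if (inherits(m, "conn_matrix")) return(unclass(m$values))
  if (inherits(m, "thresholded_graph")) return(m$values)
  as.matrix(m)
}

conn_labels <- function(m) {
  if (inherits(m, c("conn_matrix", "thresholded_graph"))) {
    return(m$channel_labels)
  }
  if (!is.null(rownames(m))) return(rownames(m))
  paste0("n", seq_len(nrow(m)))
}

conn_meta <- function(m, field) {
  if (inherits(m, c("conn_matrix", "thresholded_graph"))) m[[field]]
  else NA_character_
}

graph_from_weights <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Percolation threshold a connectivity matrix
#'
#' Removes edges in ascending weight order — equal-weight edges as one batch —
#' until the next removal would disconnect the graph, and returns the last
#' connected state. The surviving minimum weight `tau` is the largest
#' threshold that keeps the graph connected, i.e. the bottleneck (minimum
#' edge) of the maximum spanning tree.
#'
#' @param m A `"conn_matrix"` or symmetric non-negative weight matrix whose
#'   non-zero off-diagonal entries form a connected graph.
#' @return Object of class `"thresholded_graph"`: `values` (weak edges
#'   zeroed), `tau`, `connected = TRUE`, plus channel labels and any
#'   subject/session/band metadata.
#' @export
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 0.9; w[2, 3] <- w[3, 2] <- 0.8
#' w[1, 3] <- w[3, 1] <- 0.1
#' percolation_threshold(w)$tau  # 0.8; the 0.1 edge is pruned
percolation_threshold <- function(m) {
  w <- conn_values(m)
  labels <- conn_labels(m)
  dimnames(w) <- list(labels, labels)
  g <- graph_from_weights(w)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    parts <- split(labels, comp$membership)
    stop("input graph is disconnected; components: ",
         paste(vapply(parts, paste, "", collapse = ","), collapse = " | "),
         call. = FALSE)
  }
  current <- w
  repeat {
    weights <- current[upper.tri(current)]
    weights <- weights[weights > 0]
    u <- min(weights)
    trial <- current
    trial[trial == u] <- 0            # equal-weight batch removed together
    if (sum(trial[upper.tri(trial)] > 0) == 0) break
    if (igraph::components(graph_from_weights(trial))$no > 1) break
    current <- trial
  }
  surviving <- current[upper.tri(current)]
  structure(list(values = current,
                 tau = min(surviving[surviving > 0]),
                 connected = TRUE,
                 channel_labels = labels,
                 band = conn_meta(m, "band"),
                 subject = conn_meta(m, "subject"),
                 session = conn_meta(m, "session")),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  ne <- sum(x$values[upper.tri(x$values)] > 0)
  cat("<thresholded_graph> ", nrow(x$values), " nodes, ", ne,
      " edges surviving, tau = ", signif(x$tau, 4), "\n", sep = "")
  invisible(x)
}

#' Weighted closeness centrality
#'
#' For a connected weighted graph with edge lengths defined as the
#' reciprocal of the connectivity weight (stronger coupling = shorter path),
#' \deqn{C(i) = \frac{N - 1}{\sum_{j \ne i} l(i, j)}}
#' where `l(i, j)` is the weighted shortest-path distance. Multi-hop paths
#' may be shorter than the direct edge and are used when they are.
#'
#' @param g A `"thresholded_graph"`, `"conn_matrix"`, or weight matrix;
#'   must be connected.
#' @return Data frame with columns `node` and `closeness` (plus `subject`,
#'   `session`, `band` when present on the input).
#' @export
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
#' closeness_centrality(w)$closeness  # 2/3, 1, 2/3
closeness_centrality <- function(g) {
  w <- conn_values(g)
  labels <- conn_labels(g)
  ig <- graph_from_weights(w)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  if (any(!is.finite(d))) {
    stop("graph is disconnected: infinite path lengths", call. = FALSE)
  }
  n <- nrow(w)
  cl <- (n - 1) / rowSums(d)
  out <- data.frame(node = labels, closeness = as.numeric(cl),
                    row.names = NULL)
  for (field in c("subject", "session", "band")) {
    val <- conn_meta(g, field)
    if (!is.null(val) && !all(is.na(val))) out[[field]] <- val
  }
  out
}

#' Node metric table: percolation + closeness over a set of matrices
#'
#' Applies [percolation_threshold()] (optionally) then
#' [closeness_centrality()] to each connectivity matrix, returning one tidy
#' table keyed by subject, session, band and node.
#'
#' @param mats List of `"conn_matrix"` objects (e.g. from
#'   [average_sessions()]).
#' @param threshold Apply percolation thresholding first (default TRUE).
#' @return Data frame with columns `subject`, `session`, `band`, `node`,
#'   `closeness`, `tau` (`NA` when `threshold = FALSE`).
#' @export
node_metric_table <- function(mats, threshold = TRUE) {
  if (inherits(mats, "conn_matrix")) mats <- list(mats)
  rows <- lapply(mats, function(m) {
    tau <- NA_real_
    g <- m
    if (threshold) {
      g <- percolation_threshold(m)
      tau <- g$tau
    }
    cl <- closeness_centrality(g)
    cl$subject <- m$subject
    cl$session <- m$session
    cl$band <- m$band
    cl$tau <- tau
    cl[, c("subject", "session", "band", "node", "closeness", "tau")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
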