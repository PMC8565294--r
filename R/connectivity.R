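#' Fisher-z functional connectivity matrix
#'
#' Pearson correlation between every pair of node time series, clipped to
#' `[-1 + 1e-7, 1 - 1e-7]` so the Fisher r-to-z transform (`atanh`) stays
#' finite even for duplicated signals, with the diagonal set to zero.
#'
#' @param ts numeric T x N matrix (rows = timepoints, columns = nodes) or
#'   a list with elements `data` and optionally `subject_id`.
#' @return object of class `fc_matrix`: list with `z` (N x N symmetric
#'   matrix, zero diagonal), `n_timepoints`, `subject_id`.
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
#' compute_fc_matrix(x)$z["a", "b"]   # atanh(0.8) = 1.0986
#' @export
compute_fc_matrix <- function(ts) {
  subject_id <- NULL
  if (is.list(ts) && !is.data.frame(ts)) {
    subject_id <- ts$subject_id
    ts <- ts$data
  }
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 timepoints")
  if (ncol(ts) < 3) stop("need at least 3 nodes")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(ts))) colnames(ts)[bad] else bad
    stop("constant signal in node(s): ", paste(nm, collapse = ", "))
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  structure(list(z = z, n_timepoints = nrow(ts), subject_id = subject_id),
            class = "fc_matrix")
}

#' Sparsity threshold grid
#'
#' @param start,stop,step band limits and spacing; defaults give the
#'   8-point band 0.05, 0.10, ..., 0.40. `step` must divide
#'   `stop - start` (to 1e-9).
#' @return numeric vector of class `threshold_grid`, strictly increasing,
#'   all values in (0, 0.5].
#' @export
threshold_grid <- function(start = 0.05, stop = 0.40, step = 0.05) {
  if (abs((stop - start) / step - round((stop - start) / step)) > 1e-9)
    stop("step must divide (stop - start)")
  s <- seq(start, stop, by = step)
  if (any(s <= 0) || any(s > 0.5)) stop("sparsities must lie in (0, 0.5]")
  if (any(diff(s) <= 0)) stop("grid must be strictly increasing")
  structure(s, class = "threshold_grid")
}

# round half away from zero; R's round() rounds half to even
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps the `E(s) = round(s * N * (N - 1) / 2)` node pairs with the
#' largest strictly positive Fisher-z values as edges (negative and zero
#' correlations are never edges); ties are broken by ascending (i, j)
#' order. If fewer positive entries exist than `E(s)`, all positive
#' entries become edges and a warning records the shortfall.
#'
#' @param fc an `fc_matrix`.
#' @param s target sparsity in (0, 0.5].
#' @return object of class `binary_graph`: list with `adjacency` (N x N
#'   0/1 integer matrix), `sparsity`, `n_edges`.
#' @export
binarize_at_sparsity <- function(fc, s) {
  stopifnot(inherits(fc, "fc_matrix"), s > 0, s <= 0.5)
  z <- fc$z
  n <- nrow(z)
  target <- round_half_away(s * n * (n - 1) / 2)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[ut]
  pos <- vals > 0
  if (!any(pos)) stop("no positive correlations: empty graph is not analyzable")
  ut <- ut[pos, , drop = FALSE]
  vals <- vals[pos]
  if (length(vals) < target) {
    warning(sprintf("only %d positive entries for a target of %d edges at s = %g",
                    length(vals), target, s))
    keep <- seq_along(vals)
  } else {
    ord <- order(-vals, ut[, 1], ut[, 2])
    keep <- ord[seq_len(target)]
  }
  adj <- matrix(0L, n, n, dimnames = dimnames(z))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  binary_graph(adj, sparsity = s)
}

#' Construct a binary graph from an adjacency matrix
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param sparsity the sparsity the graph was thresholded at (optional).
#' @return a `binary_graph`.
#' @export
binary_graph <- function(adjacency, sparsity = NA_real_) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (!all(adjacency %in% c(0L, 1L))) stop("adjacency must be 0/1")
  if (any(diag(adjacency) != 0L)) stop("self-loops are not allowed")
  if (!identical(adjacency, t(adjacency))) stop("adjacency must be symmetric")
  structure(list(adjacency = adjacency,
                 sparsity = sparsity,
                 n_edges = sum(adjacency) %/% 2L),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("Binary graph:", nrow(x$adjacency), "nodes,", x$n_edges, "edges",
      if (!is.na(x$sparsity)) paste0("(sparsity ", x$sparsity, ")"), "\n")
  invisible(x)
}

#' Connectedness floor report
#'
#' For sparsity thresholding to yield analyzable networks the mean degree
#' should exceed `ln(N)`; this reports that check together with the
#' number of connected components (breadth-first search).
#'
#' @param g a `binary_graph`.
#' @return list: `mean_degree`, `log_n`, `above_floor`, `n_components`.
#' @export
check_connectedness_floor <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- nrow(g$adjacency)
  mean_degree <- 2 * g$n_edges / n
  comp <- cpp_components(g$adjacency)
  list(mean_degree = mean_degree,
       log_n = log(n),
       above_floor = mean_degree > log(n),
       n_components = max(comp))
}

#' Write / read FC matrices and edge lists as plain text
#'
#' FC matrices are written as full symmetric N x N TSVs; binary graphs as
#' 0-based `i<TAB>j` edge lists (i < j) with a JSON sidecar carrying N,
#' sparsity and edge count.
#'
#' @param fc an `fc_matrix`; `g` a `binary_graph`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  utils::write.table(fc$z, path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = !is.null(colnames(fc$z)))
  invisible(path)
}

#' @rdname write_fc_matrix
#' @param g a `binary_graph`.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "binary_graph"))
  ut <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  el <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE] - 1L
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("node_i", "node_j"))
  jsonlite::write_json(list(n_nodes = nrow(g$adjacency),
                            sparsity = g$sparsity, n_edges = g$n_edges),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
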