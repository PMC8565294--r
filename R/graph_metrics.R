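#' Nodal degree
#' @param g a `binary_graph`.
#' @return integer vector, edges incident on each node.
#' @export
nodal_degree <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  as.integer(colSums(g$adjacency))
}

#' Clustering coefficients
#'
#' Per-node Watts-Strogatz clustering `C_i = 2 t_i / (k_i (k_i - 1))`
#' where `t_i` counts edges among the neighbors of `i`; nodes with degree
#' below 2 get `C_i = 0` and are included in the mean (`Cp`).
#'
#' @param g a `binary_graph`.
#' @return list: `per_node` (numeric vector), `Cp` (mean).
#' @export
clustering_coefficients <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  ci <- cpp_clustering(g$adjacency)
  list(per_node = ci, Cp = mean(ci))
}

#' Pairwise shortest-path lengths
#'
#' Unweighted hop distances by breadth-first search; unreachable pairs
#' are `Inf`, the diagonal 0.
#'
#' @param g a `binary_graph`.
#' @return N x N numeric matrix.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  cpp_bfs_distances(g$adjacency)
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal distances; a `disconnected` flag is
#' set when any pair is unreachable (the mean then covers reachable pairs
#' only, so disconnection cannot poison it with infinities).
#'
#' @param g a `binary_graph`.
#' @param D optional precomputed distance matrix.
#' @return list: `Lp`, `disconnected`.
#' @export
characteristic_path_length <- function(g, D = NULL) {
  if (is.null(D)) D <- shortest_path_lengths(g)
  off <- D[row(D) != col(D)]
  finite <- off[is.finite(off)]
  if (!length(finite)) stop("graph has no edges: Lp undefined")
  list(Lp = mean(finite), disconnected = any(!is.finite(off)))
}

#' Global and nodal efficiency
#'
#' `Eglob = mean over ordered pairs of 1/d_ij` (with `1/Inf = 0`);
#' `NEg(i) = mean over j != i of 1/d_ij`. Robust to disconnection by
#' construction.
#'
#' @param g a `binary_graph`.
#' @param D optional precomputed distance matrix.
#' @return list: `Eglob`, `per_node` (NEg).
#' @export
global_efficiency <- function(g, D = NULL) {
  if (is.null(D)) {
    stopifnot(inherits(g, "binary_graph"))
    n <- nrow(g$adjacency)
    s <- cpp_inv_dist_sums(g$adjacency)
    return(list(Eglob = sum(s) / (n * (n - 1)), per_node = s / (n - 1)))
  }
  n <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  neg <- rowSums(inv) / (n - 1)
  list(Eglob = sum(inv) / (n * (n - 1)), per_node = neg)
}

#' Local efficiency
#'
#' `NEloc(i)` is the global efficiency of the subgraph induced by the
#' neighbors of `i` (node `i` excluded); 0 for degree < 2. `Eloc` is the
#' mean over all nodes (degree < 2 nodes included).
#'
#' @param g a `binary_graph`.
#' @return list: `per_node` (NEloc), `Eloc`.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  ne <- cpp_local_efficiency(g$adjacency)
  list(per_node = ne, Eloc = mean(ne))
}

#' Betweenness centrality
#'
#' `BC(i) = sum over unordered pairs s != i != t of sigma_st(i)/sigma_st`
#' where `sigma_st` counts shortest s-t paths; Brandes' accumulation.
#' Reported as raw pair counts (upper bound `(N-1)(N-2)/2`), not
#' normalized.
#'
#' @param g a `binary_graph`.
#' @return numeric vector of BC per node.
#' @export
betweenness <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  cpp_betweenness(g$adjacency)
}

#' Degree-preserving random null ensemble
#'
#' Maslov-Sneppen double-edge swaps: repeatedly pick two edges (a,b),
#' (c,d) with four distinct endpoints and rewire to (a,d),(c,b) when
#' neither new edge exists. Every null keeps the exact degree sequence of
#' the source graph. Reproducible under `seed`.
#'
#' @param g a `binary_graph`.
#' @param n_nulls number of null graphs.
#' @param n_swap_attempts swap attempts per null; default `100 * n_edges`.
#' @param seed RNG seed for the ensemble.
#' @return object of class `null_ensemble`: list with `graphs`,
#'   `n_nulls`, `n_swap_attempts`, `seed`.
#' @export
generate_null_ensemble <- function(g, n_nulls = 100,
                                   n_swap_attempts = NULL, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  if (is.null(n_swap_attempts)) n_swap_attempts <- 100L * g$n_edges
  if (!has_two_independent_edges(g$adjacency))
    stop("graph has no two independent edges: cannot rewire")
  set.seed(seed)
  graphs <- vector("list", n_nulls)
  for (k in seq_len(n_nulls)) {
    adj <- cpp_rewire(g$adjacency, as.integer(n_swap_attempts))
    graphs[[k]] <- binary_graph(adj, sparsity = g$sparsity)
  }
  structure(list(graphs = graphs, n_nulls = n_nulls,
                 n_swap_attempts = n_swap_attempts, seed = seed),
            class = "null_ensemble")
}

has_two_independent_edges <- function(adj) {
  ut <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2) return(FALSE)
  # if every edge met a fixed pair {a,b}, m could not exceed 2(n-1)
  if (m > 2 * (nrow(adj) - 1)) return(TRUE)
  for (a in seq_len(m - 1)) {
    for (b in seq(a + 1, m)) {
      if (!any(ut[a, ] %in% ut[b, ])) return(TRUE)
    }
  }
  FALSE
}

#' Small-world metrics against a null ensemble
#'
#' `gamma = Cp / mean null Cp`, `lambda = Lp / mean null Lp`,
#' `sigma = gamma / lambda`.
#'
#' @param g a `binary_graph`.
#' @param ens a `null_ensemble` built from `g` (same degree sequence).
#' @return list: `gamma`, `lambda`, `sigma`, plus the observed and
#'   null-mean `Cp`/`Lp`.
#' @export
small_world_metrics <- function(g, ens) {
  stopifnot(inherits(g, "binary_graph"), inherits(ens, "null_ensemble"))
  cp <- clustering_coefficients(g)$Cp
  lp <- characteristic_path_length(g)$Lp
  null_cp <- vapply(ens$graphs,
                    function(h) clustering_coefficients(h)$Cp, numeric(1))
  null_lp <- vapply(ens$graphs,
                    function(h) characteristic_path_length(h)$Lp, numeric(1))
  if (mean(null_cp) == 0 || mean(null_lp) == 0)
    stop("null-mean Cp or Lp is zero: normalization undefined")
  gamma <- cp / mean(null_cp)
  lambda <- lp / mean(null_lp)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = cp, Lp = lp,
       Cp_rand = mean(null_cp), Lp_rand = mean(null_lp))
}

#' Area under the curve across the threshold grid
#'
#' Trapezoidal integral of a metric over the sparsity band, a
#' threshold-independent summary: `sum (s_{k+1} - s_k) (v_k + v_{k+1})/2`.
#'
#' @param values metric value at each grid point.
#' @param grid a `threshold_grid` (or strictly increasing numeric).
#' @return scalar AUC.
#' @export
auc_over_grid <- function(values, grid) {
  grid <- as.numeric(grid)
  if (length(grid) < 2) stop("AUC needs at least 2 grid points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (length(values) != length(grid))
    stop("values and grid must have the same length")
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

all_global_metrics <- c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda", "sigma")
all_nodal_metrics <- c("DC", "BC", "NEg", "NEloc")

#' Full metric profile of one subject
#'
#' Binarizes the FC matrix at every grid point, computes the requested
#' global metrics (Cp, Lp, Eglob, Eloc and, when `n_nulls > 0`, gamma,
#' lambda, sigma against degree-preserving nulls) and nodal metrics
#' (DC, BC, NEg, NEloc), and summarizes each across the band by its AUC.
#' Deterministic given `seed`.
#'
#' @param fc an `fc_matrix`.
#' @param grid a `threshold_grid`.
#' @param n_nulls nulls per grid point for gamma/lambda/sigma; 0 skips
#'   the normalized metrics.
#' @param n_swap_attempts per-null swap attempts (default `100 * edges`).
#' @param seed RNG seed for the null ensembles.
#' @param global_metrics,nodal_metrics subsets to compute (cheaper
#'   simulation studies restrict these).
#' @return object of class `metric_profile`: `subject_id`, `global`
#'   (data.frame, one row per grid point), `nodal` (list of node x grid
#'   matrices), `auc` (list: `global` named vector, `nodal` node x metric
#'   matrix), `disconnected` (logical per grid point).
#' @export
profile_subject <- function(fc, grid = threshold_grid(), n_nulls = 0,
                            n_swap_attempts = NULL, seed = 1L,
                            global_metrics = all_global_metrics,
                            nodal_metrics = all_nodal_metrics) {
  stopifnot(inherits(fc, "fc_matrix"))
  grid_v <- as.numeric(grid)
  n <- nrow(fc$z)
  if (n_nulls == 0)
    global_metrics <- setdiff(global_metrics, c("gamma", "lambda", "sigma"))
  glob <- matrix(NA_real_, length(grid_v), length(global_metrics),
                 dimnames = list(NULL, global_metrics))
  nod <- lapply(nodal_metrics, function(m)
    matrix(NA_real_, n, length(grid_v)))
  names(nod) <- nodal_metrics
  disconnected <- logical(length(grid_v))

  need_dist <- any(c("Lp", "gamma", "lambda", "sigma") %in% global_metrics)

  for (k in seq_along(grid_v)) {
    g <- binarize_at_sparsity(fc, grid_v[k])
    D <- if (need_dist) shortest_path_lengths(g) else NULL
    disconnected[k] <- if (!is.null(D)) {
      any(!is.finite(D[row(D) != col(D)]))
    } else max(cpp_components(g$adjacency)) > 1L
    if ("Cp" %in% global_metrics)
      glob[k, "Cp"] <- clustering_coefficients(g)$Cp
    if ("Lp" %in% global_metrics)
      glob[k, "Lp"] <- characteristic_path_length(g, D)$Lp
    eff <- if (any(c("Eglob", "NEg") %in% c(global_metrics, nodal_metrics)))
      global_efficiency(g, D) else NULL
    if ("Eglob" %in% global_metrics) glob[k, "Eglob"] <- eff$Eglob
    le <- if (any(c("Eloc", "NEloc") %in% c(global_metrics, nodal_metrics)))
      local_efficiency(g) else NULL
    if ("Eloc" %in% global_metrics) glob[k, "Eloc"] <- le$Eloc
    if (any(c("gamma", "lambda", "sigma") %in% global_metrics)) {
      ens <- generate_null_ensemble(g, n_nulls = n_nulls,
                                    n_swap_attempts = n_swap_attempts,
                                    seed = seed + k)
      sw <- small_world_metrics(g, ens)
      if ("gamma" %in% global_metrics) glob[k, "gamma"] <- sw$gamma
      if ("lambda" %in% global_metrics) glob[k, "lambda"] <- sw$lambda
      if ("sigma" %in% global_metrics) glob[k, "sigma"] <- sw$sigma
    }
    if ("DC" %in% nodal_metrics) nod$DC[, k] <- nodal_degree(g)
    if ("BC" %in% nodal_metrics) nod$BC[, k] <- betweenness(g)
    if ("NEg" %in% nodal_metrics) nod$NEg[, k] <- eff$per_node
    if ("NEloc" %in% nodal_metrics) nod$NEloc[, k] <- le$per_node
  }

  auc_global <- apply(glob, 2, auc_over_grid, grid = grid_v)
  auc_nodal <- vapply(nod, function(m)
    apply(m, 1, auc_over_grid, grid = grid_v),
    numeric(n))
  structure(list(subject_id = fc$subject_id,
                 global = data.frame(sparsity = grid_v, glob),
                 nodal = nod,
                 auc = list(global = auc_global, nodal = auc_nodal),
                 grid = grid_v,
                 disconnected = disconnected),
            class = "metric_profile")
}

#' Metric profiles for every subject in a cohort
#'
#' @param series named list of T x N time-series matrices.
#' @param ... passed to [profile_subject()].
#' @return named list of `metric_profile` objects.
#' @export
profile_cohort <- function(series, ...) {
  out <- vector("list", length(series))
  names(out) <- names(series)
  for (id in names(series)) {
    fc <- compute_fc_matrix(list(subject_id = id, data = series[[id]]))
    out[[id]] <- profile_subject(fc, ...)
  }
  out
}

#' Write per-subject metric tables
#'
#' `global_metrics.tsv` (rows = grid points), `nodal_metrics.tsv` (long:
#' node_id, sparsity, DC, BC, NEg, NEloc) and `auc.tsv`.
#'
#' @param profile a `metric_profile`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(profile$global, file.path(dir, "global_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  long <- do.call(rbind, lapply(seq_along(profile$grid), function(k) {
    data.frame(node_id = seq_len(nrow(profile$nodal[[1]])),
               sparsity = profile$grid[k],
               lapply(profile$nodal, function(m) m[, k]))
  }))
  utils::write.table(long, file.path(dir, "nodal_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  auc_tab <- data.frame(metric = c(names(profile$auc$global),
                                   paste0("node_", rep(seq_len(nrow(profile$auc$nodal)),
                                                       ncol(profile$auc$nodal)),
                                          "_", rep(colnames(profile$auc$nodal),
                                                   each = nrow(profile$auc$nodal)))),
                        auc = c(profile$auc$global, as.vector(profile$auc$nodal)))
  utils::write.table(auc_tab, file.path(dir, "auc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
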