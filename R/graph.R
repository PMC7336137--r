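#' Extract an intra-hemispheric quadrant
#'
#' Principal submatrix of a 246 x 246 adjacency (canonical atlas order)
#' over one hemisphere's nodes: the right-right block is the "second
#' quadrant" (right intra-hemispheric connections) and the left-left block
#' the "fourth quadrant".
#'
#' @param adj 246 x 246 adjacency matrix in canonical atlas order.
#' @param atlas Atlas table.
#' @param side `"left"` or `"right"`.
#' @return A 123 x 123 matrix.
#' @export
extract_quadrant <- function(adj, atlas, side = c("left", "right")) {
  side <- match.arg(side)
  if (!is.matrix(adj) || any(dim(adj) != 246)) {
    stop("adjacency must be 246 x 246 in canonical atlas order",
         call. = FALSE)
  }
  blocks <- hemisphere_blocks(atlas)
  idx <- blocks[[side]]
  adj[idx, idx, drop = FALSE]
}

#' Threshold a weighted graph
#'
#' Proportional thresholding (default) keeps the `round(density * N(N-1)/2)`
#' strongest upper-triangle edges, breaking ties by smaller (i, j)
#' lexicographic index, zeroes the rest and symmetrizes. The alternative
#' absolute mode keeps edges with weight strictly above a cutoff. Edge
#' lengths for path analysis are the inverse of the retained connection
#' strengths (infinite where no edge is retained).
#'
#' @param adj Symmetric nonnegative matrix with zero diagonal.
#' @param density Retained edge fraction in (0, 1] (proportional mode).
#' @param method `"proportional"` (default) or `"absolute"`.
#' @param cutoff Absolute-mode weight cutoff (default 0.1).
#' @return A list of class `hemilat_graph` with `weights`, `lengths`,
#'   `density`, `n_edges`.
#' @export
proportional_threshold <- function(adj, density = 0.10,
                                   method = c("proportional", "absolute"),
                                   cutoff = 0.1) {
  method <- match.arg(method)
  check_square_sym(adj, "adjacency")
  if (any(adj < 0)) stop("adjacency must be nonnegative", call. = FALSE)
  n <- nrow(adj)
  pairs <- upper_pairs(n)
  w <- adj[pairs]
  if (method == "proportional") {
    if (density <= 0 || density > 1) {
      stop("density must lie in (0, 1]", call. = FALSE)
    }
    n_keep <- round(density * n * (n - 1) / 2)
    ord <- order(-w, pairs[, 1], pairs[, 2])
    keep <- ord[seq_len(n_keep)]
  } else {
    keep <- which(w > cutoff)
  }
  weights <- matrix(0, n, n)
  if (length(keep) > 0) {
    kp <- pairs[keep, , drop = FALSE]
    weights[kp] <- w[keep]
    weights <- weights + t(weights)
  }
  lengths <- ifelse(weights > 0, 1 / weights, Inf)
  diag(lengths) <- 0
  structure(list(weights = weights, lengths = lengths,
                 density = if (method == "proportional") density else NA,
                 n_edges = length(keep)),
            class = "hemilat_graph")
}

#' @keywords internal
graph_to_igraph <- function(g) {
  if (any(g$weights < 0)) stop("negative weight", call. = FALSE)
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' All-pairs weighted shortest path lengths
#'
#' Dijkstra distances on the thresholded graph, with edge length = inverse
#' connection strength; disconnected pairs get `Inf`.
#'
#' @param g A `hemilat_graph`.
#' @return An N x N distance matrix (zero diagonal).
#' @export
shortest_path_lengths <- function(g) {
  ig <- graph_to_igraph(g)
  if (igraph::ecount(ig) == 0) {
    d <- matrix(Inf, nrow(g$weights), nrow(g$weights))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(ig, weights = 1 / igraph::E(ig)$weight,
                    algorithm = "dijkstra")
}

# weighted triangle intensity t_i (Onnela), with weights normalized by max
#' @keywords internal
triangle_intensity <- function(weights) {
  mx <- max(weights)
  if (mx == 0) return(list(t = rep(0, nrow(weights)),
                           k = rep(0, nrow(weights))))
  w3 <- (weights / mx)^(1 / 3)
  t_i <- diag(w3 %*% w3 %*% w3) / 2
  k_i <- rowSums(weights > 0)
  list(t = t_i, k = k_i)
}

#' Global graph measures of a thresholded weighted graph
#'
#' Global efficiency (GE): mean inverse shortest path length over ordered
#' node pairs, counting disconnected pairs as 0. Characteristic path length
#' (CPL): mean shortest path length over *connected* pairs only (infinite
#' distances are excluded; NaN with a warning if no pair is connected).
#' Transitivity (T): collectively normalized weighted triangle density,
#' `sum_i 2 t_i / sum_i k_i (k_i - 1)` with Onnela geometric-mean triangle
#' intensities computed on weights normalized by the graph maximum.
#'
#' @param g A `hemilat_graph`.
#' @return A list with `ge`, `cpl`, `transitivity`.
#' @export
global_measures <- function(g) {
  n <- nrow(g$weights)
  d <- shortest_path_lengths(g)
  off <- d[row(d) != col(d)]
  inv <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  ge <- sum(inv) / (n * (n - 1))
  finite <- off[is.finite(off)]
  if (length(finite) == 0) {
    warning("graph has no connected pair; CPL undefined")
    cpl <- NaN
  } else {
    cpl <- mean(finite)
  }
  tri <- triangle_intensity(g$weights)
  denom <- sum(tri$k * (tri$k - 1))
  transitivity <- if (denom == 0) 0 else sum(2 * tri$t) / denom
  list(ge = ge, cpl = cpl, transitivity = transitivity)
}

#' Nodal graph measures of a thresholded weighted graph
#'
#' Clustering coefficient (CC): `2 t_i / (k_i (k_i - 1))`, 0 for nodes with
#' fewer than 2 neighbours. Nodal efficiency (NE): mean inverse shortest
#' path length from the node to all others (0 terms for disconnected
#' pairs). Betweenness centrality (BC): fraction of shortest paths through
#' the node, `sum_{s<t} sigma_st(i)/sigma_st / ((N-1)(N-2))` (raw
#' unnormalized counts available via `bc_raw = TRUE`). Eigenvector
#' centrality (EVC): unit-Euclidean-norm nonnegative principal eigenvector
#' of the thresholded weight matrix, computed by power iteration
#' (tolerance 1e-12); for a disconnected graph this is the eigenvector of
#' the whole matrix, so the component with the largest eigenvalue carries
#' the mass.
#'
#' @param g A `hemilat_graph`.
#' @param bc_raw If TRUE, return unnormalized betweenness path counts.
#' @return A data.frame with columns `node`, `cc`, `ne`, `bc`, `evc`.
#' @export
nodal_measures <- function(g, bc_raw = FALSE) {
  n <- nrow(g$weights)
  tri <- triangle_intensity(g$weights)
  cc <- ifelse(tri$k >= 2, 2 * tri$t / (tri$k * (tri$k - 1)), 0)
  d <- shortest_path_lengths(g)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  ne <- rowSums(inv) / (n - 1)
  ig <- graph_to_igraph(g)
  if (igraph::ecount(ig) > 0) {
    bc <- igraph::betweenness(ig, weights = 1 / igraph::E(ig)$weight,
                              directed = FALSE)
  } else {
    bc <- rep(0, n)
  }
  if (!bc_raw) bc <- bc / ((n - 1) * (n - 2))
  evc <- power_iteration_evc(g$weights)
  data.frame(node = seq_len(n), cc = cc, ne = ne, bc = bc, evc = evc)
}

#' @keywords internal
power_iteration_evc <- function(w, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(w)
  if (max(w) == 0) return(rep(0, n))
  # small positive diagonal shift: keeps the principal eigenvector but
  # breaks the +/- lambda_max symmetry of bipartite graphs, which would
  # make the unshifted iteration oscillate
  shift <- 0.1 * max(rowSums(w))
  ws <- w + diag(shift, n)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    v_new <- drop(ws %*% v)
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) return(rep(0, n))
    v_new <- v_new / nrm
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v[v < 0 & v > -1e-10] <- 0
  v / sqrt(sum(v^2))
}

#' Quadrant-level global measures for one subject
#'
#' Thresholds each intra-hemispheric quadrant of each band's adjacency and
#' computes GE, CPL and T, returning a long-format table.
#'
#' @param matrices Named list of 246 x 246 adjacency matrices (per band).
#' @param atlas Atlas table.
#' @param density Proportional threshold density (default 0.10).
#' @return A data.frame with columns `band`, `network`, `measure`, `value`.
#' @export
quadrant_global_measures <- function(matrices, atlas, density = 0.10) {
  rows <- list()
  for (b in names(matrices)) {
    for (side in c("left", "right")) {
      q <- extract_quadrant(matrices[[b]], atlas, side)
      gm <- global_measures(proportional_threshold(q, density))
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, network = paste0(side, "_intra"),
        measure = c("ge", "cpl", "transitivity"),
        value = c(gm$ge, gm$cpl, gm$transitivity),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
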