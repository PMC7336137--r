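#' NBS configuration
#'
#' @param primary_threshold Primary edge-level t threshold (default 3.45).
#' @param n_permutations Number of group-label permutations (default 5000,
#'   minimum 100).
#' @param alpha Component-level FWER significance level (default 0.05).
#' @param direction `"both"` (two one-sided analyses, the default),
#'   `"A_gt_B"`, or `"B_gt_A"`.
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `hemilat_nbs_config`.
#' @export
nbs_config <- function(primary_threshold = 3.45, n_permutations = 5000,
                       alpha = 0.05,
                       direction = c("both", "A_gt_B", "B_gt_A"),
                       seed = 1) {
  direction <- match.arg(direction)
  if (primary_threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (n_permutations < 100) {
    stop("n_permutations must be >= 100", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  structure(list(primary_threshold = primary_threshold,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, direction = direction, seed = seed),
            class = "hemilat_nbs_config")
}

# sentinel for infinite t (zero pooled variance, unequal means)
T_SENTINEL <- 1e10

# vectorized pooled-variance two-sample t for many permutations at once:
# x is subjects x edges, g is subjects x perms 0/1 indicator of group A
#' @keywords internal
perm_tstats <- function(x, g, n_a, n_b) {
  s1 <- crossprod(x, g)               # edges x perms, group-A sums
  s2 <- crossprod(x^2, g)
  tot1 <- colSums(x)
  tot2 <- colSums(x^2)
  mean_a <- s1 / n_a
  mean_b <- (tot1 - s1) / n_b
  ss_a <- s2 - s1^2 / n_a
  ss_b <- (tot2 - s2) - (tot1 - s1)^2 / n_b
  s_pool <- (ss_a + ss_b) / (n_a + n_b - 2)
  se <- sqrt(pmax(s_pool, 0) * (1 / n_a + 1 / n_b))
  num <- mean_a - mean_b
  t <- num / se
  bad <- se == 0
  if (any(bad)) t[bad] <- ifelse(num[bad] == 0, 0, sign(num[bad]) * T_SENTINEL)
  t
}

#' Edgewise two-sample t statistics
#'
#' Pooled-variance two-sample t per edge (group A minus group B). Edges
#' with zero pooled variance get t = 0 when the means agree and a large
#' finite sentinel of the appropriate sign otherwise.
#'
#' @param group_a,group_b Lists of symmetric adjacency matrices with
#'   identical node order (>= 2 subjects each).
#' @return A symmetric t matrix with zero diagonal.
#' @export
edge_tstats <- function(group_a, group_b) {
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  dims <- unique(lapply(c(group_a, group_b), dim))
  if (length(dims) != 1) stop("matrix shape mismatch", call. = FALSE)
  n <- dims[[1]][1]
  x <- stack_upper(c(group_a, group_b))
  g <- matrix(c(rep(1, n_a), rep(0, n_b)), ncol = 1)
  t_vec <- drop(perm_tstats(x, g, n_a, n_b))
  t_mat <- matrix(0, n, n)
  t_mat[upper.tri(t_mat)] <- t_vec
  t_mat + t(t_mat)
}

# union-find over the nodes touched by an edge list; returns the component
# id of each edge
#' @keywords internal
edge_components <- function(edges) {
  nodes <- sort(unique(as.vector(edges)))
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- match(edges[, 1], nodes)
  b <- match(edges[, 2], nodes)
  for (e in seq_len(nrow(edges))) {
    ra <- find(a[e])
    rb <- find(b[e])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(nrow(edges)), function(e) find(a[e]), integer(1))
}

#' @keywords internal
max_component_extent <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  if (nrow(edges) == 1) return(1L)
  comp <- edge_components(edges)
  max(tabulate(comp))
}

#' Connected components of supra-threshold edges
#'
#' Thresholds the (direction-signed) t matrix and groups the surviving
#' edges into connected components by union-find. Component extent is the
#' number of edges.
#'
#' @param t_mat Symmetric t matrix.
#' @param threshold Primary threshold (> 0).
#' @param direction `"A_gt_B"` keeps edges with `t > threshold`,
#'   `"B_gt_A"` edges with `-t > threshold`.
#' @return A list of components sorted by extent (descending); each has
#'   `edges` (data.frame i, j, t), `nodes`, `extent`.
#' @export
suprathreshold_components <- function(t_mat, threshold,
                                      direction = c("A_gt_B", "B_gt_A")) {
  direction <- match.arg(direction)
  check_square_sym(t_mat, "t matrix")
  s <- if (direction == "A_gt_B") t_mat else -t_mat
  up <- which(upper.tri(s) & s > threshold, arr.ind = TRUE)
  if (nrow(up) == 0) return(list())
  comp <- if (nrow(up) == 1) 1L else edge_components(up)
  out <- lapply(unique(comp), function(cid) {
    e <- up[comp == cid, , drop = FALSE]
    list(edges = data.frame(i = e[, 1], j = e[, 2],
                            t = t_mat[e]),
         nodes = sort(unique(as.vector(e))),
         extent = nrow(e))
  })
  out[order(-vapply(out, `[[`, 0L, "extent"))]
}

#' Network-based statistic permutation test
#'
#' Mass-univariate edgewise t-test, primary thresholding, component
#' identification, then permutation of group labels (group sizes preserved)
#' to build the null distribution of the maximum component extent. The
#' FWER-corrected p-value of an observed component of extent `e` is
#' `(1 + #{perm max extent >= e}) / (n_permutations + 1)`. With
#' `direction = "both"` the two one-sided analyses are run on a shared
#' permutation stream and reported separately.
#'
#' Within each group, subjects are canonically reordered (by the sum and
#' first entries of their edge vectors) before the permutation stream is
#' drawn, so results do not depend on the order subjects are supplied in.
#'
#' @param group_a,group_b Lists of adjacency matrices.
#' @param config An [nbs_config()].
#' @return A list of class `hemilat_nbs` with `components` (each carrying
#'   `fwer_p` and `direction`), `null_max_extents` per direction,
#'   `t_observed`, and the config.
#' @export
nbs_test <- function(group_a, group_b, config = nbs_config()) {
  stopifnot(inherits(config, "hemilat_nbs_config"))
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  if (choose(n_a + n_b, n_a) < 2) {
    stop("too few subjects for any distinct permutation", call. = FALSE)
  }
  n_nodes <- nrow(group_a[[1]])
  x_a <- stack_upper(group_a)
  x_b <- stack_upper(group_b)
  canon <- function(m) {
    m[order(rowSums(m), m[, 1], m[, min(2, ncol(m))]), , drop = FALSE]
  }
  x <- rbind(canon(x_a), canon(x_b))
  n <- n_a + n_b
  pairs <- upper_pairs(n_nodes)

  directions <- if (config$direction == "both") {
    c("A_gt_B", "B_gt_A")
  } else config$direction

  g_obs <- matrix(c(rep(1, n_a), rep(0, n_b)), ncol = 1)
  t_obs_vec <- drop(perm_tstats(x, g_obs, n_a, n_b))
  t_obs <- matrix(0, n_nodes, n_nodes)
  t_obs[upper.tri(t_obs)] <- t_obs_vec
  t_obs <- t_obs + t(t_obs)

  perm_idx <- with_seed(config$seed, {
    vapply(seq_len(config$n_permutations),
           function(p) sample.int(n, n_a), integer(n_a))
  })

  n_perm <- config$n_permutations
  thr <- config$primary_threshold
  ext <- .nbs_null_max_extents(x, perm_idx, pairs, n_nodes, n_a, n_b, thr)
  null_max <- list(A_gt_B = ext[, 1], B_gt_A = ext[, 2])[directions]

  components <- list()
  for (dir in directions) {
    comps <- suprathreshold_components(t_obs, thr, dir)
    for (cm in comps) {
      cm$fwer_p <- (1 + sum(null_max[[dir]] >= cm$extent)) / (n_perm + 1)
      cm$direction <- dir
      components[[length(components) + 1L]] <- cm
    }
  }
  components <- components[order(-vapply(components, `[[`, 0L, "extent"))]

  structure(list(components = components, null_max_extents = null_max,
                 t_observed = t_obs, config = config),
            class = "hemilat_nbs")
}

#' Write an NBS result to disk
#'
#' Writes each component's edge list as TSV (`node_i`, `node_j`, `t`) and a
#' JSON summary (extent, FWER p, direction, config echo).
#'
#' @param result A `hemilat_nbs`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_nbs_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(config = unclass(result$config), components = list())
  for (k in seq_along(result$components)) {
    cm <- result$components[[k]]
    edges <- cm$edges
    names(edges) <- c("node_i", "node_j", "t")
    utils::write.table(edges,
                       file.path(dir, sprintf("component_%02d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$components[[k]] <- list(extent = cm$extent,
                                    fwer_p = cm$fwer_p,
                                    direction = cm$direction,
                                    n_nodes = length(cm$nodes))
  }
  jsonlite::write_json(summary, file.path(dir, "nbs_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
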