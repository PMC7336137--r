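# Independent brute-force oracles used across the test files. These are
# deliberately naive implementations (exhaustive loops, Floyd-Warshall,
# direct enumeration) kept free of any code path they are used to check.

# exhaustive medoid: argmin over ROI voxels of summed squared distance
bf_medoid <- function(coords) {
  ssd <- apply(coords, 1, function(v) {
    sum(rowSums(sweep(coords, 2, v)^2))
  })
  coords[which.min(ssd), ]
}

# all-pairs shortest paths by Floyd-Warshall on a length matrix
bf_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  d[d == 0 & row(d) != col(d)] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# triangle intensities by direct triple loop on max-normalized weights
bf_triangles <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  t_i <- numeric(n)
  if (mx == 0) return(list(t = t_i, k = rep(0, n)))
  wh <- w / mx
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && h != j &&
            w[i, j] > 0 && w[i, h] > 0 && w[j, h] > 0) {
          acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        }
      }
    }
    t_i[i] <- acc / 2
  }
  list(t = t_i, k = rowSums(w > 0))
}

bf_global_measures <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  d <- bf_floyd_warshall(len)
  off <- d[row(d) != col(d)]
  ge <- sum(ifelse(is.finite(off), 1 / off, 0)) / (n * (n - 1))
  fin <- off[is.finite(off)]
  cpl <- if (length(fin)) mean(fin) else NaN
  tri <- bf_triangles(w)
  den <- sum(tri$k * (tri$k - 1))
  tr <- if (den == 0) 0 else sum(2 * tri$t) / den
  list(ge = ge, cpl = cpl, transitivity = tr, d = d)
}

# shortest-path counts from source s by DP over nodes ordered by distance
bf_sigma_from <- function(len, d_s, s, tol = 1e-10) {
  n <- nrow(len)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(d_s)
  for (v in ord) {
    if (v == s || !is.finite(d_s[v])) next
    for (u in seq_len(n)) {
      if (u != v && is.finite(len[u, v]) && len[u, v] > 0 &&
          is.finite(d_s[u]) &&
          abs(d_s[u] + len[u, v] - d_s[v]) <= tol * max(1, abs(d_s[v]))) {
        sigma[v] <- sigma[v] + sigma[u]
      }
    }
  }
  sigma
}

bf_nodal_measures <- function(w, tol = 1e-10) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  d <- bf_floyd_warshall(len)
  tri <- bf_triangles(w)
  cc <- ifelse(tri$k >= 2, 2 * tri$t / (tri$k * (tri$k - 1)), 0)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  ne <- rowSums(inv) / (n - 1)
  len_edge <- ifelse(w > 0, 1 / w, Inf)
  diag(len_edge) <- Inf
  sigma <- lapply(seq_len(n), function(s) {
    bf_sigma_from(len_edge, d[s, ], s, tol)
  })
  bc <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == i || t == i || !is.finite(d[s, t])) next
        if (abs(d[s, i] + d[i, t] - d[s, t]) <= tol * max(1, d[s, t])) {
          acc <- acc + sigma[[s]][i] * sigma[[t]][i] / sigma[[s]][t]
        }
      }
    }
    bc[i] <- acc / ((n - 1) * (n - 2))
  }
  evec <- eigen(w, symmetric = TRUE)$vectors[, 1]
  if (sum(evec) < 0) evec <- -evec
  evec[abs(evec) < 1e-12] <- 0
  list(cc = cc, ne = ne, bc = bc, evc = abs(evec) / sqrt(sum(evec^2)))
}

# dwPLI by direct enumeration of ordered trial pairs
bf_dwpli <- function(im) {
  num <- 0
  den <- 0
  k <- length(im)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a != b) {
        num <- num + im[a] * im[b]
        den <- den + abs(im[a] * im[b])
      }
    }
  }
  if (den == 0) 0 else num / den
}

# connected components of an edge list by breadth-first search
bf_edge_components <- function(edges) {
  nodes <- sort(unique(as.vector(edges)))
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[as.character(start)])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[as.character(v)])) next
      comp[as.character(v)] <- cid
      nb <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
      queue <- c(queue, nb[is.na(comp[as.character(nb)])])
    }
  }
  # extent per component = number of edges with both ends in it
  extents <- vapply(seq_len(cid), function(k) {
    sum(comp[as.character(edges[, 1])] == k)
  }, integer(1))
  list(membership = comp, extents = extents)
}

# random symmetric nonnegative test matrix with zero diagonal
rand_adjacency <- function(n, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  vals <- runif(sum(ut))
  vals[runif(sum(ut)) > density] <- 0
  m[ut] <- vals
  m + t(m)
}

# small null cohort helper (theta only) for NBS tests
null_theta_cohort <- function(n_per_group = 15, seed = 1) {
  generate_cohort(cohort_spec(groups = c(LP = n_per_group,
                                         RP = n_per_group),
                              effect_delta = 0, bands = "theta",
                              seed = seed))
}

# cohort with the spec'd 20-edge implanted right-theta effect
implanted_theta_cohort <- function(delta = 0.3, n_per_group = 15,
                                   seed = 1, atlas = default_atlas()) {
  ed <- right_theta_subnetwork(atlas, n_nodes = 7, n_edges = 20)
  eff <- list(LP = list(),
              RP = lapply(seq_len(nrow(ed)), function(r) {
                coupling_spec(ed[r, 1], ed[r, 2], "theta",
                              coupling = delta, phase_lag = pi / 2)
              }))
  list(cohort = generate_cohort(
         cohort_spec(groups = c(LP = n_per_group, RP = n_per_group),
                     effect_edges = eff, bands = "theta", seed = seed)),
       edges = ed)
}
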