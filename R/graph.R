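# MST-seeded density thresholding and binary graph metrics.
#
# Connectivity matrices are binarized by first taking the spanning tree of
# maximal total wPLI weight (the minimum spanning tree of distance 1 - wPLI),
# which guarantees a connected network of n nodes at every density, and then
# adding the strongest remaining edges until the target density is reached.
# Networks along a density sweep are nested by construction. Metrics are the
# binary clustering coefficient and characteristic (hop-count) path length;
# small-worldness normalizes both against degree-preserving random references.

new_adjacency_matrix <- function(m, labels = NULL) {
  n <- nrow(m)
  k <- sum(m[upper.tri(m)])
  structure(m, class = c("adjacency_matrix", "matrix"),
            density = k / (n * (n - 1) / 2), k = as.integer(k))
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("<adjacency_matrix> %d nodes, %d edges, density %.4f\n",
              nrow(x), attr(x, "k"), attr(x, "density")))
  invisible(x)
}

# Deterministic edge ordering: weight descending, then (i, j) ascending.
# Returns the upper-triangle pair table sorted accordingly.
ordered_edges <- function(w) {
  n <- nrow(w)
  pr <- upper_pairs(n)
  wt <- w[pr]
  o <- order(-wt, pr[, 1], pr[, 2])
  cbind(pr[o, , drop = FALSE], weight = wt[o])
}

#' Maximum-weight spanning tree backbone
#'
#' Kruskal's algorithm on edges ordered by weight descending (ties broken by
#' ascending node-index pair, so the result is deterministic even for
#' degenerate weights). The tree retains the n-1 strongest edges that connect
#' all nodes — equivalently the minimum spanning tree of distance
#' `1 - weight` — and serves as the thresholding starting point so every
#' binarized network is connected.
#'
#' @param conn a symmetric weight matrix (e.g. a `connectivity_matrix`)
#' @return a binary `adjacency_matrix` with n-1 edges
#' @export
spanning_tree_backbone <- function(conn) {
  w <- unclass(conn)
  stopifnot_finite_matrix(w, "connectivity matrix")
  n <- nrow(w)
  edges <- ordered_edges(w)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  adj <- matrix(0L, n, n, dimnames = dimnames(w))
  taken <- 0L
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      adj[i, j] <- adj[j, i] <- 1L
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  new_adjacency_matrix(adj)
}

#' MST-seeded density sweep
#'
#' Builds a nested family of binary networks: the spanning-tree backbone plus
#' the strongest remaining edges until `ceiling(d * n(n-1)/2)` edges at each
#' requested density `d`. Densities below the tree density `(n-1)/(n(n-1)/2)`
#' are clamped up to it with a warning.
#'
#' @param conn a symmetric weight matrix
#' @param densities strictly increasing densities in (0, 1]
#' @return a named list of `adjacency_matrix` objects (one per requested
#'   density); each carries the requested density as attribute
#'   `requested_density`
#' @export
threshold_sweep <- function(conn, densities = default_densities()) {
  stopifnot(all(diff(densities) > 0), all(densities <= 1), all(densities > 0))
  w <- unclass(conn)
  n <- nrow(w)
  max_k <- n * (n - 1) / 2
  mst <- spanning_tree_backbone(conn)
  edges <- ordered_edges(w)
  in_tree <- mst[cbind(edges[, 1], edges[, 2])] == 1
  extra <- edges[!in_tree, , drop = FALSE]  # strongest-first additions
  out <- vector("list", length(densities))
  names(out) <- format(densities)
  for (idx in seq_along(densities)) {
    d <- densities[idx]
    k_target <- ceiling(d * max_k)
    if (k_target < n - 1) {
      warning(sprintf(
        "requested density %.4f is below the spanning-tree density %.4f; clamped",
        d, (n - 1) / max_k))
      k_target <- n - 1
    }
    adj <- matrix(as.integer(unclass(mst)), n, n, dimnames = dimnames(w))
    n_add <- k_target - (n - 1)
    if (n_add > 0) {
      add <- extra[seq_len(min(n_add, nrow(extra))), , drop = FALSE]
      adj[cbind(add[, 1], add[, 2])] <- 1L
      adj[cbind(add[, 2], add[, 1])] <- 1L
    }
    am <- new_adjacency_matrix(adj)
    attr(am, "requested_density") <- d
    out[[idx]] <- am
  }
  out
}

#' Default density grid
#'
#' Nine densities spanning the biologically plausible thresholding range used
#' for whole-scalp binary networks. Values below the 28-node spanning-tree
#' density (0.0714) are clamped by [threshold_sweep()].
#' @return numeric vector of densities
#' @export
default_densities <- function() {
  c(0.036, 0.079, 0.106, 0.132, 0.159, 0.212, 0.238, 0.265, 0.291)
}

#' Binary clustering coefficient
#'
#' Per-node `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles
#' through node i (`C_i = 0` for degree < 2), and global C the mean over all
#' nodes — a measure of network segregation. Triangle counts come from the
#' diagonal of A^3 (each triangle through i is walked twice).
#'
#' @param adj a binary `adjacency_matrix`
#' @return list with `per_node` (C_i) and `global` (mean C)
#' @export
clustering_global <- function(adj) {
  a <- (unclass(adj) != 0) * 1
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  list(per_node = unname(ci), global = mean(ci))
}

#' Characteristic path length
#'
#' Unweighted shortest-path (hop count) distances from breadth-first
#' expansion; `L_i` is the mean distance from node i to all other nodes and
#' global L the mean of the `L_i` — a measure of network integration. The
#' input must be connected (guaranteed for MST-seeded networks).
#'
#' @param adj a binary connected `adjacency_matrix`
#' @return list with `per_node` (L_i) and `global` (mean L)
#' @export
path_length_global <- function(adj) {
  d <- hop_distances(unclass(adj) != 0)
  if (any(is.infinite(d))) stop("graph is disconnected; path length undefined")
  n <- nrow(d)
  li <- rowSums(d) / (n - 1)
  list(per_node = unname(li), global = mean(li))
}

# all-pairs hop-count distances by simultaneous breadth-first expansion:
# reachable-in-<=s sets grow by one boolean matrix product per step
hop_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- a | diag(TRUE, n)
  d[a] <- 1
  s <- 1L
  while (s < n) {
    new_reach <- (reach %*% a > 0) | reach
    gained <- new_reach & !reach
    if (!any(gained)) break
    s <- s + 1L
    d[gained] <- s
    reach <- new_reach
  }
  d
}

#' Degree-preserving random reference metrics
#'
#' Generates connected Maslov-Sneppen double-edge-swap surrogates of `adj`
#' (swaps that would disconnect the graph or create multi-edges/self-loops are
#' rejected), preserving each node's degree exactly, and returns the mean
#' clustering and path length over surrogates. These are the `C_rand`/`L_rand`
#' denominators of the small-world coefficients.
#'
#' @param adj a binary connected `adjacency_matrix`
#' @param n_surrogates number of surrogate networks (default 50)
#' @param swaps_per_edge attempted swaps per edge (default 10)
#' @param seed integer seed
#' @return list with `C_rand`, `L_rand` and a `per_surrogate` data frame
#' @export
random_reference <- function(adj, n_surrogates = 50, swaps_per_edge = 10,
                             seed = 1L) {
  stopifnot(n_surrogates >= 1)
  a0 <- unclass(adj) != 0
  n <- nrow(a0)
  res <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      a <- rewire_preserving_degrees(a0, swaps_per_edge)
      am <- new_adjacency_matrix(a * 1L)
      c(clustering_global(am)$global, path_length_global(am)$global)
    }, numeric(2))
  })
  list(C_rand = mean(res[1, ]), L_rand = mean(res[2, ]),
       per_surrogate = data.frame(surrogate = seq_len(n_surrogates),
                                  C = res[1, ], L = res[2, ]))
}

# One connected degree-preserving randomization of logical adjacency a0.
rewire_preserving_degrees <- function(a0, swaps_per_edge) {
  n <- nrow(a0)
  el <- which(upper.tri(a0) & a0, arr.ind = TRUE)
  k <- nrow(el)
  if (k < 2) {
    warning("graph too small for degree-preserving swaps; returning original")
    return(a0)
  }
  a <- a0
  attempts <- ceiling(swaps_per_edge * k)
  accepted <- 0L
  for (it in seq_len(attempts)) {
    idx <- sample.int(k, 2)
    e1 <- el[idx[1], ]; e2 <- el[idx[2], ]
    u <- e1[1]; v <- e1[2]; x <- e2[1]; y <- e2[2]
    # randomly orient the second edge to explore both swap variants
    if (stats::runif(1) < 0.5) { tmp <- x; x <- y; y <- tmp }
    # proposed: (u,y) and (x,v) replace (u,v) and (x,y)
    if (u == y || x == v) next
    if (a[u, y] || a[x, v]) next
    a[u, v] <- a[v, u] <- FALSE
    a[x, y] <- a[y, x] <- FALSE
    a[u, y] <- a[y, u] <- TRUE
    a[x, v] <- a[v, x] <- TRUE
    if (is_connected_adj(a)) {
      el[idx[1], ] <- sort(c(u, y))
      el[idx[2], ] <- sort(c(x, v))
      accepted <- accepted + 1L
    } else { # revert
      a[u, y] <- a[y, u] <- FALSE
      a[x, v] <- a[v, x] <- FALSE
      a[u, v] <- a[v, u] <- TRUE
      a[x, y] <- a[y, x] <- TRUE
    }
  }
  if (accepted == 0L) {
    warning("no valid degree-preserving swap found; returning original graph")
  }
  a
}

# BFS connectivity check on a logical adjacency matrix.
is_connected_adj <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(rowSums(a[, frontier, drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Small-world coefficients
#'
#' `gamma = C / C_rand`, `lambda = L / L_rand`, `sigma = gamma / lambda`.
#' A small-world network has clustering well above its random reference
#' (gamma >> 1) at comparable path length (lambda ~ 1), hence sigma > 1.
#'
#' @param C,C_rand,L,L_rand positive scalars
#' @return list with `gamma`, `lambda`, `sigma`
#' @export
small_world <- function(C, C_rand, L, L_rand) {
  vals <- c(C = C, C_rand = C_rand, L = L, L_rand = L_rand)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("small_world requires positive finite C, C_rand, L, L_rand")
  }
  gamma <- C / C_rand
  lambda <- L / L_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Graph metrics along a density sweep
#'
#' Runs [threshold_sweep()] on a connectivity matrix and computes C and L at
#' each density, optionally normalized by degree-preserving random references
#' (`n_surrogates > 0`) to obtain gamma, lambda and sigma.
#'
#' @param conn a `connectivity_matrix`
#' @param densities density grid (default [default_densities()])
#' @param n_surrogates surrogates per density for the random reference; 0
#'   skips normalization (gamma/lambda/sigma are `NA`)
#' @param swaps_per_edge passed to [random_reference()]
#' @param seed integer seed for the null model
#' @return a data frame with one row per density: `density` (requested),
#'   `density_actual`, `k`, `C`, `L`, `C_rand`, `L_rand`, `gamma`, `lambda`,
#'   `sigma`, plus band/condition/subject metadata carried from `conn`
#' @export
network_metrics <- function(conn, densities = default_densities(),
                            n_surrogates = 50, swaps_per_edge = 10, seed = 1L) {
  adjs <- threshold_sweep(conn, densities)
  rows <- lapply(seq_along(adjs), function(i) {
    adj <- adjs[[i]]
    C <- clustering_global(adj)$global
    L <- path_length_global(adj)$global
    if (n_surrogates > 0) {
      rr <- random_reference(adj, n_surrogates, swaps_per_edge,
                             seed = derive_seed(seed, "null", i))
      sw <- if (C > 0 && rr$C_rand > 0 && L > 0 && rr$L_rand > 0) {
        small_world(C, rr$C_rand, L, rr$L_rand)
      } else { # e.g. triangle-free sparse networks: gamma undefined
        list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
      }
      data.frame(density = attr(adj, "requested_density"),
                 density_actual = attr(adj, "density"), k = attr(adj, "k"),
                 C = C, L = L, C_rand = rr$C_rand, L_rand = rr$L_rand,
                 gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
    } else {
      data.frame(density = attr(adj, "requested_density"),
                 density_actual = attr(adj, "density"), k = attr(adj, "k"),
                 C = C, L = L, C_rand = NA_real_, L_rand = NA_real_,
                 gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  out$band <- attr(conn, "band") %||% NA_character_
  out$condition <- attr(conn, "condition") %||% NA_character_
  out$subject_id <- attr(conn, "subject_id") %||% NA_character_
  out
}
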