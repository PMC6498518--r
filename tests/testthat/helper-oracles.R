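# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (enumeration, closed forms) and never call the code paths
# they check.

# clustering by exhaustive triple enumeration
oracle_clustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (u in seq_along(nb)) for (v in seq_len(u - 1)) {
      if (a[nb[u], nb[v]] != 0) t_i <- t_i + 1
    }
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  list(per_node = ci, global = mean(ci))
}

# all-pairs hop distances by Floyd-Warshall
oracle_floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a != 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# brute-force BH step-up: search all cutoff ranks explicitly
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k_max <- 0
  for (k in seq_len(m)) {
    if (p[o[k]] <= k * q / m) k_max <- k
  }
  rej <- logical(m)
  if (k_max > 0) rej[o[seq_len(k_max)]] <- TRUE
  rej
}

# adjacency from an edge list on n nodes
adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1L
  }
  a
}

# connected Erdos-Renyi-like graph (resampled until connected)
random_connected_graph <- function(n, p) {
  repeat {
    a <- matrix(0L, n, n)
    up <- upper.tri(a)
    a[up] <- as.integer(stats::runif(sum(up)) < p)
    a <- a + t(a)
    if (all(is.finite(oracle_floyd_warshall(a)))) return(a)
  }
}

# ring lattice: n nodes, each connected to the k/2 nearest neighbors per side
ring_lattice <- function(n, k) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  a
}

# Watts-Strogatz rewiring of a ring lattice
watts_strogatz <- function(n, k, p) {
  a <- ring_lattice(n, k)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    if (stats::runif(1) < p) {
      candidates <- which(a[i, ] == 0 & seq_len(n) != i)
      if (length(candidates) == 0) next
      new_j <- candidates[sample.int(length(candidates), 1)]
      a[i, j] <- a[j, i] <- 0L
      a[i, new_j] <- a[new_j, i] <- 1L
    }
  }
  a
}

# minimal cross-spectral-observations object holding one channel pair with
# prescribed imaginary parts (real parts zero), for direct estimator fixtures
obs_fixture <- function(imag_values) {
  structure(
    list(band = band_spec("fixture", 1, 2, "hanning"),
         fs = 64, channel_labels = c("A", "B"),
         subject_id = "fx", condition = "EC",
         pairs = cbind(1L, 2L), freqs = 1.5,
         n_epochs = length(imag_values), n_tapers = 1L, n_bins = 1L,
         n_obs = length(imag_values), store = "sufficient",
         suff = list(sum_sign = matrix(sum(sign(imag_values))),
                     sum_imag = matrix(sum(imag_values)),
                     sum_abs = matrix(sum(abs(imag_values))),
                     n_per_bin = length(imag_values)),
         obs = NULL),
    class = "cross_spectral_obs")
}

# small helper: symmetric weight matrix from upper-triangle values
weight_matrix <- function(n, values, labels = NULL) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- values
  m + t(m)
}

# one recovery replicate: known beta-band clustering deficit, returns whether
# a successive-threshold run for C survives in beta and in theta
recovery_replicate <- function(seed) {
  cc <- cohort_config(fs = 128, duration_s = 60, conditions = "EC",
                      seed = seed)
  cohort <- generate_cohort(cc)
  rows <- list()
  for (s in cohort$subjects) {
    ep <- segment_epochs(materialize_recording(s$recordings[["EC"]]))
    for (bn in c("beta", "theta")) {
      w <- wpli(cross_spectra(ep, band_presets()[[bn]]))
      nm <- suppressWarnings(network_metrics(w, n_surrogates = 0))
      nm$group <- s$group
      rows[[length(rows) + 1]] <- nm
    }
  }
  metrics <- do.call(rbind, rows)
  sw <- sweep_group_tests(metrics, metrics_to_test = "C",
                          groups = c("AP", "RP"))
  list(beta_run = any(sw$cells$in_run[sw$cells$band == "beta"]),
       theta_run = any(sw$cells$in_run[sw$cells$band == "theta"]))
}
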