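# Group inference: Welch tests over the density sweep with the
# successive-threshold significance rule, effect sizes, edge-wise permutation
# tests on (optionally z-standardized) connectivity matrices, and
# Benjamini-Hochberg FDR control.

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value. `welch_t()` consumes raw samples (delegating to
#' [stats::t.test()]); `welch_t_summary()` evaluates the closed form from
#' group means, SDs and sizes, which allows recomputation from published
#' summary tables.
#'
#' @param x,y numeric samples (>= 2 values each, nonzero variance)
#' @return list with `t`, `df`, `p`, `mean_diff` (x minus y)
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("degenerate samples: zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(x) - mean(y))
}

#' @rdname welch_t
#' @param m1,s1,n1 mean, SD and size of the first group
#' @param m2,s2,n2 mean, SD and size of the second group
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_diff = m1 - m2)
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' @param x,y numeric samples
#' @return d = (mean(x) - mean(y)) / s_pooled, with (n-1)-weighted pooled SD
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled SD")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Welch-test sweep with the successive-threshold significance rule
#'
#' Runs a Welch test per (metric, band, condition, density) cell comparing the
#' two groups. Because networks at neighboring densities are nested (hence
#' dependent), conventional multiplicity correction across the sweep is not
#' appropriate; instead, a cell is retained only if significant at `alpha`
#' AND an adjacent density in the same metric/band/condition is also
#' significant ("two successive thresholds"). For every surviving run the
#' representative density is the retained cell with the largest |Cohen's d|.
#' A secondary marginal mask at `alpha_marginal` is reported as well.
#'
#' @param metrics long-format data frame with columns `subject_id`, `group`,
#'   `band`, `condition`, `density`, and one column per metric in `metrics_to_test`
#' @param metrics_to_test metric column names to test (default
#'   `c("C", "L", "sigma")`)
#' @param groups length-2 character vector selecting and ordering the groups
#'   (difference is group1 - group2); default: alphabetical unique groups
#' @param alpha primary significance level (default 0.05)
#' @param alpha_marginal secondary level for the marginal mask (default 0.10)
#' @return list of class `sweep_result` with `cells` (one row per tested cell:
#'   t, df, p, d, significant, in_run, marginal_run), and `representative`
#'   (one row per surviving metric/band/condition run)
#' @export
sweep_group_tests <- function(metrics, metrics_to_test = c("C", "L", "sigma"),
                              groups = NULL, alpha = 0.05,
                              alpha_marginal = 0.10) {
  stopifnot(all(c("subject_id", "group", "band", "condition", "density")
                %in% names(metrics)))
  if (is.null(groups)) groups <- sort(unique(metrics$group))
  stopifnot(length(groups) == 2)
  metrics <- metrics[metrics$group %in% groups, ]
  # density grids must agree across groups within each band/condition
  grids <- tapply(metrics$density,
                  list(metrics$group, metrics$band, metrics$condition),
                  function(d) paste(sort(unique(d)), collapse = ","))
  for (b in dimnames(grids)[[2]]) for (cc in dimnames(grids)[[3]]) {
    g <- grids[, b, cc]
    g <- g[!is.na(g)]
    if (length(unique(g)) > 1) {
      stop("density grids differ between groups for band ", b,
           ", condition ", cc)
    }
  }
  cells <- list()
  for (m in metrics_to_test) {
    if (!m %in% names(metrics)) stop("metric column missing: ", m)
    for (b in unique(metrics$band)) {
      for (cc in unique(metrics$condition)) {
        sub <- metrics[metrics$band == b & metrics$condition == cc, ]
        if (nrow(sub) == 0) next
        dens <- sort(unique(sub$density))
        for (d in dens) {
          x <- sub[[m]][sub$density == d & sub$group == groups[1]]
          y <- sub[[m]][sub$density == d & sub$group == groups[2]]
          if (length(x) < 2 || length(y) < 2) {
            stop("need >= 2 subjects per group in every cell")
          }
          degenerate <- anyNA(x) || anyNA(y) ||
            (stats::sd(x) == 0 && stats::sd(y) == 0)
          cells[[length(cells) + 1]] <- if (degenerate) {
            # degenerate cell (e.g. clustering on the triangle-free MST
            # backbone is 0 for every subject, or sigma undefined because a
            # network has no triangles): not testable, never significant
            data.frame(metric = m, band = b, condition = cc, density = d,
                       t = NA_real_, df = NA_real_, p = NA_real_, d_effect = 0,
                       direction = 0)
          } else {
            wt <- welch_t(x, y)
            data.frame(metric = m, band = b, condition = cc, density = d,
                       t = wt$t, df = wt$df, p = wt$p, d_effect = cohens_d(x, y),
                       direction = sign(wt$mean_diff))
          }
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  cells$significant <- !is.na(cells$p) & cells$p < alpha
  cells$in_run <- FALSE
  cells$marginal <- !is.na(cells$p) & cells$p < alpha_marginal
  cells$marginal_run <- FALSE
  key <- interaction(cells$metric, cells$band, cells$condition, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    idx <- idx[order(cells$density[idx])]
    for (col in c("significant", "marginal")) {
      sig <- cells[[col]][idx]
      run <- sig & (c(FALSE, sig[-length(sig)]) | c(sig[-1], FALSE))
      cells[[if (col == "significant") "in_run" else "marginal_run"]][idx] <- run
    }
  }
  rep_rows <- list()
  for (k in levels(key)) {
    idx <- which(key == k & cells$in_run)
    if (length(idx) == 0) next
    best <- idx[which.max(abs(cells$d_effect[idx]))]
    rep_rows[[length(rep_rows) + 1]] <- cells[best, c("metric", "band",
      "condition", "density", "t", "df", "p", "d_effect", "direction")]
  }
  representative <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    cells[0, c("metric", "band", "condition", "density", "t", "df", "p",
               "d_effect", "direction")]
  structure(list(cells = cells, representative = representative,
                 groups = groups, alpha = alpha,
                 alpha_marginal = alpha_marginal),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells tested (%s vs %s), alpha = %g\n",
              nrow(x$cells), x$groups[1], x$groups[2], x$alpha))
  cat(sprintf("  %d cells in surviving successive-threshold runs; %d representative thresholds\n",
              sum(x$cells$in_run), nrow(x$representative)))
  if (nrow(x$representative)) {
    print(x$representative, row.names = FALSE)
  }
  invisible(x)
}

#' Z-standardize a connectivity matrix
#'
#' Standardizes the n(n-1)/2 unique off-diagonal entries to mean 0, SD 1
#' within the matrix (per subject), preserving symmetry and the zero
#' diagonal. Used before edge-wise permutation tests so that group contrasts
#' reflect the relative importance of connections within each subject's
#' network rather than global wPLI level differences.
#'
#' @param conn a symmetric connectivity matrix
#' @return the standardized matrix (same attributes)
#' @export
zscore_matrix <- function(conn) {
  m <- unclass(conn)
  v <- m[upper.tri(m)]
  if (length(unique(v)) < 2) stop("constant matrix cannot be standardized")
  z <- (v - mean(v)) / stats::sd(v)
  out <- sym_from_upper(z, nrow(m), rownames(m))
  attributes(out) <- c(attributes(out),
                       attributes(conn)[setdiff(names(attributes(conn)),
                                                c("dim", "dimnames"))])
  out
}

#' Edge-wise permutation test between groups
#'
#' For every edge (unique channel pair) the observed group mean difference is
#' compared with its distribution under `n_perm` random relabelings of
#' subjects (the same shuffle applied to all edges, preserving the
#' between-edge dependence). Two-sided p values use the add-one estimator
#' `p = (#{|perm| >= |obs|} + 1) / (n_perm + 1)`, so the smallest attainable
#' p is `1/(n_perm + 1)`. Benjamini-Hochberg FDR is applied across edges at
#' level `q`.
#'
#' @param matrices_g1,matrices_g2 lists of symmetric connectivity matrices
#'   (>= 2 subjects per group, common dimension)
#' @param n_perm number of permutations (default 10000)
#' @param q FDR level (default 0.05)
#' @param seed integer seed
#' @param standardize if `TRUE`, apply [zscore_matrix()] to every subject
#'   matrix first
#' @return list of class `permutation_edge_result`: `diff` (observed
#'   group1 - group2 mean difference matrix), `d` (Cohen's d matrix), `p`
#'   (two-sided permutation p matrix), `fdr_mask` (logical matrix),
#'   `n_perm`, `q`, `standardized`, `seed`
#' @export
permutation_edge_test <- function(matrices_g1, matrices_g2, n_perm = 10000,
                                  q = 0.05, seed = 1L, standardize = FALSE) {
  if (length(matrices_g1) < 2 || length(matrices_g2) < 2) {
    stop("each group needs >= 2 subjects")
  }
  if (standardize) {
    matrices_g1 <- lapply(matrices_g1, zscore_matrix)
    matrices_g2 <- lapply(matrices_g2, zscore_matrix)
  }
  n <- nrow(matrices_g1[[1]])
  labels <- rownames(matrices_g1[[1]])
  vecs <- function(ml) t(vapply(ml, function(m) {
    m <- unclass(m)
    if (nrow(m) != n) stop("matrices have mismatched dimensions")
    m[upper.tri(m)]
  }, numeric(n * (n - 1) / 2)))
  x1 <- vecs(matrices_g1)
  x2 <- vecs(matrices_g2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  xall <- rbind(x1, x2)
  obs <- colMeans(x1) - colMeans(x2)
  tot <- colSums(xall)
  count <- rep(0L, ncol(xall))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      sel <- sample.int(n1 + n2, n1)
      s1 <- colSums(xall[sel, , drop = FALSE])
      pd <- s1 / n1 - (tot - s1) / n2
      count <- count + (abs(pd) >= abs(obs))
    }
  })
  pvals <- (count + 1) / (n_perm + 1)
  dvec <- vapply(seq_len(ncol(xall)), function(e) cohens_d(x1[, e], x2[, e]),
                 numeric(1))
  mask <- bh_fdr(pvals, q)
  structure(list(diff = sym_from_upper(obs, n, labels),
                 d = sym_from_upper(dvec, n, labels),
                 p = sym_from_upper(pvals, n, labels),
                 fdr_mask = sym_from_upper(as.numeric(mask), n, labels) > 0,
                 n_perm = n_perm, q = q, standardized = standardize,
                 seed = seed),
            class = "permutation_edge_result")
}

#' @export
print.permutation_edge_result <- function(x, ...) {
  cat(sprintf("<permutation_edge_result> %d edges, %d permutations%s, FDR q = %g: %d edges pass\n",
              sum(upper.tri(x$p)), x$n_perm,
              if (x$standardized) " (z-standardized matrices)" else "",
              x$q, sum(x$fdr_mask[upper.tri(x$fdr_mask)])))
  invisible(x)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `q`: reject the hypotheses with the `k`
#' smallest p values, where `k` is the largest rank with
#' `p_(k) <= k q / m`.
#'
#' @param pvalues numeric vector of p values in `[0, 1]`
#' @param q FDR level
#' @return logical rejection mask aligned with `pvalues`
#' @export
bh_fdr <- function(pvalues, q) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= q
}
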