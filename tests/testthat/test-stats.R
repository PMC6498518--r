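test_that("Welch test matches the closed form and handles degenerate input", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(4)
  for (i in 1:10) {
    x <- stats::rnorm(sample(5:40, 1)); y <- stats::rnorm(sample(5:40, 1), 0.3)
    wt <- welch_t(x, y)
    v1 <- stats::var(x) / length(x); v2 <- stats::var(y) / length(y)
    t_o <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df_o <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    expect_equal(wt$t, t_o, tolerance = 1e-10)
    expect_equal(wt$df, df_o, tolerance = 1e-10)
    expect_equal(wt$p, 2 * stats::pt(-abs(t_o), df_o), tolerance = 1e-10)
    ws <- welch_t_summary(mean(x), stats::sd(x), length(x),
                          mean(y), stats::sd(y), length(y))
    expect_equal(ws$t, wt$t, tolerance = 1e-10)
    expect_equal(ws$df, wt$df, tolerance = 1e-10)
  }
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("Cohen's d uses the (n-1)-weighted pooled SD", {
  expect_equal(cohens_d(c(0, 2), c(0, 2)), 0)
  x <- c(0.5, 1.5, 0.8, 1.2); y <- x - 1
  sp <- sqrt((3 * stats::var(x) + 3 * stats::var(y)) / 6)
  expect_equal(cohens_d(x, y), 1 / sp)
  set.seed(5)
  a <- stats::rnorm(20); b <- stats::rnorm(25, 0.4)
  sp2 <- ((19 * stats::var(a) + 24 * stats::var(b)) / 43)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sqrt(sp2),
               tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

make_metrics <- function(effect_at = numeric(0), n1 = 15, n2 = 15,
                         densities = seq(0.1, 0.5, by = 0.05), seed = 1,
                         delta = 1) {
  set.seed(seed)
  rows <- list()
  for (g in c("G1", "G2")) {
    for (s in seq_len(if (g == "G1") n1 else n2)) {
      for (b in c("beta", "theta")) for (d in densities) {
        val <- stats::rnorm(1)
        if (g == "G2" && b == "beta" && d %in% effect_at) val <- val - delta
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = paste0(g, s), group = g, band = b, condition = "EC",
          density = d, C = val)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("successive-threshold rule keeps runs and drops isolated hits", {
  dens <- seq(0.1, 0.5, by = 0.05)
  # adjacent injected effects survive; representative is the max-|d| cell
  m <- make_metrics(effect_at = dens[4:6], seed = 2, delta = 1.5)
  sw <- sweep_group_tests(m, metrics_to_test = "C")
  beta_run <- sw$cells[sw$cells$band == "beta" & sw$cells$in_run, ]
  expect_true(all(dens[4:6] %in% beta_run$density))
  expect_false(any(sw$cells$in_run[sw$cells$band == "theta"]))
  rep_row <- sw$representative[sw$representative$band == "beta", ]
  expect_equal(nrow(rep_row), 1)
  in_run_cells <- sw$cells[sw$cells$band == "beta" & sw$cells$in_run, ]
  expect_equal(rep_row$density,
               in_run_cells$density[which.max(abs(in_run_cells$d_effect))])
  # the same strong effect at one isolated density does not survive
  m1 <- make_metrics(effect_at = dens[4], seed = 2, delta = 3)
  sw1 <- sweep_group_tests(m1, metrics_to_test = "C")
  iso <- sw1$cells[sw1$cells$band == "beta" & sw1$cells$density == dens[4], ]
  expect_true(iso$significant)
  expect_false(iso$in_run)
  # pure null: with no significant cells the mask is empty
  m0 <- make_metrics(seed = 3, delta = 0)
  sw0 <- sweep_group_tests(m0, metrics_to_test = "C", alpha = 1e-6)
  expect_false(any(sw0$cells$in_run))
  expect_equal(nrow(sw0$representative), 0)
})

test_that("sweep rejects mismatched density grids across groups", {
  m <- make_metrics(seed = 4)
  m <- m[!(m$group == "G2" & m$density == 0.1), ]
  expect_error(sweep_group_tests(m, metrics_to_test = "C"), "grids differ")
})

test_that("matrix z-standardization preserves structure", {
  set.seed(6)
  w <- weight_matrix(6, stats::runif(15), labels = paste0("c", 1:6))
  z <- zscore_matrix(w)
  v <- z[upper.tri(z)]
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(stats::sd(v), 1, tolerance = 1e-12)
  expect_equal(unclass(z), t(unclass(z)))
  expect_true(all(diag(z) == 0))
  # affine invariance
  expect_equal(unclass(zscore_matrix(2.5 * w + 3)), unclass(z),
               tolerance = 1e-12)
  # 3x3 hand fixture: values {1, 2, 3} -> {-1, 0, 1}
  w3 <- weight_matrix(3, c(1, 2, 3))
  z3 <- zscore_matrix(w3)
  expect_equal(sort(z3[upper.tri(z3)]), c(-1, 0, 1))
  expect_error(zscore_matrix(weight_matrix(3, c(2, 2, 2))), "constant")
})

test_that("permutation edge test is seeded, bounded and detects a shifted edge", {
  set.seed(8)
  n <- 6; ne <- n * (n - 1) / 2
  mats <- function(nsub, shift_edge = NA, shift = 0) {
    lapply(seq_len(nsub), function(i) {
      v <- stats::rnorm(ne)
      if (!is.na(shift_edge)) v[shift_edge] <- v[shift_edge] + shift
      weight_matrix(n, v, labels = paste0("c", 1:n))
    })
  }
  g1 <- mats(30, shift_edge = 1, shift = 2)  # edge 1 shifted by 2 pooled SDs
  g2 <- mats(30)
  pe <- permutation_edge_test(g1, g2, n_perm = 500, seed = 10)
  expect_true(all(pe$p[upper.tri(pe$p)] >= 1 / 501))
  expect_equal(unclass(pe$p), t(unclass(pe$p)))
  expect_true(pe$fdr_mask[1, 2])
  expect_equal(pe$p[1, 2], 1 / 501)
  expect_gt(pe$d[1, 2], 1)
  # same seed reproduces everything; different seed moves the p values
  pe2 <- permutation_edge_test(g1, g2, n_perm = 500, seed = 10)
  expect_identical(pe$p, pe2$p)
  # observed difference equals the group mean contrast
  m1 <- Reduce(`+`, lapply(g1, unclass)) / 30
  m2 <- Reduce(`+`, lapply(g2, unclass)) / 30
  expect_equal(unclass(pe$diff), m1 - m2, tolerance = 1e-12)
  # standardized variant consumes z-scored matrices
  pz <- permutation_edge_test(g1, g2, n_perm = 200, seed = 3,
                              standardize = TRUE)
  expect_true(pz$standardized)
  expect_error(permutation_edge_test(g1[1], g2, n_perm = 10), ">= 2")
})

test_that("BH mask equals the brute-force step-up search", {
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))
  expect_true(bh_fdr(0.01, 0.05))
  p_fix <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
             0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569,
             0.594, 0.696)
  expect_identical(bh_fdr(p_fix, 0.05), oracle_bh(p_fix, 0.05))
  set.seed(11)
  for (i in 1:20) {
    p <- stats::runif(sample(5:60, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(bh_fdr(p, q), oracle_bh(p, q))
  }
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("OLS regression agrees with the normal-equations oracle", {
  set.seed(12)
  n <- 40
  X <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  y <- 1 + 2 * X$x1 - 0.5 * X$x2 + stats::rnorm(n, 0, 0.7)
  fit <- ols_regression(y, X)
  Xm <- cbind(1, as.matrix(X))
  beta_o <- solve(crossprod(Xm), crossprod(Xm, y))
  expect_equal(fit$coefficients$estimate, as.numeric(beta_o),
               tolerance = 1e-10)
  rss <- sum((y - Xm %*% beta_o)^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(fit$r2, 1 - rss / tss, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1 - (1 - fit$r2) * (n - 1) / (n - 3),
               tolerance = 1e-10)
  # Gaussian AIC convention: n log(2 pi RSS/n) + n + 2 (p + 2)
  expect_equal(fit$aic, n * log(2 * pi * rss / n) + n + 2 * (2 + 2),
               tolerance = 1e-10)
  # exact linear response (suppress lm's perfect-fit note)
  fit1 <- suppressWarnings(ols_regression(2 * X$x1 + 1, X["x1"]))
  expect_equal(fit1$r2, 1, tolerance = 1e-12)
  expect_error(ols_regression(y, cbind(X, x3 = X$x1 * 2)), "rank")
  expect_error(ols_regression(y[1:3], X[1:3, ]), "n >")
})

test_that("model comparison ranks by AIC with stable ties", {
  set.seed(13)
  n <- 50
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)  # x2 is pure noise
  y <- x1 + stats::rnorm(n, 0, 0.5)
  fits <- list(signal = ols_regression(y, data.frame(x1 = x1)),
               with_noise = ols_regression(y, data.frame(x1 = x1, x2 = x2)),
               noise_only = ols_regression(y, data.frame(x2 = x2)))
  tab <- compare_models(fits)
  expect_identical(tab$model[1], "signal")
  expect_identical(tab$model[3], "noise_only")
  expect_true(all(diff(tab$aic) >= 0))
  # manual AIC recomputation confirms the ordering decision
  aic_m <- vapply(fits, function(f) stats::AIC(f$fit), numeric(1))
  expect_equal(sort(aic_m), tab$aic, tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated model: tie broken stably (original order)
  tab2 <- compare_models(list(a = fits$signal, b = fits$signal))
  expect_identical(tab2$model, c("a", "b"))
  expect_error(compare_models(list(a = fits$signal,
                                   b = ols_regression(y[1:30],
                                                      data.frame(x = x1[1:30])))),
               "sample sizes")
})

test_that("mediation bootstrap identifies full mediation and respects the seed", {
  set.seed(14)
  n <- 60
  x <- stats::rnorm(n)
  m_full <- x + stats::rnorm(n, 0, 0.1)  # near-full mediation (exact m = x is collinear)
  y_full <- m_full + stats::rnorm(n, 0, 0.3)
  med <- mediation(x, m_full, y_full, n_boot = 500, seed = 21)
  expect_true(med$significant)
  expect_equal(med$indirect, med$total, tolerance = 0.15)
  med2 <- mediation(x, m_full, y_full, n_boot = 500, seed = 21)
  expect_identical(med$ci, med2$ci)
  # independent mediator: no indirect effect detectable
  m_ind <- stats::rnorm(n)
  y_ind <- x + stats::rnorm(n, 0, 0.5)
  med0 <- mediation(x, m_ind, y_ind, n_boot = 500, seed = 22)
  expect_false(med0$significant)
  expect_error(mediation(x, rep(1, n), y_ind), "degenerate")
})

test_that("correlation tables are symmetric with exact limiting cases", {
  set.seed(15)
  df <- data.frame(a = stats::rnorm(30))
  df$b <- -2 * df$a + 5          # exactly anti-linear
  df$c <- stats::rnorm(30)
  ct <- pearson_corr_table(df)
  expect_equal(diag(ct$r), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(ct$r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(ct$r, t(ct$r))
  # direct covariance-formula oracle
  r_o <- sum((df$a - mean(df$a)) * (df$c - mean(df$c))) /
    sqrt(sum((df$a - mean(df$a))^2) * sum((df$c - mean(df$c))^2))
  expect_equal(ct$r["a", "c"], r_o, tolerance = 1e-12)
  expect_error(pearson_corr_table(data.frame(a = 1:5, b = rep(2, 5))),
               "constant")
})
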