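# Regression layer: multiple regression with R^2 / AIC model comparison,
# bivariate Pearson correlation tables, and percentile-bootstrap mediation
# (product of coefficients).

#' Ordinary least squares regression with fit summaries
#'
#' Fits `y ~ predictors` (intercept included) via [stats::lm()] and collects
#' the quantities used for model comparison: coefficient table, R^2, adjusted
#' R^2, overall F with degrees of freedom, and AIC. AIC uses the Gaussian
#' log-likelihood convention of [stats::AIC()] (equivalent to
#' `n log(RSS/n) + 2(p+1)` up to an additive constant depending only on n,
#' so model rankings on a common response are unaffected by the convention).
#'
#' @param y numeric response
#' @param predictors data frame or numeric matrix of predictors (full rank)
#' @return list of class `regression_result`: `coefficients` (estimate, se,
#'   t, p per term), `r2`, `adj_r2`, `f`, `df1`, `df2`, `p`, `aic`, `n`,
#'   `fit` (the lm object)
#' @export
ols_regression <- function(y, predictors) {
  predictors <- as.data.frame(predictors)
  stopifnot(length(y) == nrow(predictors))
  if (length(y) <= ncol(predictors) + 1) {
    stop("need n > number of predictors + 1")
  }
  dat <- cbind(data.frame(.y = y), predictors)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient predictor matrix")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  if (is.null(fstat)) { # intercept-only model
    fstat <- c(value = NA_real_, numdf = 0, dendf = length(y) - 1)
    overall_p <- NA_real_
  } else {
    overall_p <- stats::pf(fstat[["value"]], fstat[["numdf"]],
                           fstat[["dendf"]], lower.tail = FALSE)
  }
  co <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], t = co[, 3], p = co[, 4],
                              row.names = NULL),
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    f = unname(fstat[["value"]]), df1 = unname(fstat[["numdf"]]),
    df2 = unname(fstat[["dendf"]]), p = unname(overall_p),
    aic = stats::AIC(fit), n = length(y), fit = fit),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d: R2 = %.3f (adj %.3f), F(%g, %g) = %.3f, p = %.3g, AIC = %.2f\n",
              x$n, x$r2, x$adj_r2, x$df1, x$df2, x$f, x$p, x$aic))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rank regression models by AIC
#'
#' All fits must share the same response values and sample size. Sorted by
#' AIC ascending (smaller is better); ties broken by adjusted R^2 descending,
#' then by original order (stable).
#'
#' @param fits named list of `regression_result` objects
#' @return data frame with one row per model: `model`, `r2`, `adj_r2`, `f`,
#'   `p`, `aic`, `rank`
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) > 1) stop("models fitted on different sample sizes")
  ys <- lapply(fits, function(f) unname(stats::model.frame(f$fit)[[1]]))
  if (length(unique(vapply(ys, function(v) paste(signif(v, 12), collapse = ","),
                           character(1)))) > 1) {
    stop("models must share the same response")
  }
  tab <- data.frame(
    model = names(fits) %||% paste0("model", seq_along(fits)),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
    f = vapply(fits, `[[`, numeric(1), "f"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    row.names = NULL)
  o <- order(tab$aic, -tab$adj_r2)
  tab <- tab[o, ]
  tab$rank <- seq_len(nrow(tab))
  tab
}

#' Percentile-bootstrap mediation (product of coefficients)
#'
#' Simple mediation x -> m -> y: `a` is the slope of `m ~ x`, `b` the slope
#' of `m` in `y ~ x + m`; the indirect effect is `a * b`. The confidence
#' interval is a percentile bootstrap over case resampling. The effect is
#' called significant when the CI excludes zero.
#'
#' @param x predictor, `m` mediator, `y` outcome (equal-length, n >= 10)
#' @param m mediator
#' @param y outcome
#' @param n_boot bootstrap replicates (default 5000)
#' @param seed integer seed
#' @param conf confidence level (default 0.95)
#' @return list of class `mediation_result`: `indirect`, `a`, `b`,
#'   `direct` (x coefficient in `y ~ x + m`), `total` (slope of `y ~ x`),
#'   `ci`, `significant`, `n_boot`, `seed`
#' @export
mediation <- function(x, m, y, n_boot = 5000, seed = 1L, conf = 0.95) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, n >= 10)
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance in x, m or y")
  }
  ab <- function(xi, mi, yi) {
    a <- stats::coef(stats::lm(mi ~ xi))[2]
    fit2 <- stats::coef(stats::lm(yi ~ xi + mi))
    c(a = unname(a), b = unname(fit2[3]), direct = unname(fit2[2]))
  }
  est <- ab(x, m, y)
  total <- unname(stats::coef(stats::lm(y ~ x))[2])
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      e <- ab(x[idx], m[idx], y[idx])
      e[["a"]] * e[["b"]]
    }, numeric(1))
  })
  alpha2 <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha2, 1 - alpha2), na.rm = TRUE))
  structure(list(indirect = est[["a"]] * est[["b"]], a = est[["a"]],
                 b = est[["b"]], direct = est[["direct"]], total = total,
                 ci = ci, significant = ci[1] > 0 || ci[2] < 0,
                 n_boot = n_boot, seed = seed, conf = conf),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> indirect = %.4g (a = %.4g, b = %.4g), %.0f%% CI [%.4g, %.4g] -> %s\n",
              x$indirect, x$a, x$b, 100 * x$conf, x$ci[1], x$ci[2],
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Pairwise Pearson correlation table
#'
#' Pearson r and two-sided p (t approximation) for every pair of numeric
#' columns, complete cases per pair.
#'
#' @param scores data frame of numeric variables (>= 3 complete cases per pair)
#' @return list with matrices `r` (unit diagonal) and `p`
#' @export
pearson_corr_table <- function(scores) {
  scores <- as.data.frame(scores)
  num <- vapply(scores, is.numeric, logical(1))
  scores <- scores[num]
  k <- ncol(scores)
  stopifnot(k >= 2)
  r <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(names(scores), names(scores))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    cc <- stats::complete.cases(scores[[i]], scores[[j]])
    if (sum(cc) < 3) stop("fewer than 3 complete cases for pair ",
                          names(scores)[i], " x ", names(scores)[j])
    if (stats::sd(scores[[i]][cc]) == 0 || stats::sd(scores[[j]][cc]) == 0) {
      stop("constant column: ", names(scores)[i], " or ", names(scores)[j])
    }
    ct <- stats::cor.test(scores[[i]][cc], scores[[j]][cc])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}
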