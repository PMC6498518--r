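# End-to-end orchestration: simulate (optional) -> epoch -> cross-spectra ->
# wPLI -> MST-seeded density sweep -> graph metrics -> behavioral scores ->
# Welch sweep with the successive-threshold rule -> representative thresholds
# -> edge-wise permutation tests -> regressions / correlations / mediation.
# Every artifact is written as TSV with a JSON provenance block carrying the
# full configuration and seed, so two runs with the same config are
# byte-identical.

#' Pipeline configuration
#'
#' Validates and freezes every tunable of the analysis before any computation
#' runs. The single `seed` deterministically derives all per-stage and
#' per-subject sub-seeds.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort to
#'   generate (its own seed is overridden by a sub-seed of `seed`)
#' @param bands character vector of band preset names (see [band_presets()])
#' @param densities strictly increasing density grid
#' @param estimator `"wpli"` or `"pli"`
#' @param pooling observation pooling for wPLI (`"pooled"` or `"per_bin"`)
#' @param epoch_length_s epoch length in seconds
#' @param n_surrogates random-reference surrogates per network (0 disables
#'   gamma/lambda/sigma normalization)
#' @param swaps_per_edge attempted degree-preserving swaps per edge
#' @param metrics_to_test metric columns entering the Welch sweep
#' @param alpha,alpha_marginal primary and marginal sweep significance levels
#' @param q FDR level for edge permutation tests
#' @param n_perm permutations for edge tests
#' @param n_boot bootstrap replicates for mediation
#' @param drop_epochs optional named list `subject_id -> condition -> indices`
#'   of epochs to remove (artifact-rejection hook)
#' @param seed master integer seed
#' @param out_dir output directory for artifacts
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            bands = c("delta", "theta", "alpha", "beta", "gamma"),
                            densities = default_densities(),
                            estimator = c("wpli", "pli"),
                            pooling = "pooled",
                            epoch_length_s = 4,
                            n_surrogates = 50,
                            swaps_per_edge = 10,
                            metrics_to_test = c("C", "L", "sigma"),
                            alpha = 0.05, alpha_marginal = 0.10,
                            q = 0.05, n_perm = 10000, n_boot = 5000,
                            drop_epochs = list(),
                            seed = 1L, out_dir = tempfile("apnet_run_")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(cohort, "cohort_config"),
            all(diff(densities) > 0), all(densities > 0 & densities <= 1),
            epoch_length_s > 0, n_surrogates >= 0, alpha > 0, alpha < 1,
            q > 0, q < 1, n_perm >= 1, n_boot >= 1)
  band_list <- band_presets(bands)
  if (n_surrogates == 0 && "sigma" %in% metrics_to_test) {
    stop("sigma requires n_surrogates > 0 (random-reference normalization)")
  }
  structure(list(cohort = cohort, bands = bands, band_list = band_list,
                 densities = densities, estimator = estimator,
                 pooling = pooling, epoch_length_s = epoch_length_s,
                 n_surrogates = n_surrogates, swaps_per_edge = swaps_per_edge,
                 metrics_to_test = metrics_to_test, alpha = alpha,
                 alpha_marginal = alpha_marginal, q = q, n_perm = n_perm,
                 n_boot = n_boot, drop_epochs = drop_epochs,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_as_list <- function(config) {
  cc <- config$cohort
  list(
    cohort = list(n_per_group = as.list(cc$n_per_group),
                  montage = cc$montage, fs = cc$fs,
                  duration_s = cc$duration_s, conditions = cc$conditions,
                  noise_exponent = cc$noise_exponent),
    bands = config$bands, densities = config$densities,
    estimator = config$estimator, pooling = config$pooling,
    epoch_length_s = config$epoch_length_s,
    n_surrogates = config$n_surrogates,
    swaps_per_edge = config$swaps_per_edge,
    metrics_to_test = config$metrics_to_test,
    alpha = config$alpha, alpha_marginal = config$alpha_marginal,
    q = config$q, n_perm = config$n_perm, n_boot = config$n_boot,
    seed = config$seed)
}

stage_msg <- function(log, stage, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(sprintf("[%s] %s", stage, msg))
  c(log, stats::setNames(list(msg), stage))
}

#' Run the full pipeline
#'
#' Executes every stage on a freshly generated synthetic cohort and writes
#' all result tables to `config$out_dir`. See [pipeline_config()] for the
#' knobs. Stage failures abort with a stage-tagged error.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the in-memory results: `cohort_summary`,
#'   `metrics`, `scores`, `sweep`, `edge_tests`, `regressions`,
#'   `model_comparison`, `correlations`, `mediation`, `out_dir`, `log`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  # -- simulate ------------------------------------------------------------
  cc <- config$cohort
  cc$seed <- derive_seed(config$seed, "cohort")
  cohort <- tryCatch(generate_cohort(cc),
                     error = function(e) stop("[simulate] ", conditionMessage(e)))
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  log <- stage_msg(log, "simulate", "%d subjects (%s), conditions %s",
                   length(cohort$subjects),
                   paste(sprintf("%s=%d", names(table(groups)), table(groups)),
                         collapse = ", "),
                   paste(cc$conditions, collapse = "/"))

  # -- connectivity + graph metrics ---------------------------------------
  n_nodes <- length(cc$montage)
  tree_density <- (n_nodes - 1) / (n_nodes * (n_nodes - 1) / 2)
  clamped <- config$densities[config$densities < tree_density]
  if (length(clamped)) {
    log <- stage_msg(log, "graph_grid",
                     "density grid values below the %d-node spanning-tree density %.4f are clamped: %s",
                     n_nodes, tree_density,
                     paste(format(clamped), collapse = ", "))
  }
  conns <- list()   # [[band]][[condition]][[subject_id]]
  metric_rows <- list()
  epochs_kept <- 0L
  for (s in cohort$subjects) {
    for (cond in cc$conditions) {
      rec <- materialize_recording(s$recordings[[cond]])
      ep <- tryCatch(segment_epochs(rec, config$epoch_length_s),
                     error = function(e) stop("[epoch] ", conditionMessage(e)))
      di <- config$drop_epochs[[s$subject_id]][[cond]]
      if (!is.null(di)) ep <- drop_epochs(ep, di)
      epochs_kept <- epochs_kept + dim(ep$data)[1]
      for (bn in config$bands) {
        cs <- tryCatch(cross_spectra(ep, config$band_list[[bn]]),
                       error = function(e) stop("[connect] ", conditionMessage(e)))
        cm <- if (config$estimator == "wpli") {
          wpli(cs, pooling = config$pooling)
        } else pli(cs)
        conns[[bn]][[cond]][[s$subject_id]] <- cm
        # the clamp was logged once above; silence the per-call warnings
        nm <- tryCatch(suppressWarnings(network_metrics(
          cm, densities = config$densities,
          n_surrogates = config$n_surrogates,
          swaps_per_edge = config$swaps_per_edge,
          seed = derive_seed(config$seed, "null", s$subject_id, cond, bn))),
          error = function(e) stop("[graph] ", conditionMessage(e)))
        nm$group <- s$group
        metric_rows[[length(metric_rows) + 1]] <- nm
      }
    }
  }
  metrics <- do.call(rbind, metric_rows)
  utils::write.table(metrics, file.path(config$out_dir, "network_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- stage_msg(log, "connect",
                   "%d connectivity matrices (%s), %d epochs kept in total",
                   length(cohort$subjects) * length(cc$conditions) *
                     length(config$bands),
                   config$estimator, epochs_kept)
  log <- stage_msg(log, "graph", "%d metric rows over %d densities",
                   nrow(metrics), length(config$densities))

  # -- behavior ------------------------------------------------------------
  ref_group <- names(cc$n_per_group)[length(cc$n_per_group)]
  scores <- tryCatch(score_cohort(cohort, reference_group = ref_group),
                     error = function(e) stop("[score] ", conditionMessage(e)))
  utils::write.table(scores, file.path(config$out_dir, "behavior_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- stage_msg(log, "score", "behavioral scores for %d subjects (reference %s)",
                   nrow(scores), ref_group)

  # -- sweep tests ---------------------------------------------------------
  sweep <- tryCatch(
    sweep_group_tests(metrics, metrics_to_test = config$metrics_to_test,
                      groups = names(cc$n_per_group)[1:2],
                      alpha = config$alpha,
                      alpha_marginal = config$alpha_marginal),
    error = function(e) stop("[stats] ", conditionMessage(e)))
  utils::write.table(sweep$cells, file.path(config$out_dir, "sweep_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sweep$representative,
                     file.path(config$out_dir, "sweep_representative.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- stage_msg(log, "stats",
                   "%d cells, %d in surviving runs, %d representative thresholds",
                   nrow(sweep$cells), sum(sweep$cells$in_run),
                   nrow(sweep$representative))

  # -- edge permutation tests on surviving band x condition ---------------
  edge_tests <- list()
  if (nrow(sweep$representative) > 0) {
    bc <- unique(sweep$representative[, c("band", "condition")])
    for (r in seq_len(nrow(bc))) {
      bn <- bc$band[r]; cond <- bc$condition[r]
      g1 <- conns[[bn]][[cond]][groups == names(cc$n_per_group)[1]]
      g2 <- conns[[bn]][[cond]][groups == names(cc$n_per_group)[2]]
      for (std in c(TRUE, FALSE)) {
        key <- sprintf("%s_%s_%s", bn, cond,
                       if (std) "standardized" else "raw")
        pe <- tryCatch(permutation_edge_test(
          g1, g2, n_perm = config$n_perm, q = config$q,
          seed = derive_seed(config$seed, "perm", bn, cond, std),
          standardize = std),
          error = function(e) stop("[stats] ", conditionMessage(e)))
        edge_tests[[key]] <- pe
        base <- file.path(config$out_dir, paste0("edges_", key))
        write_matrix_tsv(pe$p, paste0(base, "_p.tsv"))
        write_matrix_tsv(pe$d, paste0(base, "_d.tsv"))
        write_matrix_tsv(pe$diff, paste0(base, "_diff.tsv"))
        jsonlite::write_json(list(n_perm = pe$n_perm, q = pe$q,
                                  seed = pe$seed, standardized = pe$standardized,
                                  n_edges_fdr = sum(pe$fdr_mask[upper.tri(pe$fdr_mask)])),
                             paste0(base, ".json"), auto_unbox = TRUE)
      }
    }
    log <- stage_msg(log, "posthoc", "edge permutation tests on %d band/condition combinations",
                     nrow(bc))
  } else {
    log <- stage_msg(log, "posthoc", "no surviving runs; edge tests skipped")
  }

  # -- regressions, correlations, mediation -------------------------------
  regressions <- list()
  model_comparison <- list()
  correlations <- NULL
  med <- NULL
  if (nrow(sweep$representative) > 0) {
    pred <- scores[, c("subject_id", "group", "aq_total", "pis_correct",
                       "z_mad", "z_sdfom", "starting_age")]
    for (r in seq_len(nrow(sweep$representative))) {
      rr <- sweep$representative[r, ]
      sel <- metrics$band == rr$band & metrics$condition == rr$condition &
        metrics$density == rr$density
      mcol <- metrics[sel, c("subject_id", rr$metric)]
      names(mcol)[2] <- sprintf("%s_%s_%s", rr$metric, rr$band, rr$condition)
      pred <- merge(pred, mcol, by = "subject_id")
    }
    net_cols <- setdiff(names(pred), c("subject_id", "group", "aq_total",
                                       "pis_correct", "z_mad", "z_sdfom",
                                       "starting_age"))
    # predict passive (PIS) and active (Z_MAD) absolute pitch proficiency
    regressions$pis <- ols_regression(
      pred$pis_correct, pred[, c("aq_total", net_cols), drop = FALSE])
    regressions$pat <- ols_regression(
      pred$z_mad, pred[, c("aq_total", "starting_age", net_cols), drop = FALSE])
    # model comparison: joint trait + proficiency models per network metric
    for (ncol_ in net_cols) {
      fits <- list(
        aq_plus_mad = ols_regression(pred[[ncol_]],
                                     pred[, c("aq_total", "z_mad")]),
        mad_only = ols_regression(pred[[ncol_]], pred[, "z_mad", drop = FALSE]),
        aq_plus_pis = ols_regression(pred[[ncol_]],
                                     pred[, c("aq_total", "pis_correct")]),
        pis_only = ols_regression(pred[[ncol_]],
                                  pred[, "pis_correct", drop = FALSE]))
      model_comparison[[ncol_]] <- compare_models(fits)
      utils::write.table(model_comparison[[ncol_]],
                         file.path(config$out_dir,
                                   paste0("models_", ncol_, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    correlations <- pearson_corr_table(
      pred[, c("pis_correct", "aq_total", "z_mad", "z_sdfom", "starting_age",
               net_cols)])
    write_matrix_tsv(correlations$r,
                     file.path(config$out_dir, "correlations_r.tsv"))
    write_matrix_tsv(correlations$p,
                     file.path(config$out_dir, "correlations_p.tsv"))
    if (nrow(pred) >= 10) {
      med <- mediation(pred[[net_cols[1]]], pred$aq_total, pred$z_mad,
                       n_boot = config$n_boot,
                       seed = derive_seed(config$seed, "mediation"))
      log <- stage_msg(log, "model",
                       "regressions on %d predictors; mediation indirect = %.4g (CI %.4g..%.4g)",
                       2 + length(net_cols), med$indirect, med$ci[1], med$ci[2])
    } else {
      log <- stage_msg(log, "model",
                       "regressions on %d predictors; cohort too small for mediation (n < 10)",
                       2 + length(net_cols))
    }
  } else {
    log <- stage_msg(log, "model", "no representative thresholds; regression layer skipped")
  }

  # -- provenance ----------------------------------------------------------
  jsonlite::write_json(
    list(config = config_as_list(config),
         log = log,
         counts = list(subjects = length(cohort$subjects),
                       epochs_kept = epochs_kept,
                       cells = nrow(sweep$cells),
                       cells_in_runs = sum(sweep$cells$in_run),
                       representative = nrow(sweep$representative))),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort_summary = table(groups), metrics = metrics,
                 scores = scores, sweep = sweep, edge_tests = edge_tests,
                 regressions = regressions,
                 model_comparison = model_comparison,
                 correlations = correlations, mediation = med,
                 out_dir = config$out_dir, log = log))
}
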