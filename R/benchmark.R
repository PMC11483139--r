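#' Configuration of a benchmark scenario
#'
#' Describes one end-to-end experiment: simulate a paired dataset, add a
#' confounding scenario, train each requested model with `repetitions`
#' different seeds (each repetition redraws the 80:20 train/validation
#' split and the initialisation), consensus-cluster, and evaluate.
#' The confounding effects are drawn once per scenario; repetitions
#' resample splits and seeds only.
#'
#' @param scenario One of `"none"`, `"linear"`, `"square"`,
#'   `"categorical"`, `"mixed"`.
#' @param models Subset of `c("lr_pca", "xvae", "xvae_fs", "cxvae",
#'   "adv_xvae", "cr_xvae")`.
#' @param repetitions Number of repeated runs (50 at full scale).
#' @param n,p,q,k Data dimensions and number of true clusters.
#' @param signal Cluster separation of the generator.
#' @param base_seed Integer; repetition r uses seed `base_seed + r`.
#' @param n_draws Consensus draws per run.
#' @param model_cfg An [xvae_config()] template (its seed is overridden
#'   per repetition).
#' @param fs,adv,cr Strategy settings for the respective models.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(scenario = c("none", "linear", "square",
                                          "categorical", "mixed"),
                             models = c("xvae", "cxvae"),
                             repetitions = 5L,
                             n = 600L, p = 50L, q = 50L, k = 6L,
                             signal = 1.5, base_seed = 1L, n_draws = 50L,
                             model_cfg = xvae_config(view_hidden = 128L,
                                                     fused_hidden = 128L,
                                                     latent_dim = 16L,
                                                     epochs = 50L,
                                                     learning_rate = 5e-3,
                                                     early_stop_patience = 20L),
                             fs = fs_criterion("abs_corr", 0.5),
                             adv = adversary_config(),
                             cr = cr_penalty_spec(),
                             output_dir = NULL) {
  scenario <- match.arg(scenario)
  all_models <- c("lr_pca", "xvae", "xvae_fs", "cxvae", "adv_xvae", "cr_xvae")
  models <- match.arg(models, all_models, several.ok = TRUE)
  if (repetitions < 1) stopf("repetitions must be >= 1")
  structure(list(scenario = scenario, models = models,
                 repetitions = as.integer(repetitions),
                 n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 k = as.integer(k), signal = signal,
                 base_seed = as.integer(base_seed),
                 n_draws = as.integer(n_draws), model_cfg = model_cfg,
                 fs = fs, adv = adv, cr = cr, output_dir = output_dir),
            class = "benchmark_config")
}

## Rescale both views of a paired dataset to [0, 1]
rescale_paired <- function(data) {
  data$view1 <- rescale_unit(data$view1)
  data$view2 <- rescale_unit(data$view2)
  data
}

## Build scenario dataset plus the confounder vectors used by the models.
## Under scenario "none" a random 6-level confounder (unrelated to the
## data) is supplied to the deconfounding models, but not evaluated.
scenario_dataset <- function(cfg) {
  base <- rescale_paired(generate_paired_omics(cfg$n, cfg$p, cfg$q, cfg$k,
                                               signal = cfg$signal,
                                               seed = cfg$base_seed))
  sd1 <- derive_seed(cfg$base_seed, 101L)
  sd2 <- derive_seed(cfg$base_seed, 102L)
  sd3 <- derive_seed(cfg$base_seed, 103L)
  if (cfg$scenario == "none") {
    cf <- draw_numeric_confounder(cfg$n, seed = derive_seed(cfg$base_seed, 104L))
    return(list(data = base, true_labels = base$true_labels,
                eval_confounders = list(),
                model_confounders = list(random = factor(cf))))
  }
  effects <- switch(cfg$scenario,
    linear = list(linear = linear_effect(
      cfg$n, cfg$p, cfg$q,
      draw_numeric_confounder(cfg$n, seed = derive_seed(sd1, 11L)), seed = sd1)),
    square = list(square = square_effect(
      cfg$n, cfg$p, cfg$q,
      draw_numeric_confounder(cfg$n, seed = derive_seed(sd2, 13L)), seed = sd2)),
    categorical = list(categorical = categorical_effect(
      cfg$n, cfg$p, cfg$q, seed = sd3)),
    mixed = mixed_effect(cfg$n, cfg$p, cfg$q, seeds = c(sd1, sd2, sd3))
  )
  data <- apply_effects(base, effects)
  ## model-facing confounder vectors: ordinal scenarios keep the numeric
  ## value (standardised-scalar conditioning), categorical ones a factor
  model_conf <- lapply(effects, function(e) {
    if (e$kind == "categorical") factor(e$confounder_label)
    else as.numeric(e$confounder_label)
  })
  list(data = data, true_labels = base$true_labels,
       eval_confounders = confounder_labels(data),
       model_confounders = model_conf)
}

run_one_model <- function(model_name, sc, cfg, seed_r) {
  mcfg <- cfg$model_cfg
  mcfg$seed <- seed_r
  v <- dataset_views(sc$data)
  confs <- sc$model_confounders
  k <- cfg$k
  if (model_name == "lr_pca") {
    res <- lr_pca_baseline(v$X1, v$X2, confs, n_pcs = mcfg$latent_dim,
                           k = k, seed = seed_r)
    return(list(labels = res$labels, cm = NULL, recon = NULL))
  }
  trained <- switch(model_name,
    xvae = , xvae_fs = train_xvae(build_xvae(cfg$p, cfg$q, mcfg), sc$data),
    cxvae = {
      enc <- encode_confounders(confs)
      train_xvae(build_cxvae(cfg$p, cfg$q, mcfg, enc), sc$data)
    },
    adv_xvae = train_adv_xvae(build_xvae(cfg$p, cfg$q, mcfg), sc$data,
                              confs, adv = cfg$adv),
    cr_xvae = train_cr_xvae(build_xvae(cfg$p, cfg$q, mcfg), sc$data,
                            confs, spec = cfg$cr),
    stopf("unknown model '%s'", model_name))
  keep <- NULL
  if (model_name == "xvae_fs") {
    post <- encode(trained, v$X1, v$X2)
    keep <- filter_latent_features(post$mean, confs, crit = cfg$fs)
  }
  cc <- consensus_cluster_pipeline(trained, sc$data, k = k,
                                   n_draws = cfg$n_draws,
                                   seed = derive_seed(seed_r, 5L),
                                   keep_dims = keep)
  recon <- reconstruct(trained, v$X1, v$X2)
  list(labels = cc$labels, cm = cc$consensus, recon = recon)
}

#' Run a benchmark scenario
#'
#' Executes the full protocol of [benchmark_config()]: one dataset per
#' scenario, `repetitions` training runs per model with seeds
#' `base_seed + r`, consensus clustering, and evaluation (combined
#' relative reconstruction error, consensus dispersion, ARI/NMI versus
#' true labels and versus each simulated confounder). Failures of a
#' single model/repetition are recorded and skipped in aggregation.
#'
#' @param cfg A [benchmark_config()].
#' @return List with `per_run` (one row per model and repetition),
#'   `summary` (mean ± sd table from [aggregate_results()]), and the
#'   scenario metadata. Written as CSV/JSON to `cfg$output_dir` when set.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "benchmark_config"))
  sc <- scenario_dataset(cfg)
  v <- dataset_views(sc$data)
  rows <- list()
  for (r in seq_len(cfg$repetitions)) {
    seed_r <- cfg$base_seed + r
    for (mn in cfg$models) {
      res <- tryCatch(run_one_model(mn, sc, cfg, seed_r),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("%s repetition %d failed: %s", mn, r, conditionMessage(res)))
        row <- data.frame(model = mn, repetition = r, status = "failed",
                          re_combined = NA_real_, dispersion = NA_real_,
                          ari_true = NA_real_, nmi_true = NA_real_)
        for (nm in names(sc$eval_confounders)) {
          row[[paste0("ari_conf_", nm)]] <- NA_real_
        }
      } else {
        row <- data.frame(
          model = mn, repetition = r, status = "ok",
          re_combined = if (is.null(res$recon)) NA_real_ else
            relative_error_combined(v$X1, res$recon$x1, v$X2, res$recon$x2),
          dispersion = if (is.null(res$cm)) NA_real_ else dispersion(res$cm),
          ari_true = ari(res$labels, sc$true_labels),
          nmi_true = nmi(res$labels, sc$true_labels))
        for (nm in names(sc$eval_confounders)) {
          row[[paste0("ari_conf_", nm)]] <-
            ari(res$labels, sc$eval_confounders[[nm]])
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  per_run <- do.call(rbind, rows)
  summary <- aggregate_results(per_run)
  out <- list(scenario = cfg$scenario, per_run = per_run, summary = summary)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_run, file.path(cfg$output_dir, "per_run.csv"),
                     row.names = FALSE)
    utils::write.csv(summary$table, file.path(cfg$output_dir, "summary.csv"),
                     row.names = FALSE)
    manifest <- cfg[c("scenario", "models", "repetitions", "n", "p", "q",
                      "k", "signal", "base_seed", "n_draws")]
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Aggregate per-run benchmark records into a mean ± sd table
#'
#' Sample standard deviation (n - 1 denominator); a model with a single
#' completed run reports sd 0 and is flagged through the `n_runs`
#' column. Formatted as `"mean (± sd)"` with three decimals.
#'
#' @param per_run Data frame from [run_scenario()] (or any frame with a
#'   `model` column, optional `status`, and numeric metric columns).
#' @return List with `stats` (long-format mean/sd per model and metric)
#'   and `table` (wide formatted table, one row per model).
#' @export
aggregate_results <- function(per_run) {
  ok <- if ("status" %in% names(per_run)) per_run$status == "ok" else
    rep(TRUE, nrow(per_run))
  metrics <- setdiff(names(per_run)[vapply(per_run, is.numeric, TRUE)],
                     "repetition")
  models <- unique(per_run$model)
  stats_rows <- list()
  for (mn in models) {
    sel <- per_run$model == mn & ok
    for (met in metrics) {
      x <- per_run[[met]][sel]
      x <- x[!is.na(x)]
      m <- if (length(x)) mean(x) else NA_real_
      s <- if (length(x) > 1) stats::sd(x) else if (length(x) == 1) 0 else NA_real_
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(model = mn, metric = met, mean = m, sd = s,
                   n_runs = length(x))
    }
  }
  stats <- do.call(rbind, stats_rows)
  wide <- data.frame(model = models, stringsAsFactors = FALSE)
  for (met in metrics) {
    vals <- vapply(models, function(mn) {
      row <- stats[stats$model == mn & stats$metric == met, ]
      if (is.na(row$mean)) "-" else
        sprintf("%.3f (± %.3f)", row$mean, row$sd)
    }, "")
    wide[[met]] <- vals
  }
  list(stats = stats, table = wide)
}
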