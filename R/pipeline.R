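#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage parameter with the analysis defaults: Cp cutoff 37,
#' negative-control margin 3, efficiency floor 1.6, detection rate 0.8,
#' low-expression quantile 0.2, score threshold 0.8, network threshold 0.40,
#' combination size 2, t-test alpha 0.05. Input is either a simulation config
#' or paths to a Cp panel / expression matrix on disk.
#'
#' @param simulation a [synth_config()], or NULL when reading from disk.
#' @param cp_panel_path,expression_path optional input paths (long-format Cp
#'   panel, or an already-normalized expression matrix).
#' @param cp_cutoff,nc_margin,efficiency_floor,detection_rate,low_expr_quantile
#'   preprocessing parameters, see [preprocess_panel()].
#' @param score_threshold marker threshold on `|r1 - r2|`.
#' @param p_method `"lrt"` or `"fisher"`, see [diffcorr()].
#' @param combo_size pairs per combination in the combination search.
#' @param r_threshold correlation-network edge threshold.
#' @param alpha t-test selection threshold.
#' @param seed integer seed for the simulation stage.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = synth_config(),
                            cp_panel_path = NULL, expression_path = NULL,
                            cp_cutoff = 37, nc_margin = 3,
                            efficiency_floor = 1.6, detection_rate = 0.8,
                            low_expr_quantile = 0.20,
                            score_threshold = 0.8,
                            p_method = c("lrt", "fisher"),
                            combo_size = 2, r_threshold = 0.40,
                            alpha = 0.05, seed = 1L) {
  p_method <- match.arg(p_method)
  cfg <- list(simulation = simulation, cp_panel_path = cp_panel_path,
              expression_path = expression_path, cp_cutoff = cp_cutoff,
              nc_margin = nc_margin, efficiency_floor = efficiency_floor,
              detection_rate = detection_rate,
              low_expr_quantile = low_expr_quantile,
              score_threshold = score_threshold, p_method = p_method,
              combo_size = combo_size, r_threshold = r_threshold,
              alpha = alpha, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$simulation, "synth_config")) {
    cfg$simulation <- unclass(cfg$simulation)
  }
  cfg
}

#' Run the full differential-correlation pipeline
#'
#' Executes simulate (or load) -> preprocess -> rank pairs -> evaluate marker
#' pairs -> combination search -> t-test baseline -> correlation networks,
#' writing every report, a structured log with per-stage record counts, a
#' machine-readable manifest, and (for synthetic input) a truth-vs-found
#' recovery report into `out_dir`. Re-running with the same config and seed
#' reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @param seed optional integer overriding the config seed.
#' @return invisibly, a list with the fitted objects (`expression`, `fit`,
#'   `combos`, `baseline`, `network`, `truth`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("dcmarker")),
                   r_version = as.character(getRversion()),
                   parameters = config_as_list(config),
                   stages = list())
  finish_stage <- function(name, counts) {
    manifest$stages[[name]] <<- counts
  }
  abort_stage <- function(name, err) {
    manifest$stages[[name]] <<- list(failed = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(err)), call. = FALSE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) abort_stage(name, e))
  }

  truth <- NULL
  es <- run_stage("input", {
    if (!is.null(config$expression_path)) {
      note("input: expression matrix from %s", config$expression_path)
      read_expression(config$expression_path)
    } else {
      panel <- if (!is.null(config$cp_panel_path)) {
        note("input: Cp panel from %s", config$cp_panel_path)
        read_cp_panel(config$cp_panel_path)
      } else {
        sim <- simulate_cp_panel(config$simulation, seed = config$seed)
        truth <- sim$truth
        write_truth(truth, file.path(out_dir, "truth.json"))
        note("input: simulated Cp panel (seed %d): %d records",
             config$seed, nrow(sim$panel))
        write_cp_panel(sim$panel, file.path(out_dir, "cp_panel.tsv"))
        sim$panel
      }
      pre <- preprocess_panel(panel, config$cp_cutoff, config$nc_margin,
                              config$efficiency_floor, config$detection_rate,
                              config$low_expr_quantile)
      qc <- attr(pre, "qc")
      note("preprocess: %d records -> %d samples x %d molecules", qc$n_records,
           qc$n_samples, qc$n_molecules)
      note("preprocess: removed %d undetected, %d low-efficiency, %d by detection rate, %d low-expression",
           qc$removed_not_detected, qc$removed_low_efficiency,
           qc$removed_detection_rate, qc$removed_low_expression)
      jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      finish_stage("preprocess", qc)
      pre
    }
  })
  write_expression(es, file.path(out_dir, "expression.tsv"))
  finish_stage("input", list(n_samples = nrow(es$values),
                             n_molecules = ncol(es$values)))

  fit <- run_stage("rank_pairs", {
    f <- diffcorr(es, p_method = config$p_method,
                  score_threshold = config$score_threshold)
    note("rank_pairs: %d ranked pairs from %d molecules (%d excluded)",
         nrow(f$pairs), ncol(es$values), nrow(f$excluded))
    finish_stage("rank_pairs", list(n_pairs = nrow(f$pairs),
                                    n_excluded = nrow(f$excluded)))
    f
  })

  fit <- run_stage("evaluate", {
    f <- evaluate_pairs(fit)
    mk <- suppressWarnings(markers(f))
    note("evaluate: %d marker pairs at |r1-r2| > %.3g; AUC %.3f +/- %.3f",
         nrow(mk), config$score_threshold, f$auc_summary[["mean"]],
         f$auc_summary[["sd"]])
    finish_stage("evaluate", list(n_markers = nrow(mk),
                                  auc_mean = unname(f$auc_summary[["mean"]]),
                                  auc_sd = unname(f$auc_summary[["sd"]])))
    f
  })
  write_pair_table(fit, file.path(out_dir, "pair_table.tsv"))

  n_mk <- nrow(suppressWarnings(markers(fit)))
  combos <- NULL
  if (n_mk >= config$combo_size) {
    combos <- run_stage("search_combos", {
      cs <- search_pair_combos(fit, combo_size = config$combo_size)
      note("search_combos: %d combinations of %d pairs; best AUC %.3f",
           nrow(cs), config$combo_size, cs$auc[1])
      finish_stage("search_combos", list(n_combos = nrow(cs),
                                         best_auc = cs$auc[1]))
      utils::write.table(as.data.frame(cs),
                         file.path(out_dir, "combo_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cs
    })
  } else {
    note("search_combos: skipped (%d marker pairs < combo size %d)",
         n_mk, config$combo_size)
    finish_stage("search_combos", list(skipped = TRUE, n_markers = n_mk))
  }

  baseline <- run_stage("baseline", {
    bl <- ttest_markers(es, alpha = config$alpha)
    s <- attr(bl, "auc_summary")
    note("baseline: %d/%d molecules selected at alpha %.3g; AUC %.3f +/- %.3f",
         sum(bl$selected), nrow(bl), config$alpha, s[["mean"]], s[["sd"]])
    finish_stage("baseline", list(n_selected = sum(bl$selected),
                                  auc_mean = unname(s[["mean"]]),
                                  auc_sd = unname(s[["sd"]])))
    utils::write.table(as.data.frame(bl),
                       file.path(out_dir, "ttest_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bl
  })

  run_stage("comparison", {
    mk <- suppressWarnings(markers(fit))
    dc_mols <- sort(unique(c(mk$molecule_a, mk$molecule_b)))
    tt_mols <- sort(baseline$molecule[baseline$selected])
    len <- max(length(dc_mols), length(tt_mols), 1)
    cmp <- data.frame(
      differential_correlation = c(dc_mols, rep("", len - length(dc_mols))),
      t_test = c(tt_mols, rep("", len - length(tt_mols))),
      stringsAsFactors = FALSE)
    cmp$in_both <- cmp$differential_correlation != "" &
      cmp$differential_correlation %in% tt_mols
    utils::write.table(cmp, file.path(out_dir, "marker_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("comparison: %d differential-correlation molecules, %d t-test molecules, %d shared",
         length(dc_mols), length(tt_mols), sum(cmp$in_both))
    finish_stage("comparison", list(n_dc = length(dc_mols),
                                    n_tt = length(tt_mols),
                                    n_shared = sum(cmp$in_both)))
  })

  network <- run_stage("network", {
    mk <- suppressWarnings(markers(fit))
    net_all <- build_network(es, r_threshold = config$r_threshold,
                             restrict_to = NULL)
    net_mk <- build_network(es, r_threshold = config$r_threshold,
                            restrict_to = mk)
    export_network(net_all, file.path(out_dir, "network_all"))
    export_network(net_mk, file.path(out_dir, "network_markers"))
    note("network: |r| > %.2f edges per class: %s (all), %s (markers only)",
         config$r_threshold,
         paste(table(net_all$class), collapse = "/"),
         paste(table(net_mk$class), collapse = "/"))
    finish_stage("network", list(n_edges_all = nrow(net_all),
                                 n_edges_markers = nrow(net_mk)))
    list(all = net_all, markers_only = net_mk)
  })

  if (!is.null(truth)) {
    run_stage("recovery", {
      mk <- suppressWarnings(markers(fit))
      tp <- truth$differential_pairs
      keys <- paste(fit$pairs$molecule_a, fit$pairs$molecule_b)
      tkey1 <- paste(tp$molecule_a, tp$molecule_b)
      tkey2 <- paste(tp$molecule_b, tp$molecule_a)
      pos <- pmin(match(tkey1, keys, nomatch = NA),
                  match(tkey2, keys, nomatch = NA), na.rm = TRUE)
      rec <- cbind(tp, found_rank = fit$pairs$rank[pos],
                   found_score = fit$pairs$score[pos],
                   selected = fit$pairs$score[pos] > config$score_threshold)
      utils::write.table(rec, file.path(out_dir, "recovery_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("recovery: %d/%d planted pairs selected as markers",
           sum(rec$selected, na.rm = TRUE), nrow(rec))
      finish_stage("recovery", list(n_planted = nrow(rec),
                                    n_selected = sum(rec$selected, na.rm = TRUE)))
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(expression = es, fit = fit, combos = combos,
                 baseline = baseline, network = network, truth = truth,
                 manifest = manifest))
}
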