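# End-to-end orchestration: simulate -> preprocess -> connect -> graph ->
# stats -> report, with per-stage artifacts and a deterministic provenance
# manifest. All stage seeds derive from the master seed, so rerunning a
# configuration reproduces every output bit for bit.

#' Run the analysis pipeline
#'
#' Executes the pipeline stages in order on a synthetic cohort: cohort
#' generation, preprocessing of every recording, stage-A/B/R connectivity,
#' graph metrics with AUC summaries, group statistics, and report rendering.
#' Artifacts are written under `out_dir` (`cohort.tsv`, per-subject FC
#' matrices, `qc_report.json`, `metric_profiles.tsv`, `auc.tsv`,
#' `edge_stats.tsv`, `moderation.tsv`, `manifest.json`).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages contiguous prefix of
#'   `c("simulate", "preprocess", "connect", "graph", "stats", "report")`;
#'   earlier stages always run (they are cheap and deterministic), later ones
#'   are skipped.
#' @return Invisibly, the pipeline state (cohort, hemo series, matrices,
#'   network summaries, statistics).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "preprocess", "connect",
                                    "graph", "stats", "report")) {
  all_stages <- c("simulate", "preprocess", "connect", "graph", "stats",
                  "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  last <- max(match(stages, all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed
  state <- list(config = config)

  # -- simulate ---------------------------------------------------------
  sim_args <- config$sim
  cfg <- do.call(sim_config, c(sim_args, list(seed = seed)))
  coh <- generate_cohort(config$n_patients, config$n_controls, cfg,
                         seed = derive_seed(seed, "simulate"),
                         signals = TRUE)
  state$cohort <- coh$cohort
  state$subjects <- coh$subjects
  state$ground_truth <- coh$ground_truth
  utils::write.table(coh$cohort, file.path(out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(effects = coh$ground_truth$effects,
                            seed = seed),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (last >= 2) {
    # -- preprocess -----------------------------------------------------
    state$hemo <- lapply(names(coh$subjects), function(id) {
      lapply(coh$subjects[[id]], function(rec)
        preprocess_recording(rec, seed = derive_seed(seed, paste0("pp_", id))))
    })
    names(state$hemo) <- names(coh$subjects)
    qc <- lapply(state$hemo, function(h) h$task$qc)
    jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (last >= 3) {
    # -- connect --------------------------------------------------------
    mats <- connectivity_stage(state$hemo, state$cohort, config, seed)
    state$fc <- mats
    dir.create(file.path(out_dir, "fc"), showWarnings = FALSE)
    for (i in seq_along(mats$r_mats))
      write_fc_matrix(mats$r_mats[[i]],
                      file.path(out_dir, "fc",
                                paste0(state$cohort$id[i], "_residual.tsv")))
  }
  if (last >= 4) {
    # -- graph ----------------------------------------------------------
    hemi <- state$subjects[[1]]$task$montage$hemisphere
    np <- network_profiles(state$fc$b_task, hemi,
                           groups = state$cohort$group,
                           grid = threshold_grid(config$grid[1],
                                                 config$grid[2],
                                                 config$grid[3]),
                           n_rand = config$n_rand,
                           seed = derive_seed(seed, "graph"))
    state$network <- np
    utils::write.table(np$profiles,
                       file.path(out_dir, "metric_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(np$auc, file.path(out_dir, "auc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (last >= 5) {
    # -- stats ----------------------------------------------------------
    pat <- state$cohort$group == "epilepsy"
    es <- edgewise_permutation_test(state$fc$r_mats[pat],
                                    state$fc$r_mats[!pat],
                                    n_perm = config$n_perm,
                                    seed = derive_seed(seed, "stats"),
                                    alpha = config$alpha)
    state$edge_stats <- es
    mods <- lapply(c("eloc_L", "eloc_R", "gamma_L", "gamma_R", "lambda",
                     "eglob", "sigma"), function(m) {
      fit <- tryCatch(
        moderation_regression(state$network$auc[[m]],
                              state$cohort$estimated_iq,
                              state$cohort$group),
        error = function(e) {
          warning("moderation model for ", m, " not fitted: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(fit))
        return(data.frame(metric = m, F = NA_real_, p_model = NA_real_,
                          adj_r_squared = NA_real_,
                          beta_interaction = NA_real_,
                          p_interaction = NA_real_, stringsAsFactors = FALSE))
      data.frame(metric = m, F = fit$F, p_model = fit$p_model,
                 adj_r_squared = fit$adj_r_squared,
                 beta_interaction = fit$coefficients["iq_x_group", "estimate"],
                 p_interaction = fit$coefficients["iq_x_group", "p"],
                 stringsAsFactors = FALSE)
    })
    state$moderation <- do.call(rbind, mods)
    utils::write.table(state$moderation, file.path(out_dir, "moderation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    edge_df <- edge_stats_table(es, state$subjects[[1]]$task$montage)
    utils::write.table(edge_df, file.path(out_dir, "edge_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (last >= 6) render_reports(out_dir, state)

  manifest <- list(config_hash = config_hash(config),
                   master_seed = seed,
                   stages = all_stages[seq_len(last)],
                   package_version = as.character(utils::packageVersion("nirsnet")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(state)
}

# stage A -> Fisher -> age regression -> residual matrices for a cohort
connectivity_stage <- function(hemo, cohort, config, seed) {
  n <- nrow(cohort)
  a_task <- vector("list", n); a_rest <- vector("list", n)
  for (i in seq_len(n)) {
    for (cond in c("task", "rest")) {
      h <- hemo[[i]][[cond]]
      a <- stage_a_matrix(h$hbo, h$fs, n_windows = config$n_windows,
                          win_s = config$win_s, valid_mask = h$valid_mask,
                          subject = cohort$id[i], condition = cond,
                          seed = derive_seed(seed, paste0("fc_", i, "_", cond)))
      if (cond == "task") a_task[[i]] <- fisher_transform(a)
      else a_rest[[i]] <- fisher_transform(a)
    }
  }
  b_task <- regress_age(a_task, cohort$age)$b_mats
  b_rest <- regress_age(a_rest, cohort$age)$b_mats
  r_mats <- lapply(seq_len(n), function(i)
    residual_matrix(b_task[[i]], b_rest[[i]]))
  names(b_task) <- names(b_rest) <- names(r_mats) <- cohort$id
  list(a_task = a_task, a_rest = a_rest, b_task = b_task, b_rest = b_rest,
       r_mats = r_mats)
}

# connectogram-ready edge list from edgewise statistics
edge_stats_table <- function(es, montage) {
  n <- nrow(es$t)
  ij <- which(upper.tri(es$t), arr.ind = TRUE)
  data.frame(
    from = montage$channel[ij[, 1]], to = montage$channel[ij[, 2]],
    region_pair = paste0(montage$hemisphere[ij[, 1]], "-",
                         montage$region[ij[, 1]], ":",
                         montage$hemisphere[ij[, 2]], "-",
                         montage$region[ij[, 2]]),
    t = es$t[ij], p = es$p[ij], d = es$d[ij],
    direction = c("patients<controls", "ns",
                  "patients>controls")[sign(es$t[ij]) *
                                         (es$p[ij] < es$alpha) + 2],
    stringsAsFactors = FALSE)
}

#' Render report artifacts
#'
#' Writes connectogram-ready significant-edge lists, metric-versus-threshold
#' curve tables, and AUC group summaries; when ggplot2 is installed, also
#' saves FC heatmap and metric-curve figures as PDFs. Idempotent: rerunning
#' overwrites the same files with identical content.
#'
#' @param out_dir pipeline output directory.
#' @param state pipeline state (from [run_pipeline()]); when `NULL`, tables
#'   are re-read from `out_dir`.
#' @return Invisibly, the files written.
#' @export
render_reports <- function(out_dir, state = NULL) {
  files <- character()
  prof_path <- file.path(out_dir, "metric_profiles.tsv")
  edge_path <- file.path(out_dir, "edge_stats.tsv")
  if (!file.exists(prof_path) || !file.exists(edge_path)) {
    warning("missing stats outputs; report skipped")
    return(invisible(files))
  }
  profiles <- utils::read.table(prof_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  edges <- utils::read.table(edge_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)

  sig <- edges[!is.na(edges$p) & edges$direction != "ns", , drop = FALSE]
  f <- file.path(out_dir, "significant_edges.tsv")
  utils::write.table(sig, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  curves <- stats::aggregate(normalized ~ tau + metric + group,
                             data = profiles, FUN = mean)
  f <- file.path(out_dir, "metric_curves.tsv")
  utils::write.table(curves, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  auc_path <- file.path(out_dir, "auc.tsv")
  if (file.exists(auc_path)) {
    auc <- utils::read.table(auc_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    num <- vapply(auc, is.numeric, logical(1))
    summ <- stats::aggregate(auc[num], by = list(group = auc$group), FUN = mean)
    f <- file.path(out_dir, "auc_group_means.tsv")
    utils::write.table(summ, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(curves,
                          ggplot2::aes(x = tau, y = normalized,
                                       colour = group)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = "sparsity threshold", y = "normalized metric")
    f <- file.path(out_dir, "metric_curves.pdf")
    ggplot2::ggsave(f, gg, width = 8, height = 6)
    files <- c(files, f)
  }
  invisible(files)
}
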