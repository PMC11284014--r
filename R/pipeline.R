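#' Run the full receptivity-testing pipeline on a synthetic cohort
#'
#' Wires every stage end to end on simulated data: generate a training
#' cohort with three-point biopsies (P+3/P+5/P+7) transferred at each
#' patient's true WOI, keep pregnancy-confirmed cycles and construct their
#' hour labels; rank marker genes; fit (optionally cross-validate) the
#' hour-offset forest; report receptivity for an independent test cohort
#' from a single P+5 biopsy each; schedule personalized transfers; and
#' compare simulated pregnancy outcomes of the personalized arm against a
#' standard-timing arm with 2x2 statistics. All artifacts are plain text
#' (TSV/CSV/JSON) and a manifest records the seed, a content hash of the
#' configuration, and the MD5 of every file, so a rerun with the same
#' configuration is bit-identical.
#'
#' @param out_dir Output directory for artifacts.
#' @param config A [cohort_config()] describing the simulated population;
#'   its `n_patients` is used for the training cohort.
#' @param n_test Number of patients in the held-out clinical cohort
#'   (personalized arm); the standard-timing arm has `2 * n_test`.
#' @param n_markers Marker-panel size passed to [select_markers()].
#' @param hp List of forest hyperparameters (`n_trees`, `mtry`,
#'   `min_node_size`, `max_depth`); unset entries use [woi_forest()]
#'   defaults.
#' @param cv_grid Optional data frame of hyperparameter settings; when
#'   given, [cv_forest()] selects the best row before the final fit.
#' @param halfwidth Receptive half-width in hours.
#' @param transfer_clock Clinic transfer hour-of-day.
#' @param seed Global integer seed; every stage derives its own seed from
#'   it deterministically.
#' @return An object of class `pipeline_run`: list with `summary`
#'   (receptive fraction, CV mean R-squared if run, outcome table),
#'   `manifest`, and `paths`.
#' @export
run_pipeline <- function(out_dir,
                         config = cohort_config(n_patients = 150, seed = 1L),
                         n_test = 100L,
                         n_markers = 175L,
                         hp = list(n_trees = 300L),
                         cv_grid = NULL,
                         halfwidth = 12,
                         transfer_clock = 15,
                         seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  paths <- list()

  ## stage 1: simulate -------------------------------------------------
  # one cohort provides both arms so train and test share gene parameters
  # (the same assay); patients are split disjointly
  n_total <- config$n_patients + 3L * as.integer(n_test)
  full_cfg <- config
  full_cfg$n_patients <- n_total
  full_cfg$seed <- seed
  cohort <- generate_cohort(full_cfg)
  idx_train <- seq_len(config$n_patients)
  idx_test <- config$n_patients + seq_len(n_test)
  idx_fet <- config$n_patients + n_test + seq_len(2L * n_test)

  train_expr <- sample_biopsies(cohort, c(72, 120, 168))
  truth <- cohort$truth
  keep_train <- train_expr$meta$patient_id %in% truth$patient_id[idx_train]
  train_meta <- train_expr$meta[keep_train, ]
  train_mat <- train_expr$matrix[, keep_train, drop = FALSE]

  # training labels come from pregnancy-confirmed transfers at the true WOI
  train_truth <- truth[idx_train, ]
  out_train <- simulate_transfer_outcome(train_truth,
                                         train_truth$true_woi_center,
                                         full_cfg, seed = seed + 11L)
  pregnant <- train_truth$patient_id[out_train$clinical]
  lab_meta <- train_meta[train_meta$patient_id %in% pregnant, ]
  transfer_of <- stats::setNames(train_truth$true_woi_center,
                                 train_truth$patient_id)
  raw <- transfer_of[lab_meta$patient_id] - lab_meta$sampling_time
  in_grid <- abs(raw) <= 108
  lab_meta <- lab_meta[in_grid, ]
  lab_meta$label <- label_from_outcome(
    lab_meta$sampling_time, transfer_of[lab_meta$patient_id])
  lab_mat <- train_mat[, lab_meta$sample_id, drop = FALSE]

  paths$matrix <- file.path(out_dir, "train_matrix.tsv")
  write_matrix_tsv(lab_mat, paths$matrix)
  paths$meta <- file.path(out_dir, "train_meta.csv")
  utils::write.csv(lab_meta, paths$meta, row.names = FALSE)
  paths$truth <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth, paths$truth, row.names = FALSE)

  ## stage 2: marker panel ---------------------------------------------
  panel <- select_markers(lab_mat, lab_meta$label, k = n_markers)
  paths$panel <- file.path(out_dir, "markers.csv")
  write_panel(panel, paths$panel)

  ## stage 3: train (optionally with CV model selection) ---------------
  X_train <- t(lab_mat[panel$gene_id, , drop = FALSE])
  cv <- NULL
  hp_full <- utils::modifyList(
    list(n_trees = 300L, mtry = ceiling(nrow(panel) / 3),
         min_node_size = 5L, max_depth = 0L), hp)
  if (!is.null(cv_grid)) {
    cv <- cv_forest(X_train, lab_meta$label, lab_meta$patient_id,
                    k = min(10L, length(unique(lab_meta$patient_id))),
                    hp_grid = cv_grid, seed = seed + 23L)
    hp_full <- utils::modifyList(hp_full, as.list(cv$selected))
  }
  model <- woi_forest(X_train, lab_meta$label,
                      n_trees = hp_full$n_trees, mtry = hp_full$mtry,
                      min_node_size = hp_full$min_node_size,
                      max_depth = hp_full$max_depth, seed = seed + 37L)
  paths$model <- file.path(out_dir, "model.json")
  write_forest_json(model, paths$model)

  ## stage 4: receptivity reports for the test cohort ------------------
  test_expr <- sample_biopsies(cohort, 120)
  keep_test <- test_expr$meta$patient_id %in% truth$patient_id[idx_test]
  X_test <- t(test_expr$matrix[panel$gene_id, keep_test, drop = FALSE])
  pred <- predict(model, X_test)
  reports <- lapply(seq_len(nrow(pred)), function(i) {
    report_receptivity(pred$offset_hours[i], sampling_time = 120,
                       reference_woi = config$reference_woi_hours,
                       halfwidth = halfwidth, se_hours = pred$se_hours[i])
  })
  rep_df <- do.call(rbind, lapply(reports, as.data.frame))
  rep_df$patient_id <- test_expr$meta$patient_id[keep_test]
  paths$receptivity <- file.path(out_dir, "receptivity.json")
  jsonlite::write_json(rep_df, paths$receptivity, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  summary_fractions <- cohort_receptivity_summary(reports)

  ## stage 5: transfer plans --------------------------------------------
  plans <- lapply(rep_df$optimal_woi_hours, plan_transfer,
                  transfer_clock = transfer_clock)
  plan_df <- data.frame(
    patient_id = rep_df$patient_id,
    injection_clock = vapply(plans, `[[`, numeric(1), "injection_clock"),
    transfer_day_index = vapply(plans, `[[`, integer(1),
                                "transfer_day_index"),
    transfer_clock = transfer_clock,
    elapsed_hours = rep_df$optimal_woi_hours)
  paths$plans <- file.path(out_dir, "plans.json")
  jsonlite::write_json(plan_df, paths$plans, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)

  ## stage 6: outcome evaluation ----------------------------------------
  # personalized arm transfers at the predicted optimum; the comparison
  # arm at the standard reference time
  test_truth <- truth[idx_test, ]
  out_pet <- simulate_transfer_outcome(test_truth, rep_df$optimal_woi_hours,
                                       full_cfg, seed = seed + 41L)
  fet_truth <- truth[idx_fet, ]
  out_fet <- simulate_transfer_outcome(fet_truth,
                                       config$reference_woi_hours,
                                       full_cfg, seed = seed + 43L)
  tab <- outcome_table(
    list(n = nrow(out_pet), hcg = sum(out_pet$hcg),
         biochemical = sum(out_pet$biochemical),
         clinical = sum(out_pet$clinical)),
    list(n = nrow(out_fet), hcg = sum(out_fet$hcg),
         biochemical = sum(out_fet$biochemical),
         clinical = sum(out_fet$clinical)))
  paths$outcomes <- file.path(out_dir, "outcomes.csv")
  utils::write.csv(tab, paths$outcomes, row.names = FALSE)

  ## manifest ------------------------------------------------------------
  files <- vapply(paths, identity, character(1))
  manifest <- list(
    seed = seed,
    config_hash = config_hash(full_cfg),
    stages = c("simulate", "markers", "train", "report", "schedule",
               "evaluate"),
    files = lapply(stats::setNames(as.list(files), names(paths)),
                   function(f) list(file = basename(f),
                                    md5 = unname(tools::md5sum(f)))))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)

  structure(list(summary = list(receptivity = summary_fractions,
                                cv_mean_r_squared = if (!is.null(cv))
                                  max(cv$summary$mean_r_squared) else NA_real_,
                                outcome_table = tab,
                                n_training_samples = nrow(lab_meta)),
                 cv = cv, manifest = manifest, paths = paths),
            class = "pipeline_run")
}

# stable content hash of a configuration: MD5 of its canonical JSON
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("rsERT pipeline run\n")
  fr <- x$summary$receptivity
  cat(sprintf("  receptive %.1f%% / delayed %.1f%% / advanced %.1f%%\n",
              100 * fr[["receptive"]], 100 * fr[["delayed"]],
              100 * fr[["advanced"]]))
  if (is.finite(x$summary$cv_mean_r_squared)) {
    cat(sprintf("  CV mean R^2: %.3f\n", x$summary$cv_mean_r_squared))
  }
  cat("  outcome comparison (personalized vs standard timing):\n")
  print(x$summary$outcome_table[, c("outcome", "exposed", "unexposed",
                                    "odds_ratio", "p_value")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
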