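#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], which callers
#' can modify and pass back (or store as YAML via [write_run_config()]).
#' Stages can be disabled individually: with `quality$enabled = FALSE` the
#' gate is skipped, with `segmentation$enabled = FALSE` the true generated
#' vessel maps feed the classifier directly (the stage-substitution contract:
#' any stage may be replaced by inputs honouring its output contract).
#'
#' @param seed run-level seed; every stage derives its own stream from it.
#' @param output_dir where artifacts and reports are written.
#' @return nested named list.
#' @export
default_pipeline_config <- function(seed = 1L, output_dir = tempfile("run")) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    synthdata = list(image_size = 64L, n_ad = 20L, n_controls_per_ad = 5L,
                     branch_depth = 3L, small_vessel_effect = 0.5,
                     pixel_noise_sd = 0.02),
    quality = list(enabled = TRUE, n_train_per_class = 30L,
                   n_distractors = 10L, seeds = 101:105),
    segmentation = list(enabled = TRUE, scales = c(1, 2, 4),
                        low_threshold = 0.08, high_threshold = 0.25),
    classify = list(resize_to = 32L, use_selection = TRUE, alpha = 0.01,
                    also_without_selection = FALSE,
                    c_grid = 10^seq(-1, 2), gamma_grid = 10^seq(-3, 0),
                    outer_folds = 5L, inner_folds = 5L),
    saliency = list(enabled = TRUE, scales = c(1, 2, 4, 8))
  )
}

# render a batch of faulty training images spanning all fault kinds
.faulty_batch <- function(config, n, seed) {
  kinds <- c("exposure", "focus", "composition", "artifact")
  lapply(seq_len(n), function(i) {
    v <- generate_vessel_tree(config, "NC", derive_seed(seed, "qtree", i))
    sev <- with_seed(derive_seed(seed, "qsev", i), stats::runif(1, 0.6, 1))
    render_fundus(v, kinds[(i - 1) %% 4 + 1], sev,
                  derive_seed(seed, "qrender", i))
  })
}

.clean_batch <- function(config, n, seed) {
  lapply(seq_len(n), function(i) {
    v <- generate_vessel_tree(config, "NC", derive_seed(seed, "ctree", i))
    render_fundus(v, "none", 0)
  })
}

#' Run the full retinal-vasculature classification pipeline
#'
#' Executes the study stages in order on a synthetic cohort (or on supplied
#' vessel maps): data generation, ensemble quality gating (unanimous vote,
#' with extra faulty distractor images demonstrating the gate), vesselness
#' segmentation of the rendered fundus images, exact matched-control
#' construction, one nested-CV RBF-SVM evaluation per control group with the
#' per-group metrics averaged, and an occlusion saliency map from a model
#' fitted on the first control group. The run is deterministic given the
#' configuration seed; `cv_results.json` in the output directory is
#' byte-identical across reruns of the same config.
#'
#' @param config a configuration list as from [default_pipeline_config()],
#'   or a path to a YAML file holding one.
#' @param maps optional named list of [vessel_map()] keyed by image id; with
#'   `table`, substitutes the synthetic generation + quality + segmentation
#'   stages by precomputed vessel maps.
#' @param table optional subject table matching `maps`.
#' @return an object of class `run_report` (invisibly written to
#'   `report.json` as well).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         maps = NULL, table = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message("[pipeline] ", msg)
  }
  flow <- NULL
  sc <- do.call(simulation_config,
                c(config$synthdata, list(seed = seed)))
  if (is.null(maps)) {
    cohort <- generate_cohort(sc, seed)
    table <- cohort$table
    maps <- cohort$maps
    say("generated cohort: ", sum(table$diagnosis == "AD"), " AD / ",
        sum(table$diagnosis == "NC"), " NC images")
    gate_seg <- isTRUE(config$quality$enabled) ||
      isTRUE(config$segmentation$enabled)
    if (gate_seg) {
      renders <- lapply(names(maps), function(id) {
        render_fundus(maps[[id]], "none", 0)
      })
      names(renders) <- names(maps)
      if (isTRUE(config$quality$enabled)) {
        qseed <- derive_seed(seed, "quality")
        ens <- train_quality_ensemble(
          .clean_batch(sc, config$quality$n_train_per_class, qseed),
          .faulty_batch(sc, config$quality$n_train_per_class, qseed),
          seeds = config$quality$seeds)
        distract <- .faulty_batch(sc, config$quality$n_distractors,
                                  derive_seed(seed, "distractors"))
        batch <- c(renders, distract)
        flow <- run_selection_flow(ens, batch)
        keep <- flow$pass_index[flow$pass_index <= length(renders)]
        say("quality gate: ", length(batch), " images in, ", flow$final_pass,
            " unanimous passes (", length(renders) - length(keep),
            " cohort images rejected, ",
            sum(flow$pass_index > length(renders)), " distractors slipped)")
        renders <- renders[keep]
        table <- table[table$image_id %in% names(renders), , drop = FALSE]
      }
      if (isTRUE(config$segmentation$enabled)) {
        scfg <- segmentation_config(config$segmentation$scales,
                                    config$segmentation$low_threshold,
                                    config$segmentation$high_threshold)
        maps <- lapply(renders, segment_vessels, cfg = scfg)
        say("segmented ", length(maps), " fundus renderings")
      } else {
        maps <- maps[names(renders)]
      }
    }
  } else {
    stopifnot(!is.null(table))
    say("using ", length(maps), " precomputed vessel maps")
  }
  n_groups <- sc$n_controls_per_ad
  assign <- match_controls(table, n_groups, derive_seed(seed, "match"))
  say("matched ", n_groups, " control groups of ",
      sum(table$diagnosis == "AD"), " images each")
  cl <- config$classify
  cfg <- svm_config(cl$c_grid, cl$gamma_grid, cl$outer_folds,
                    cl$inner_folds, seed = derive_seed(seed, "cv"))
  ad_ids <- table$image_id[table$diagnosis == "AD"]
  run_group <- function(g, use_sel) {
    ids <- c(ad_ids, control_group_ids(assign, g))
    nested_cv(maps[ids], c(rep("AD", length(ad_ids)),
                           rep("NC", length(ids) - length(ad_ids))),
              cfg, use_selection = use_sel, alpha = cl$alpha,
              resize_to = cl$resize_to)
  }
  cv_results <- lapply(seq_len(n_groups), run_group,
                       use_sel = isTRUE(cl$use_selection))
  mean_acc <- mean(vapply(cv_results, function(r) r$mean[["accuracy"]],
                          numeric(1)))
  say(sprintf("mean accuracy over %d control groups: %.3f",
              n_groups, mean_acc))
  cv_results_ns <- NULL
  if (isTRUE(cl$also_without_selection)) {
    cv_results_ns <- lapply(seq_len(n_groups), run_group, use_sel = FALSE)
    say(sprintf("without selection: %.3f",
                mean(vapply(cv_results_ns, function(r) r$mean[["accuracy"]],
                            numeric(1)))))
  }
  saliency_path <- NULL
  if (isTRUE(config$saliency$enabled)) {
    ids <- c(ad_ids, control_group_ids(assign, 1))
    labs <- c(rep("AD", length(ad_ids)), rep("NC", length(ids) - length(ad_ids)))
    model <- fit_ad_classifier(maps[ids], labs, cfg,
                               use_selection = isTRUE(cl$use_selection),
                               alpha = cl$alpha, resize_to = cl$resize_to)
    target <- resize_map(maps[[ad_ids[1]]], cl$resize_to)
    s <- saliency_map(model, target, config$saliency$scales)
    saliency_path <- file.path(config$output_dir, "saliency_example.png")
    write_saliency_png(s, saliency_path,
                       file.path(config$output_dir, "saliency_overlay.png"),
                       target)
    say("wrote saliency map for image ", ad_ids[1],
        " (label ", s$label_explained, ")")
  }
  cv_json <- file.path(config$output_dir, "cv_results.json")
  serial <- function(r) list(folds = r$folds, mean = as.list(r$mean),
                             sd = as.list(r$sd))
  jsonlite::write_json(
    list(with_selection = lapply(cv_results, serial),
         without_selection = if (!is.null(cv_results_ns))
           lapply(cv_results_ns, serial)),
    cv_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  write_subject_table(table, file.path(config$output_dir, "subjects.csv"))
  report <- structure(
    list(config = config, selection_flow = flow,
         cohort = list(n_ad = sum(table$diagnosis == "AD"),
                       n_nc = sum(table$diagnosis == "NC")),
         cv_results = cv_results, cv_results_no_selection = cv_results_ns,
         mean_accuracy = mean_acc,
         saliency_path = saliency_path, cv_json = cv_json,
         seed = seed, timestamp = format(Sys.time()), log = log),
    class = "run_report")
  jsonlite::write_json(
    list(seed = seed, timestamp = report$timestamp,
         cohort = report$cohort, mean_accuracy = mean_acc,
         selection_flow = if (!is.null(flow)) flow$stages,
         artifacts = list(cv_results = cv_json, saliency = saliency_path),
         log = log),
    file.path(config$output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  cat(" cohort:", x$cohort$n_ad, "AD /", x$cohort$n_nc, "NC images\n")
  cat(sprintf(" mean accuracy over %d control groups: %.3f\n",
              length(x$cv_results), x$mean_accuracy))
  invisible(x)
}
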