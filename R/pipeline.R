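#' Pipeline configuration
#'
#' Single configuration object driving the full analysis: cohort synthesis,
#' segmentation, feature extraction, dimension reduction, classifier
#' training and cutoff evaluation. Every random stage derives its seed from
#' the one `seed` given to [run_pipeline()].
#'
#' @param cohort a [cohort_config()].
#' @param iauc_window iAUC window in seconds.
#' @param rules a [curve_type_rules()].
#' @param pca_cutoff eigenvalue retention cutoff.
#' @param mlp an [mlp_config()] (its `seed` is overridden by the pipeline
#'   seed).
#' @param train_fraction train split fraction (default 0.70).
#' @param cutoff_sensitivities named minimum sensitivities defining the
#'   high-sensitivity cutoffs (default `c(C1 = 1.00, C2 = 0.95)`).
#' @param ci_method `"clopper-pearson"` or `"wilson"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            iauc_window = 90,
                            rules = curve_type_rules(),
                            pca_cutoff = 3,
                            mlp = mlp_config(),
                            train_fraction = 0.70,
                            cutoff_sensitivities = c(C1 = 1.00, C2 = 0.95),
                            ci_method = "clopper-pearson") {
  stopifnot(inherits(cohort, "cohort_config"), inherits(mlp, "mlp_config"))
  if (is.null(names(cutoff_sensitivities)))
    names(cutoff_sensitivities) <- paste0("C", seq_along(cutoff_sensitivities))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' generate -> segment -> fit pharmacokinetics -> extract 86 features ->
#' split 70/30 -> PCA (training only) -> train MLP -> pick high-sensitivity
#' cutoffs on training -> evaluate on the untouched test set. Lesions whose
#' seed voxel fails the enhancement threshold are excluded with a warning
#' and listed in the summary.
#'
#' @param config a [pipeline_config()].
#' @param seed master integer seed; stage seeds are derived from it.
#' @param out_dir optional directory; when given, the feature table,
#'   manifest, models and summary are written there.
#' @param verbose print stage progress.
#' @return list with `features` (data.frame incl. lesion_id, label, split,
#'   pseudo_probability), `pca`, `mlp`, `roc_train`, `roc_test`,
#'   `thresholds`, `reports` (per cutoff), and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL, verbose = interactive()) {
  seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage 1/6: generating %d synthetic lesions", config$cohort$n_lesions)
  coh <- generate_cohort(config$cohort, seed = seed)

  say("stage 2/6: segmentation + feature extraction")
  n <- nrow(coh$truth)
  feats <- vector("list", n)
  excluded <- character(0)
  fallbacks <- 0L
  for (i in seq_len(n)) {
    les <- coh$lesions[[i]]
    mask <- tryCatch(
      segment_lesion(les, les$seed_voxel, threshold = config$rules$washin_threshold),
      error = function(e) e)
    if (inherits(mask, "error")) {
      warning("lesion ", coh$truth$lesion_id[i], " excluded: ",
              conditionMessage(mask))
      excluded <- c(excluded, coh$truth$lesion_id[i])
      next
    }
    fx <- extract_lesion_features(les, mask, aif = config$cohort$aif,
                                  alpha = config$cohort$alpha,
                                  iauc_window = config$iauc_window,
                                  rules = config$rules)
    if (fx$clusters$fallback) fallbacks <- fallbacks + 1L
    feats[[i]] <- fx$features
  }
  done <- !vapply(feats, is.null, logical(1))
  X <- do.call(rbind, feats[done])
  truth <- coh$truth[done, , drop = FALSE]
  say("  %d lesions segmented (%d excluded, %d cluster fallbacks)",
      sum(done), length(excluded), fallbacks)

  say("stage 3/6: 70/30 split + PCA")
  sp <- split_cohort(truth$label, config$train_fraction, seed = seed + 1L)
  pca <- withCallingHandlers(
    fit_pca(X[sp$train, , drop = FALSE], config$pca_cutoff),
    warning = function(w) invokeRestart("muffleWarning"))
  scores <- pca_project(pca, X)

  say("stage 4/6: MLP training (architecture search)")
  mlpcfg <- config$mlp
  mlpcfg$seed <- seed + 2L
  mlp <- train_mlp(scores[sp$train, , drop = FALSE], truth$label[sp$train],
                   mlpcfg)
  prob <- predict_pseudo_probability(mlp, scores)

  say("stage 5/6: ROC analysis")
  roc_train <- roc_curve(prob[sp$train], truth$label[sp$train])
  roc_test <- roc_curve(prob[sp$test], truth$label[sp$test])

  say("stage 6/6: high-sensitivity cutoffs")
  thresholds <- vapply(config$cutoff_sensitivities, function(ms)
    as.numeric(find_sensitivity_cutoff(prob[sp$train],
                                       truth$label[sp$train], ms)),
    numeric(1))
  train_reports <- evaluate_cutoffs(prob[sp$train], truth$label[sp$train],
                                    thresholds, truth$lesion_id[sp$train],
                                    config$ci_method)
  test_reports <- evaluate_cutoffs(prob[sp$test], truth$label[sp$test],
                                   thresholds, truth$lesion_id[sp$test],
                                   config$ci_method)

  features <- data.frame(lesion_id = truth$lesion_id, label = truth$label,
                         split = ifelse(seq_len(nrow(truth)) %in% sp$train,
                                        "train", "test"),
                         pseudo_probability = prob,
                         X, check.names = FALSE,
                         stringsAsFactors = FALSE)
  summary <- list(
    seed = seed,
    n_lesions = nrow(truth), n_excluded = length(excluded),
    excluded_ids = excluded, cluster_fallbacks = fallbacks,
    n_train = length(sp$train), n_test = length(sp$test),
    n_malignant_train = sum(truth$label[sp$train] == "malignant"),
    n_malignant_test = sum(truth$label[sp$test] == "malignant"),
    n_components = pca$n_retained,
    mlp_architecture = sprintf("%d:%d:2", pca$n_retained, mlp$n_hidden),
    mlp_activation = mlp$activation,
    train_auc = roc_train$auc, train_auc_ci = roc_train$auc_ci,
    test_auc = roc_test$auc, test_auc_ci = roc_test$auc_ci,
    thresholds = as.list(thresholds))

  res <- list(features = features, pca = pca, mlp = mlp,
              roc_train = roc_train, roc_test = roc_test,
              thresholds = thresholds,
              reports = list(train = train_reports, test = test_reports),
              split = sp, summary = summary, truth = truth)
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

# Persist the machine-readable artifacts of a pipeline run.
write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(res$roc_test$points, file.path(out_dir, "roc_test.csv"),
                   row.names = FALSE)
  write_pca_json(res$pca, file.path(out_dir, "pca_model.json"))
  write_mlp_json(res$mlp, file.path(out_dir, "mlp_model.json"))
  rep_list <- lapply(res$reports, function(split_reports)
    lapply(split_reports, function(r)
      list(threshold = r$threshold, counts = as.list(r$counts),
           sensitivity = r$sensitivity, sensitivity_ci = r$sensitivity_ci,
           specificity = r$specificity, specificity_ci = r$specificity_ci,
           ppv = r$ppv, npv = r$npv, accuracy = r$accuracy,
           plr = r$plr, nlr = r$nlr,
           avoidable_biopsy_fraction = r$avoidable_biopsy_fraction,
           false_negative_ids = r$false_negative_ids)))
  jsonlite::write_json(c(res$summary, list(reports = rep_list)),
                       file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
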