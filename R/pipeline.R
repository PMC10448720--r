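#' @title End-to-end pipeline orchestration
#' @description Runs the stages -- assay selection, KE scoring,
#'   toxicokinetic overlay, structural clustering, and logistic
#'   modeling -- against a directory of input CSVs, writing each
#'   stage's declared file outputs plus a manifest recording the
#'   configuration hash and seed. Deterministic stages are
#'   bit-identical across reruns with the same config and inputs.
#' @name cli_pipeline
NULL

#' Pipeline configuration
#'
#' Defaults equal the reference analysis settings wherever one is
#' stated: FDR 0.15, 70% similarity cutoff, 0.5 classification
#' threshold, 1 pM - 100 mM grid.
#'
#' @param curve_fits,labels,css,ke_map,smiles Input CSV paths (any may
#'   be NA to skip dependent stages; `css`/`smiles` are only needed for
#'   the overlay/cluster/Model-2 stages).
#' @param points_per_decade Grid density (default 10).
#' @param fdr BH false discovery rate (default 0.15).
#' @param ke_mode KE aggregation: `"mean"` (default) or `"sum"`.
#' @param similarity_cutoff Butina Tanimoto cutoff (default 0.70).
#' @param lambda_per_n Ridge penalty per observation (default 1e-4).
#' @param threshold Classification threshold (fixed at 0.5).
#' @param restrict_to_selected Score KEs over selected assays only
#'   (default TRUE, as in the reference workflow).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(curve_fits, labels, css = NA, ke_map,
                            smiles = NA, points_per_decade = 10L,
                            fdr = 0.15, ke_mode = c("mean", "sum"),
                            similarity_cutoff = 0.70,
                            lambda_per_n = 1e-4, threshold = 0.5,
                            restrict_to_selected = TRUE, seed = 1L) {
  ke_mode <- match.arg(ke_mode)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# Derive a reproducible per-stage seed from the master seed: stage
# names are hashed (md5) and folded into [0, 2^31).
.stage_seed <- function(seed, stage) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(seed, stage), f)
  h <- tools::md5sum(f)[[1]]
  (strtoi(substr(h, 1, 7), 16L) + as.integer(seed)) %% .Machine$integer.max
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(config), file = f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for stage artifacts.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  message("[load] reading inputs")
  fits <- stage("load", read_curve_fits(config$curve_fits))
  labels <- stage("load", read_labels(config$labels))
  ke_map <- stage("load", read_ke_assignments(config$ke_map))
  css <- if (!is.na(config$css)) stage("load", read_css(config$css))
  smiles <- if (!is.na(config$smiles))
    stage("load", read_smiles(config$smiles))
  grid <- build_grid(config$points_per_decade)

  message("[select-assays] Fisher + BH at FDR ", config$fdr)
  sel <- stage("select-assays",
               select_relevant_assays(fits, labels, fdr = config$fdr))
  write_table(sel$results, file.path(out_dir, "assay_selection.csv"))

  message("[ke-scores] ", length(sel$union), " selected assays")
  scored_map <- if (config$restrict_to_selected)
    ke_map[ke_map$assay_id %in% sel$union, , drop = FALSE] else ke_map
  chem_ids <- sort(unique(fits$chem_id))
  surfaces <- stage("ke-scores", build_surfaces(fits, grid))
  scores <- if (nrow(scored_map) > 0)
    stage("ke-scores", ke_score_table(scored_map, surfaces, chem_ids,
                                      grid, mode = config$ke_mode))
  else data.frame(chem_id = character(0), ke_id = character(0),
                  raw_auc = numeric(0), scaled_score = numeric(0))
  write_table(scores, file.path(out_dir, "ke_scores.csv"))
  roc <- if (nrow(scores) > 0) ke_roc_table(scores, labels) else
    data.frame(ke_id = character(0), n_pos = integer(0),
               n_neg = integer(0), roc_auc = numeric(0))
  write_table(roc, file.path(out_dir, "ke_roc.csv"))

  overlay <- NULL
  if (!is.null(css) && nrow(scored_map) > 0) {
    message("[tk-overlay] Css overlay for ", nrow(css), " chemicals")
    overlay <- stage("tk-overlay",
                     realized_activity_table(scored_map, surfaces, css,
                                             grid = grid,
                                             mode = config$ke_mode))
    write_table(overlay, file.path(out_dir, "tk_overlay.csv"))
  }

  clusters <- NULL
  if (!is.null(smiles)) {
    message("[cluster] Butina at cutoff ", config$similarity_cutoff)
    fps <- stage("cluster", morgan_fingerprints(smiles))
    asg <- stage("cluster",
                 butina_cluster(fps, config$similarity_cutoff))
    clusters <- stage("cluster",
                      enriched_clusters(asg, labels,
                                        score_table = if (nrow(scores))
                                          scores))
    cl_out <- merge(asg, clusters$clusters[
      , c("cluster_id", "hepatotoxicant_fraction", "enriched")],
      by = "cluster_id")
    write_table(cl_out, file.path(out_dir, "clusters.csv"))
  }

  models <- NULL
  if (nrow(scores) > 0) {
    message("[fit-models] undersample + LOO logistic models")
    bal_seed <- .stage_seed(config$seed, "fit-models")
    keep <- stage("fit-models", undersample_balance(labels, bal_seed))
    bal_labels <- labels[labels$chem_id %in% keep, , drop = FALSE]
    f1 <- stage("fit-models", assemble_features(scores, bal_labels))
    m1 <- stage("fit-models",
                loo_cv(f1$x, f1$y, model_id = 1L,
                       lambda = config$lambda_per_n * nrow(f1$x)))
    models <- list(model1 = m1)
    if (!is.null(css) && !is.null(smiles)) {
      desc <- stage("fit-models", lipinski_descriptors(smiles))
      f2 <- stage("fit-models",
                  assemble_features(scores, bal_labels, css, desc))
      m2 <- stage("fit-models",
                  loo_cv(f2$x, f2$y, model_id = 2L,
                         lambda = config$lambda_per_n * nrow(f2$x)))
      models$model2 <- m2
      common <- intersect(m1$chem_id, m2$chem_id)
      models$comparison <- compare_models(.subset_result(m1, common),
                                          .subset_result(m2, common))
    }
    preds <- do.call(rbind, lapply(models[grep("^model", names(models))],
      function(m) data.frame(chem_id = m$chem_id, model_id = m$model_id,
                             probability = m$probability,
                             predicted = m$predicted, actual = m$actual,
                             stringsAsFactors = FALSE)))
    write_table(preds, file.path(out_dir, "model_predictions.csv"))
    metrics <- lapply(models[grep("^model", names(models))], function(m)
      list(model_id = m$model_id, n = m$n, TP = m$TP, FP = m$FP,
           TN = m$TN, FN = m$FN, accuracy = m$accuracy,
           recall = m$recall))
    jsonlite::write_json(unname(metrics),
                         file.path(out_dir, "model_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(config_hash = .config_hash(config),
                   seed = config$seed,
                   n_chemicals = length(chem_ids),
                   n_assays = length(unique(fits$assay_id)),
                   n_selected_assays = length(sel$union),
                   outputs = sort(unique(c(list.files(out_dir),
                                           "manifest.json"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(selection = sel, scores = scores, roc = roc,
                 overlay = overlay, clusters = clusters,
                 models = models, manifest = manifest))
}

# Restrict an aop_model_result to a chemical subset (for comparing
# models fit on slightly different assembled sets).
.subset_result <- function(res, chem_ids) {
  i <- match(chem_ids, res$chem_id)
  out <- res
  out$chem_id <- res$chem_id[i]
  out$probability <- res$probability[i]
  out$predicted <- res$predicted[i]
  out$actual <- res$actual[i]
  out$n <- length(i)
  tp <- sum(out$predicted == 1 & out$actual == 1)
  fp <- sum(out$predicted == 1 & out$actual == 0)
  tn <- sum(out$predicted == 0 & out$actual == 0)
  fn <- sum(out$predicted == 0 & out$actual == 1)
  out$TP <- tp; out$FP <- fp; out$TN <- tn; out$FN <- fn
  out$accuracy <- (tp + tn) / out$n
  out$recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  out
}
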