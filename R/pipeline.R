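# End-to-end orchestration. Each stage reads/writes plain artifacts
# (NIfTI / CSV / JSON) under the output directory so any stage can be rerun
# or tested in isolation.

PIPELINE_STAGES <- c("simulate", "prep", "extract", "impute", "compare",
                     "survive", "predict")

#' Default pipeline configuration
#'
#' All defaults match the analysis constants: target voxel spacing
#' 0.75 x 0.75 x 3.0 mm, 32 gray levels, k = 3 imputation, alpha = 0.05,
#' Q3 (0.75) dichotomization quantile, linear-SVM cost grid.
#'
#' @param outDir output directory for stage artifacts.
#' @param seed RNG seed for the simulate and predict stages.
#' @return A nested configuration list (YAML-serializable).
#' @export
pipelineConfig <- function(outDir = "mbrad-out", seed = 1L) {
  list(
    paths = list(out_dir = outDir),
    cohort = list(n_per_subgroup = c(7L, 12L, 8L, 11L),
                  grid_shape = c(32L, 32L, 16L), seed = as.integer(seed)),
    prep = list(target_spacing = c(0.75, 0.75, 3.0)),
    radiomics = list(ng = 32L),
    imputation = list(k = 3L),
    stats = list(alpha = 0.05),
    survival = list(quantile = 0.75),
    prediction = list(algorithm = "mrmr", max_features = 5L,
                      c_grid = c(0.01, 0.1, 1, 10, 100),
                      modality_scope = "all"))
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [pipelineConfig()] defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  def <- pipelineConfig()
  merge2 <- function(d, u) {
    for (k in names(u))
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]]))
        merge2(d[[k]], u[[k]]) else u[[k]]
    d
  }
  merge2(def, user)
}

.log <- function(...) message(sprintf("[mbRadiomics] %s", sprintf(...)))

.featureCsv <- function(dir) file.path(dir, "features.csv")
.completeCsv <- function(dir) file.path(dir, "features_complete.csv")

writeFeatureCSV <- function(table, path) {
  X <- featureMatrix(table)
  df <- data.frame(subject_id = rownames(X), X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

readFeatureCSV <- function(path, clinical) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$subject_id
  storage.mode(X) <- "double"
  RadiomicsFeatureTable(X, clinical)
}

#' Run the pipeline
#'
#' Executes the requested stages in order: `simulate` (synthetic cohort to
#' NIfTI + clinical CSV), `prep` (harmonization), `extract` (feature table
#' CSV), `impute` (k-NN-completed CSV), `compare` (Dunn results CSV + JSON
#' summary), `survive` (Cox/KM JSON + KM table CSV), `predict`
#' (nested-LOOCV report JSON). A stage whose upstream artifact is absent
#' raises a dependency error naming the stage. Rerunning with an identical
#' configuration reproduces artifact content.
#'
#' @param config a [pipelineConfig()] list (or path handled by
#'   [readPipelineConfig()]).
#' @param stages subset of
#'   `c("simulate","prep","extract","impute","compare","survive","predict")`,
#'   or `"all"`.
#' @return Invisible list of per-stage artifact paths.
#' @export
runPipeline <- function(config = pipelineConfig(), stages = "all") {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out <- config$paths$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rawDir <- file.path(out, "raw"); prepDir <- file.path(out, "prep")
  artifacts <- list()
  need <- function(path, stage, upstream) {
    if (!all(file.exists(path)))
      stop(sprintf("stage '%s' requires artifact(s) from '%s': missing %s",
                   stage, upstream, paste(path[!file.exists(path)],
                                          collapse = ", ")))
  }
  clinical <- function() read.csv(file.path(rawDir, "clinical.csv"),
                                  stringsAsFactors = FALSE)

  if ("simulate" %in% stages) {
    cfg <- cohortConfig(nPerSubgroup = config$cohort$n_per_subgroup,
                        gridShape = config$cohort$grid_shape,
                        seed = config$cohort$seed)
    cohort <- generateCohort(cfg)
    writeCohort(cohort, rawDir)
    .log("simulate: %d subjects -> %s", length(subjects(cohort)), rawDir)
    artifacts$simulate <- rawDir
  }
  if ("prep" %in% stages) {
    need(file.path(rawDir, "clinical.csv"), "prep", "simulate")
    cohort <- readCohort(rawDir)
    prepped <- prepareCohort(cohort,
                             targetSpacing = config$prep$target_spacing)
    writeCohort(prepped, prepDir)
    .log("prep: harmonized %d subjects -> %s",
         length(subjects(prepped)), prepDir)
    artifacts$prep <- prepDir
  }
  if ("extract" %in% stages) {
    need(file.path(prepDir, "clinical.csv"), "extract", "prep")
    prepped <- readCohort(prepDir)
    tab <- extractCohortFeatures(prepped, ng = config$radiomics$ng)
    writeFeatureCSV(tab, .featureCsv(out))
    .log("extract: %d x %d feature table -> %s",
         nrow(featureMatrix(tab)), ncol(featureMatrix(tab)),
         .featureCsv(out))
    artifacts$extract <- .featureCsv(out)
  }
  if ("impute" %in% stages) {
    need(.featureCsv(out), "impute", "extract")
    tab <- readFeatureCSV(.featureCsv(out), clinical())
    comp <- knnImpute(tab, k = config$imputation$k)
    writeFeatureCSV(comp, .completeCsv(out))
    .log("impute: k=%d -> %s", config$imputation$k, .completeCsv(out))
    artifacts$impute <- .completeCsv(out)
  }
  if ("compare" %in% stages) {
    need(.completeCsv(out), "compare", "impute")
    tab <- readFeatureCSV(.completeCsv(out), clinical())
    cmp <- compareAllFeatures(tab, alpha = config$stats$alpha)
    write.csv(cmp$results, file.path(out, "dunn_results.csv"),
              row.names = FALSE)
    jsonlite::write_json(cmp$summary, file.path(out, "dunn_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    .log("compare: %d features level>=3", cmp$summary$level3_count +
           cmp$summary$level4_count)
    artifacts$compare <- file.path(out, "dunn_summary.json")
  }
  if ("survive" %in% stages) {
    need(.completeCsv(out), "survive", "impute")
    tab <- readFeatureCSV(.completeCsv(out), clinical())
    sv <- survivalStage(tab, alpha = config$stats$alpha)
    rep0 <- list(significant_univariate = sv$univariate$significant,
                 prognosticator = sv$prognosticator,
                 threshold = sv$threshold,
                 medians = if (!is.null(sv$km)) as.list(sv$km$medians),
                 HR = if (!is.null(sv$km)) sv$km$HR,
                 ciLow = if (!is.null(sv$km)) sv$km$ciLow,
                 ciHigh = if (!is.null(sv$km)) sv$km$ciHigh,
                 logrank_p = if (!is.null(sv$km)) sv$km$p)
    jsonlite::write_json(rep0, file.path(out, "survival.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(sv$km))
      write.csv(sv$km$kmTable, file.path(out, "km_table.csv"),
                row.names = FALSE)
    .log("survive: prognosticator %s",
         sv$prognosticator %||% "(none)")
    artifacts$survive <- file.path(out, "survival.json")
  }
  if ("predict" %in% stages) {
    need(.completeCsv(out), "predict", "impute")
    tab <- readFeatureCSV(.completeCsv(out), clinical())
    rep0 <- nestedLOOCV(tab,
                        algorithm = config$prediction$algorithm,
                        maxFeatures = config$prediction$max_features,
                        Cgrid = config$prediction$c_grid,
                        modality = config$prediction$modality_scope)
    jsonlite::write_json(
      list(accuracy = rep0$accuracy, auc = as.list(rep0$auc),
           algorithm = rep0$algorithm, modality = rep0$modality),
      file.path(out, "prediction.json"), auto_unbox = TRUE, digits = NA)
    .log("predict: ACC %.3f", rep0$accuracy)
    artifacts$predict <- file.path(out, "prediction.json")
  }
  invisible(artifacts)
}
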