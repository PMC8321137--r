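FIRST_ORDER_NAMES <- c(
  "energy", "total.energy", "entropy", "minimum", "p10", "p90", "maximum",
  "mean", "median", "range", "mad", "rms", "skewness", "kurtosis", "sd",
  "uniformity")

SHAPE_NAMES <- c(
  "volume", "surface.area", "surface.to.volume", "sphericity",
  "compactness1", "compactness2", "spherical.disproportion", "max.diameter3D")

GLCM_NAMES <- c(
  "autocorrelation", "cluster.prominence", "cluster.shade",
  "cluster.tendency", "contrast", "correlation", "difference.entropy",
  "dissimilarity", "energy", "entropy", "homogeneity1", "homogeneity2",
  "imc1", "imc2", "idmn", "idn", "inverse.variance", "max.probability",
  "sum.average", "sum.entropy", "sum.variance", "variance")

GLRLM_NAMES <- c(
  "SRE", "LRE", "GLN", "RLN", "RP", "LGLRE", "HGLRE", "SRLGLE", "SRHGLE",
  "LRLGLE", "LRHGLE")

#' The 57-feature radiomics catalog
#'
#' 16 first-order intensity statistics, 8 3D shape features, 22 gray-level
#' co-occurrence (GLCM) and 11 gray-level run-length (GLRLM) texture
#' features. Intensity and texture features (49) are computed per modality
#' over the five MR sequences (CET1, T1WI, T2WI, FLAIR, ADC) giving 245
#' features; shape features are computed once from the tumour mask; 253
#' qualified features in total.
#'
#' @return A data.frame with columns `name`, `category` (`first_order`,
#'   `shape`, `glcm`, `glrlm`), `modality` (`"shape"` for shape features) and
#'   `qualified` (e.g. `"CET1.glcm.contrast"`, `"shape.volume"`), 253 rows.
#' @examples
#' nrow(featureCatalog())      # 253
#' table(featureCatalog()$category)
#' @export
featureCatalog <- function() {
  per <- rbind(
    data.frame(name = FIRST_ORDER_NAMES, category = "first_order"),
    data.frame(name = GLCM_NAMES, category = "glcm"),
    data.frame(name = GLRLM_NAMES, category = "glrlm"))
  out <- do.call(rbind, lapply(MODALITIES, function(m) {
    data.frame(name = per$name, category = per$category, modality = m,
               qualified = paste(m, ifelse(per$category == "first_order",
                                           "fo", per$category),
                                 per$name, sep = "."),
               stringsAsFactors = FALSE)
  }))
  shp <- data.frame(name = SHAPE_NAMES, category = "shape",
                    modality = "shape",
                    qualified = paste("shape", SHAPE_NAMES, sep = "."),
                    stringsAsFactors = FALSE)
  rbind(out, shp)
}

#' Catalog name sets
#'
#' The 57 distinct feature names of the catalog (16 first-order, 8 shape,
#' 22 GLCM, 11 GLRLM).
#'
#' @return Named list of character vectors.
#' @export
catalogNames <- function() {
  list(first_order = FIRST_ORDER_NAMES, shape = SHAPE_NAMES,
       glcm = GLCM_NAMES, glrlm = GLRLM_NAMES)
}
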