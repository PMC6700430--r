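#' @import methods
NULL

#' Catalog of regional/structural morphometry features
#'
#' A \code{FeatureSchema} describes every regional or structural feature the
#' pipeline knows about: its identifier, anatomical region, hemisphere,
#' measure kind (cortical thickness in mm or volume in mm^3), tissue class,
#' the stats table it is read from, and whether it is excluded from analysis
#' (cerebellar structures are excluded because Alzheimer pathology is not
#' expected to drive cerebellar atrophy).
#'
#' @slot entries data.frame with columns \code{feature_id}, \code{region},
#'   \code{hemisphere} (\code{left}/\code{right}/\code{none}),
#'   \code{measure} (\code{thickness}/\code{volume}), \code{tissue}
#'   (\code{cortical_gm}, \code{cortical_wm}, \code{subcortical},
#'   \code{ventricle}, \code{other}), \code{source_table}, \code{excluded}.
#'
#' @seealso [defaultFeatureSchema()]
#' @export
setClass("FeatureSchema", representation(entries = "data.frame"))

setValidity("FeatureSchema", function(object) {
  e <- object@entries
  need <- c("feature_id", "region", "hemisphere", "measure", "tissue",
            "source_table", "excluded")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$feature_id))
    return("feature_id values must be unique")
  if (!all(e$hemisphere %in% c("left", "right", "none")))
    return("hemisphere must be left/right/none")
  if (!all(e$measure %in% c("thickness", "volume")))
    return("measure must be thickness or volume")
  if (!all(e$tissue %in% c("cortical_gm", "cortical_wm", "subcortical",
                           "ventricle", "other")))
    return("unknown tissue class")
  if (any(e$measure == "thickness" & e$tissue != "cortical_gm"))
    return("every thickness feature must have tissue cortical_gm")
  TRUE
})

#' Raw morphometry for one cohort timepoint
#'
#' Subjects-by-features matrix of raw morphometry (thickness in mm, volumes
#' in mm^3 or, after [normalizeToICV()], in percent of intracranial volume),
#' with per-subject cohort labels and intracranial volume.
#'
#' @slot values numeric matrix, subjects x features, dimnames set.
#' @slot cohort character vector, per subject, \code{"CN"} or \code{"MCI"}.
#' @slot timepoint \code{"baseline"} or \code{"m36"}.
#' @slot icv per-subject total intracranial volume (mm^3), strictly positive.
#' @slot schema the [FeatureSchema-class] the columns follow.
#' @slot volumeUnit \code{"mm3"} for raw volumes, \code{"pctICV"} after
#'   ICV scaling.
#'
#' @export
setClass("CohortMatrix",
         representation(values = "matrix", cohort = "character",
                        timepoint = "character", icv = "numeric",
                        schema = "FeatureSchema", volumeUnit = "character"))

setValidity("CohortMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have subject and feature dimnames")
  if (length(object@cohort) != nrow(v))
    return("cohort length must equal subject count")
  if (!all(object@cohort %in% c("CN", "MCI")))
    return("cohort labels must be CN or MCI")
  if (length(object@icv) != nrow(v))
    return("icv length must equal subject count")
  if (any(!is.finite(object@icv)) || any(object@icv <= 0))
    return("icv must be strictly positive")
  if (!object@timepoint %in% c("baseline", "m36"))
    return("timepoint must be baseline or m36")
  if (!object@volumeUnit %in% c("mm3", "pctICV"))
    return("volumeUnit must be mm3 or pctICV")
  keep <- activeFeatures(object@schema)
  if (!identical(colnames(v), keep))
    return("columns must be exactly the schema's non-excluded features, in order")
  if (any(apply(v, 2, function(x) all(is.na(x)))))
    return("no feature column may be entirely missing")
  TRUE
})

#' Robust-Z score matrix
#'
#' Subjects-by-features matrix of robust Z scores: raw values centred on the
#' CN reference median and scaled by 1.3489 / reference IQR, so that under
#' normality the score matches standard-deviation units. The
#' \code{subtracted} dataset holds the 36-month minus baseline difference.
#'
#' @slot values numeric matrix, subjects x features.
#' @slot datasetTag \code{"baseline"}, \code{"m36"} or \code{"subtracted"}.
#' @slot constant the fixed IQR-to-SD normalization constant, 1.3489.
#' @slot degenerate feature ids dropped because the reference IQR was zero.
#'
#' @export
setClass("ZMatrix",
         representation(values = "matrix", datasetTag = "character",
                        constant = "numeric", degenerate = "character"))

setValidity("ZMatrix", function(object) {
  if (!object@datasetTag %in% c("baseline", "m36", "subtracted"))
    return("datasetTag must be baseline/m36/subtracted")
  if (!isTRUE(all.equal(object@constant, 1.3489)))
    return("normalization constant is fixed at 1.3489")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    return("values must have dimnames")
  TRUE
})

#' Per-feature reference statistics from the CN cohort
#'
#' @slot stats data.frame with columns \code{feature_id}, \code{median_ref},
#'   \code{iqr_ref}, \code{n_ref}, \code{degenerate}.
#' @slot timepoint timepoint of the CN reference.
#' @export
setClass("ReferenceStats",
         representation(stats = "data.frame", timepoint = "character"))

setValidity("ReferenceStats", function(object) {
  s <- object@stats
  if (!all(c("feature_id", "median_ref", "iqr_ref", "n_ref", "degenerate")
           %in% names(s)))
    return("stats must have feature_id/median_ref/iqr_ref/n_ref/degenerate")
  if (any(s$iqr_ref < 0)) return("iqr_ref must be >= 0")
  if (any(s$n_ref < 2)) return("n_ref must be >= 2")
  TRUE
})

#' Per-dataset signed networks and their consensus topological overlap
#'
#' Holds, for each input dataset (typically baseline and subtracted robust-Z
#' matrices), the signed adjacency at the chosen soft power, its topological
#' overlap matrix (TOM), the quantile-scaled TOMs, and their elementwise
#' minimum — the consensus TOM — together with the parameters that produced
#' them.
#'
#' @slot power soft-thresholding power beta.
#' @slot fitTable scale-free fit index per candidate power per dataset.
#' @slot powerFallback TRUE when no candidate reached the scale-free
#'   criterion in both datasets and the argmax fallback was used.
#' @slot adjacency named list of adjacency matrices.
#' @slot tom named list of unscaled TOMs.
#' @slot scaledTom named list of quantile-scaled TOMs.
#' @slot scaleExponents per-dataset exponents used in scaling.
#' @slot scaleQuantile the matched quantile (default 0.95).
#' @slot consensus the consensus TOM.
#' @export
setClass("ConsensusNetwork",
         representation(power = "numeric", fitTable = "data.frame",
                        powerFallback = "logical",
                        adjacency = "list", tom = "list",
                        scaledTom = "list", scaleExponents = "numeric",
                        scaleQuantile = "numeric", consensus = "matrix"))

#' Consensus modules, eigengenes and trait correlations
#'
#' @slot assignment named character vector, feature -> module color
#'   (\code{"grey"} = unassigned).
#' @slot dendrogram the average-linkage tree (\code{hclust}) over
#'   1 - consensus TOM.
#' @slot eigengenes named list (per dataset) of subjects x modules matrices.
#' @slot varExplained named list (per dataset) of per-module leading
#'   eigenvalue shares.
#' @slot traitTables named list (per dataset) of long-format module x trait
#'   Spearman correlation tables.
#' @slot params list: h_cut, min_module_size, merge_cut, power, seed, ...
#' @export
setClass("ModuleSet",
         representation(assignment = "character", dendrogram = "ANY",
                        eigengenes = "list", varExplained = "list",
                        traitTables = "list", params = "list"))

setValidity("ModuleSet", function(object) {
  if (is.null(names(object@assignment)))
    return("assignment must be named by feature id")
  sizes <- table(object@assignment[object@assignment != "grey"])
  ms <- object@params$min_module_size
  if (!is.null(ms) && length(sizes) && any(sizes < ms))
    return("all non-grey modules must reach min_module_size")
  TRUE
})

setMethod("show", "FeatureSchema", function(object) {
  e <- object@entries
  cat(sprintf("FeatureSchema: %d features (%d active, %d excluded)\n",
              nrow(e), sum(!e$excluded), sum(e$excluded)))
  cat("  measures:",
      paste(sprintf("%s=%d", names(table(e$measure[!e$excluded])),
                    table(e$measure[!e$excluded])), collapse = ", "), "\n")
})

setMethod("show", "CohortMatrix", function(object) {
  cat(sprintf("CohortMatrix [%s]: %d subjects (%d CN, %d MCI) x %d features; volumes in %s\n",
              object@timepoint, nrow(object@values),
              sum(object@cohort == "CN"), sum(object@cohort == "MCI"),
              ncol(object@values), object@volumeUnit))
})

setMethod("show", "ZMatrix", function(object) {
  cat(sprintf("ZMatrix [%s]: %d subjects x %d features (c = %.4f; %d degenerate dropped)\n",
              object@datasetTag, nrow(object@values), ncol(object@values),
              object@constant, length(object@degenerate)))
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf("ConsensusNetwork: %d features, %d datasets (%s), beta = %d%s\n",
              nrow(object@consensus), length(object@tom),
              paste(names(object@tom), collapse = ", "),
              as.integer(object@power),
              if (object@powerFallback) " [fallback: criterion not reached]" else ""))
})

setMethod("show", "ModuleSet", function(object) {
  a <- object@assignment
  mods <- sort(table(a[a != "grey"]), decreasing = TRUE)
  cat(sprintf("ModuleSet: %d features, %d modules (+%d grey)\n",
              length(a), length(mods), sum(a == "grey")))
  if (length(mods))
    cat("  ", paste(sprintf("%s(%d)", names(mods), mods), collapse = " "), "\n")
})
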