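# Feature catalog: 34 bilateral Desikan-Killiany cortical regions (gray
# matter thickness + white matter volume), 2 unsegmented white matter
# regions, 26 further subcortical structures/parcellations = 164 analysis
# features, plus the cerebellar volumes that are catalogued but excluded.

.dkRegions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

.bilateralSubcortical <- data.frame(
  region = c("Lateral.Ventricle", "Thalamus.Proper", "Caudate", "Putamen",
             "Pallidum", "Hippocampus", "Amygdala", "Accumbens.area",
             "VentralDC"),
  tissue = c("ventricle", "subcortical", "subcortical", "subcortical",
             "subcortical", "subcortical", "subcortical", "subcortical",
             "subcortical"),
  stringsAsFactors = FALSE)

.midlineStructures <- data.frame(
  region = c("3rd.Ventricle", "WM.hypointensities", "non.WM.hypointensities",
             "CC_Anterior", "CC_Mid_Anterior", "CC_Central",
             "CC_Mid_Posterior", "CC_Posterior"),
  tissue = c("ventricle", "other", "other", "other", "other", "other",
             "other", "other"),
  stringsAsFactors = FALSE)

#' Default feature schema (164 regional/structural features)
#'
#' Builds the default catalog: per hemisphere, mean cortical thickness of the
#' 34 Desikan-Killiany regions (68 features) and the corresponding white
#' matter parcellation volumes (68), the left/right unsegmented white matter
#' volumes (2), and 26 subcortical structures/parcellations (volumes),
#' giving 164 analysis features. Cerebellar cortex and white matter volumes
#' are catalogued with \code{excluded = TRUE} and dropped at load time.
#'
#' Feature-id conventions follow the flat table exports: thickness columns
#' carry a \code{.x} (right) or \code{.y} (left) suffix, white matter
#' parcellations a \code{wm.rh.}/\code{wm.lh.} prefix, and subcortical
#' structures a \code{Right.}/\code{Left.} prefix where lateralized.
#'
#' @return a [FeatureSchema-class] with 164 non-excluded features.
#' @examples
#' sch <- defaultFeatureSchema()
#' length(activeFeatures(sch))  # 164
#' @export
defaultFeatureSchema <- function() {
  thick <- data.frame(
    feature_id = c(paste0(.dkRegions, ".x"), paste0(.dkRegions, ".y")),
    region = rep(.dkRegions, 2),
    hemisphere = rep(c("right", "left"), each = length(.dkRegions)),
    measure = "thickness", tissue = "cortical_gm",
    source_table = rep(c("rh.aparc", "lh.aparc"), each = length(.dkRegions)),
    excluded = FALSE, stringsAsFactors = FALSE)

  wm <- data.frame(
    feature_id = c(paste0("wm.rh.", .dkRegions), paste0("wm.lh.", .dkRegions)),
    region = rep(.dkRegions, 2),
    hemisphere = rep(c("right", "left"), each = length(.dkRegions)),
    measure = "volume", tissue = "cortical_wm",
    source_table = "wmparc", excluded = FALSE, stringsAsFactors = FALSE)

  unseg <- data.frame(
    feature_id = c("Right.UnsegmentedWhiteMatter", "Left.UnsegmentedWhiteMatter"),
    region = "UnsegmentedWhiteMatter", hemisphere = c("right", "left"),
    measure = "volume", tissue = "cortical_wm", source_table = "wmparc",
    excluded = FALSE, stringsAsFactors = FALSE)

  bi <- .bilateralSubcortical
  sub <- data.frame(
    feature_id = c(paste0("Right.", bi$region), paste0("Left.", bi$region)),
    region = rep(bi$region, 2),
    hemisphere = rep(c("right", "left"), each = nrow(bi)),
    measure = "volume", tissue = rep(bi$tissue, 2),
    source_table = "aseg", excluded = FALSE, stringsAsFactors = FALSE)

  mid <- data.frame(
    feature_id = .midlineStructures$region,
    region = .midlineStructures$region, hemisphere = "none",
    measure = "volume", tissue = .midlineStructures$tissue,
    source_table = "aseg", excluded = FALSE, stringsAsFactors = FALSE)

  cereb <- data.frame(
    feature_id = c("Right.Cerebellum.Cortex", "Left.Cerebellum.Cortex",
                   "Right.Cerebellum.White.Matter", "Left.Cerebellum.White.Matter"),
    region = rep(c("Cerebellum.Cortex", "Cerebellum.White.Matter"), each = 2),
    hemisphere = rep(c("right", "left"), 2),
    measure = "volume", tissue = "other", source_table = "aseg",
    excluded = TRUE, stringsAsFactors = FALSE)

  methods::new("FeatureSchema",
               entries = rbind(thick, wm, unseg, sub, mid, cereb))
}

# Plausible per-feature reference scales used by the synthetic generator:
# thickness in mm, volumes as percent of ICV.
.referenceScales <- function(schema) {
  e <- schemaEntries(schema)
  mean_ref <- numeric(nrow(e))
  sd_ref <- numeric(nrow(e))
  thick <- e$measure == "thickness"
  mean_ref[thick] <- 2.5
  sd_ref[thick] <- 0.15
  vol <- !thick
  m <- c(cortical_wm = 0.45, subcortical = 0.30, ventricle = 1.00,
         other = 0.08, cortical_gm = NA_real_)
  mean_ref[vol] <- m[e$tissue[vol]]
  sd_ref[vol] <- 0.10 * mean_ref[vol]
  data.frame(feature_id = e$feature_id, measure = e$measure,
             mean_ref = mean_ref, sd_ref = sd_ref,
             excluded = e$excluded, stringsAsFactors = FALSE)
}

# The default planted layout: a bilateral temporal-lobe thickness module
# whose co-atrophy is conversion-linked from baseline, and a bilateral
# parietal-lobe thickness module whose conversion link appears only at the
# 36-month timepoint.
.temporalMembers <- function() {
  r <- c("entorhinal", "middletemporal", "inferiortemporal",
         "superiortemporal", "temporalpole")
  c(paste0(r, ".x"), paste0(r, ".y"))
}

.parietalMembers <- function() {
  r <- c("inferiorparietal", "superiorparietal", "precuneus",
         "supramarginal", "postcentral")
  c(paste0(r, ".x"), paste0(r, ".y"))
}
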