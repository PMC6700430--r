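# One-call orchestration: config -> (simulate | load) -> normalize ->
# univariate -> consensus network -> modules -> trait correlation ->
# results + manifest.

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

.runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Default analysis configuration
#'
#' @param seed simulation seed.
#' @return nested list mirroring the YAML configuration layout: a
#'   \code{simulate} block (passed to [simConfig()]), a \code{network}
#'   block (passed to [networkConfig()]), a \code{modules} block
#'   (\code{min_module_size}, \code{merge_cut}, \code{h_cut_frac}) and the
#'   \code{traits} to correlate with.
#' @export
defaultConfig <- function(seed = 1) {
  list(simulate = list(n_cn = 140, n_mci = 200, seed = seed),
       network = list(power_grid = 1:20, sft_threshold = 0.80,
                      scale_quantile = 0.95, n_bins = 10),
       modules = list(min_module_size = 2, merge_cut = 0.2,
                      h_cut_frac = 0.99),
       traits = c("converted", "adas_speed", "adas_baseline", "age_years"))
}

.mergeConfig <- function(user, default) {
  for (k in names(default)) {
    if (is.null(user[[k]])) user[[k]] <- default[[k]]
    else if (is.list(default[[k]]) && is.list(user[[k]]))
      user[[k]] <- .mergeConfig(user[[k]], default[[k]])
  }
  user
}

.buildTraits <- function(clinical, z, traitNames) {
  speed <- adasProgressionSpeed(clinical)
  tr <- data.frame(row.names = clinical$subject_id,
                   converted = as.numeric(clinical$converted),
                   adas_speed = as.numeric(speed),
                   adas_baseline = clinical$adas_baseline,
                   age_years = clinical$age_years)
  extra <- setdiff(traitNames, names(tr))
  for (cl in extra)
    if (cl %in% names(clinical) && is.numeric(clinical[[cl]]))
      tr[[cl]] <- clinical[[cl]]
  tr[rownames(zValues(z)), intersect(traitNames, names(tr)), drop = FALSE]
}

#' Run the full consensus co-atrophy analysis
#'
#' Executes the whole pipeline: obtain the cohort (from a \code{simulate}
#' block or from FreeSurfer-style stats files named in an \code{inputs}
#' block), ICV-normalize, robust-Z both timepoints against their CN
#' references, derive the subtracted dataset and the ADAS speed trait,
#' compute univariate feature statistics, select the soft power on the
#' baseline and subtracted datasets, build adjacency/TOM/scaled
#' TOM/consensus, detect and merge consensus modules, correlate module
#' eigengenes with traits in both datasets, and (optionally) write all
#' result files plus a machine-readable run manifest.
#'
#' @param config path to a YAML configuration, or an equivalent nested
#'   list; see [defaultConfig()] for the layout.
#' @param seed optional integer overriding the configured simulation seed.
#' @param outdir optional output directory for [writeResults()].
#' @return list: \code{modules} ([ModuleSet-class]), \code{network}
#'   ([ConsensusNetwork-class]), \code{z} (list of the three
#'   [ZMatrix-class] datasets), \code{univariate} (correlation and
#'   importance tables), \code{traits}, \code{clinical}, \code{sim} (when
#'   simulated), \code{manifest}.
#' @export
runConsensusAnalysis <- function(config = defaultConfig(), seed = NULL,
                                 outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .mergeConfig(config, defaultConfig())
  if (!is.null(seed)) config$simulate$seed <- as.integer(seed)

  sim <- NULL
  if (!is.null(config$inputs)) {
    .stageLog("fs_io", "loading stats tables")
    res <- .runStage("fs_io", {
      clin <- loadClinical(config$inputs$clinical)
      schema <- defaultFeatureSchema()
      base <- loadFreeSurferTables(config$inputs$baseline, schema, clin,
                                   timepoint = "baseline")
      m36 <- loadFreeSurferTables(config$inputs$m36, schema, clin,
                                  timepoint = "m36")
      list(base = base, m36 = m36, clin = clin)
    })
  } else {
    .stageLog("synthetic_data", "simulating cohort (seed ",
              config$simulate$seed, ")")
    res <- .runStage("synthetic_data", {
      sc <- do.call(simConfig, config$simulate)
      sim <- simulateCohort(sc)
      list(base = sim$baseline, m36 = sim$m36, clin = sim$clinical,
           sim = sim)
    })
    sim <- res$sim
  }

  .stageLog("normalization", "ICV scaling + robust Z")
  zs <- .runStage("normalization", {
    basePct <- normalizeToICV(res$base)
    m36Pct <- normalizeToICV(res$m36)
    zbase <- robustZ(basePct, referenceStats(basePct))
    zm36 <- robustZ(m36Pct, referenceStats(m36Pct))
    list(baseline = zbase, m36 = zm36,
         subtracted = subtractZ(zm36, zbase))
  })

  .stageLog("univariate", "feature-trait statistics")
  uni <- .runStage("univariate", {
    traitsBase <- .buildTraits(res$clin, zs$baseline, config$traits)
    traitsSub <- .buildTraits(res$clin, zs$subtracted, config$traits)
    impConv <- variableImportance(zs$baseline, traitsBase$converted)
    impAdas <- variableImportance(zs$baseline, traitsBase$adas_speed)
    list(correlations = list(
           baseline = spearmanTraitCorrelations(zs$baseline, traitsBase),
           subtracted = spearmanTraitCorrelations(zs$subtracted, traitsSub)),
         importance = list(converted = impConv, adas_speed = impAdas),
         agreement = importanceAgreement(impConv, impAdas),
         traits = list(baseline = traitsBase, subtracted = traitsSub))
  })

  .stageLog("network_core", "consensus network (baseline + subtracted)")
  net <- .runStage("network_core", {
    cfg <- networkConfig(powerGrid = config$network$power_grid,
                         sftThreshold = config$network$sft_threshold,
                         scaleQuantile = config$network$scale_quantile,
                         nBins = config$network$n_bins)
    buildConsensusNetwork(list(baseline = zs$baseline,
                               subtracted = zs$subtracted), cfg)
  })
  .stageLog("network_core", "soft power beta = ", networkPower(net))

  .stageLog("module_detection", "clustering, cut, merge, colors")
  ms <- .runStage("module_detection", {
    zList <- list(baseline = zs$baseline, subtracted = zs$subtracted)
    dend <- clusterFeatures(consensusMatrix(net))
    hCut <- config$modules$h_cut_frac * max(dend$height)
    m <- detectModules(net, zList, hCut = hCut,
                       minSize = config$modules$min_module_size,
                       mergeCut = config$modules$merge_cut)
    tt <- list(
      baseline = moduleTraitCorrelation(moduleEigengenes(m, "baseline"),
                                        uni$traits$baseline, "baseline"),
      subtracted = moduleTraitCorrelation(moduleEigengenes(m, "subtracted"),
                                          uni$traits$subtracted,
                                          "subtracted"))
    methods::initialize(m, traitTables = tt)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("coatrophy")),
    seed = config$simulate$seed,
    simulated = is.null(config$inputs),
    n_subjects = nrow(morphValues(res$base)),
    n_features = ncol(zValues(zs$baseline)),
    power = networkPower(net),
    power_fallback = net@powerFallback,
    sft_threshold = config$network$sft_threshold,
    scale_quantile = net@scaleQuantile,
    scale_exponents = as.list(net@scaleExponents),
    h_cut = ms@params$h_cut,
    min_module_size = config$modules$min_module_size,
    merge_cut = config$modules$merge_cut,
    quantile_convention = "linear interpolation (type 7)",
    degenerate_features = as.list(zs$baseline@degenerate),
    n_modules = length(setdiff(unique(moduleAssignment(ms)), "grey")))
  ms@params <- utils::modifyList(ms@params, manifest)

  if (!is.null(outdir)) {
    .stageLog("fs_io", "writing results to ", outdir)
    .runStage("fs_io", writeResults(ms, outdir))
  }
  .stageLog("pipeline", "done: ", manifest$n_modules, " modules")
  list(modules = ms, network = net, z = zs, univariate = uni,
       traits = uni$traits, clinical = res$clin, sim = sim,
       manifest = manifest)
}
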