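# Seeded synthetic CN/MCI cohorts with planted co-atrophy modules.
#
# Atrophy is modelled subtractively: each planted module has a latent
# severity factor per MCI subject, and member features lose
# loading * factor * reference-sd from their reference mean, so stronger
# factors mean lower thickness/volume and positively correlated robust-Z
# scores among members.

#' Simulation configuration for the synthetic cohort generator
#'
#' @param n_cn,n_mci subject counts (both >= 10).
#' @param seed integer seed; identical seeds give bitwise-identical cohorts.
#' @param modules list of planted modules, each a list with \code{name},
#'   \code{members} (feature ids), \code{loading} (lambda in (0,1]),
#'   \code{trait_effect} (log-odds of conversion per factor SD),
#'   \code{adas_effect} (ADAS-speed points/month per factor SD) and
#'   \code{timepoint_active} (\code{"baseline"}, \code{"m36"} or
#'   \code{"both"}): when the module's factor drives the clinical traits.
#'   Structural co-atrophy (the loading) is present at both timepoints for
#'   every planted module; a module active only at \code{"m36"} is
#'   trait-independent at baseline and gains its conversion link through the
#'   converter increment at 36 months.
#' @param noise_sd measurement noise SD for module members, in units of the
#'   feature's reference SD.
#' @param progression_sd SD of the per-subject, per-module progression
#'   innovation added to every planted factor at 36 months (heterogeneous
#'   atrophy progression).
#' @param converter_shift increment added at 36 months to the factors of
#'   subjects who converted, for modules active at m36.
#' @param conversion_intercept intercept alpha of the conversion logit.
#' @param icv_log_mean,icv_log_sd log-normal parameters of intracranial
#'   volume (mm^3).
#' @param adas_speed_mean,adas_speed_sd mean/SD (points/month) of the
#'   trait-independent part of MCI ADAS-cog13 progression speed.
#' @param schema a [FeatureSchema-class]; default [defaultFeatureSchema()].
#'
#' @details Defaults plant two bilateral 10-feature thickness modules:
#' a temporal-lobe module whose severity factor drives conversion and ADAS
#' decline from baseline, and a parietal-lobe module that is co-atrophic at
#' both timepoints but becomes conversion-linked only through its 36-month
#' increment — so trait-linked co-atrophy extends from the temporal to the
#' parietal module over follow-up.
#'
#' @return a validated \code{SimConfig} list (class \code{"SimConfig"}).
#' @export
simConfig <- function(n_cn = 140, n_mci = 200, seed = 1,
                      modules = defaultPlantedModules(),
                      noise_sd = 0.5, progression_sd = 1.0,
                      converter_shift = 1.5, conversion_intercept = 0,
                      icv_log_mean = log(1.5e6), icv_log_sd = 0.08,
                      adas_speed_mean = 0.18, adas_speed_sd = 0.1,
                      schema = defaultFeatureSchema()) {
  stopifnot(n_cn >= 10, n_mci >= 10, noise_sd > 0, icv_log_sd >= 0)
  feats <- schemaEntries(schema)$feature_id
  members <- unlist(lapply(modules, `[[`, "members"))
  if (anyDuplicated(members))
    stop("planted module member lists must be disjoint")
  bad <- setdiff(members, feats)
  if (length(bad))
    stop("module members not in schema: ", paste(bad, collapse = ", "))
  for (m in modules) {
    stopifnot(m$loading >= 0, m$loading <= 1,
              m$timepoint_active %in% c("baseline", "m36", "both"))
  }
  structure(list(n_cn = n_cn, n_mci = n_mci, seed = as.integer(seed),
                 modules = modules, noise_sd = noise_sd,
                 progression_sd = progression_sd,
                 converter_shift = converter_shift,
                 conversion_intercept = conversion_intercept,
                 icv_log_mean = icv_log_mean, icv_log_sd = icv_log_sd,
                 adas_speed_mean = adas_speed_mean,
                 adas_speed_sd = adas_speed_sd, schema = schema),
            class = "SimConfig")
}

#' Default planted module layout (temporal + parietal)
#'
#' @return list of two module descriptors: \code{"temporal"} (10 bilateral
#'   temporal thickness features, trait-linked from baseline) and
#'   \code{"parietal"} (10 bilateral parietal thickness features,
#'   trait-linked only at 36 months).
#' @export
defaultPlantedModules <- function() {
  list(
    list(name = "temporal", members = .temporalMembers(), loading = 0.8,
         trait_effect = 1.5, adas_effect = 0.12, timepoint_active = "both"),
    list(name = "parietal", members = .parietalMembers(), loading = 0.8,
         trait_effect = 0, adas_effect = 0, timepoint_active = "m36"))
}

#' Planted feature-to-module truth labels
#'
#' @param config a [simConfig()] object.
#' @return named character vector over the schema's non-excluded features;
#'   members carry their module name, all other features \code{"grey"}.
#'   Independent of the seed.
#' @export
plantedTruth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  feats <- activeFeatures(config$schema)
  truth <- stats::setNames(rep("grey", length(feats)), feats)
  for (m in config$modules) truth[m$members] <- m$name
  truth
}

# Draw one timepoint's feature matrix (all schema features, excluded
# included) given per-subject, per-module factors (0 for CN).
.drawValues <- function(config, factors, subjects) {
  scales <- .referenceScales(config$schema)
  p <- nrow(scales)
  n <- length(subjects)
  vals <- matrix(stats::rnorm(n * p), nrow = n,
                 dimnames = list(subjects, scales$feature_id))
  vals <- sweep(vals, 2, scales$sd_ref, `*`)
  vals <- sweep(vals, 2, scales$mean_ref, `+`)
  for (m in config$modules) {
    idx <- match(m$members, scales$feature_id)
    f <- factors[subjects, m$name]
    # members: mean - lambda*f*sd + N(0, noise_sd*sd)
    noise <- matrix(stats::rnorm(n * length(idx), sd = config$noise_sd),
                    nrow = n)
    noise <- sweep(noise, 2, scales$sd_ref[idx], `*`)
    vals[, idx] <- matrix(scales$mean_ref[idx], n, length(idx), byrow = TRUE) -
      outer(f, m$loading * scales$sd_ref[idx]) + noise
  }
  vals
}

# Convert a value matrix whose volume columns are in %ICV into raw mm^3.
.toRawUnits <- function(vals, schema, icv) {
  scales <- .referenceScales(schema)
  volIdx <- which(scales$measure == "volume")
  vals[, volIdx] <- (vals[, volIdx] / 100) * icv
  vals
}

.makeCohortMatrix <- function(vals, schema, cohort, icv, timepoint) {
  keep <- activeFeatures(schema)
  methods::new("CohortMatrix", values = vals[, keep, drop = FALSE],
               cohort = cohort, timepoint = timepoint, icv = icv,
               schema = schema, volumeUnit = "mm3")
}

#' Generate a synthetic two-timepoint CN/MCI cohort
#'
#' Draws, under a fixed seed, a baseline and a 36-month cohort with planted
#' block-correlated atrophy modules plus clinical traits driven by the
#' module factors, in the units and layout of the FreeSurfer-style exports.
#'
#' Per MCI subject, each planted module m has a baseline severity factor
#' f_m ~ N(0,1). Member features take value
#' mean_ref - loading * f_m * sd_ref + N(0, noise_sd * sd_ref); non-members
#' and all CN features are reference noise mean_ref + N(0, sd_ref).
#' Volumes are drawn on the percent-of-ICV scale and multiplied by the
#' subject's log-normal ICV. Conversion is Bernoulli with logit
#' alpha + sum over baseline-active modules of trait_effect * f_m; ADAS
#' progression speed is a linear combination of the same factors plus noise.
#' At 36 months each factor receives an N(0, progression_sd) innovation and,
#' for modules active at m36, \code{converter_shift} more for converters, so
#' conversion-linked co-atrophy extends to the second planted module.
#'
#' @param config a [simConfig()].
#' @return list with elements \code{baseline}, \code{m36}
#'   ([CohortMatrix-class]), \code{clinical} (data.frame), \code{truth}
#'   (from [plantedTruth()]), \code{factors} (per-subject latent factors,
#'   baseline and m36) and \code{fullValues} (both timepoints including
#'   excluded cerebellar columns, for fixture writing).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  schema <- config$schema
  cn_ids <- sprintf("CN%03d", seq_len(config$n_cn))
  mci_ids <- sprintf("MCI%03d", seq_len(config$n_mci))
  subjects <- c(cn_ids, mci_ids)
  cohort <- c(rep("CN", config$n_cn), rep("MCI", config$n_mci))
  modNames <- vapply(config$modules, `[[`, "", "name")

  # latent factors: 0 for CN, N(0,1) per module for MCI
  fac <- matrix(0, length(subjects), length(modNames),
                dimnames = list(subjects, modNames))
  fac[mci_ids, ] <- stats::rnorm(config$n_mci * length(modNames))

  # conversion and ADAS speed from baseline-trait-active modules
  eta <- rep(config$conversion_intercept, config$n_mci)
  speed <- stats::rnorm(config$n_mci, config$adas_speed_mean,
                        config$adas_speed_sd)
  for (m in config$modules) {
    if (m$timepoint_active %in% c("baseline", "both")) {
      eta <- eta + m$trait_effect * fac[mci_ids, m$name]
      speed <- speed + m$adas_effect * fac[mci_ids, m$name]
    }
  }
  converted <- stats::rbinom(config$n_mci, 1, stats::plogis(eta))

  # 36-month factors: progression innovation + converter increment
  fac36 <- fac
  for (m in config$modules) {
    fac36[mci_ids, m$name] <- fac[mci_ids, m$name] +
      stats::rnorm(config$n_mci, 0, config$progression_sd)
    if (m$timepoint_active %in% c("m36", "both"))
      fac36[mci_ids, m$name] <- fac36[mci_ids, m$name] +
        config$converter_shift * converted
  }

  icv <- stats::setNames(
    stats::rlnorm(length(subjects), config$icv_log_mean, config$icv_log_sd),
    subjects)

  valsBase <- .toRawUnits(.drawValues(config, fac, subjects), schema, icv)
  valsM36 <- .toRawUnits(.drawValues(config, fac36, subjects), schema, icv)

  age <- round(c(stats::rnorm(config$n_cn, 68, 4),
                 stats::rnorm(config$n_mci, 74, 4)), 1)
  sex <- sample(c("F", "M"), length(subjects), replace = TRUE)
  adas0 <- round(pmax(0, c(stats::rnorm(config$n_cn, 7.5, 2.5),
                           stats::rnorm(config$n_mci, 20, 5))), 1)
  cnSpeed <- stats::rnorm(config$n_cn, -0.02, 0.06)
  allSpeed <- c(cnSpeed, speed)
  clinical <- data.frame(
    subject_id = subjects, cohort = cohort, age_years = age, sex = sex,
    adas_baseline = adas0,
    adas_last = round(adas0 + 36 * allSpeed, 1),
    adas_last_month = 36L,
    converted = c(rep(NA, config$n_cn), converted),
    stringsAsFactors = FALSE)

  list(baseline = .makeCohortMatrix(valsBase, schema, cohort, icv, "baseline"),
       m36 = .makeCohortMatrix(valsM36, schema, cohort, icv, "m36"),
       clinical = clinical, truth = plantedTruth(config),
       factors = list(baseline = fac, m36 = fac36),
       fullValues = list(baseline = valsBase, m36 = valsM36),
       icv = icv, config = config)
}

#' Write a simulated cohort as FreeSurfer-style fixture files
#'
#' Emits, under \code{dir}, the four tab-separated stats tables per
#' timepoint (\code{baseline/} and \code{m36/} subdirectories) plus one
#' \code{clinical.csv}, in exactly the formats [loadFreeSurferTables()] and
#' [loadClinical()] read. Cerebellar columns are included in the aseg table
#' (the parser must drop them), and the aseg table carries the
#' \code{EstimatedTotalIntraCranialVol} column.
#'
#' @param sim output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFixtures <- function(sim, dir) {
  e <- schemaEntries(sim$config$schema)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tp in c("baseline", "m36")) {
    tpdir <- file.path(dir, tp)
    dir.create(tpdir, showWarnings = FALSE)
    vals <- sim$fullValues[[tp]]
    for (tab in c("lh.aparc", "rh.aparc", "aseg", "wmparc")) {
      cols <- e$feature_id[e$source_table == tab]
      df <- data.frame(subject_id = rownames(vals),
                       vals[, cols, drop = FALSE],
                       check.names = FALSE, stringsAsFactors = FALSE)
      if (tab == "aseg")
        df$EstimatedTotalIntraCranialVol <- sim$icv[rownames(vals)]
      p <- file.path(tpdir, paste0(tab, ".stats.tsv"))
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  cp <- file.path(dir, "clinical.csv")
  utils::write.csv(sim$clinical, cp, row.names = FALSE, quote = FALSE)
  invisible(c(paths, cp))
}
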