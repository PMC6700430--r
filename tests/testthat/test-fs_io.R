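test_that("default schema catalogs exactly 164 analysis features", {
  sch <- defaultFeatureSchema()
  e <- schemaEntries(sch)
  act <- e[!e$excluded, ]
  expect_equal(nrow(act), 164)
  expect_equal(sum(act$measure == "thickness"), 68)
  expect_equal(sum(act$measure == "volume"), 96)
  expect_false(anyDuplicated(e$feature_id) > 0)
  expect_true(all(act$tissue[act$measure == "thickness"] == "cortical_gm"))
  cereb <- e[grepl("Cerebellum", e$feature_id), ]
  expect_gt(nrow(cereb), 0)
  expect_true(all(cereb$excluded))
})

test_that("fixtures round-trip through the FreeSurfer-style parser", {
  sim <- cachedSmallSim()
  dir <- withr::local_tempdir()
  writeFixtures(sim, dir)
  clin <- loadClinical(file.path(dir, "clinical.csv"))
  paths <- list(
    "lh.aparc" = file.path(dir, "baseline", "lh.aparc.stats.tsv"),
    "rh.aparc" = file.path(dir, "baseline", "rh.aparc.stats.tsv"),
    "aseg" = file.path(dir, "baseline", "aseg.stats.tsv"),
    "wmparc" = file.path(dir, "baseline", "wmparc.stats.tsv"))
  cm <- loadFreeSurferTables(paths, defaultFeatureSchema(), clin)
  expect_s4_class(cm, "CohortMatrix")
  expect_equal(ncol(morphValues(cm)), 164)
  expect_false(any(grepl("Cerebellum", colnames(morphValues(cm)))))
  # lossless up to the text formatting precision (>= 12 significant digits)
  orig <- morphValues(sim$baseline)[rownames(morphValues(cm)), ]
  expect_equal(morphValues(cm), orig, tolerance = 1e-12)
  expect_equal(unname(subjectICV(cm)),
               unname(sim$icv[rownames(morphValues(cm))]),
               tolerance = 1e-12)
})

test_that("parsing is order-independent under row permutation", {
  sim <- cachedSmallSim()
  dir <- withr::local_tempdir()
  writeFixtures(sim, dir)
  clin <- loadClinical(file.path(dir, "clinical.csv"))
  paths <- as.list(file.path(dir, "baseline",
                             paste0(c("lh.aparc", "rh.aparc", "aseg",
                                      "wmparc"), ".stats.tsv")))
  names(paths) <- c("lh.aparc", "rh.aparc", "aseg", "wmparc")
  cm1 <- loadFreeSurferTables(paths, defaultFeatureSchema(), clin)
  # permute the rows of one table
  tab <- utils::read.delim(paths$aseg, check.names = FALSE)
  set.seed(11)
  utils::write.table(tab[sample(nrow(tab)), ], paths$aseg, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cm2 <- loadFreeSurferTables(paths, defaultFeatureSchema(), clin)
  expect_equal(morphValues(cm1), morphValues(cm2), tolerance = 1e-12)
})

test_that("parser enforces ICV, subject intersection, and unknown columns", {
  sim <- cachedSmallSim()
  dir <- withr::local_tempdir()
  writeFixtures(sim, dir)
  clin <- loadClinical(file.path(dir, "clinical.csv"))
  paths <- as.list(file.path(dir, "baseline",
                             paste0(c("lh.aparc", "rh.aparc", "aseg",
                                      "wmparc"), ".stats.tsv")))
  names(paths) <- c("lh.aparc", "rh.aparc", "aseg", "wmparc")

  # drop the ICV column -> hard error naming it
  aseg <- utils::read.delim(paths$aseg, check.names = FALSE)
  noicv <- file.path(dir, "aseg_noicv.tsv")
  utils::write.table(aseg[, setdiff(names(aseg), "EstimatedTotalIntraCranialVol")],
                     noicv, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paths; p2$aseg <- noicv
  expect_error(loadFreeSurferTables(p2, defaultFeatureSchema(), clin),
               "EstimatedTotalIntraCranialVol")

  # drop one subject from one table -> error listing the id
  dropped <- aseg$subject_id[3]
  part <- file.path(dir, "aseg_partial.tsv")
  utils::write.table(aseg[aseg$subject_id != dropped, ], part, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p3 <- paths; p3$aseg <- part
  expect_error(loadFreeSurferTables(p3, defaultFeatureSchema(), clin),
               dropped)

  # an unknown column is ignored with a warning
  lh <- utils::read.delim(paths$"lh.aparc", check.names = FALSE)
  lh$MeanThickness.y <- 2.4
  utils::write.table(lh, paths$"lh.aparc", sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_warning(cm <- loadFreeSurferTables(paths, defaultFeatureSchema(),
                                            clin),
                 "MeanThickness")
  expect_equal(ncol(morphValues(cm)), 164)
})

test_that("clinical loader types rows and rejects malformed tables", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "clin.csv")
  writeLines(c("subject_id,cohort,age_years,adas_baseline,adas_last,adas_last_month",
               "S1,CN,68,7.5,7.0,36",
               "S2,MCI,75,21,,36",
               "S3,MCI,73,18,27,36"), p)
  clin <- suppressMessages(loadClinical(p))
  expect_equal(nrow(clin), 3)
  expect_true(is.na(clin$adas_last[2]))
  expect_type(clin$age_years, "double")

  writeLines(c("subject_id,cohort", "S1,CN", "S1,MCI"), p)
  expect_error(loadClinical(p), "duplicate")

  writeLines(c("subject_id,cohort", "S1,AD"), p)
  expect_error(loadClinical(p), "cohort")
})

test_that("result writer emits a complete, lossless file set", {
  run <- cachedRun()
  dir <- withr::local_tempdir()
  files <- writeResults(run$modules, dir)
  expect_true(all(file.exists(files)))
  expect_true(all(c("assignment", "eigengenes_baseline",
                    "module_trait_baseline", "manifest") %in% names(files)))

  asn <- utils::read.csv(files["assignment"])
  expect_equal(nrow(asn), 164)
  expect_equal(sort(asn$feature_id),
               sort(names(moduleAssignment(run$modules))))

  eg <- utils::read.csv(files["eigengenes_baseline"], check.names = FALSE)
  orig <- moduleEigengenes(run$modules, "baseline")
  expect_equal(unname(as.matrix(eg[, -1])),
               unname(orig[, colnames(eg)[-1], drop = FALSE]),
               tolerance = 1e-12)

  man <- jsonlite::read_json(files["manifest"])
  expect_true(all(c("power", "merge_cut", "seed", "h_cut") %in% names(man)))
})
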