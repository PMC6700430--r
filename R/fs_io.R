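# Readers for FreeSurfer-style flat table exports (one row per subject,
# one column per region) and the clinical table; writers for all pipeline
# outputs.

.icvColumn <- "EstimatedTotalIntraCranialVol"

#' Load the four FreeSurfer-style stats tables into a CohortMatrix
#'
#' Reads the \code{lh.aparc}, \code{rh.aparc}, \code{aseg} and \code{wmparc}
#' tab-separated exports, merges them by subject id, drops excluded
#' (cerebellar) columns, and returns a typed [CohortMatrix-class] containing
#' exactly the schema's 164 non-excluded features. The subject set is the
#' strict intersection: a subject present in only some of the four files is
#' an error (silent partial rows would corrupt correlations downstream).
#'
#' @param paths named character vector or list with elements
#'   \code{lh.aparc}, \code{rh.aparc}, \code{aseg}, \code{wmparc}.
#' @param schema a [FeatureSchema-class].
#' @param clinical data.frame from [loadClinical()] (supplies cohort labels),
#'   or a named character vector of CN/MCI labels.
#' @param timepoint \code{"baseline"} or \code{"m36"}.
#' @return a [CohortMatrix-class] in raw units (mm / mm^3).
#' @export
loadFreeSurferTables <- function(paths, schema, clinical,
                                 timepoint = "baseline") {
  need <- c("lh.aparc", "rh.aparc", "aseg", "wmparc")
  if (is.null(names(paths)) || !all(need %in% names(paths)))
    stop("paths must be named: ", paste(need, collapse = ", "))
  e <- schemaEntries(schema)
  tabs <- lapply(need, function(tab) {
    df <- utils::read.delim(paths[[tab]], check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(df))
      stop("table '", tab, "' has no subject_id column")
    if (tab == "aseg" && !.icvColumn %in% names(df))
      stop("aseg table is missing the required ICV column '",
           .icvColumn, "'")
    known <- c("subject_id", e$feature_id,
               if (tab == "aseg") .icvColumn)
    unknown <- setdiff(names(df), known)
    if (length(unknown)) {
      warning("ignoring unknown column(s) in ", tab, ": ",
              paste(unknown, collapse = ", "))
      df <- df[, setdiff(names(df), unknown), drop = FALSE]
    }
    if (anyDuplicated(df$subject_id))
      stop("duplicate subject_id in ", tab)
    df
  })
  names(tabs) <- need

  ids <- lapply(tabs, function(d) d$subject_id)
  common <- Reduce(intersect, ids)
  all_ids <- Reduce(union, ids)
  partial <- setdiff(all_ids, common)
  if (length(partial))
    stop("subject(s) present in only some tables: ",
         paste(sort(partial), collapse = ", "))
  common <- sort(common)

  keep <- activeFeatures(schema)
  mats <- lapply(need, function(tab) {
    df <- tabs[[tab]]
    df <- df[match(common, df$subject_id), , drop = FALSE]
    want <- intersect(e$feature_id[e$source_table == tab & !e$excluded],
                      keep)
    missing <- setdiff(want, names(df))
    if (length(missing))
      stop("table '", tab, "' is missing schema column(s): ",
           paste(missing, collapse = ", "))
    as.matrix(df[, want, drop = FALSE])
  })
  vals <- do.call(cbind, mats)
  rownames(vals) <- common
  vals <- vals[, keep, drop = FALSE]

  icv <- tabs$aseg[match(common, tabs$aseg$subject_id), .icvColumn]
  if (any(!is.finite(icv)) || any(icv <= 0))
    stop("non-positive or missing ICV for subject(s): ",
         paste(common[!is.finite(icv) | icv <= 0], collapse = ", "))

  if (is.data.frame(clinical)) {
    cohort <- stats::setNames(clinical$cohort, clinical$subject_id)
  } else cohort <- clinical
  absent <- setdiff(common, names(cohort))
  if (length(absent))
    stop("no cohort label for subject(s): ", paste(absent, collapse = ", "))

  methods::new("CohortMatrix", values = vals,
               cohort = unname(cohort[common]), timepoint = timepoint,
               icv = as.numeric(icv), schema = schema, volumeUnit = "mm3")
}

#' Load the clinical table
#'
#' Reads a comma-separated clinical table with at least \code{subject_id}
#' and \code{cohort} columns; numeric columns are typed, and unparseable
#' numeric cells become missing values (counted in a message). The
#' \code{converted} flag is meaningful only for MCI rows; values on CN rows
#' are blanked with a warning.
#'
#' @param path path to the CSV file.
#' @return a typed data.frame.
#' @export
loadClinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("subject_id", "cohort") %in% names(df)))
    stop("clinical table must have subject_id and cohort columns")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in clinical table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  bad <- setdiff(unique(df$cohort), c("CN", "MCI"))
  if (length(bad))
    stop("cohort values outside {CN, MCI}: ", paste(bad, collapse = ", "))

  numCols <- setdiff(names(df), c("subject_id", "cohort", "sex", "converted"))
  n_bad <- 0L
  for (cl in numCols) {
    x <- df[[cl]]
    xn <- suppressWarnings(as.numeric(as.character(x)))
    n_bad <- n_bad + sum(is.na(xn) & !is.na(x) & trimws(as.character(x)) != "")
    df[[cl]] <- xn
  }
  if (n_bad > 0)
    message("loadClinical: ", n_bad,
            " unparseable numeric cell(s) set to missing")
  if ("converted" %in% names(df)) {
    df$converted <- as.logical(df$converted)
    cnconv <- df$cohort == "CN" & !is.na(df$converted)
    if (any(cnconv)) {
      warning("converted flag set on ", sum(cnconv),
              " CN row(s); blanked (defined only for MCI)")
      df$converted[cnconv] <- NA
    }
  }
  df
}

#' Write the full result set of a consensus run
#'
#' Writes, under \code{outdir}: the feature-to-module assignment table, one
#' eigengene matrix per dataset, one module-by-trait correlation table per
#' dataset (rho and p per cell), the dendrogram in Newick form, and a
#' machine-readable JSON run manifest recording every analysis parameter
#' (soft power, cut height, merge cut, scale exponents, seed, drops).
#' All tables are comma-separated, written at full double precision so a
#' read-back is lossless to at least 12 significant digits.
#'
#' @param moduleset a [ModuleSet-class].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
writeResults <- function(moduleset, outdir) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- c()
  asn <- moduleAssignment(moduleset)
  write.csv2 <- function(d, f) {
    p <- file.path(outdir, f)
    utils::write.csv(d, p, row.names = FALSE, quote = FALSE)
    p
  }
  files["assignment"] <- write.csv2(
    data.frame(feature_id = names(asn), module = unname(asn),
               stringsAsFactors = FALSE), "module_assignment.csv")
  for (ds in names(moduleset@eigengenes)) {
    eg <- moduleset@eigengenes[[ds]]
    files[paste0("eigengenes_", ds)] <- write.csv2(
      data.frame(subject_id = rownames(eg), eg, check.names = FALSE),
      paste0("eigengenes_", ds, ".csv"))
  }
  for (ds in names(moduleset@traitTables)) {
    files[paste0("module_trait_", ds)] <- write.csv2(
      moduleset@traitTables[[ds]], paste0("module_trait_", ds, ".csv"))
  }
  if (!is.null(moduleset@dendrogram)) {
    p <- file.path(outdir, "dendrogram.nwk")
    ape::write.tree(ape::as.phylo(moduleset@dendrogram), file = p)
    files["dendrogram"] <- p
  }
  p <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(moduleset@params, p, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files["manifest"] <- p
  invisible(files)
}
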