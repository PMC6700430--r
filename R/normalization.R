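# Robust-Z normalization against the CN reference cohort, ICV scaling of
# volumes, the subtracted (longitudinal) dataset, and the ADAS-cog13
# progression-speed trait.

#' The IQR-to-SD normalization constant, 1.3489
#'
#' Returns the spread of the standard normal distribution between its 25th
#' and 75th percentiles, truncated (not rounded) to 4 decimals: 1.3489.
#' Multiplying an IQR-scaled deviation by this constant makes the robust Z
#' score match standard-deviation units under normality. The pipeline uses
#' the fixed literal 1.3489 for reproducibility.
#'
#' @param digits number of decimals to truncate to.
#' @return the truncated constant.
#' @export
iqrNormalConstant <- function(digits = 4) {
  spread <- stats::qnorm(0.75) - stats::qnorm(0.25)
  trunc(spread * 10^digits) / 10^digits
}

.ROBUST_Z_C <- 1.3489

#' Express volume features as a percentage of intracranial volume
#'
#' Every volume feature is replaced by 100 * volume / ICV of its subject;
#' cortical thickness features are left unchanged (thickness is not a
#' head-size-dependent quantity).
#'
#' @param m a [CohortMatrix-class] in raw units.
#' @return a [CohortMatrix-class] with \code{volumeUnit = "pctICV"}.
#' @export
normalizeToICV <- function(m) {
  stopifnot(is(m, "CohortMatrix"))
  if (m@volumeUnit == "pctICV") stop("volumes already ICV-normalized")
  bad <- !is.finite(m@icv) | m@icv <= 0
  if (any(bad))
    stop("non-positive ICV for subject(s): ",
         paste(rownames(m@values)[bad], collapse = ", "))
  e <- schemaEntries(m@schema)
  volCols <- intersect(colnames(m@values),
                       e$feature_id[e$measure == "volume"])
  v <- m@values
  v[, volCols] <- 100 * v[, volCols] / m@icv
  methods::initialize(m, values = v, volumeUnit = "pctICV")
}

#' Per-feature reference statistics from the CN cohort
#'
#' Computes, per feature, the median and interquartile range (75th minus
#' 25th percentile, linear-interpolation quantiles) over the CN subjects of
#' the matching timepoint. Features whose reference IQR is zero are flagged
#' degenerate (a zero-spread reference makes the robust Z undefined) and
#' dropped by [robustZ()].
#'
#' @param m a [CohortMatrix-class]; only its CN rows are used.
#' @return a [ReferenceStats-class].
#' @export
referenceStats <- function(m) {
  stopifnot(is(m, "CohortMatrix"))
  cn <- m@values[m@cohort == "CN", , drop = FALSE]
  stat <- lapply(colnames(cn), function(f) {
    x <- cn[, f]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      stop("feature '", f, "' is all-missing in the CN reference")
    if (length(x) < 2)
      stop("fewer than 2 CN reference values for feature '", f, "'")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(feature_id = f, median_ref = q[2], iqr_ref = q[3] - q[1],
               n_ref = length(x), degenerate = (q[3] - q[1]) == 0,
               stringsAsFactors = FALSE)
  })
  out <- methods::new("ReferenceStats", stats = do.call(rbind, stat),
                      timepoint = m@timepoint)
  deg <- degenerateFeatures(out)
  if (length(deg))
    warning("degenerate reference (IQR = 0) for feature(s): ",
            paste(deg, collapse = ", "))
  out
}

#' Robust Z scores against a CN reference
#'
#' Z = (raw - median_ref) * 1.3489 / IQR_ref, elementwise, where the
#' constant 1.3489 is the standard-normal 25-75% quantile spread so that
#' IQR scaling matches SD scaling for normal data. Degenerate features
#' (reference IQR zero) are dropped with a logged list. Subjects missing
#' more than \code{maxMissing} of their features are dropped with a warning;
#' remaining missing raw values propagate as missing Z.
#'
#' @param m a [CohortMatrix-class], normally ICV-normalized.
#' @param ref a [ReferenceStats-class] from the same timepoint.
#' @param cohort which rows to score: \code{"MCI"} (default), \code{"CN"},
#'   or \code{"all"}.
#' @param maxMissing maximum tolerated per-subject missing fraction.
#' @return a [ZMatrix-class] tagged with the cohort matrix's timepoint.
#' @export
robustZ <- function(m, ref, cohort = "MCI", maxMissing = 0.2) {
  stopifnot(is(m, "CohortMatrix"), is(ref, "ReferenceStats"))
  rs <- referenceTable(ref)
  if (!identical(sort(rs$feature_id), sort(colnames(m@values))))
    stop("feature mismatch between cohort matrix and reference stats")
  if (!identical(ref@timepoint, m@timepoint))
    stop("reference timepoint (", ref@timepoint,
         ") does not match cohort matrix (", m@timepoint, ")")
  rows <- if (cohort == "all") rep(TRUE, nrow(m@values)) else m@cohort == cohort
  v <- m@values[rows, , drop = FALSE]

  missFrac <- rowMeans(is.na(v))
  dropSubj <- missFrac > maxMissing
  if (any(dropSubj)) {
    warning("dropping ", sum(dropSubj), " subject(s) missing > ",
            round(100 * maxMissing), "% of features: ",
            paste(rownames(v)[dropSubj], collapse = ", "))
    v <- v[!dropSubj, , drop = FALSE]
  }

  rs <- rs[match(colnames(v), rs$feature_id), ]
  keep <- !rs$degenerate
  if (any(!keep))
    message("robustZ: dropping ", sum(!keep), " degenerate feature(s): ",
            paste(rs$feature_id[!keep], collapse = ", "))
  z <- sweep(v[, keep, drop = FALSE], 2, rs$median_ref[keep], `-`)
  z <- sweep(z, 2, .ROBUST_Z_C / rs$iqr_ref[keep], `*`)
  methods::new("ZMatrix", values = z, datasetTag = m@timepoint,
               constant = .ROBUST_Z_C, degenerate = rs$feature_id[!keep])
}

#' Subtracted (longitudinal) robust-Z dataset
#'
#' Per-subject difference of 36-month and baseline robust-Z matrices over
#' the subjects present at both timepoints; represents net longitudinal
#' atrophy change over follow-up.
#'
#' @param z36,zbase [ZMatrix-class] objects tagged \code{m36} and
#'   \code{baseline}.
#' @return a [ZMatrix-class] tagged \code{subtracted}.
#' @export
subtractZ <- function(z36, zbase) {
  stopifnot(is(z36, "ZMatrix"), is(zbase, "ZMatrix"))
  feats <- intersect(colnames(z36@values), colnames(zbase@values))
  if (length(feats) == 0) stop("no shared features between the Z matrices")
  extra <- length(union(colnames(z36@values), colnames(zbase@values))) -
    length(feats)
  if (extra > 0)
    message("subtractZ: ", extra,
            " feature(s) present in only one dataset; using the intersection")
  subj <- intersect(rownames(z36@values), rownames(zbase@values))
  if (length(subj) == 0)
    stop("no subjects present at both timepoints")
  vals <- z36@values[subj, feats, drop = FALSE] -
    zbase@values[subj, feats, drop = FALSE]
  methods::new("ZMatrix", values = vals, datasetTag = "subtracted",
               constant = .ROBUST_Z_C,
               degenerate = union(z36@degenerate, zbase@degenerate))
}

#' ADAS-cog13 progression speed (points per month)
#'
#' (last score - baseline score) / months between baseline and the last
#' ADAS visit. Missing inputs give a missing speed (the subject is
#' retained); a zero-month interval with differing scores is an error.
#'
#' @param clinical data.frame with \code{adas_baseline}, \code{adas_last}
#'   and \code{adas_last_month} columns (e.g. from [loadClinical()]).
#' @return named numeric vector of speeds, one per clinical row.
#' @export
adasProgressionSpeed <- function(clinical) {
  stopifnot(all(c("adas_baseline", "adas_last", "adas_last_month")
                %in% names(clinical)))
  d <- clinical$adas_last - clinical$adas_baseline
  mo <- clinical$adas_last_month
  if (any(!is.na(mo) & mo < 0)) stop("adas_last_month must be >= 0")
  zero_bad <- !is.na(mo) & mo == 0 & !is.na(d) & d != 0
  if (any(zero_bad))
    stop("zero follow-up interval with differing ADAS scores for: ",
         paste(clinical$subject_id[zero_bad], collapse = ", "))
  speed <- ifelse(!is.na(mo) & mo == 0, 0, d / mo)
  n_na <- sum(is.na(speed))
  if (n_na > 0)
    message("adasProgressionSpeed: ", n_na, " missing speed(s)")
  stats::setNames(speed, clinical$subject_id)
}
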