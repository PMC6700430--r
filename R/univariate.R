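# Per-feature univariate statistics: Spearman trait correlations with BH
# correction, and variable importance (ROC-AUC for binary traits, R^2 for
# continuous ones, min-max scaled to 0-100).

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH over one correction family: sort ascending, take
#' adj_i = min over j >= i of p_j * m / j, clip at 1, return in input order.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values (FDR) in input order.
#' @export
bhAdjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] <= 0 | pvalues[ok] > 1))
    stop("p-values must lie in (0, 1]")
  out <- pvalues
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

.spearmanCell <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Spearman correlations between features and clinical traits
#'
#' Computes, per feature x trait, Spearman's rho and the two-sided p-value
#' under pairwise-complete deletion, then applies BH correction separately
#' within each trait column (one family per heatmap column). Cells with
#' fewer than 3 pairs or a constant variable are returned missing.
#'
#' @param z a [ZMatrix-class] or numeric subjects x features matrix.
#' @param traits data.frame or matrix of numeric trait columns, rows
#'   aligned by subject id with \code{z}.
#' @return long-format data.frame: feature, trait, rho, p, fdr, n.
#' @export
spearmanTraitCorrelations <- function(z, traits) {
  zv <- if (is(z, "ZMatrix")) zValues(z) else z
  traits <- as.data.frame(traits)
  if (!is.null(rownames(traits)) && !is.null(rownames(zv)) &&
      all(rownames(zv) %in% rownames(traits)))
    traits <- traits[rownames(zv), , drop = FALSE]
  if (nrow(traits) != nrow(zv))
    stop("traits rows must align with the Z matrix subjects")
  out <- do.call(rbind, lapply(names(traits), function(tr) {
    cells <- t(apply(zv, 2, .spearmanCell, y = traits[[tr]]))
    df <- data.frame(feature = colnames(zv), trait = tr,
                     rho = cells[, "rho"], p = cells[, "p"],
                     n = as.integer(cells[, "n"]),
                     stringsAsFactors = FALSE, row.names = NULL)
    # a perfect monotone relation gives p = 0 in floating point; clamp so
    # the (0,1] contract of bhAdjust holds
    df$fdr <- bhAdjust(pmax(df$p, .Machine$double.xmin))
    df
  }))
  n_bad <- sum(is.na(out$rho))
  if (n_bad > 0)
    message("spearmanTraitCorrelations: ", n_bad,
            " undefined cell(s) (constant variable or < 3 pairs)")
  out[, c("feature", "trait", "rho", "p", "fdr", "n")]
}

# Mann-Whitney AUC via the rank identity, midranks for ties.
.rankAUC <- function(x, cls) {
  ok <- !is.na(x) & !is.na(cls)
  x <- x[ok]; cls <- cls[ok]
  n1 <- sum(cls); n0 <- sum(!cls)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(x)
  u <- sum(r[cls]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Per-feature variable importance for a clinical trait
#'
#' For a binary trait, raw importance is the discriminating ROC-AUC per
#' feature (rank/U-statistic identity, midrank ties), folded to be
#' direction-agnostic as max(AUC, 1 - AUC). For a continuous trait, raw
#' importance is the per-feature R^2; by default the squared Pearson
#' correlation, or any per-feature predictor supplied through
#' \code{predictor}. Raw importances are then min-max rescaled across
#' features to [0, 100].
#'
#' @param z a [ZMatrix-class] or numeric subjects x features matrix.
#' @param trait numeric or logical vector aligned with the subjects; treated
#'   as binary when it has exactly two distinct non-missing values.
#' @param predictor optional function(feature_values, trait) returning an
#'   R^2 in [0, 1], used for continuous traits instead of squared Pearson
#'   correlation.
#' @return data.frame: feature, raw (AUC or R^2), scaled (0-100), type.
#' @export
variableImportance <- function(z, trait, predictor = NULL) {
  zv <- if (is(z, "ZMatrix")) zValues(z) else z
  if (length(trait) != nrow(zv))
    stop("trait length must equal subject count")
  lv <- unique(trait[!is.na(trait)])
  binary <- length(lv) == 2
  if (length(lv) < 2) stop("trait has a single class/value")
  if (binary) {
    cls <- trait == max(lv)
    raw <- apply(zv, 2, function(x) {
      a <- .rankAUC(x, cls)
      if (is.na(a)) NA_real_ else max(a, 1 - a)
    })
    type <- "auc"
  } else if (!is.null(predictor)) {
    raw <- apply(zv, 2, predictor, trait = trait)
    type <- "r2_custom"
  } else {
    raw <- apply(zv, 2, function(x) {
      ok <- !is.na(x) & !is.na(trait)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0) return(NA_real_)
      stats::cor(x[ok], trait[ok])^2
    })
    type <- "r2"
  }
  rng <- range(raw, na.rm = TRUE)
  scaled <- if (diff(rng) == 0) rep(0, length(raw)) else
    100 * (raw - rng[1]) / diff(rng)
  data.frame(feature = colnames(zv), raw = unname(raw),
             scaled = unname(scaled), type = type,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Agreement between two per-feature importance rankings
#'
#' Spearman correlation across features between two importance tables
#' (e.g. importance for conversion vs importance for ADAS progression
#' speed).
#'
#' @param imp1,imp2 data.frames from [variableImportance()] over the same
#'   feature set.
#' @return list with \code{rho} and \code{p}.
#' @export
importanceAgreement <- function(imp1, imp2) {
  if (!identical(imp1$feature, imp2$feature))
    stop("importance tables must cover the same features in the same order")
  ct <- suppressWarnings(
    stats::cor.test(imp1$raw, imp2$raw, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
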