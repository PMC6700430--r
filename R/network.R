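# Signed weighted network construction: Spearman correlation, signed
# soft-thresholded adjacency, scale-free fit and power selection,
# topological overlap, cross-dataset quantile scaling, consensus TOM.

#' Network construction parameters
#'
#' @param powerGrid candidate soft powers (sorted ascending integers).
#' @param sftThreshold scale-free fit index a power must reach in every
#'   dataset (default 0.80).
#' @param scaleQuantile quantile matched when scaling TOMs across datasets.
#' @param nBins equal-width connectivity bins for the scale-free fit.
#' @return a validated list of class \code{"NetworkConfig"}.
#' @export
networkConfig <- function(powerGrid = 1:20, sftThreshold = 0.80,
                          scaleQuantile = 0.95, nBins = 10) {
  stopifnot(length(powerGrid) >= 1, all(powerGrid >= 1),
            !is.unsorted(powerGrid),
            sftThreshold > 0, sftThreshold < 1,
            scaleQuantile > 0, scaleQuantile < 1, nBins >= 2)
  structure(list(powerGrid = as.integer(powerGrid),
                 sftThreshold = sftThreshold,
                 scaleQuantile = scaleQuantile, nBins = as.integer(nBins)),
            class = "NetworkConfig")
}

#' Pairwise Spearman correlation matrix of features
#'
#' @param z a [ZMatrix-class] or numeric subjects x features matrix
#'   (>= 3 subjects); pairwise-complete observations.
#' @return symmetric features x features matrix with unit diagonal.
#' @export
correlationMatrix <- function(z) {
  zv <- if (is(z, "ZMatrix")) zValues(z) else z
  if (nrow(zv) < 3) stop("need at least 3 subjects")
  sds <- apply(zv, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    stop("constant feature(s) make Spearman rho undefined: ",
         paste(colnames(zv)[is.na(sds) | sds == 0], collapse = ", "))
  s <- stats::cor(zv, method = "spearman", use = "pairwise.complete.obs")
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Signed soft-thresholded adjacency
#'
#' a_ij = ((1 + s_ij) / 2) ^ beta off-diagonal, unit diagonal: the signed
#' transform maps correlation -1 to adjacency 0 and +1 to 1, and the power
#' beta emphasizes large adjacencies while suppressing small ones without a
#' hard cutoff.
#'
#' @param s symmetric correlation matrix in [-1, 1].
#' @param beta soft power (>= 1).
#' @return adjacency matrix in [0, 1], attribute \code{"power"} set.
#' @export
signedAdjacency <- function(s, beta) {
  if (beta < 1) stop("soft power beta must be >= 1")
  if (max(abs(s - t(s))) > 1e-8) stop("correlation matrix must be symmetric")
  if (min(s) < -1 - 1e-12 || max(s) > 1 + 1e-12)
    stop("correlations must lie in [-1, 1]")
  a <- ((1 + s) / 2)^beta
  diag(a) <- 1
  attr(a, "power") <- beta
  a
}

#' Scale-free topology fit index
#'
#' Bins node connectivity k_i = sum_j a_ij (j != i) into \code{nBins}
#' equal-width bins, regresses log10(bin frequency) on log10(bin mean k)
#' over usable bins, and returns R^2 times minus the sign of the slope —
#' positive only for decaying (power-law-like) degree distributions.
#'
#' @param a adjacency matrix from [signedAdjacency()].
#' @param nBins number of equal-width connectivity bins.
#' @return fit index in [-1, 1]; 0 (with a warning) when degenerate.
#' @export
scaleFreeFit <- function(a, nBins = 10) {
  if (nrow(a) < 3) stop("need at least 3 features")
  k <- rowSums(a) - diag(a)
  if (diff(range(k)) < .Machine$double.eps^0.5 * max(1, max(k))) {
    warning("all connectivities identical; scale-free fit undefined")
    return(0)
  }
  bins <- cut(k, breaks = seq(min(k), max(k), length.out = nBins + 1),
              include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  use <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(use) < 2) {
    warning("fewer than 2 usable connectivity bins; returning 0")
    return(0)
  }
  fit <- stats::lm(log10(freq[use]) ~ log10(kmean[use]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  unname(r2 * (-sign(slope)))
}

#' Select the soft power by the scale-free criterion across datasets
#'
#' Returns the lowest candidate power whose scale-free fit index reaches
#' \code{sftThreshold} in every dataset. If no candidate qualifies, falls
#' back to the power maximizing the minimum fit across datasets and emits a
#' prominent warning.
#'
#' @param zList named list of [ZMatrix-class] objects (or matrices).
#' @param cfg a [networkConfig()].
#' @return list: \code{power}, \code{fitTable} (power x dataset fit
#'   indices, long data.frame), \code{fallback} flag.
#' @export
pickSoftPower <- function(zList, cfg = networkConfig()) {
  stopifnot(length(zList) >= 1)
  if (is.null(names(zList))) names(zList) <- paste0("dataset", seq_along(zList))
  cors <- lapply(zList, correlationMatrix)
  fitTable <- do.call(rbind, lapply(cfg$powerGrid, function(b) {
    fits <- vapply(cors, function(s)
      scaleFreeFit(signedAdjacency(s, b), cfg$nBins), numeric(1))
    data.frame(power = b, dataset = names(zList), fit = unname(fits),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  minFit <- tapply(fitTable$fit, fitTable$power, min)
  grid <- as.integer(names(minFit))
  ok <- which(minFit >= cfg$sftThreshold)
  if (length(ok)) {
    power <- grid[min(ok)]
    fallback <- FALSE
  } else {
    power <- grid[which.max(minFit)]
    fallback <- TRUE
    warning("no candidate power reached scale-free fit ",
            cfg$sftThreshold, " in all datasets; falling back to beta = ",
            power, " (max of min-across-dataset fit = ",
            signif(max(minFit), 3), ")")
  }
  list(power = power, fitTable = fitTable, fallback = fallback)
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' l_ij = sum over u != i,j of a_iu * a_uj and k_i = sum over u != i of
#' a_iu; the diagonal is set to 1. Combines direct connection strength with
#' shared-neighbour strength; 1 - TOM is the clustering dissimilarity.
#'
#' @param a adjacency matrix (symmetric, [0, 1], unit diagonal).
#' @return TOM in [0, 1].
#' @export
computeTOM <- function(a) {
  stopifnot(nrow(a) == ncol(a))
  d <- diag(a)
  aa <- a %*% a
  # remove u = i and u = j terms from the path counts
  l <- aa - outer(d, rep(1, ncol(a))) * a - a * outer(rep(1, nrow(a)), d)
  k <- rowSums(a) - d
  denom <- outer(k, k, pmin) + 1 - a
  diag(denom) <- 1  # diagonal is overwritten below; keep the guard off it
  if (any(denom <= 0)) stop("non-positive TOM denominator")
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

.upperTri <- function(m) m[upper.tri(m)]

#' Scale TOMs across datasets by quantile matching
#'
#' Each TOM is raised elementwise to the exponent
#' log(q_target) / log(q_s), where q_s is the q-th quantile of that TOM's
#' off-diagonal entries. By default the target is the geometric mean of the
#' per-dataset quantiles, which makes the scaling — and hence the consensus
#' — independent of dataset order; passing \code{reference = i} instead
#' matches every TOM to dataset i's quantile (that TOM's exponent is then
#' exactly 1). After scaling all TOMs share the same q-th quantile, and a
#' power transform keeps values in [0, 1] and preserves ranks.
#'
#' @param toms named list of >= 2 TOMs with identical dimensions.
#' @param q quantile to match (default 0.95).
#' @param reference optional index of a reference TOM; \code{NULL}
#'   (default) uses the symmetric geometric-mean target.
#' @return list: \code{scaled} (list of TOMs), \code{exponents} (per
#'   dataset), \code{target} (the shared quantile value).
#' @export
scaleTOMs <- function(toms, q = 0.95, reference = NULL) {
  stopifnot(length(toms) >= 2)
  dims <- vapply(toms, nrow, 1L)
  if (length(unique(dims)) != 1 ||
      any(vapply(toms, ncol, 1L) != dims[1]))
    stop("all TOMs must share dimensions")
  # type-1 (order statistic) quantile: a monotone power transform then maps
  # the quantile exactly, so the scaled TOMs share it to machine precision
  qs <- vapply(toms, function(m)
    stats::quantile(.upperTri(m), q, names = FALSE, type = 1), numeric(1))
  if (any(qs <= 0 | qs >= 1))
    stop("degenerate TOM: scaling quantile at 0 or 1")
  target <- if (is.null(reference)) exp(mean(log(qs))) else qs[reference]
  expo <- log(target) / log(qs)
  scaled <- lapply(seq_along(toms), function(i) {
    m <- toms[[i]]^expo[i]
    diag(m) <- 1
    m
  })
  names(scaled) <- names(toms)
  names(expo) <- names(toms)
  list(scaled = scaled, exponents = expo, target = target)
}

#' Consensus topological overlap
#'
#' Elementwise minimum of the (scaled) TOMs: an edge is only as strong in
#' the consensus as it is in its weakest dataset, so consensus modules are
#' preserved in every dataset.
#'
#' @param scaled list of aligned scaled TOMs.
#' @return consensus TOM with unit diagonal.
#' @export
consensusTOM <- function(scaled) {
  stopifnot(length(scaled) >= 1)
  dims <- vapply(scaled, dim, integer(2))
  if (any(dims != dims[, 1])) stop("TOM dimension mismatch")
  cons <- Reduce(pmin, scaled)
  diag(cons) <- 1
  dimnames(cons) <- dimnames(scaled[[1]])
  cons
}

#' Build per-dataset networks and the consensus TOM in one call
#'
#' Convenience wrapper: picks the soft power over all datasets by the
#' scale-free criterion, builds signed adjacencies and TOMs, scales the
#' TOMs to a shared quantile and takes their elementwise minimum.
#'
#' @param zList named list of [ZMatrix-class] objects (typically
#'   \code{baseline} and \code{subtracted}).
#' @param cfg a [networkConfig()].
#' @return a [ConsensusNetwork-class].
#' @export
buildConsensusNetwork <- function(zList, cfg = networkConfig()) {
  pick <- pickSoftPower(zList, cfg)
  cors <- lapply(zList, correlationMatrix)
  adj <- lapply(cors, signedAdjacency, beta = pick$power)
  toms <- lapply(adj, computeTOM)
  sc <- scaleTOMs(toms, cfg$scaleQuantile)
  cons <- consensusTOM(sc$scaled)
  methods::new("ConsensusNetwork", power = as.numeric(pick$power),
               fitTable = pick$fitTable, powerFallback = pick$fallback,
               adjacency = adj, tom = toms, scaledTom = sc$scaled,
               scaleExponents = sc$exponents,
               scaleQuantile = cfg$scaleQuantile, consensus = cons)
}
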