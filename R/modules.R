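# Consensus module detection: average-linkage clustering of 1 - consensus
# TOM, static branch cut with a minimum module size, eigengene-based module
# merging, standard color labelling, and module-trait correlation.

.wgcnaColors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
  "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
  "brown4", "bisque4", "darkslateblue", "plum2", "thistle2", "thistle1",
  "salmon4", "palevioletred3", "navajowhite2", "maroon", "lightpink4",
  "lavenderblush3", "honeydew1", "darkseagreen4", "coral1",
  "antiquewhite4", "coral2")

#' Hierarchical clustering of the consensus TOM
#'
#' Average-linkage clustering on the TOM-based dissimilarity 1 - TOM;
#' modules are branches of the resulting dendrogram.
#'
#' @param consensus consensus TOM (features x features).
#' @return an \code{hclust} tree.
#' @export
clusterFeatures <- function(consensus) {
  if (nrow(consensus) < 2) stop("need at least 2 features to cluster")
  stats::hclust(stats::as.dist(1 - consensus), method = "average")
}

#' Static branch cut with a minimum module size
#'
#' Cuts the dendrogram at height \code{hCut} (default 0.99 times the
#' maximum merge height); branches with at least \code{minSize} members
#' become provisional modules, smaller branches go to grey (label 0).
#'
#' @param dendrogram an \code{hclust} tree from [clusterFeatures()].
#' @param hCut cut height in (0, max merge height].
#' @param minSize minimum module size (default 2 regions/structures).
#' @return named integer vector: provisional module labels (0 = grey),
#'   numbered by descending module size.
#' @export
cutTree <- function(dendrogram, hCut = NULL, minSize = 2) {
  hmax <- max(dendrogram$height)
  if (hmax == 0) {  # all features identical: a single module
    labels <- stats::cutree(dendrogram, h = 0)
    return(labels)
  }
  if (is.null(hCut)) hCut <- 0.99 * hmax
  if (hCut <= 0 || hCut > hmax)
    stop("hCut must lie in (0, max merge height = ", signif(hmax, 4), "]")
  labels <- stats::cutree(dendrogram, h = hCut)
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < minSize])
  labels[labels %in% small] <- 0L
  # renumber surviving branches by descending size, ties by first feature
  keep <- sort(unique(labels[labels != 0L]))
  if (length(keep)) {
    ord <- order(-as.integer(table(factor(labels[labels != 0L],
                                          levels = keep))),
                 match(keep, labels))
    relabel <- stats::setNames(seq_along(keep), keep[ord])
    labels[labels != 0L] <- relabel[as.character(labels[labels != 0L])]
  }
  labels
}

#' Module eigengene (first principal component)
#'
#' First principal component of the column-standardized member submatrix,
#' used as the module's representative atrophy profile. Missing cells are
#' imputed at the member mean (0 after standardization, logged);
#' zero-variance members are dropped with a warning. The eigengene is
#' standardized to unit SD and its sign is chosen so that its correlation
#' with the member-mean profile is non-negative.
#'
#' @param z a [ZMatrix-class] or subjects x features matrix.
#' @param members feature ids of the module (>= 1).
#' @return list: \code{eigengene} (named per-subject score),
#'   \code{varExplained} (leading eigenvalue share in [0, 1]),
#'   \code{members} (those used).
#' @export
moduleEigengene <- function(z, members) {
  zv <- if (is(z, "ZMatrix")) zValues(z) else z
  stopifnot(length(members) >= 1)
  miss <- setdiff(members, colnames(zv))
  if (length(miss))
    stop("member feature(s) not in matrix: ", paste(miss, collapse = ", "))
  x <- zv[, members, drop = FALSE]
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warning("dropping zero-variance member(s): ",
            paste(members[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
    if (ncol(x) == 0) stop("no members with variance remain")
  }
  x <- scale(x)
  nimp <- sum(is.na(x))
  if (nimp > 0) {
    message("moduleEigengene: imputing ", nimp, " missing cell(s) at the member mean")
    x[is.na(x)] <- 0
  }
  sv <- svd(x)
  e <- sv$u[, 1]
  e <- e / stats::sd(e)
  mprof <- rowMeans(x)
  if (stats::sd(mprof) > 0 && stats::cor(e, mprof) < 0) e <- -e
  list(eigengene = stats::setNames(as.numeric(e), rownames(zv)),
       varExplained = sv$d[1]^2 / sum(sv$d^2),
       members = colnames(x))
}

.eigengeneMatrix <- function(zv, assignment, labels = NULL) {
  if (is.null(labels)) labels <- setdiff(unique(assignment), c(0L, "grey"))
  out <- lapply(labels, function(l) {
    moduleEigengene(zv, names(assignment)[assignment == l])
  })
  names(out) <- as.character(labels)
  out
}

#' Merge modules with similar consensus eigengenes
#'
#' Iteratively merges the pair of provisional modules whose consensus
#' eigengene dissimilarity — the maximum over datasets of
#' 1 - cor(eigengene_1, eigengene_2) — is smallest and below
#' \code{mergeCut}, recomputing the merged module's eigengene after every
#' merge, until no pair qualifies. A cut of 0.2 corresponds to requiring
#' at least 0.8 eigengene similarity in every dataset for a merge.
#'
#' @param assignment named vector from [cutTree()] (0/\code{"grey"} =
#'   unassigned).
#' @param zList named list of [ZMatrix-class] objects (the datasets the
#'   consensus is built from).
#' @param mergeCut dissimilarity threshold (default 0.2).
#' @return assignment of the same form with merged labels.
#' @export
mergeModules <- function(assignment, zList, mergeCut = 0.2) {
  zvs <- lapply(zList, function(z) if (is(z, "ZMatrix")) zValues(z) else z)
  greyLab <- if (is.character(assignment)) "grey" else 0L
  repeat {
    labels <- setdiff(unique(assignment), greyLab)
    if (length(labels) < 2) break
    egs <- lapply(zvs, .eigengeneMatrix, assignment = assignment,
                  labels = labels)
    pairs <- utils::combn(seq_along(labels), 2)
    diss <- apply(pairs, 2, function(pr) {
      max(vapply(egs, function(eg) {
        1 - stats::cor(eg[[pr[1]]]$eigengene, eg[[pr[2]]]$eigengene)
      }, numeric(1)))
    })
    if (min(diss) >= mergeCut) break
    best <- pairs[, which.min(diss)]
    from <- labels[best[2]]; into <- labels[best[1]]
    assignment[assignment == from] <- into
  }
  assignment
}

#' Standard module color labels
#'
#' Orders non-grey modules by descending size (ties by first member index)
#' and assigns the conventional color sequence (turquoise, blue, brown,
#' yellow, ...); unassigned features become \code{"grey"}.
#'
#' @param assignment named vector of module labels (0/\code{"grey"} =
#'   unassigned).
#' @return named character vector of color labels.
#' @export
assignColors <- function(assignment) {
  greyLab <- if (is.character(assignment)) "grey" else 0L
  labels <- setdiff(unique(assignment), greyLab)
  out <- stats::setNames(rep("grey", length(assignment)), names(assignment))
  if (length(labels)) {
    sizes <- vapply(labels, function(l) sum(assignment == l), numeric(1))
    first <- vapply(labels, function(l) which(assignment == l)[1], numeric(1))
    ord <- order(-sizes, first)
    colors <- if (length(labels) <= length(.wgcnaColors))
      .wgcnaColors[seq_along(labels)] else
        c(.wgcnaColors, paste0("module", seq_len(length(labels) -
                                                   length(.wgcnaColors))))
    for (i in seq_along(ord))
      out[assignment == labels[ord[i]]] <- colors[i]
  }
  out
}

#' Correlate module eigengenes with clinical traits
#'
#' Spearman rho and two-sided p per module x trait for one dataset; the
#' grey (unassigned) pseudo-module is included but flagged. All-missing
#' trait columns are skipped with a warning.
#'
#' @param eigengenes subjects x modules matrix (may include a \code{grey}
#'   column).
#' @param traits data.frame of numeric traits, rows aligned by subject id.
#' @param dataset tag recorded in the output.
#' @param adjust when TRUE, add a BH-adjusted \code{fdr} column (one
#'   correction family per trait); p-values are always reported raw.
#' @return long-format data.frame: module, trait, rho, p, n, is_grey,
#'   dataset (and \code{fdr} when \code{adjust}).
#' @export
moduleTraitCorrelation <- function(eigengenes, traits,
                                   dataset = "baseline", adjust = FALSE) {
  traits <- as.data.frame(traits)
  if (!is.null(rownames(traits)) && !is.null(rownames(eigengenes)) &&
      all(rownames(eigengenes) %in% rownames(traits)))
    traits <- traits[rownames(eigengenes), , drop = FALSE]
  if (nrow(traits) != nrow(eigengenes))
    stop("trait rows must align with eigengene subjects")
  keep <- vapply(traits, function(x) !all(is.na(x)), logical(1))
  if (any(!keep))
    warning("skipping all-missing trait(s): ",
            paste(names(traits)[!keep], collapse = ", "))
  traits <- traits[, keep, drop = FALSE]
  out <- do.call(rbind, lapply(names(traits), function(tr) {
    cells <- t(apply(eigengenes, 2, .spearmanCell, y = traits[[tr]]))
    df <- data.frame(module = colnames(eigengenes), trait = tr,
                     rho = cells[, "rho"], p = cells[, "p"],
                     n = as.integer(cells[, "n"]),
                     is_grey = colnames(eigengenes) == "grey",
                     dataset = dataset, stringsAsFactors = FALSE,
                     row.names = NULL)
    if (adjust) df$fdr <- bhAdjust(pmax(df$p, .Machine$double.xmin))
    df
  }))
  out
}

#' Adjusted Rand index against the planted truth
#'
#' Agreement between a detected module assignment and the generating
#' labels, with grey treated as its own cluster; 1 = identical partitions,
#' 0 = chance agreement.
#'
#' @param assignment named character vector of detected labels.
#' @param truth named character vector from [plantedTruth()] over the same
#'   features.
#' @return the adjusted Rand index.
#' @export
recoveryScore <- function(assignment, truth) {
  if (!setequal(names(assignment), names(truth)))
    stop("assignment and truth must cover the same features")
  truth <- truth[names(assignment)]
  mclust::adjustedRandIndex(assignment, truth)
}

#' Detect consensus modules end to end
#'
#' Runs clustering, static cut, minimum-size filtering, eigengene-based
#' merging and color assignment on a consensus TOM, then computes per-
#' dataset eigengenes (including the grey pseudo-module).
#'
#' @param network a [ConsensusNetwork-class] (or a consensus TOM matrix).
#' @param zList named list of [ZMatrix-class] objects.
#' @param hCut static cut height; default 0.99 x max merge height.
#' @param minSize minimum module size (default 2).
#' @param mergeCut eigengene-merge threshold (default 0.2).
#' @return a [ModuleSet-class] (trait tables empty; see
#'   [moduleTraitCorrelation()]).
#' @export
detectModules <- function(network, zList, hCut = NULL, minSize = 2,
                          mergeCut = 0.2) {
  cons <- if (is(network, "ConsensusNetwork")) consensusMatrix(network)
          else network
  dend <- clusterFeatures(cons)
  prov <- cutTree(dend, hCut = hCut, minSize = minSize)
  names(prov) <- colnames(cons)
  merged <- mergeModules(prov, zList, mergeCut = mergeCut)
  colors <- assignColors(merged)

  egs <- list(); ve <- list()
  mods <- setdiff(unique(colors), "grey")
  for (ds in names(zList)) {
    zv <- zValues(zList[[ds]])
    cols <- c(mods, if (any(colors == "grey")) "grey")
    mat <- matrix(NA_real_, nrow(zv), length(cols),
                  dimnames = list(rownames(zv), cols))
    vex <- stats::setNames(numeric(length(cols)), cols)
    for (mod in cols) {
      eg <- moduleEigengene(zv, names(colors)[colors == mod])
      mat[, mod] <- eg$eigengene
      vex[mod] <- eg$varExplained
    }
    egs[[ds]] <- mat
    ve[[ds]] <- vex
  }
  methods::new("ModuleSet", assignment = colors, dendrogram = dend,
               eigengenes = egs, varExplained = ve, traitTables = list(),
               params = list(h_cut = if (is.null(hCut))
                 0.99 * max(dend$height) else hCut,
                 min_module_size = minSize, merge_cut = mergeCut,
                 power = if (is(network, "ConsensusNetwork"))
                   networkPower(network) else NA))
}
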