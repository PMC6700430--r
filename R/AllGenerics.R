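#' Accessors for coatrophy classes
#'
#' Small accessor family in the Bioconductor style: user code should reach
#' slots through these, never through \code{@}.
#'
#' @param x a coatrophy S4 object.
#' @param dataset for [ModuleSet-class] accessors, which dataset
#'   (\code{"baseline"}, \code{"subtracted"}, ...) to return.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("schemaEntries", function(x) standardGeneric("schemaEntries"))
#' @rdname accessors
#' @export
setMethod("schemaEntries", "FeatureSchema", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("activeFeatures", function(x) standardGeneric("activeFeatures"))
#' @rdname accessors
#' @export
setMethod("activeFeatures", "FeatureSchema",
          function(x) x@entries$feature_id[!x@entries$excluded])
#' @rdname accessors
#' @export
setMethod("activeFeatures", "CohortMatrix",
          function(x) activeFeatures(x@schema))

#' @rdname accessors
#' @export
setGeneric("morphValues", function(x) standardGeneric("morphValues"))
#' @rdname accessors
#' @export
setMethod("morphValues", "CohortMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setMethod("cohortLabels", "CohortMatrix", function(x) {
  stats::setNames(x@cohort, rownames(x@values))
})

#' @rdname accessors
#' @export
setGeneric("subjectICV", function(x) standardGeneric("subjectICV"))
#' @rdname accessors
#' @export
setMethod("subjectICV", "CohortMatrix", function(x) {
  stats::setNames(x@icv, rownames(x@values))
})

#' @rdname accessors
#' @export
setGeneric("featureSchema", function(x) standardGeneric("featureSchema"))
#' @rdname accessors
#' @export
setMethod("featureSchema", "CohortMatrix", function(x) x@schema)

#' @rdname accessors
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
#' @rdname accessors
#' @export
setMethod("zValues", "ZMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))
#' @rdname accessors
#' @export
setMethod("datasetTag", "ZMatrix", function(x) x@datasetTag)

#' @rdname accessors
#' @export
setGeneric("degenerateFeatures", function(x) standardGeneric("degenerateFeatures"))
#' @rdname accessors
#' @export
setMethod("degenerateFeatures", "ZMatrix", function(x) x@degenerate)
#' @rdname accessors
#' @export
setMethod("degenerateFeatures", "ReferenceStats",
          function(x) x@stats$feature_id[x@stats$degenerate])

#' @rdname accessors
#' @export
setGeneric("referenceTable", function(x) standardGeneric("referenceTable"))
#' @rdname accessors
#' @export
setMethod("referenceTable", "ReferenceStats", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("networkPower", function(x) standardGeneric("networkPower"))
#' @rdname accessors
#' @export
setMethod("networkPower", "ConsensusNetwork", function(x) x@power)

#' @rdname accessors
#' @export
setGeneric("scaledTOMs", function(x) standardGeneric("scaledTOMs"))
#' @rdname accessors
#' @export
setMethod("scaledTOMs", "ConsensusNetwork", function(x) x@scaledTom)

#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setMethod("consensusMatrix", "ConsensusNetwork", function(x) x@consensus)

#' @rdname accessors
#' @export
setGeneric("fitTable", function(x) standardGeneric("fitTable"))
#' @rdname accessors
#' @export
setMethod("fitTable", "ConsensusNetwork", function(x) x@fitTable)

#' @rdname accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname accessors
#' @export
setMethod("moduleAssignment", "ModuleSet", function(x) x@assignment)

#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(x, dataset) standardGeneric("moduleEigengenes"))
#' @rdname accessors
#' @export
setMethod("moduleEigengenes", "ModuleSet", function(x, dataset) {
  if (missing(dataset)) return(x@eigengenes)
  x@eigengenes[[dataset]]
})

#' @rdname accessors
#' @export
setGeneric("traitTables", function(x, dataset) standardGeneric("traitTables"))
#' @rdname accessors
#' @export
setMethod("traitTables", "ModuleSet", function(x, dataset) {
  if (missing(dataset)) return(x@traitTables)
  x@traitTables[[dataset]]
})

#' @rdname accessors
#' @export
setGeneric("runParams", function(x) standardGeneric("runParams"))
#' @rdname accessors
#' @export
setMethod("runParams", "ModuleSet", function(x) x@params)
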