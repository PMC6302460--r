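#' Accessors for pathway collections and related objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a [PathwayCollection], [GeneSet], [PathwayTopology],
#'   [IntegratedInput] or [SimTruth].
#' @param value replacement value (for setters).
#'
#' @return `pathwayIds` and `targetIds` return character vectors;
#'   `geneSets` and `topologies` return named lists; `members` returns the
#'   gene symbols of a set or topology; `deGenes`, `background` and
#'   `rankedProfile` return the corresponding pieces of an
#'   [IntegratedInput]; `plantedIds` the planted pathway ids of a
#'   [SimTruth].
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("topologies", function(x) standardGeneric("topologies"))

#' @rdname accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname accessors
#' @export
setGeneric("targetIds<-", function(x, value) standardGeneric("targetIds<-"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("deGenes", function(x) standardGeneric("deGenes"))

#' @rdname accessors
#' @export
setGeneric("combinedFc", function(x) standardGeneric("combinedFc"))

#' @rdname accessors
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname accessors
#' @export
setGeneric("rankedProfile", function(x) standardGeneric("rankedProfile"))

#' @rdname accessors
#' @export
setGeneric("plantedIds", function(x) standardGeneric("plantedIds"))

#' @rdname accessors
#' @export
setMethod("pathwayIds", "PathwayCollection",
          function(x) names(x@geneSets))

#' @rdname accessors
#' @export
setMethod("geneSets", "PathwayCollection", function(x) x@geneSets)

#' @rdname accessors
#' @export
setMethod("topologies", "PathwayCollection", function(x) x@topologies)

#' @rdname accessors
#' @export
setMethod("targetIds", "PathwayCollection", function(x) x@targetIds)

#' @rdname accessors
#' @export
setReplaceMethod("targetIds", "PathwayCollection", function(x, value) {
    x@targetIds <- as.character(value)
    validObject(x)
    x
})

#' @rdname accessors
#' @export
setMethod("members", "GeneSet", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("members", "PathwayTopology", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("deGenes", "IntegratedInput", function(x) x@deGenes)

#' @rdname accessors
#' @export
setMethod("combinedFc", "IntegratedInput", function(x) x@combinedFc)

#' @rdname accessors
#' @export
setMethod("background", "IntegratedInput", function(x) x@background)

#' @rdname accessors
#' @export
setMethod("rankedProfile", "IntegratedInput", function(x) x@profile)

#' @rdname accessors
#' @export
setMethod("plantedIds", "SimTruth", function(x) x@plantedIds)
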