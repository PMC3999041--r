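## Generics, accessors and show methods.

#' @rdname FeatureTable-class
#' @param object,x a `FeatureTable`.
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname FeatureTable-class
#' @export
setGeneric("tableState", function(x) standardGeneric("tableState"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname FeatureTable-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname FeatureTable-class
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' @rdname FeatureTable-class
#' @export
setMethod("featureKind", "FeatureTable", function(x) x@kind)

#' @rdname FeatureTable-class
#' @export
setMethod("tableState", "FeatureTable", function(x) x@state)

#' @rdname FeatureTable-class
#' @export
setMethod("featureIds", "FeatureTable", function(x) rownames(x))

#' @rdname FeatureTable-class
#' @export
setMethod("sampleIds", "FeatureTable", function(x) colnames(x))

#' @rdname FeatureTable-class
#' @export
setMethod("abundanceValues", "FeatureTable",
          function(x) SummarizedExperiment::assay(x, "abundance"))

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d %s features x %d samples [%s]\n",
              nrow(object), object@kind, ncol(object), object@state))
})

#' Network accessors
#'
#' @param x a [CooccurrenceNetwork-class].
#' @return `networkNodes`: character vector of node ids; `networkEdges`:
#'   the edge data.frame; `networkAlpha`: the edge-calling level.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname network-accessors
#' @export
setGeneric("networkAlpha", function(x) standardGeneric("networkAlpha"))

#' @rdname network-accessors
#' @export
setMethod("networkNodes", "CooccurrenceNetwork", function(x) x@nodes)

#' @rdname network-accessors
#' @export
setMethod("networkEdges", "CooccurrenceNetwork", function(x) x@edges)

#' @rdname network-accessors
#' @export
setMethod("networkAlpha", "CooccurrenceNetwork", function(x) x@alpha)

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf("CooccurrenceNetwork [%s]: %d nodes, %d edges (p < %g)\n",
              object@context, length(object@nodes), nrow(object@edges),
              object@alpha))
})

#' Graph properties of a network
#'
#' NetworkAnalyzer-style topology summaries; see
#' [graphProperties,CooccurrenceNetwork-method].
#'
#' @param x a [CooccurrenceNetwork-class] or an `igraph` graph.
#' @param ... unused.
#' @export
setGeneric("graphProperties", function(x, ...) standardGeneric("graphProperties"))

#' Convert to an igraph graph
#'
#' @param x a [CooccurrenceNetwork-class].
#' @return an undirected `igraph` graph whose edges carry `rho`,
#'   `reboot_z`, `p_value` and `sign` attributes.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname PatternGroups-class
#' @param x a `PatternGroups`.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname PatternGroups-class
#' @export
setMethod("groupLabels", "PatternGroups", function(x) x@labels)

setMethod("show", "PatternGroups", function(object) {
  k <- length(unique(object@labels))
  cat(sprintf("PatternGroups: %d features in %d groups\n",
              length(object@labels), k))
})

setMethod("show", "WindowSeries", function(object) {
  cat(sprintf("WindowSeries: %d windows of %d samples (step %d)\n",
              length(object@windows), object@windowSize, object@step))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d samples, %d genera, functional tables: %s\n",
    nrow(object@metadata), nrow(object@genusCounts),
    paste(names(object@functionalTables), collapse = ", ")))
})

#' @rdname WindowSeries-class
#' @param x a `WindowSeries`.
#' @export
setGeneric("windowProperties", function(x) standardGeneric("windowProperties"))

#' @rdname WindowSeries-class
#' @export
setMethod("windowProperties", "WindowSeries", function(x) x@properties)
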