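#' Taxon ids of an object
#'
#' @param x a network, function table, path-count or community object.
#' @return Character vector of taxon ids.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' Number of taxa
#'
#' @param x a network-like object.
#' @return Integer count of taxa.
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' Edge table of a network
#'
#' @param x a [RawNetwork-class] or [AssociationNetwork-class].
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Whether a network carries weights
#'
#' @param x an [AssociationNetwork-class] or [PathCounts-class].
#' @return Logical scalar.
#' @export
setGeneric("isWeighted", function(x) standardGeneric("isWeighted"))

#' Layer names of a configuration or function table
#'
#' @param x a [LayerConfig-class] or [FunctionTable-class].
#' @return Character vector of layer names.
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Layer weights (alpha)
#'
#' @param x a [LayerConfig-class].
#' @return Named numeric vector of signed layer weights.
#' @export
setGeneric("alphaWeights", function(x) standardGeneric("alphaWeights"))

#' Layer redundancy parameters (beta)
#'
#' @param x a [LayerConfig-class].
#' @return Named numeric vector of redundancy parameters.
#' @export
setGeneric("betaWeights", function(x) standardGeneric("betaWeights"))

#' Balance strength gamma
#'
#' @param x a [LayerConfig-class].
#' @return Numeric scalar in \[0, 1\].
#' @export
setGeneric("balanceGamma", function(x) standardGeneric("balanceGamma"))

#' Balance weighting parameter delta
#'
#' @param x a [LayerConfig-class].
#' @return Numeric scalar in \[0, 1\].
#' @export
setGeneric("balanceDelta", function(x) standardGeneric("balanceDelta"))

#' Module membership vector
#'
#' @param x a [ModuleAssignment-class].
#' @return Named integer vector, taxon -> module id.
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))

#' Modularity Q of a partition
#'
#' @param x a [ModuleAssignment-class].
#' @return Numeric scalar.
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' Specificity of taxa to sample conditions
#'
#' Randomization z-scores of a per-condition abundance statistic against a
#' sample-label permutation null; see the method for matrices for details.
#'
#' @param abundance a taxa x samples count matrix or a
#'   `SummarizedExperiment`.
#' @param ... passed to methods.
#' @return A [SpecificityTable-class].
#' @export
setGeneric("specificityScores",
           function(abundance, ...) standardGeneric("specificityScores"))

#' Prevalence filter for abundance tables
#'
#' Retains taxa present (count > 0) in at least `minSamples` samples.
#'
#' @param abundance a taxa x samples matrix or `SummarizedExperiment`.
#' @param minSamples minimum number of samples with nonzero count.
#' @return Object of the same class with rows filtered.
#' @export
setGeneric("filterPrevalence",
           function(abundance, minSamples) standardGeneric("filterPrevalence"))
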