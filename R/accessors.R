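#' @describeIn RawNetwork-class taxon ids
#' @param x object.
#' @export
setMethod("taxa", "RawNetwork", function(x) x@taxa)

#' @describeIn AssociationNetwork-class taxon ids
#' @param x object.
#' @export
setMethod("taxa", "AssociationNetwork", function(x) x@taxa)

#' @describeIn FunctionTable-class taxon ids (rownames)
#' @export
setMethod("taxa", "FunctionTable", function(x) rownames(x@values))

#' @describeIn PathCounts-class taxon ids
#' @export
setMethod("taxa", "PathCounts", function(x) x@taxa)

#' @describeIn SyntheticCommunity-class taxon ids of the network
#' @export
setMethod("taxa", "SyntheticCommunity", function(x) x@network@taxa)

#' @describeIn RawNetwork-class number of taxa
#' @export
setMethod("nTaxa", "RawNetwork", function(x) length(x@taxa))

#' @describeIn AssociationNetwork-class number of taxa
#' @export
setMethod("nTaxa", "AssociationNetwork", function(x) length(x@taxa))

#' @describeIn RawNetwork-class edge table
#' @export
setMethod("edgeTable", "RawNetwork", function(x) x@edges)

#' @describeIn AssociationNetwork-class edge table
#' @export
setMethod("edgeTable", "AssociationNetwork", function(x) x@edges)

#' @describeIn AssociationNetwork-class weighted mode flag
#' @export
setMethod("isWeighted", "AssociationNetwork", function(x) x@weighted)

#' @describeIn PathCounts-class whether weighted distances were used
#' @export
setMethod("isWeighted", "PathCounts", function(x) x@weighted)

#' @describeIn LayerConfig-class layer names
#' @param x object.
#' @export
setMethod("layerNames", "LayerConfig", function(x) x@layers)

#' @describeIn FunctionTable-class layer names (colnames)
#' @export
setMethod("layerNames", "FunctionTable", function(x) colnames(x@values))

#' @describeIn LayerConfig-class signed layer weights
#' @export
setMethod("alphaWeights", "LayerConfig",
          function(x) stats::setNames(x@alpha, x@layers))

#' @describeIn LayerConfig-class redundancy parameters
#' @export
setMethod("betaWeights", "LayerConfig",
          function(x) stats::setNames(x@beta, x@layers))

#' @describeIn LayerConfig-class balance strength gamma
#' @export
setMethod("balanceGamma", "LayerConfig", function(x) x@gamma)

#' @describeIn LayerConfig-class balance parameter delta
#' @export
setMethod("balanceDelta", "LayerConfig", function(x) x@delta)

#' @describeIn ModuleAssignment-class taxon -> module vector
#' @param x object.
#' @export
setMethod("moduleMembership", "ModuleAssignment", function(x) x@membership)

#' @describeIn ModuleAssignment-class modularity Q
#' @export
setMethod("modularityScore", "ModuleAssignment", function(x) x@modularity)

#' @describeIn FunctionTable-class binary matrix, taxa x layers
#' @param row.names,optional,... as in [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "FunctionTable",
          function(x, row.names = NULL, optional = FALSE, ...)
            as.data.frame(x@values, row.names = row.names,
                          optional = optional, ...))

#' @describeIn ScoreTable-class the score data.frame
#' @param x object.
#' @param row.names,optional,... as in [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "ScoreTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@scores)

#' @describeIn SpecificityTable-class the specificity data.frame
#' @param x object.
#' @param row.names,optional,... as in [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "SpecificityTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@scores)

#' @describeIn CoreSet-class members as a data.frame (rank, taxon, C_func)
#' @param x object.
#' @param row.names,optional,... as in [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "CoreSet",
          function(x, row.names = NULL, optional = FALSE, ...)
            data.frame(rank = seq_along(x@taxa), taxon = x@taxa,
                       C_func = x@cfunc, module = rep(x@module,
                                                      length(x@taxa))))

setMethod("show", "RawNetwork", function(object) {
  cat("RawNetwork:", length(object@taxa), "taxa,", nrow(object@edges),
      "edges (", sum(object@edges$weight < 0), "negative )\n")
})

setMethod("show", "AssociationNetwork", function(object) {
  cat("AssociationNetwork:", length(object@taxa), "taxa,",
      nrow(object@edges), "edges,",
      if (object@weighted) "weighted" else "binary", "\n")
})

setMethod("show", "FunctionTable", function(object) {
  cat("FunctionTable:", nrow(object@values), "taxa x",
      ncol(object@values), "layers (",
      paste(colnames(object@values), collapse = ", "), ")\n")
})

setMethod("show", "LayerConfig", function(object) {
  cat("LayerConfig:", length(object@layers), "layers; gamma =",
      object@gamma, ", delta =", object@delta, "\n")
  print(data.frame(layer = object@layers, alpha = object@alpha,
                   beta = object@beta))
})

setMethod("show", "PathCounts", function(object) {
  cat("PathCounts over", length(object@taxa), "taxa (",
      if (object@weighted) "weighted" else "binary", "distances )\n")
})

setMethod("show", "ModuleAssignment", function(object) {
  k <- if (length(object@membership)) max(object@membership) else 0L
  cat("ModuleAssignment:", length(object@membership), "taxa in", k,
      "modules; Q =", format(object@modularity, digits = 4),
      paste0("(", object@method, ")\n"))
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", nrow(object@scores), "taxa\n")
  print(utils::head(object@scores, 6L))
  if (nrow(object@scores) > 6L) cat("...\n")
})

setMethod("show", "SpecificityTable", function(object) {
  cat("SpecificityTable:", length(unique(object@scores$taxon)), "taxa x",
      length(unique(object@scores$condition)), "conditions;",
      object@nPermutations,
      if (object@exhaustive) "exhaustive assignments;" else "permutations;",
      "statistic =", object@statistic, "\n")
})

setMethod("show", "CoreSet", function(object) {
  cat("CoreSet: module", object@module, "-", length(object@taxa),
      "taxa (rule:", object@rule, ")\n")
  print(as.data.frame(object))
})

setMethod("show", "SyntheticCommunity", function(object) {
  cat("SyntheticCommunity:", nTaxa(object@network), "taxa,",
      nrow(object@network@edges), "edges,", ncol(object@abundance),
      "samples,", length(unique(object@conditions)), "conditions\n")
})
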