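#' @import methods
NULL

.EDGE_COLS <- c("from", "to", "weight")

## order every pair so that from <= to; canonical row order by (from, to)
.canonicalEdges <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  out <- data.frame(from = from, to = to,
                    weight = as.numeric(edges$weight),
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## collapse duplicate rows for the same unordered pair; conflicting weights
## (difference > tol) are an error naming the pair
.dedupEdges <- function(edges, tol = 1e-9) {
  if (nrow(edges) == 0L) return(edges)
  key <- paste(edges$from, edges$to, sep = "\r")
  dup <- duplicated(key)
  if (!any(dup)) return(edges)
  for (k in unique(key[dup])) {
    w <- edges$weight[key == k]
    if (diff(range(w)) > tol) {
      pair <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      stop("conflicting duplicate edge between '", pair[1L], "' and '",
           pair[2L], "': weights ", paste(unique(w), collapse = ", "))
    }
  }
  out <- edges[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Raw association network as read from file
#'
#' Holds an edge list exactly as parsed (signed weights and self-loops are
#' retained) together with the full taxon set. Sanitization into an
#' [AssociationNetwork-class] is a separate, logged step
#' ([sanitizeNetwork()]).
#'
#' @slot edges data.frame with columns `from`, `to`, `weight`; pairs are
#'   stored unordered (`from <= to` lexicographically).
#' @slot taxa character vector of unique taxon identifiers (network nodes,
#'   including isolated ones).
#' @aliases RawNetwork
#' @export
setClass("RawNetwork", slots = c(edges = "data.frame", taxa = "character"))

setValidity("RawNetwork", function(object) {
  e <- object@edges
  if (!all(.EDGE_COLS %in% names(e)))
    return("edges must have columns from, to, weight")
  if (anyDuplicated(object@taxa))
    return("taxa ids must be unique")
  if (any(!nzchar(object@taxa)) || anyNA(object@taxa))
    return("taxa ids must be non-empty strings")
  bad <- setdiff(c(e$from, e$to), object@taxa)
  if (length(bad))
    return(paste0("edge endpoints not in taxa: ",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  if (anyNA(e$weight)) return("edge weights must be numeric, not NA")
  TRUE
})

#' Construct a RawNetwork
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (signed
#'   weights allowed).
#' @param taxa optional character vector of node ids; defaults to the union
#'   of edge endpoints. Extra ids become isolated nodes.
#' @return A [RawNetwork-class] object.
#' @export
RawNetwork <- function(edges, taxa = NULL) {
  edges <- .dedupEdges(.canonicalEdges(edges))
  if (is.null(taxa)) taxa <- character()
  taxa <- sort(unique(c(as.character(taxa), edges$from, edges$to)))
  new("RawNetwork", edges = edges, taxa = taxa)
}

#' Sanitized undirected association network
#'
#' A simple undirected graph over taxa: no self-loops, no negative or zero
#' weights. In binary mode (the default downstream of
#' [sanitizeNetwork()]) all weights are exactly 1; in weighted mode weights
#' are positive association strengths.
#'
#' @slot edges data.frame with columns `from`, `to`, `weight` (unordered
#'   pairs, canonical order).
#' @slot taxa ordered character vector of node ids.
#' @slot weighted logical scalar; `FALSE` means binary mode.
#' @aliases AssociationNetwork
#' @export
setClass("AssociationNetwork",
         slots = c(edges = "data.frame", taxa = "character",
                   weighted = "logical"))

setValidity("AssociationNetwork", function(object) {
  e <- object@edges
  if (!all(.EDGE_COLS %in% names(e)))
    return("edges must have columns from, to, weight")
  if (anyDuplicated(object@taxa)) return("taxa ids must be unique")
  bad <- setdiff(c(e$from, e$to), object@taxa)
  if (length(bad))
    return(paste0("edge endpoints not in taxa: ",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  if (any(e$from == e$to)) return("self-loops are not allowed")
  if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
    return("duplicate edges are not allowed")
  if (length(object@weighted) != 1L || is.na(object@weighted))
    return("weighted must be TRUE or FALSE")
  if (any(!is.finite(e$weight)) || any(e$weight <= 0))
    return("all edge weights must be finite and > 0 after sanitization")
  if (!object@weighted && any(e$weight != 1))
    return("binary mode requires all edge weights to be exactly 1")
  TRUE
})

#' Construct an AssociationNetwork
#'
#' Most users obtain one via [sanitizeNetwork()]; this constructor is for
#' programmatic graphs (tests, simulations).
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `weight` (defaults to 1).
#' @param taxa optional node ids (defaults to edge endpoints).
#' @param weighted logical; keep weights (`TRUE`) or binary mode.
#' @return An [AssociationNetwork-class].
#' @export
AssociationNetwork <- function(edges, taxa = NULL, weighted = FALSE) {
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges <- .dedupEdges(.canonicalEdges(edges))
  if (!weighted) edges$weight <- rep(1, nrow(edges))
  if (is.null(taxa)) taxa <- character()
  taxa <- sort(unique(c(as.character(taxa), edges$from, edges$to)))
  new("AssociationNetwork", edges = edges, taxa = taxa, weighted = weighted)
}

#' Binary taxon-by-layer function table
#'
#' Presence (1) / absence (0) of each functional layer (e.g. nitrogen
#' fixation, plant pathogenicity) for each taxon. Strictly binary; every
#' network taxon must have a row (missing taxa are an error when joined,
#' never implicit zeros).
#'
#' @slot values numeric matrix, taxa in rows, layers in columns, entries in
#'   \{0, 1\}, with dimnames.
#' @aliases FunctionTable
#' @export
setClass("FunctionTable", slots = c(values = "matrix"))

setValidity("FunctionTable", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("function table needs taxon rownames and layer colnames")
  if (anyDuplicated(rownames(v))) return("duplicate taxon ids")
  if (anyDuplicated(colnames(v))) return("duplicate layer names")
  if (!is.numeric(v) || anyNA(v) || !all(v %in% c(0, 1))) {
    bad <- which(!(v %in% c(0, 1)) | is.na(v), arr.ind = TRUE)
    if (nrow(bad) == 0L) return("function table must be numeric 0/1")
    return(sprintf(
      "non-binary cell at taxon '%s', layer '%s' (value %s)",
      rownames(v)[bad[1L, 1L]], colnames(v)[bad[1L, 2L]],
      format(v[bad[1L, , drop = FALSE]])))
  }
  TRUE
})

#' Construct a FunctionTable
#'
#' @param values matrix (or data.frame) of 0/1 values with taxon rownames
#'   and layer colnames.
#' @return A [FunctionTable-class].
#' @export
FunctionTable <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("FunctionTable", values = values)
}

#' Per-layer scoring parameters
#'
#' Holds the layer weights (alpha), redundancy parameters (beta) and the
#' global balance parameters gamma and delta. Layers with positive alpha
#' form the beneficial set, layers with negative alpha the detrimental set;
#' layers with alpha = 0 are inert.
#'
#' @slot layers character vector of layer names.
#' @slot alpha signed numeric layer weights.
#' @slot beta numeric redundancy parameters (>= 0); the score of a bridged
#'   pair in which both endpoints carry a layer is weighted by beta.
#' @slot gamma balance strength in \[0, 1\]: 0 disables the balance penalty.
#' @slot delta in \[0, 1\]: mixes layer counting (delta = 1) and alpha
#'   weighting (delta = 0) inside the balance factor, via
#'   `D_n = delta + (1 - delta) * alpha_n`.
#' @aliases LayerConfig
#' @export
setClass("LayerConfig",
         slots = c(layers = "character", alpha = "numeric", beta = "numeric",
                   gamma = "numeric", delta = "numeric"))

setValidity("LayerConfig", function(object) {
  k <- length(object@layers)
  if (anyDuplicated(object@layers)) return("duplicate layer names")
  if (length(object@alpha) != k || length(object@beta) != k)
    return("alpha and beta must have one value per layer")
  if (anyNA(object@alpha) || anyNA(object@beta))
    return("alpha and beta must not be NA")
  if (any(object@beta < 0)) return("beta must be >= 0")
  for (p in c("gamma", "delta")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(paste(p, "must be a single value in [0, 1]"))
  }
  TRUE
})

#' Construct a LayerConfig
#'
#' @param alpha named numeric vector of signed layer weights (names are the
#'   layer names), or unnamed with `layers` given.
#' @param beta numeric redundancy parameters, recycled to the number of
#'   layers (default 1).
#' @param gamma balance strength in \[0, 1\] (default 1).
#' @param delta balance weighting parameter in \[0, 1\] (default 0:
#'   balance uses the alpha weights).
#' @param layers layer names if `alpha` is unnamed.
#' @return A [LayerConfig-class].
#' @export
LayerConfig <- function(alpha, beta = 1, gamma = 1, delta = 0,
                        layers = names(alpha)) {
  if (is.null(layers))
    layers <- paste0("layer", seq_along(alpha))
  alpha <- as.numeric(alpha)
  beta <- rep_len(as.numeric(beta), length(alpha))
  new("LayerConfig", layers = as.character(layers), alpha = alpha,
      beta = beta, gamma = as.numeric(gamma), delta = as.numeric(delta))
}

#' All-pairs shortest-path counts
#'
#' Distance matrix and shortest-path count matrix over the network taxa,
#' produced by [pathCounts()]. `sigma[k, l]` is the number of shortest
#' paths between k and l (0 when disconnected); per-intermediate counts are
#' derived on demand with [pathSigmaThrough()].
#'
#' @slot dist numeric distance matrix (Inf for disconnected pairs).
#' @slot sigma numeric shortest-path count matrix.
#' @slot taxa taxon ids (row/column order of both matrices).
#' @slot weighted logical; whether weighted distances were used.
#' @aliases PathCounts
#' @export
setClass("PathCounts",
         slots = c(dist = "matrix", sigma = "matrix", taxa = "character",
                   weighted = "logical"))

setValidity("PathCounts", function(object) {
  n <- length(object@taxa)
  if (!all(dim(object@dist) == n) || !all(dim(object@sigma) == n))
    return("dist and sigma must be n x n with n = length(taxa)")
  TRUE
})

#' Module assignment of network taxa
#'
#' Partition of taxa into network modules (densely interconnected groups)
#' found by modularity maximization. Module ids are dense integers from 1,
#' ordered by decreasing module size (ties by smallest member id).
#'
#' @slot membership named integer vector, taxon -> module id.
#' @slot modularity modularity Q of the partition.
#' @slot method character, the community-detection method used.
#' @aliases ModuleAssignment
#' @export
setClass("ModuleAssignment",
         slots = c(membership = "integer", modularity = "numeric",
                   method = "character"))

setValidity("ModuleAssignment", function(object) {
  m <- object@membership
  if (is.null(names(m))) return("membership must be named by taxon")
  if (length(m) && (anyNA(m) || any(m < 1L)))
    return("module ids must be integers >= 1")
  if (length(m) && !setequal(unique(m), seq_len(max(m))))
    return("module ids must be dense from 1")
  TRUE
})

#' Per-taxon score table
#'
#' One row per taxon with the topology score `T` (betweenness), the
#' portfolio score `TP`, the balance-adjusted score `TPB`, the functional
#' coreness `C_func`, and the module id (NA when modules were not
#' assigned). Rows are sorted by module, then descending `C_func`, ties by
#' taxon id.
#'
#' @slot scores data.frame with columns `module`, `taxon`, `T`, `TP`,
#'   `TPB`, `C_func`.
#' @aliases ScoreTable
#' @export
setClass("ScoreTable", slots = c(scores = "data.frame"))

setValidity("ScoreTable", function(object) {
  s <- object@scores
  need <- c("module", "taxon", "T", "TP", "TPB", "C_func")
  if (!identical(names(s), need))
    return(paste("score table columns must be:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$taxon)) return("duplicate taxa in score table")
  for (cl in c("T", "TP", "C_func"))
    if (any(!is.finite(s[[cl]]))) return(paste(cl, "scores must be finite"))
  if (any(!is.finite(s$TPB) & !is.na(s$TPB)))
    return("TPB scores must be finite or NA")
  TRUE
})

#' Construct a ScoreTable
#'
#' Sorts rows by module (ascending, NA last), then descending `C_func`,
#' ties broken by taxon id ascending.
#'
#' @param scores data.frame with columns `module`, `taxon`, `T`, `TP`,
#'   `TPB`, `C_func`.
#' @return A [ScoreTable-class].
#' @export
ScoreTable <- function(scores) {
  scores <- as.data.frame(scores)[, c("module", "taxon", "T", "TP",
                                      "TPB", "C_func")]
  scores$module <- as.integer(scores$module)
  scores$taxon <- as.character(scores$taxon)
  ord <- order(scores$module, -scores$C_func, scores$taxon, na.last = TRUE)
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL
  new("ScoreTable", scores = scores)
}

#' Taxon-by-condition specificity table
#'
#' Randomization z-scores of taxon abundance against sample conditions,
#' from [specificityScores()]. Each row holds the observed statistic, the
#' permutation-null mean and SD, and the z-score `s`.
#'
#' @slot scores data.frame with columns `taxon`, `condition`, `s`,
#'   `n_original`, `null_mean`, `null_sd`.
#' @slot nPermutations number of null assignments used.
#' @slot exhaustive logical; whether the null enumerated all distinct
#'   label assignments.
#' @slot statistic `"mean_reads"` or `"occurrence"`.
#' @slot sdType `"population"` or `"sample"`.
#' @aliases SpecificityTable
#' @export
setClass("SpecificityTable",
         slots = c(scores = "data.frame", nPermutations = "integer",
                   exhaustive = "logical", statistic = "character",
                   sdType = "character"))

setValidity("SpecificityTable", function(object) {
  need <- c("taxon", "condition", "s", "n_original", "null_mean", "null_sd")
  if (!identical(names(object@scores), need))
    return(paste("specificity columns must be:", paste(need, collapse = ", ")))
  TRUE
})

#' A designed functional core microbiome
#'
#' An ordered set of taxa (descending functional coreness) drawn from a
#' single network module, selected by [selectCoreSet()].
#'
#' @slot module integer module id the set was drawn from.
#' @slot taxa ordered member taxa (descending `C_func`).
#' @slot cfunc the members' `C_func` values, same order.
#' @slot rule selection rule used (`"knee"` or `"top_k"`).
#' @slot parameters list of rule diagnostics (e.g. relative drops, cut
#'   rank, `k`).
#' @aliases CoreSet
#' @export
setClass("CoreSet",
         slots = c(module = "integer", taxa = "character", cfunc = "numeric",
                   rule = "character", parameters = "list"))

setValidity("CoreSet", function(object) {
  if (length(object@taxa) != length(object@cfunc))
    return("taxa and cfunc must have equal length")
  if (is.unsorted(rev(object@cfunc)))
    return("cfunc must be non-increasing")
  TRUE
})

#' Synthetic community specification
#'
#' Parameters of the seeded generator: a planted-partition association
#' network with boosted-degree hub taxa, per-module functional layer
#' probabilities, and condition-structured negative-binomial read counts.
#' See [communitySpec()] for defaults and units.
#'
#' @slot nModules number of planted modules.
#' @slot taxaPerModule taxa per module.
#' @slot pIn,pOut within/between-module edge probabilities.
#' @slot functionProb matrix (module x layer) of per-taxon function
#'   probabilities.
#' @slot hubsPerModule planted hubs per module.
#' @slot hubFraction fraction of its module each hub is wired to.
#' @slot conditions condition labels.
#' @slot samplesPerCondition samples per condition.
#' @slot moduleMeans matrix (module x condition) of mean abundance
#'   multipliers.
#' @slot baseMean baseline expected reads per taxon per sample.
#' @slot dispersion negative-binomial size parameter.
#' @slot config the [LayerConfig-class] paired with the function layers.
#' @slot seed integer seed; outputs are fully determined by it.
#' @aliases CommunitySpec
#' @export
setClass("CommunitySpec",
         slots = c(nModules = "integer", taxaPerModule = "integer",
                   pIn = "numeric", pOut = "numeric",
                   functionProb = "matrix", hubsPerModule = "integer",
                   hubFraction = "numeric", conditions = "character",
                   samplesPerCondition = "integer", moduleMeans = "matrix",
                   baseMean = "numeric", dispersion = "numeric",
                   config = "LayerConfig", seed = "integer"))

setValidity("CommunitySpec", function(object) {
  for (p in c("pIn", "pOut", "hubFraction")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(paste(p, "must be a single probability in [0, 1]"))
  }
  if (any(object@functionProb < 0) || any(object@functionProb > 1))
    return("functionProb entries must be probabilities")
  if (object@nModules < 1L || object@taxaPerModule < 1L)
    return("counts must be >= 1")
  if (nrow(object@functionProb) != object@nModules)
    return("functionProb needs one row per module")
  if (ncol(object@functionProb) != length(object@config@layers))
    return("functionProb needs one column per layer")
  if (length(object@conditions) < 1L)
    return("at least one condition")
  if (length(object@samplesPerCondition) != length(object@conditions))
    return("samplesPerCondition must match conditions")
  if (any(object@samplesPerCondition < 1L))
    return("samplesPerCondition must be >= 1")
  if (!all(dim(object@moduleMeans) ==
           c(object@nModules, length(object@conditions))))
    return("moduleMeans must be nModules x nConditions")
  if (any(object@moduleMeans <= 0)) return("moduleMeans must be > 0")
  if (object@baseMean <= 0 || object@dispersion <= 0)
    return("baseMean and dispersion must be > 0")
  TRUE
})

#' A generated synthetic community
#'
#' Output bundle of [generateCommunity()]: the association network, the
#' function table and its layer configuration, the abundance matrix, the
#' sample condition labels, and the planted ground truth (true module
#' membership, hub ids, condition-enriched modules).
#'
#' @slot network an [AssociationNetwork-class].
#' @slot functions a [FunctionTable-class].
#' @slot config a [LayerConfig-class].
#' @slot abundance taxa x samples count matrix.
#' @slot conditions named character vector, sample -> condition.
#' @slot groundTruth list with elements `modules`, `hubs`, `moduleMeans`,
#'   `enrichedModules`.
#' @slot spec the generating [CommunitySpec-class].
#' @aliases SyntheticCommunity
#' @export
setClass("SyntheticCommunity",
         slots = c(network = "AssociationNetwork",
                   functions = "FunctionTable", config = "LayerConfig",
                   abundance = "matrix", conditions = "character",
                   groundTruth = "list", spec = "CommunitySpec"))
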