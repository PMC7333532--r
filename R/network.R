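## igraph view of a network; vertices keep the canonical taxon order
.asIgraph <- function(net) {
  e <- edgeTable(net)
  igraph::graph_from_data_frame(
    e[, c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(name = taxa(net)))
}

#' Sanitize a raw network
#'
#' Applies the preprocessing required before betweenness-based scoring:
#' self-loops and edges with negative or zero weight are removed (scores
#' computed on networks that still contain negative associations are
#' misleading), and in binary mode all surviving weights are set to 1.
#' Removal counts are reported via [message()].
#'
#' @param raw a [RawNetwork-class] (or an [AssociationNetwork-class],
#'   returned unchanged apart from the mode).
#' @param weighted keep positive weights (`TRUE`) or binarize (default).
#' @return An [AssociationNetwork-class] over the same taxon set.
#' @export
sanitizeNetwork <- function(raw, weighted = FALSE) {
  e <- edgeTable(raw)
  loops <- e$from == e$to
  nonpos <- !loops & e$weight <= 0
  keep <- !loops & !nonpos
  if (any(loops)) message("removed ", sum(loops), " self-loop(s)")
  if (any(nonpos))
    message("removed ", sum(nonpos), " non-positive edge(s)")
  if (nrow(e) > 0L && !any(keep))
    warning("no edges remain after sanitization; network is edgeless")
  AssociationNetwork(e[keep, , drop = FALSE], taxa = taxa(raw),
                     weighted = weighted)
}

## membership of connected components as a named integer vector
.componentMembership <- function(net) {
  if (nTaxa(net) == 0L) return(stats::setNames(integer(), character()))
  comp <- igraph::components(.asIgraph(net))
  stats::setNames(as.integer(comp$membership), taxa(net))
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component; ties between
#' equally sized components are broken by the component containing the
#' lexicographically smallest taxon id.
#'
#' @param net an [AssociationNetwork-class].
#' @return An [AssociationNetwork-class] restricted to the component; an
#'   empty network yields an empty result.
#' @export
largestComponent <- function(net) {
  if (nTaxa(net) == 0L) return(net)
  memb <- .componentMembership(net)
  sizes <- table(memb)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(big) > 1L) {
    ## tie: component holding the smallest member id (taxa are sorted)
    big <- memb[[which(memb %in% big)[1L]]]
  }
  keep <- names(memb)[memb == big]
  e <- edgeTable(net)
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  AssociationNetwork(e, taxa = keep, weighted = isWeighted(net))
}

#' All-pairs shortest-path counts
#'
#' Computes the distance matrix and the number of shortest paths between
#' every pair of taxa. In binary mode every edge has length 1 (breadth
#' first); in weighted mode edge length is `1/weight` by default (a larger
#' association weight means a closer pair) or the raw weight with
#' `distance = "raw"`. Counts are obtained by dynamic programming over the
#' shortest-path DAG of each source.
#'
#' @param net an [AssociationNetwork-class].
#' @param distance edge-length convention in weighted mode: `"inverse"`
#'   (default) or `"raw"`.
#' @param tol relative tolerance for identifying shortest-path
#'   predecessors in weighted mode.
#' @return A [PathCounts-class].
#' @export
pathCounts <- function(net, distance = c("inverse", "raw"), tol = 1e-9) {
  distance <- match.arg(distance)
  tx <- taxa(net)
  n <- length(tx)
  e <- edgeTable(net)
  len <- if (!isWeighted(net)) rep(1, nrow(e))
         else if (distance == "inverse") 1 / e$weight
         else e$weight
  D <- matrix(Inf, n, n, dimnames = list(tx, tx))
  S <- matrix(0, n, n, dimnames = list(tx, tx))
  if (n == 0L) {
    return(new("PathCounts", dist = D, sigma = S, taxa = tx,
               weighted = isWeighted(net)))
  }
  diag(D) <- 0
  diag(S) <- 1
  if (nrow(e) > 0L) {
    g <- .asIgraph(net)
    D <- igraph::distances(
      g, weights = if (isWeighted(net)) len else NA)
    dimnames(D) <- list(tx, tx)
    ## adjacency structures for the predecessor scan
    ii <- match(e$from, tx)
    jj <- match(e$to, tx)
    W <- matrix(Inf, n, n)
    W[cbind(ii, jj)] <- len
    W[cbind(jj, ii)] <- len
    adj <- lapply(seq_len(n), function(v)
      c(jj[ii == v], ii[jj == v]))
    for (s in seq_len(n)) {
      d <- D[s, ]
      reach <- which(is.finite(d) & seq_len(n) != s)
      sig <- numeric(n)
      sig[s] <- 1
      for (v in reach[order(d[reach])]) {
        nb <- adj[[v]]
        pred <- nb[abs(d[nb] + W[cbind(nb, v)] - d[v]) <=
                     tol * (1 + abs(d[v]))]
        sig[v] <- sum(sig[pred])
      }
      S[s, ] <- sig
    }
  }
  new("PathCounts", dist = D, sigma = S, taxa = tx,
      weighted = isWeighted(net))
}

#' Number of shortest paths between a pair
#'
#' @param pc a [PathCounts-class].
#' @param k,l taxon ids.
#' @return sigma(k, l): 0 iff k and l are disconnected.
#' @export
pathSigma <- function(pc, k, l) {
  if (identical(k, l)) stop("k and l must differ")
  s <- pc@sigma[k, l]
  if (!is.finite(pc@dist[k, l])) 0 else unname(s)
}

#' Shortest paths through each intermediate taxon
#'
#' For an unordered pair (k, l), the number of shortest paths passing
#' through each other taxon i: `sigma[k, i] * sigma[i, l]` whenever i lies
#' on a shortest path (`d(k, i) + d(i, l) = d(k, l)`), else 0. Endpoints
#' are excluded.
#'
#' @param pc a [PathCounts-class].
#' @param k,l taxon ids.
#' @param tol relative tolerance on the distance identity (weighted mode).
#' @return Named numeric vector over all taxa except k and l.
#' @export
pathSigmaThrough <- function(pc, k, l, tol = 1e-9) {
  if (identical(k, l)) stop("k and l must differ")
  tx <- pc@taxa
  others <- setdiff(tx, c(k, l))
  d <- pc@dist
  if (!is.finite(d[k, l]))
    return(stats::setNames(numeric(length(others)), others))
  on <- abs(d[k, others] + d[others, l] - d[k, l]) <=
    tol * (1 + abs(d[k, l]))
  out <- ifelse(on, pc@sigma[k, others] * pc@sigma[others, l], 0)
  stats::setNames(as.numeric(out), others)
}

## Core aggregation: for each focal taxon i, sum over connected unordered
## pairs {k, l} (k != i != l) of (sigma_kl(i)/sigma_kl) * G[k, l] for each
## pair-weight matrix in `weights`. Betweenness is the all-ones case.
## Accumulation order is fixed (column-major over the upper triangle) for
## reproducibility.
.pairAggregate <- function(pc, weights, tol = 1e-9) {
  D <- pc@dist
  S <- pc@sigma
  n <- length(pc@taxa)
  out <- matrix(0, n, length(weights),
                dimnames = list(pc@taxa, names(weights)))
  if (n < 3L) return(out)
  connected <- is.finite(D) & D > 0 & upper.tri(D)
  for (i in seq_len(n)) {
    di <- D[, i]
    onPath <- abs(outer(di, di, "+") - D) <= tol * (1 + abs(D))
    ok <- onPath & connected
    ok[i, ] <- FALSE
    ok[, i] <- FALSE
    if (!any(ok)) next
    ratio <- (S[, i] %o% S[i, ])[ok] / S[ok]
    for (m in seq_along(weights))
      out[i, m] <- sum(ratio * weights[[m]][ok])
  }
  out
}

#' Betweenness centrality (topology score)
#'
#' Unnormalized betweenness: for each taxon i, the sum over unordered
#' pairs \{k, l\} (both distinct from i) of the fraction of shortest k-l
#' paths that pass through i. Disconnected pairs contribute nothing. In
#' weighted mode shortest paths use the [pathCounts()] distance
#' convention.
#'
#' @param net an [AssociationNetwork-class].
#' @param paths optional precomputed [PathCounts-class].
#' @param distance passed to [pathCounts()].
#' @return Named numeric vector T(i) over taxa.
#' @export
betweennessScores <- function(net, paths = NULL,
                              distance = c("inverse", "raw")) {
  if (is.null(paths))
    paths <- pathCounts(net, distance = match.arg(distance))
  n <- length(paths@taxa)
  ones <- matrix(1, n, n)
  drop(.pairAggregate(paths, list(T = ones))[, 1L, drop = TRUE])
}

#' Detect network modules by modularity maximization
#'
#' Partitions the network into modules (communities). The default greedy
#' agglomerative modularity maximization is deterministic; the Louvain
#' method is randomized and requires a seed for reproducibility. Module
#' ids are relabeled densely from 1 in order of decreasing module size
#' (ties by smallest member id), so the labeling is deterministic given
#' method and seed. Taxa in singleton components form their own modules.
#'
#' @param net a non-empty [AssociationNetwork-class].
#' @param method `"greedy"` (fast greedy modularity) or `"louvain"`.
#' @param seed integer seed used for the Louvain method.
#' @return A [ModuleAssignment-class] with the partition and its
#'   modularity Q.
#' @export
detectModules <- function(net, method = c("greedy", "louvain"),
                          seed = NULL) {
  method <- match.arg(method)
  if (nTaxa(net) == 0L) stop("cannot detect modules in an empty network")
  g <- .asIgraph(net)
  w <- if (isWeighted(net)) igraph::E(g)$weight else NULL
  if (nrow(edgeTable(net)) == 0L) {
    ## no edges: every taxon is its own (singleton) module
    memb <- stats::setNames(seq_len(nTaxa(net)), taxa(net))
    return(new("ModuleAssignment", membership = memb,
               modularity = NaN, method = method))
  }
  if (method == "louvain" && !is.null(seed)) set.seed(seed)
  cm <- if (method == "greedy") igraph::cluster_fast_greedy(g, weights = w)
        else igraph::cluster_louvain(g, weights = w)
  memb <- igraph::membership(cm)
  q <- suppressWarnings(igraph::modularity(cm))
  if (method == "greedy" && !is.null(cm$modularity)) {
    ## pick the merge-path cut with maximal modularity; within a 1e-10
    ## tie, prefer the coarser partition (fewer modules) so that e.g. a
    ## complete graph yields one module despite floating-point noise
    qs <- cm$modularity
    best <- which(qs >= max(qs) - 1e-10)
    ## community count at merge step i is vcount - i + 1 (the merge path
    ## of a disconnected graph stops at one community per component)
    nComm <- igraph::vcount(g) - best + 1L
    memb <- igraph::cut_at(cm, no = min(nComm))
    q <- igraph::modularity(g, memb, weights = w)
  }
  memb <- stats::setNames(as.integer(memb), taxa(net))
  ## dense relabeling: by decreasing size, ties by smallest member id
  sizes <- table(memb)
  firstMember <- vapply(names(sizes), function(id)
    min(names(memb)[memb == as.integer(id)]), character(1))
  ord <- order(-as.integer(sizes), firstMember)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  memb <- stats::setNames(as.integer(relabel[as.character(memb)]),
                          names(memb))
  new("ModuleAssignment", membership = memb, modularity = as.numeric(q),
      method = method)
}
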