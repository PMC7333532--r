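#' Redundancy mapping z
#'
#' Maps the number of endpoints of a bridged pair that carry a layer to
#' its score contribution: `z(0) = 0`, `z(1) = 1`, `z(2) = beta` — both
#' endpoints carrying a function is rewarded in proportion to the layer's
#' redundancy parameter.
#'
#' @param fsum 0, 1 or 2 (sum of the two binary endpoint values);
#'   vectorized.
#' @param beta redundancy parameter of the layer (recycled).
#' @return Numeric vector of z values.
#' @export
zValue <- function(fsum, beta) {
  if (any(!(fsum %in% c(0, 1, 2))))
    stop("fsum must be in {0, 1, 2}; binary function table invariant broken")
  ifelse(fsum == 2, beta, fsum)
}

## Align a FunctionTable to a network's taxa and a LayerConfig's layers.
## Missing taxa are an error (never implicit zeros); layer sets must match.
.alignFunctions <- function(net, functions, config) {
  v <- functions@values
  missing <- setdiff(taxa(net), rownames(v))
  if (length(missing))
    stop("function table is missing network taxa: ",
         paste(missing, collapse = ", "))
  if (!setequal(colnames(v), layerNames(config)))
    stop("function table layers (", paste(colnames(v), collapse = ", "),
         ") do not match layer config (",
         paste(layerNames(config), collapse = ", "), ")")
  v[taxa(net), layerNames(config), drop = FALSE]
}

## Pair-weight matrix sum_{n in L} alpha_n z(f_nk + f_nl) over a layer
## subset L (closed form: z(s) = s + (beta - 2) [s == 2], and
## [s == 2] = f_k f_l for binary f).
.portfolioMatrix <- function(F, alpha, beta, L) {
  n <- nrow(F)
  if (length(L) == 0L) return(matrix(0, n, n))
  Fl <- F[, L, drop = FALSE]
  a <- drop(Fl %*% alpha[L])
  outer(a, a, "+") +
    sweep(Fl, 2L, alpha[L] * (beta[L] - 2), "*") %*% t(Fl)
}

## Balance factor matrix 1 - gamma |sum_L D_n (f_nk - f_nl)| / sum_L D_n.
## Caller guarantees sum(D[L]) > 0 (or gamma == 0, or L empty -> factor 1).
.balanceMatrix <- function(F, D, gamma, L) {
  n <- nrow(F)
  if (gamma == 0 || length(L) == 0L) return(matrix(1, n, n))
  u <- drop(F[, L, drop = FALSE] %*% D[L])
  1 - gamma * abs(outer(u, u, "-")) / sum(D[L])
}

.balanceD <- function(config) {
  delta <- balanceDelta(config)
  delta + (1 - delta) * config@alpha
}

## pair-weight matrices of the scoring family; `need` selects which to
## build. TPB with a non-positive all-layer balance denominator is an
## error (tpb = "error") or dropped with a warning (tpb = "na").
.pairWeightMatrices <- function(F, config, need = c("TP", "TPB", "C_func"),
                                tpb = c("error", "na")) {
  tpb <- match.arg(tpb)
  alpha <- stats::setNames(config@alpha, config@layers)
  beta <- stats::setNames(config@beta, config@layers)
  gamma <- balanceGamma(config)
  D <- stats::setNames(.balanceD(config), config@layers)
  all <- config@layers[alpha != 0]
  pos <- config@layers[alpha > 0]
  neg <- config@layers[alpha < 0]
  out <- list()
  if (any(c("TP", "TPB") %in% need))
    out$TP <- .portfolioMatrix(F, alpha, beta, all)
  if ("TPB" %in% need) {
    if (gamma > 0 && length(all) && sum(D[all]) <= 0) {
      msg <- paste0("balance denominator sum(D) = ", sum(D[all]),
                    " <= 0 over all layers with gamma > 0; the",
                    " all-layer balance score is undefined for this",
                    " configuration")
      if (tpb == "error") stop(msg)
      warning(msg, "; TPB set to NA")
    } else {
      out$TPB <- out$TP * .balanceMatrix(F, D, gamma, all)
    }
  }
  if ("C_func" %in% need) {
    ## positive-layer D_n are > 0 for delta in [0, 1], so the split
    ## balance denominator is safe; empty positive set -> factor 1 (the
    ## positive term is 0 anyway)
    out$C_func <- .portfolioMatrix(F, alpha, beta, pos) *
      .balanceMatrix(F, D, gamma, pos) +
      .portfolioMatrix(F, alpha, beta, neg)
  }
  out[intersect(need, names(out))]
}

.scoreOne <- function(net, functions, config, paths, which) {
  if (is.null(paths)) paths <- pathCounts(net)
  F <- .alignFunctions(net, functions, config)
  W <- .pairWeightMatrices(F, config, need = which, tpb = "error")
  drop(.pairAggregate(paths, W)[, 1L, drop = TRUE])
}

#' Topology-and-portfolio score TP
#'
#' For each taxon i, sums over connected unordered pairs \{k, l\} the
#' fraction of shortest k-l paths through i times the pair's functional
#' weight `sum_n alpha_n z(f_nk + f_nl)`, over all layers.
#'
#' @param net an [AssociationNetwork-class].
#' @param functions a [FunctionTable-class] covering all network taxa.
#' @param config a [LayerConfig-class].
#' @param paths optional precomputed [PathCounts-class].
#' @return Named numeric vector TP(i).
#' @export
scoreTP <- function(net, functions, config, paths = NULL) {
  .scoreOne(net, functions, config, paths, "TP")
}

#' Topology, portfolio and balance score TPB
#'
#' Extends [scoreTP()] by multiplying every pair contribution with the
#' balance factor `1 - gamma |sum_n D_n (f_nk - f_nl)| / sum_n D_n`
#' (all layers; `D_n = delta + (1 - delta) alpha_n`), which penalizes taxa
#' that bridge functionally lopsided pairs. The per-pair factor lies in
#' \[1 - gamma, 1\]; `gamma = 0` reduces TPB to TP.
#'
#' With mixed-sign alpha the all-layer denominator `sum_n D_n` can be
#' non-positive; that configuration is rejected as an error (the sign
#' split of [scoreCfunc()] is the defined endpoint there).
#'
#' @inheritParams scoreTP
#' @return Named numeric vector TPB(i).
#' @export
scoreTPB <- function(net, functions, config, paths = NULL) {
  .scoreOne(net, functions, config, paths, "TPB")
}

#' Functional coreness C_func
#'
#' The scoring endpoint: layers are split by the sign of alpha into a
#' beneficial set (alpha > 0) and a detrimental set (alpha < 0). Each
#' pair's contribution is the balanced beneficial term (balance factor
#' computed over the beneficial set only) plus the unbalanced detrimental
#' term, weighted by the fraction of shortest paths through the focal
#' taxon. Layers with alpha = 0 are inert. C_func may be negative.
#'
#' @inheritParams scoreTP
#' @return Named numeric vector C_func(i).
#' @export
scoreCfunc <- function(net, functions, config, paths = NULL) {
  .scoreOne(net, functions, config, paths, "C_func")
}

#' Full functional-coreness scoring
#'
#' Computes T (betweenness), TP, TPB and C_func for every taxon in one
#' pass and returns them as a sorted [ScoreTable-class]. When the
#' all-layer balance denominator is non-positive (possible with
#' mixed-sign alpha and small delta), TPB is reported as NA with a
#' warning; C_func is always defined.
#'
#' @inheritParams scoreTP
#' @param modules optional [ModuleAssignment-class]; adds module ids to
#'   the table (NA otherwise).
#' @param distance weighted-mode distance convention, see [pathCounts()].
#' @return A [ScoreTable-class].
#' @export
functionalCoreness <- function(net, functions, config, modules = NULL,
                               paths = NULL,
                               distance = c("inverse", "raw")) {
  if (is.null(paths))
    paths <- pathCounts(net, distance = match.arg(distance))
  F <- .alignFunctions(net, functions, config)
  W <- .pairWeightMatrices(F, config, tpb = "na")  # all three scores
  n <- nTaxa(net)
  W <- c(list(T = matrix(1, n, n)), W)
  res <- .pairAggregate(paths, W)
  tpb <- if ("TPB" %in% colnames(res)) res[, "TPB"] else rep(NA_real_, n)
  mod <- rep(NA_integer_, n)
  if (!is.null(modules)) {
    memb <- moduleMembership(modules)
    missing <- setdiff(taxa(net), names(memb))
    if (length(missing))
      stop("module assignment is missing taxa: ",
           paste(missing, collapse = ", "))
    mod <- as.integer(memb[taxa(net)])
  }
  ScoreTable(data.frame(module = mod, taxon = taxa(net),
                        T = res[, "T"], TP = res[, "TP"], TPB = tpb,
                        C_func = res[, "C_func"],
                        stringsAsFactors = FALSE))
}

## ---- brute-force oracle -------------------------------------------------

## All shortest paths between k and l by exhaustive depth-first search,
## pruned only by the distance matrix (every shortest path is enumerated
## explicitly). Returns a list of vertex-index paths.
.enumerateShortestPaths <- function(adj, W, D, k, l, tol = 1e-9) {
  target <- D[k, l]
  if (!is.finite(target)) return(list())
  out <- list()
  walk <- function(path, len) {
    v <- path[length(path)]
    if (v == l) {
      if (abs(len - target) <= tol * (1 + target))
        out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (u in adj[[v]]) {
      if (u %in% path) next
      newLen <- len + W[v, u]
      ## prune branches that can no longer realize a shortest path
      if (newLen + D[u, l] > target + tol * (1 + target)) next
      walk(c(path, u), newLen)
    }
  }
  walk(k, 0)
  out
}

#' Brute-force functional-coreness oracle
#'
#' Validation-only reimplementation: enumerates every shortest path
#' between every pair of taxa by exhaustive search (distances from a
#' Floyd-Warshall recursion, no shared code with [pathCounts()]) and
#' accumulates the T, TP, TPB and C_func sums term by term with explicit
#' per-layer [zValue()] calls. Intended for networks of at most ~12 taxa;
#' larger inputs are refused.
#'
#' @inheritParams scoreTP
#' @param maxTaxa refuse networks larger than this (default 12).
#' @param distance weighted-mode distance convention, see [pathCounts()].
#' @return List with named numeric vectors `T`, `TP`, `TPB`, `C_func`
#'   (TPB is all-NA when the all-layer balance denominator is invalid).
#' @export
corenessOracle <- function(net, functions, config, maxTaxa = 12,
                           distance = c("inverse", "raw")) {
  distance <- match.arg(distance)
  tx <- taxa(net)
  n <- length(tx)
  if (n > maxTaxa)
    stop("oracle refuses networks with more than ", maxTaxa, " taxa")
  F <- .alignFunctions(net, functions, config)
  alpha <- config@alpha
  beta <- config@beta
  gamma <- balanceGamma(config)
  D_n <- .balanceD(config)
  act <- which(alpha != 0)
  pos <- which(alpha > 0)
  neg <- which(alpha < 0)
  tpbValid <- !(gamma > 0 && length(act) && sum(D_n[act]) <= 0)

  e <- edgeTable(net)
  len <- if (!isWeighted(net)) rep(1, nrow(e))
         else if (distance == "inverse") 1 / e$weight
         else e$weight
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  ii <- match(e$from, tx); jj <- match(e$to, tx)
  W[cbind(ii, jj)] <- len
  W[cbind(jj, ii)] <- len
  D <- W
  for (m in seq_len(n))                       # Floyd-Warshall
    D <- pmin(D, outer(D[, m], D[m, ], "+"))
  adj <- lapply(seq_len(n), function(v) sort(c(jj[ii == v], ii[jj == v])))

  zero <- stats::setNames(numeric(n), tx)
  res <- list(T = zero, TP = zero, TPB = zero, C_func = zero)
  pairTerm <- function(fk, fl, layers, balanced, Dsum) {
    tot <- 0
    for (nn in layers)
      tot <- tot + alpha[nn] * zValue(fk[nn] + fl[nn], beta[nn])
    if (balanced && length(layers)) {
      dev <- 0
      for (nn in layers) dev <- dev + D_n[nn] * (fk[nn] - fl[nn])
      tot <- tot * (1 - gamma * abs(dev) / Dsum)
    }
    tot
  }
  for (k in seq_len(n - 1L)) {
    for (l in seq((k + 1L), n)) {
      paths <- .enumerateShortestPaths(adj, W, D, k, l)
      sigma <- length(paths)
      if (sigma == 0L) next
      through <- numeric(n)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        through[interior] <- through[interior] + 1
      }
      fk <- F[k, ]; fl <- F[l, ]
      tp <- pairTerm(fk, fl, act, FALSE, NA)
      tpb <- if (tpbValid)
        pairTerm(fk, fl, act, TRUE, sum(D_n[act])) else NA_real_
      cf <- pairTerm(fk, fl, pos, TRUE, sum(D_n[pos])) +
        pairTerm(fk, fl, neg, FALSE, NA)
      idx <- which(through > 0)
      ratio <- through[idx] / sigma
      res$T[idx] <- res$T[idx] + ratio
      res$TP[idx] <- res$TP[idx] + ratio * tp
      res$TPB[idx] <- res$TPB[idx] + ratio * tpb
      res$C_func[idx] <- res$C_func[idx] + ratio * cf
    }
  }
  if (!tpbValid) res$TPB <- stats::setNames(rep(NA_real_, n), tx)
  res
}
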