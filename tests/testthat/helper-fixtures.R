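## Fixtures built in code: random graphs, random binary layers, random
## valid parameter sets. All seeded so tests are reproducible.

randomNetwork <- function(n, p = 0.4, seed = 1, weighted = FALSE) {
  set.seed(seed)
  tx <- sprintf("n%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  w <- if (weighted) stats::runif(sum(keep), 0.2, 2)
       else rep(1, sum(keep))
  AssociationNetwork(
    data.frame(from = tx[pairs[keep, 1L]], to = tx[pairs[keep, 2L]],
               weight = w, stringsAsFactors = FALSE),
    taxa = tx, weighted = weighted)
}

randomFunctionTable <- function(net, nLayers = 3, seed = 1, prob = 0.5) {
  set.seed(seed + 1000L)
  tx <- taxa(net)
  m <- matrix(stats::rbinom(length(tx) * nLayers, 1L, prob),
              nrow = length(tx),
              dimnames = list(tx, paste0("L", seq_len(nLayers))))
  FunctionTable(m)
}

randomConfig <- function(nLayers = 3, seed = 1, signed = TRUE) {
  set.seed(seed + 2000L)
  alpha <- round(stats::runif(nLayers, 0.2, 2), 3)
  if (signed && nLayers > 1L) {
    flip <- sample(nLayers, size = sample(0:(nLayers - 1L), 1L))
    alpha[flip] <- -alpha[flip]
  }
  names(alpha) <- paste0("L", seq_len(nLayers))
  LayerConfig(alpha = alpha,
              beta = round(stats::runif(nLayers, 0, 3), 3),
              gamma = round(stats::runif(1), 3),
              delta = round(stats::runif(1), 3))
}

## the three-taxon path a-b-c used in several worked examples
pathNetwork <- function() {
  AssociationNetwork(data.frame(from = c("a", "b"), to = c("b", "c")))
}

## exhaustive specificity oracle: enumerates every distinct label
## assignment directly (independent of the package's internals)
exhaustiveSpecificityOracle <- function(counts, labels, condition) {
  perms <- unique(combinat_perms(labels))
  stats <- vapply(perms, function(p) mean(counts[p == condition]),
                  numeric(1))
  obs <- mean(counts[labels == condition])
  mu <- mean(stats)
  sd0 <- sqrt(mean((stats - mu)^2))
  if (sd0 == 0) 0 else (obs - mu) / sd0
}

## all permutations of a small vector (n <= 7), plain recursion
combinat_perms <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
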