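#' Specify a synthetic community
#'
#' Defines the seeded generator of test communities: a planted-partition
#' association network (dense within modules, sparse between), one or more
#' boosted-degree hub taxa per module, a binary function table with
#' per-module per-layer presence probabilities, and a condition-structured
#' taxa x samples count table with negative-binomial (overdispersed, like
#' amplicon read counts) noise. Defaults emulate the shape of field
#' microbiome inputs: three modules of 20 taxa, one hub per module wired
#' to 80% of its module, a beneficial layer (alpha = 1, beta = 2) and a
#' detrimental layer (alpha = -1, beta = 1) with gamma = 1, delta = 0, two
#' conditions of 20 samples each, and a 5-fold abundance enrichment of
#' module 1 under the first condition.
#'
#' @param nModules number of planted modules.
#' @param taxaPerModule taxa per module.
#' @param pIn,pOut within/between-module edge probabilities.
#' @param config a [LayerConfig-class] defining the functional layers.
#' @param functionProb matrix (module x layer) of per-taxon function
#'   probabilities. The default plants a sharp functional contrast as
#'   ground truth, analogous to the pIn/pOut contrast for modules:
#'   beneficial (positive-alpha) layers are carried by every taxon of the
#'   focal module (module 1; probability 1) and rarely elsewhere (0.05),
#'   while detrimental layers are absent from the focal module and carried
#'   at 0.1 in the others. The focal module's hub therefore bridges
#'   function-carrying pairs, whereas cross-module pairs are functionally
#'   lopsided and suppressed by the balance factor.
#' @param hubsPerModule planted hubs per module (0 disables hubs).
#' @param hubFraction fraction of its module each hub is wired to.
#' @param conditions condition labels.
#' @param samplesPerCondition samples per condition (recycled).
#' @param moduleMeans matrix (module x condition) of mean-abundance
#'   multipliers; default all 1 except `moduleMeans[1, 1] = enrichment`.
#' @param enrichment multiplier used for the default `moduleMeans`.
#' @param baseMean baseline expected reads per taxon per sample.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param seed integer seed; the generated community is fully determined
#'   by it.
#' @return A [CommunitySpec-class].
#' @export
communitySpec <- function(nModules = 3, taxaPerModule = 20, pIn = 0.3,
                          pOut = 0.01,
                          config = LayerConfig(
                            alpha = c(beneficial = 1, deleterious = -1),
                            beta = c(2, 1), gamma = 1, delta = 0),
                          functionProb = NULL, hubsPerModule = 1,
                          hubFraction = 0.8, conditions = c("A", "B"),
                          samplesPerCondition = 20, moduleMeans = NULL,
                          enrichment = 5, baseMean = 100, dispersion = 5,
                          seed = 1) {
  nLayers <- length(layerNames(config))
  if (is.null(functionProb)) {
    functionProb <- matrix(ifelse(rep(config@alpha > 0, each = nModules),
                                  0.05, 0.1),
                           nrow = nModules, ncol = nLayers)
    functionProb[1L, config@alpha > 0] <- 1
    functionProb[1L, config@alpha < 0] <- 0
  }
  colnames(functionProb) <- layerNames(config)
  if (is.null(moduleMeans)) {
    moduleMeans <- matrix(1, nModules, length(conditions))
    moduleMeans[1L, 1L] <- enrichment
  }
  dimnames(moduleMeans) <- list(NULL, conditions)
  new("CommunitySpec", nModules = as.integer(nModules),
      taxaPerModule = as.integer(taxaPerModule), pIn = pIn, pOut = pOut,
      functionProb = functionProb,
      hubsPerModule = as.integer(hubsPerModule),
      hubFraction = hubFraction, conditions = as.character(conditions),
      samplesPerCondition = rep_len(as.integer(samplesPerCondition),
                                    length(conditions)),
      moduleMeans = moduleMeans, baseMean = baseMean,
      dispersion = dispersion, config = config, seed = as.integer(seed))
}

#' Generate a synthetic community
#'
#' Draws a community from a [communitySpec()]: edges are sampled
#' independently with probability `pIn` within and `pOut` between planted
#' modules; each hub is additionally wired to a fixed fraction of its
#' module (boosted degree); layer presence is Bernoulli per taxon with the
#' module's probability; counts are
#' `NB(mu = taxonBase * moduleMeans[module, condition], size =
#' dispersion)` with a lognormal per-taxon baseline around `baseMean`.
#' Fully determined by `spec@seed`.
#'
#' @param spec a [CommunitySpec-class].
#' @return A [SyntheticCommunity-class] whose `groundTruth` records the
#'   planted module membership, hub ids, mean multipliers and
#'   condition-enriched modules.
#' @export
generateCommunity <- function(spec) {
  set.seed(spec@seed)
  nMod <- spec@nModules
  per <- spec@taxaPerModule
  n <- nMod * per
  tx <- sprintf("taxon_%03d", seq_len(n))
  mod <- rep(seq_len(nMod), each = per)
  names(mod) <- tx

  ## planted-partition edges
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sameMod <- mod[pairs[, 1L]] == mod[pairs[, 2L]]
  p <- ifelse(sameMod, spec@pIn, spec@pOut)
  present <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(from = tx[pairs[present, 1L]],
                      to = tx[pairs[present, 2L]],
                      weight = 1, stringsAsFactors = FALSE)

  ## hubs: first taxa of each module, wired to a fixed module fraction
  hubs <- character(0)
  if (spec@hubsPerModule > 0L) {
    for (h in seq_len(nMod)) {
      members <- tx[mod == h]
      modHubs <- members[seq_len(min(spec@hubsPerModule, per))]
      hubs <- c(hubs, modHubs)
      for (hub in modHubs) {
        others <- setdiff(members, modHubs)
        nWire <- round(spec@hubFraction * length(others))
        wired <- sample(others, nWire)
        if (length(wired))
          edges <- rbind(edges,
                         data.frame(from = hub, to = wired, weight = 1,
                                    stringsAsFactors = FALSE))
      }
    }
  }
  net <- AssociationNetwork(edges, taxa = tx, weighted = FALSE)

  ## binary function table
  layers <- layerNames(spec@config)
  F <- matrix(0, n, length(layers), dimnames = list(tx, layers))
  for (j in seq_along(layers))
    F[, j] <- stats::rbinom(n, 1L, spec@functionProb[mod, j])

  ## condition-structured negative-binomial counts
  lab <- rep(spec@conditions, times = spec@samplesPerCondition)
  samples <- sprintf("sample_%03d", seq_along(lab))
  names(lab) <- samples
  taxonBase <- stats::rlnorm(n, meanlog = log(spec@baseMean) - 0.125,
                             sdlog = 0.5)
  mu <- taxonBase * spec@moduleMeans[mod, match(lab, spec@conditions),
                                     drop = FALSE]
  counts <- matrix(stats::rnbinom(n * length(lab), mu = mu,
                                  size = spec@dispersion),
                   nrow = n, dimnames = list(tx, samples))

  enriched <- which(apply(spec@moduleMeans, 1L, function(r)
    max(r) > min(r)))
  ## the functional module: highest beneficial-layer probability; its
  ## hub(s) are the planted functional hubs the scoring should surface
  posProb <- spec@functionProb[, spec@config@alpha > 0, drop = FALSE]
  funMod <- if (ncol(posProb)) which.max(rowMeans(posProb)) else 1L
  new("SyntheticCommunity", network = net, functions = FunctionTable(F),
      config = spec@config, abundance = counts, conditions = lab,
      groundTruth = list(modules = mod, hubs = hubs,
                         functionalModule = as.integer(funMod),
                         functionalHubs = hubs[hubs %in% tx[mod == funMod]],
                         moduleMeans = spec@moduleMeans,
                         enrichedModules = as.integer(enriched)),
      spec = spec)
}

#' Write a synthetic community as an input bundle
#'
#' Writes everything a scoring run needs as plain text: `network.tsv`
#' (edge list), `functions.tsv`, `layers.yml`, `abundance.tsv`,
#' `conditions.tsv`, and the planted ground truth as
#' `ground_truth.json`.
#'
#' @param community a [SyntheticCommunity-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCommunityBundle <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNetwork(community@network, file.path(dir, "network.tsv"),
               format = "edge_list")
  writeFunctionTable(community@functions, file.path(dir, "functions.tsv"))
  writeLayerConfig(community@config, file.path(dir, "layers.yml"))
  writeAbundanceTable(community@abundance, file.path(dir, "abundance.tsv"))
  writeConditionLabels(community@conditions,
                       file.path(dir, "conditions.tsv"))
  gt <- community@groundTruth
  jsonlite::write_json(
    list(modules = as.list(gt$modules), hubs = gt$hubs,
         moduleMeans = gt$moduleMeans,
         enrichedModules = gt$enrichedModules,
         seed = community@spec@seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
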