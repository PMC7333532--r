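test_that("z mapping is exact and rejects non-binary sums", {
  expect_equal(zValue(0, beta = 2), 0)
  expect_equal(zValue(1, beta = 2), 1)
  expect_equal(zValue(2, beta = 2), 2)
  expect_equal(zValue(2, beta = 0.5), 0.5)
  expect_error(zValue(3, beta = 1), "\\{0, 1, 2\\}")
})

test_that("TP matches closed forms on the three-taxon path and star", {
  net <- pathNetwork()
  ft <- function(fa, fc) FunctionTable(
    matrix(c(fa, 0, fc), ncol = 1, dimnames = list(c("a", "b", "c"), "L1")))
  cfg <- LayerConfig(alpha = c(L1 = 1), beta = 2, gamma = 0)
  expect_equal(scoreTP(net, ft(1, 1), cfg)[["b"]], 2)  # z(2) = beta = 2
  expect_equal(scoreTP(net, ft(1, 0), cfg)[["b"]], 1)  # z(1) = 1

  star <- AssociationNetwork(data.frame(from = "x",
                                        to = c("l1", "l2", "l3")))
  allOn <- FunctionTable(matrix(1, 4, 1,
                                dimnames = list(taxa(star), "L1")))
  cfgStar <- LayerConfig(alpha = c(L1 = 2), beta = 3, gamma = 0)
  expect_equal(scoreTP(star, allOn, cfgStar)[["x"]], 18)  # 3 pairs x 2*3
})

test_that("TPB applies the balance penalty per pair", {
  net <- pathNetwork()
  cfg <- LayerConfig(alpha = c(L1 = 1), beta = 2, gamma = 1, delta = 0)
  lopsided <- FunctionTable(matrix(c(1, 0, 0), ncol = 1,
                                   dimnames = list(c("a", "b", "c"), "L1")))
  expect_equal(scoreTPB(net, lopsided, cfg)[["b"]], 0)  # full penalty
  even <- FunctionTable(matrix(c(1, 0, 1), ncol = 1,
                               dimnames = list(c("a", "b", "c"), "L1")))
  expect_equal(scoreTPB(net, even, cfg)[["b"]], 2)      # no penalty

  ## two layers held by opposite endpoints cancel in the balance sum
  twoLayer <- FunctionTable(matrix(c(1, 0, 0, 0, 0, 1), ncol = 2,
                                   dimnames = list(c("a", "b", "c"),
                                                   c("L1", "L2"))))
  cfg2 <- LayerConfig(alpha = c(L1 = 1, L2 = 1), beta = c(1, 1),
                      gamma = 1, delta = 0)
  expect_equal(scoreTPB(net, twoLayer, cfg2)[["b"]], 2)
})

test_that("C_func combines balanced beneficial and raw detrimental terms", {
  net <- pathNetwork()
  both <- FunctionTable(matrix(c(1, 0, 1, 1, 0, 1), ncol = 2,
                               dimnames = list(c("a", "b", "c"),
                                               c("good", "bad"))))
  cfg <- LayerConfig(alpha = c(good = 1, bad = -1), beta = c(2, 1),
                     gamma = 1, delta = 0)
  expect_equal(scoreCfunc(net, both, cfg)[["b"]], 1)  # 2 + (-1)

  none <- FunctionTable(matrix(0, 3, 2,
                               dimnames = list(c("a", "b", "c"),
                                               c("good", "bad"))))
  expect_equal(unname(scoreCfunc(net, none, cfg)), c(0, 0, 0))
})

test_that("all-layer balance with non-positive denominator is an error", {
  net <- pathNetwork()
  ft <- FunctionTable(matrix(c(1, 0, 1, 1, 0, 1), ncol = 2,
                             dimnames = list(c("a", "b", "c"),
                                             c("good", "bad"))))
  cfg <- LayerConfig(alpha = c(good = 1, bad = -1), beta = c(1, 1),
                     gamma = 1, delta = 0)   # sum(D) = 0
  expect_error(scoreTPB(net, ft, cfg), "denominator")
  ## the combined table keeps C_func and degrades TPB to NA
  expect_warning(st <- functionalCoreness(net, ft, cfg), "TPB set to NA")
  expect_true(all(is.na(as.data.frame(st)$TPB)))
  expect_true(all(is.finite(as.data.frame(st)$C_func)))
})

test_that("with only detrimental layers the balance factor is inert", {
  net <- pathNetwork()
  ft <- FunctionTable(matrix(c(1, 0, 1), ncol = 1,
                             dimnames = list(c("a", "b", "c"), "bad")))
  cfg <- LayerConfig(alpha = c(bad = -1), beta = 1, gamma = 1, delta = 0)
  expect_equal(scoreCfunc(net, ft, cfg)[["b"]], -1)  # z(2) = beta = 1
})

test_that("degenerate parameters reduce C_func to betweenness exactly", {
  for (s in 1:8) {
    net <- randomNetwork(sample(6:14, 1), p = runif(1, 0.2, 0.6),
                         seed = 300 + s)
    allOn <- FunctionTable(matrix(1, nTaxa(net), 1,
                                  dimnames = list(taxa(net), "L1")))
    cfg <- LayerConfig(alpha = c(L1 = 1), beta = 1, gamma = 0)
    st <- as.data.frame(functionalCoreness(net, allOn, cfg))
    expect_equal(st$C_func, st$T, tolerance = 1e-12)
    expect_equal(st$TP, st$T, tolerance = 1e-12)
    expect_equal(st$TPB, st$T, tolerance = 1e-12)
  }
})

test_that("gamma = 0 makes TPB identical to TP", {
  for (s in 1:6) {
    net <- randomNetwork(10, p = 0.4, seed = 400 + s)
    ft <- randomFunctionTable(net, 3, seed = s)
    cfgBase <- randomConfig(3, seed = s, signed = FALSE)
    cfg <- LayerConfig(alpha = alphaWeights(cfgBase),
                       beta = betaWeights(cfgBase), gamma = 0,
                       delta = balanceDelta(cfgBase))
    expect_equal(scoreTPB(net, ft, cfg), scoreTP(net, ft, cfg),
                 tolerance = 1e-12)
  }
})

test_that("TP is linear and the beneficial C_func term homogeneous in alpha", {
  net <- randomNetwork(10, p = 0.4, seed = 500)
  ft <- randomFunctionTable(net, 3, seed = 5)
  alpha <- c(L1 = 0.8, L2 = 1.5, L3 = 0.3)
  beta <- c(2, 1, 0.5)
  for (c0 in c(0.5, 2, 7)) {
    cfg1 <- LayerConfig(alpha = alpha, beta = beta, gamma = 1, delta = 0)
    cfg2 <- LayerConfig(alpha = c0 * alpha, beta = beta, gamma = 1,
                        delta = 0)
    expect_equal(scoreTP(net, ft, cfg2), c0 * scoreTP(net, ft, cfg1),
                 tolerance = 1e-9)
    ## all-positive alpha: C_func is the balanced beneficial term, and with
    ## delta = 0 the balance factor is scale-invariant
    expect_equal(scoreCfunc(net, ft, cfg2),
                 c0 * scoreCfunc(net, ft, cfg1), tolerance = 1e-9)
  }
})

test_that("raising beta never decreases TP for a positive-weight layer", {
  net <- randomNetwork(9, p = 0.45, seed = 600)
  ft <- randomFunctionTable(net, 2, seed = 6)
  base <- scoreTP(net, ft, LayerConfig(alpha = c(L1 = 1, L2 = 0.5),
                                       beta = c(1, 1), gamma = 0))
  for (b in c(1.5, 2, 4)) {
    up <- scoreTP(net, ft, LayerConfig(alpha = c(L1 = 1, L2 = 0.5),
                                       beta = c(b, 1), gamma = 0))
    expect_true(all(up - base >= -1e-12))
  }
})

test_that("the per-pair balance factor stays within [1 - gamma, 1]", {
  ## scored on single-edge pairs so each factor is observable directly
  for (s in 1:5) {
    gamma <- runif(1)
    cfg <- LayerConfig(alpha = c(L1 = 1, L2 = 2), beta = c(1, 1),
                       gamma = gamma, delta = runif(1))
    net <- pathNetwork()
    for (fa in 0:1) for (fc in 0:1) {
      ft <- FunctionTable(matrix(c(fa, 0, fc, 1, 0, 0), ncol = 2,
                                 dimnames = list(c("a", "b", "c"),
                                                 c("L1", "L2"))))
      tp <- scoreTP(net, ft, cfg)[["b"]]
      tpb <- scoreTPB(net, ft, cfg)[["b"]]
      if (tp > 0) {
        expect_gte(tpb / tp, 1 - gamma - 1e-12)
        expect_lte(tpb / tp, 1 + 1e-12)
      }
    }
  }
})

test_that("fast scores equal the exhaustive oracle on random graphs", {
  for (s in 1:25) {
    net <- randomNetwork(sample(5:10, 1), p = runif(1, 0.25, 0.7),
                         seed = 700 + s)
    nL <- sample(1:4, 1)
    ft <- randomFunctionTable(net, nL, seed = s)
    cfg <- randomConfig(nL, seed = s)
    o <- corenessOracle(net, ft, cfg)
    expect_equal(scoreCfunc(net, ft, cfg), o$C_func, tolerance = 1e-9)
    expect_equal(scoreTP(net, ft, cfg), o$TP, tolerance = 1e-9)
    expect_equal(betweennessScores(net), o$T, tolerance = 1e-9)
    if (!anyNA(o$TPB))
      expect_equal(scoreTPB(net, ft, cfg), o$TPB, tolerance = 1e-9)
  }
})

test_that("oracle handles edgeless graphs and refuses large ones", {
  lone <- AssociationNetwork(data.frame(from = character(),
                                        to = character(),
                                        weight = numeric()),
                             taxa = c("a", "b", "c"))
  ft <- FunctionTable(matrix(1, 3, 1, dimnames = list(c("a", "b", "c"),
                                                      "L1")))
  cfg <- LayerConfig(alpha = c(L1 = 1))
  o <- corenessOracle(lone, ft, cfg)
  expect_equal(unname(o$C_func), c(0, 0, 0))

  big <- randomNetwork(13, p = 0.3, seed = 1)
  ftb <- randomFunctionTable(big, 1, seed = 1)
  expect_error(corenessOracle(big, ftb, LayerConfig(alpha = c(L1 = 1))),
               "refuses")
})

test_that("functionalCoreness attaches module ids and sorts", {
  com <- generateCommunity(communitySpec(nModules = 2, taxaPerModule = 8,
                                         pIn = 0.6, pOut = 0.02,
                                         seed = 12))
  mods <- detectModules(com@network)
  ## default layers have alpha = (1, -1), delta = 0 -> TPB NA warning
  st <- suppressWarnings(
    functionalCoreness(com@network, com@functions, com@config,
                       modules = mods))
  df <- as.data.frame(st)
  expect_setequal(df$taxon, taxa(com@network))
  expect_false(anyNA(df$module))
  expect_true(!is.unsorted(df$module))
})
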