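toyMatrix <- function(counts) {
  matrix(counts, nrow = 1,
         dimnames = list("t1", paste0("s", seq_along(counts))))
}
toyLabels <- function(lab) {
  stats::setNames(lab, paste0("s", seq_along(lab)))
}

test_that("the exhaustive null reproduces the hand-computed toy z-score", {
  ## counts (10,10,0,0) over labels (H,H,U,U): 6 distinct assignments,
  ## null mean 5, population SD sqrt(50/6), s(H) = sqrt(3)
  sp <- specificityScores(toyMatrix(c(10, 10, 0, 0)),
                          toyLabels(c("H", "H", "U", "U")))
  expect_true(sp@exhaustive)
  expect_equal(sp@nPermutations, 6L)
  df <- as.data.frame(sp)
  expect_equal(df$s[df$condition == "H"], sqrt(3), tolerance = 1e-12)
  expect_equal(df$null_mean[df$condition == "H"], 5)
  expect_equal(df$null_sd[df$condition == "H"], sqrt(50 / 6),
               tolerance = 1e-12)

  ## reversed counts flip the sign
  rev <- as.data.frame(specificityScores(
    toyMatrix(c(0, 0, 10, 10)), toyLabels(c("H", "H", "U", "U"))))
  expect_equal(rev$s[rev$condition == "H"], -sqrt(3), tolerance = 1e-12)
})

test_that("a constant taxon scores 0 under the degenerate null", {
  df <- as.data.frame(specificityScores(
    toyMatrix(c(5, 5, 5, 5)), toyLabels(c("H", "H", "U", "U"))))
  expect_equal(df$s, c(0, 0))
})

test_that("exhaustive scores match an independent permutation oracle", {
  set.seed(13)
  for (rep in 1:4) {
    counts <- rpois(6, 20) * rbinom(6, 1, 0.7)
    lab <- sample(c("A", "A", "A", "B", "B", "B"))
    df <- as.data.frame(specificityScores(toyMatrix(counts),
                                          toyLabels(lab),
                                          exhaustive = "always"))
    for (cond in c("A", "B")) {
      expect_equal(df$s[df$condition == cond],
                   exhaustiveSpecificityOracle(counts, lab, cond),
                   tolerance = 1e-12)
    }
  }
})

test_that("with two equal-sized conditions the z-scores are antisymmetric", {
  set.seed(21)
  m <- matrix(rnbinom(80, mu = 30, size = 2), nrow = 10,
              dimnames = list(sprintf("t%02d", 1:10), paste0("s", 1:8)))
  lab <- toyLabels(rep(c("H", "U"), each = 4))
  df <- as.data.frame(specificityScores(m, lab, exhaustive = "always"))
  wide <- reshape(df[, c("taxon", "condition", "s")], idvar = "taxon",
                  timevar = "condition", direction = "wide")
  expect_equal(wide$s.H, -wide$s.U, tolerance = 1e-9)
})

test_that("Monte-Carlo scores converge to the exhaustive value", {
  set.seed(33)
  counts <- c(25, 18, 30, 2, 0, 5, 1, 3)
  lab <- c("A", "A", "A", "A", "B", "B", "B", "B")
  ex <- as.data.frame(specificityScores(toyMatrix(counts),
                                        toyLabels(lab),
                                        exhaustive = "always"))
  mc <- as.data.frame(specificityScores(toyMatrix(counts),
                                        toyLabels(lab), R = 20000,
                                        seed = 9, exhaustive = "never"))
  expect_lt(max(abs(mc$s - ex$s)), 0.05)
})

test_that("a fixed seed makes Monte-Carlo results bitwise identical", {
  com <- generateCommunity(communitySpec(nModules = 2, taxaPerModule = 6,
                                         samplesPerCondition = 6,
                                         seed = 4))
  a <- specificityScores(com@abundance, com@conditions, R = 200, seed = 11,
                         exhaustive = "never")
  b <- specificityScores(com@abundance, com@conditions, R = 200, seed = 11,
                         exhaustive = "never")
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("permuting sample order (labels carried along) changes nothing", {
  com <- generateCommunity(communitySpec(nModules = 2, taxaPerModule = 6,
                                         samplesPerCondition = 4,
                                         seed = 6))
  m <- com@abundance
  lab <- com@conditions
  perm <- sample(ncol(m))
  a <- as.data.frame(specificityScores(m, lab, exhaustive = "always"))
  b <- as.data.frame(specificityScores(m[, perm], lab[perm],
                                       exhaustive = "always"))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the occurrence statistic counts presence instead of reads", {
  m <- toyMatrix(c(7, 3, 0, 0))
  lab <- toyLabels(c("H", "H", "U", "U"))
  sp <- specificityScores(m, lab, statistic = "occurrence")
  df <- as.data.frame(sp)
  expect_equal(df$n_original[df$condition == "H"], 2)  # 2 samples occupied
  expect_equal(df$s[df$condition == "H"], sqrt(3), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  m <- toyMatrix(c(1, 2, 3, 4))
  expect_error(specificityScores(m, toyLabels(rep("A", 4))),
               "at least 2 conditions")
  expect_error(specificityScores(m, toyLabels(c("A", "A", "A", "B"))[1:3]),
               "without a condition label")
  expect_error(specificityScores(m, toyLabels(c("A", "A", "B", "B")),
                                 R = 0, exhaustive = "never"), "R must be")
})

test_that("module condition scores average member specificity", {
  sp <- new("SpecificityTable",
            scores = data.frame(
              taxon = rep(c("t1", "t2", "t3"), each = 2),
              condition = rep(c("A", "B"), 3),
              s = c(1, -1, 3, -3, 0.5, -0.5),
              n_original = 0, null_mean = 0, null_sd = 1),
            nPermutations = 6L, exhaustive = TRUE,
            statistic = "mean_reads", sdType = "population")
  mods <- new("ModuleAssignment",
              membership = c(t1 = 1L, t2 = 1L, t3 = 2L),
              modularity = 0.5, method = "greedy")
  out <- moduleConditionScores(sp, mods)
  expect_equal(out$s_module[out$module == 1 & out$condition == "A"], 2)
  expect_equal(out$size[out$module == 1][1], 2L)
  ## singleton module equals its member
  expect_equal(out$s_module[out$module == 2 & out$condition == "B"], -0.5)

  missing <- new("ModuleAssignment",
                 membership = c(t1 = 1L, zz = 2L),
                 modularity = 0, method = "greedy")
  expect_error(moduleConditionScores(sp, missing), "zz")
})

test_that("a random module's score equals an independent hand sum", {
  set.seed(44)
  n <- 6
  sdf <- data.frame(taxon = rep(sprintf("t%d", 1:n), each = 2),
                    condition = rep(c("A", "B"), n),
                    s = round(rnorm(2 * n), 3),
                    n_original = 0, null_mean = 0, null_sd = 1)
  sp <- new("SpecificityTable", scores = sdf, nPermutations = 10L,
            exhaustive = FALSE, statistic = "mean_reads",
            sdType = "population")
  mods <- new("ModuleAssignment",
              membership = stats::setNames(rep(1L, n), sprintf("t%d", 1:n)),
              modularity = 0, method = "greedy")
  out <- moduleConditionScores(sp, mods)
  byHand <- sum(sdf$s[sdf$condition == "A"]) / n
  expect_equal(out$s_module[out$condition == "A"], byHand,
               tolerance = 1e-12)
})

test_that("SummarizedExperiment input matches the matrix route", {
  com <- generateCommunity(communitySpec(nModules = 2, taxaPerModule = 5,
                                         samplesPerCondition = 4,
                                         seed = 10))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = com@abundance),
    colData = S4Vectors::DataFrame(condition = unname(com@conditions),
                                   row.names = names(com@conditions)))
  a <- as.data.frame(specificityScores(se, conditionCol = "condition",
                                       exhaustive = "always"))
  b <- as.data.frame(specificityScores(com@abundance, com@conditions,
                                       exhaustive = "always"))
  expect_equal(a, b, tolerance = 1e-12)
})
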