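## distinct assignments of a label multiset: n! / prod(counts!)
.nDistinctAssignments <- function(labels) {
  counts <- table(labels)
  exp(lfactorial(length(labels)) - sum(lfactorial(counts)))
}

## all distinct permutations of a label multiset, one per column
.multisetPermutations <- function(labels) {
  rec <- function(counts) {
    if (sum(counts) == 0L)
      return(matrix(character(0), nrow = 0, ncol = 1))
    cols <- list()
    for (v in names(counts)[counts > 0L]) {
      c2 <- counts
      c2[v] <- c2[v] - 1L
      sub <- rec(c2)
      cols[[v]] <- rbind(matrix(v, nrow = 1, ncol = ncol(sub)), sub)
    }
    do.call(cbind, cols)
  }
  counts <- table(labels)
  rec(stats::setNames(as.integer(counts), names(counts)))
}

## per-condition statistic for one label assignment:
## mean_reads -> mean count over the condition's samples;
## occurrence -> number of the condition's samples with count > 0
.conditionStatistic <- function(X, assign, conditions, statistic) {
  vapply(conditions, function(j) {
    cols <- assign == j
    if (statistic == "mean_reads") rowMeans(X[, cols, drop = FALSE])
    else rowSums(X[, cols, drop = FALSE] > 0)
  }, numeric(nrow(X)))
}

#' @describeIn specificityScores matrix method.
#'
#' For each taxon i and condition j the observed statistic (mean read
#' count of i over the condition-j samples, or the number of condition-j
#' samples in which i occurs) is compared with its null distribution under
#' random reassignment of the sample condition labels:
#' `s(i, j) = (observed - mean(null)) / SD(null)`. The null is either the
#' exhaustive set of distinct label assignments (automatic when there are
#' at most `R` of them, the original assignment included) or `R` seeded
#' random permutations of the label vector. A degenerate null
#' (`SD = 0`, e.g. a taxon with identical counts in every sample) yields
#' `s = 0`: such a taxon carries no condition signal.
#'
#' @param abundance taxa x samples count matrix (rownames, colnames
#'   required).
#' @param conditions named character vector, sample -> condition label;
#'   every sample needs exactly one label and every condition at least one
#'   sample.
#' @param R number of random permutations in Monte-Carlo mode (and the
#'   cutoff below which the exhaustive null is used); default 10000.
#' @param seed integer seed for the Monte-Carlo null; the result is
#'   bitwise reproducible given a seed.
#' @param exhaustive `"auto"` (exhaustive when feasible), `"always"`, or
#'   `"never"`.
#' @param statistic `"mean_reads"` (default) or `"occurrence"`.
#' @param sdType `"population"` (default; the null set is the full
#'   reference distribution) or `"sample"`.
#' @export
setMethod("specificityScores", "matrix",
function(abundance, conditions, R = 10000L, seed = NULL,
         exhaustive = c("auto", "always", "never"),
         statistic = c("mean_reads", "occurrence"),
         sdType = c("population", "sample")) {
  exhaustive <- match.arg(exhaustive)
  statistic <- match.arg(statistic)
  sdType <- match.arg(sdType)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs taxon rownames and sample colnames")
  if (any(abundance < 0)) stop("abundance must be non-negative")
  samples <- colnames(abundance)
  missing <- setdiff(samples, names(conditions))
  if (length(missing))
    stop("samples without a condition label: ",
         paste(missing, collapse = ", "))
  lab <- as.character(conditions[samples])
  conds <- sort(unique(lab))
  if (length(conds) < 2L)
    stop("specificity needs at least 2 conditions")
  if (any(table(lab) < 1L)) stop("every condition needs >= 1 sample")
  if (exhaustive != "always") {
    if (length(R) != 1L || is.na(R) || R < 1)
      stop("R must be a single integer >= 1")
    R <- as.integer(R)
  }

  X <- if (statistic == "mean_reads") abundance else (abundance > 0) * 1
  nDistinct <- .nDistinctAssignments(lab)
  useExhaustive <- exhaustive == "always" ||
    (exhaustive == "auto" && nDistinct <= R)

  observed <- .conditionStatistic(X, lab, conds, statistic)
  if (useExhaustive) {
    assigns <- .multisetPermutations(lab)
  } else {
    if (!is.null(seed)) set.seed(seed)
    assigns <- vapply(seq_len(R), function(r) sample(lab),
                      character(length(lab)))
  }
  nNull <- ncol(assigns)
  nullArr <- array(0, dim = c(nrow(X), length(conds), nNull))
  for (r in seq_len(nNull))
    nullArr[, , r] <- .conditionStatistic(X, assigns[, r], conds, statistic)
  nullMean <- apply(nullArr, c(1, 2), mean)
  nullSd <- sqrt(apply(nullArr, c(1, 2), function(v) {
    ss <- sum((v - mean(v))^2)
    ss / (if (sdType == "population") length(v) else max(length(v) - 1L, 1L))
  }))
  z <- (observed - nullMean) / nullSd
  ## SD = 0 => no condition signal
  z[nullSd <= 1e-12 * (1 + abs(nullMean))] <- 0

  df <- data.frame(
    taxon = rep(rownames(X), times = length(conds)),
    condition = rep(conds, each = nrow(X)),
    s = as.vector(z),
    n_original = as.vector(observed),
    null_mean = as.vector(nullMean),
    null_sd = as.vector(nullSd),
    stringsAsFactors = FALSE)
  df <- df[order(df$taxon, df$condition), , drop = FALSE]
  rownames(df) <- NULL
  new("SpecificityTable", scores = df, nPermutations = as.integer(nNull),
      exhaustive = useExhaustive, statistic = statistic, sdType = sdType)
})

#' @describeIn specificityScores SummarizedExperiment method: uses the
#'   first assay as counts and a colData column as the condition label.
#' @param conditionCol name of the colData column holding the condition
#'   (SummarizedExperiment method).
#' @export
setMethod("specificityScores", "SummarizedExperiment",
function(abundance, conditionCol = "condition", ...) {
  cd <- SummarizedExperiment::colData(abundance)
  if (!conditionCol %in% colnames(cd))
    stop("colData has no column '", conditionCol, "'")
  m <- as.matrix(SummarizedExperiment::assay(abundance, 1L))
  conds <- stats::setNames(as.character(cd[[conditionCol]]), colnames(m))
  specificityScores(m, conditions = conds, ...)
})

#' Module condition scores
#'
#' Mean member specificity per module and condition:
#' `s_module(h, j) = sum_{i in module h} s(i, j) / |module h|`. A
#' singleton module's score equals its member's.
#'
#' @param spec a [SpecificityTable-class].
#' @param modules a [ModuleAssignment-class]; every module member must
#'   have specificity scores.
#' @return data.frame with columns `module`, `condition`, `s_module`,
#'   `size`.
#' @export
moduleConditionScores <- function(spec, modules) {
  memb <- moduleMembership(modules)
  if (length(memb) == 0L) stop("empty module assignment")
  df <- spec@scores
  missing <- setdiff(names(memb), df$taxon)
  if (length(missing))
    stop("no specificity scores for module member(s): ",
         paste(missing, collapse = ", "))
  df <- df[df$taxon %in% names(memb), , drop = FALSE]
  df$module <- memb[df$taxon]
  agg <- stats::aggregate(s ~ module + condition, data = df, FUN = mean)
  sizes <- table(memb)
  out <- data.frame(module = as.integer(agg$module),
                    condition = agg$condition,
                    s_module = agg$s,
                    size = as.integer(sizes[as.character(agg$module)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$module, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
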